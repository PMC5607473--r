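#' Strand-orientation artifact metric (FoxoG)
#'
#' Quantifies the read-pair orientation skew of alt-supporting reads that
#' is characteristic of 8-oxoguanine (oxoG) damage.  The metric is 0 for
#' any substitution other than C>A (or its reverse-complement G>T) and for
#' indels.  For C>A it is the fraction of alt-supporting read pairs in the
#' artifact-prone orientation, F2R1; for G>T the orientations swap and
#' F1R2 is artifact-prone.  A zero orientation denominator yields 0.
#'
#' @param ref,alt site alleles (vectorized).
#' @param f1r2_alt,f2r1_alt alt-supporting read-pair counts by orientation.
#' @return numeric vector in [0,1].
#' @examples
#' foxog_metric("C", "A", f1r2_alt = 0, f2r1_alt = 10)  # 1: pure artifact
#' foxog_metric("C", "A", f1r2_alt = 5, f2r1_alt = 5)   # 0.5: balanced
#' foxog_metric("A", "G", f1r2_alt = 0, f2r1_alt = 10)  # 0: not C>A
#' @export
foxog_metric <- function(ref, alt, f1r2_alt, f2r1_alt) {
  n <- max(length(ref), length(alt), length(f1r2_alt), length(f2r1_alt))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  f1 <- rep_len(f1r2_alt, n); f2 <- rep_len(f2r1_alt, n)
  is_ca <- nchar(ref) == 1L & nchar(alt) == 1L & ref == "C" & alt == "A"
  is_gt <- nchar(ref) == 1L & nchar(alt) == 1L & ref == "G" & alt == "T"
  tot <- f1 + f2
  out <- numeric(n)
  ok <- tot > 0
  out[is_ca & ok] <- (f2 / tot)[is_ca & ok]
  out[is_gt & ok] <- (f1 / tot)[is_gt & ok]
  out
}

offspring_carrier_status <- function(gt, ref_reads, alt_reads, depth,
                                     config = run_config()) {
  ab <- allelic_balance(ref_reads, alt_reads)
  missing <- gt == "missing" | is.na(gt) | depth < config$offspring_min_depth
  altcall <- gt_carries_alt(gt)
  low_support <- altcall & (alt_reads < config$offspring_min_alt |
                              is.na(ab) | ab < config$offspring_min_ab)
  status <- ifelse(missing | low_support, NA, altcall)
  status
}

#' Transmission label of a DNM candidate in a three-generation family
#'
#' Checks whether segregation of the candidate allele to the proband's
#' offspring is consistent with haplotype transmission.  Offspring calls
#' are treated as missing below 10 reads of depth, and alt-supporting
#' calls additionally require at least 2 alt reads and allelic balance of
#' at least 0.1.  The label is \code{"unevaluable"} unless at least two
#' non-missing offspring carry distinct proband haplotypes;
#' \code{"consistent"} when one proband haplotype exactly 2-colors the
#' carriers (every non-missing offspring on that haplotype carries the
#' allele and every offspring on the other does not); otherwise
#' \code{"inconsistent"}.  At X sites a male offspring carrying the allele
#' without being homozygous-alt forces \code{"inconsistent"}.
#'
#' @param offspring data.frame with one row per offspring of the proband:
#'   \code{id}, \code{sex}, \code{hap} (proband haplotype inherited at the
#'   site, \code{"paternal"}/\code{"maternal"}, \code{NA} when
#'   unassigned), \code{gt}, \code{ref_reads}, \code{alt_reads},
#'   \code{depth}.
#' @param x_site logical: is the candidate on the X chromosome?
#' @param config a \code{dnm_config}.
#' @return list with \code{label} (one of \code{"consistent"},
#'   \code{"inconsistent"}, \code{"unevaluable"}) and
#'   \code{n_offspring_informative}.
#' @export
assess_transmission <- function(offspring, x_site = FALSE,
                                config = run_config()) {
  if (!nrow(offspring))
    return(list(label = "unevaluable", n_offspring_informative = 0L))
  status <- offspring_carrier_status(offspring$gt, offspring$ref_reads,
                                     offspring$alt_reads, offspring$depth,
                                     config)
  informative <- !is.na(status) & !is.na(offspring$hap)
  n_inf <- sum(informative)
  haps <- offspring$hap[informative]
  carry <- status[informative]
  if (n_inf < config$min_offspring || length(unique(haps)) < 2L)
    return(list(label = "unevaluable", n_offspring_informative = n_inf))
  if (x_site) {
    male_het <- informative & status & offspring$sex == "male" &
      offspring$gt != "hom_alt"
    if (any(male_het, na.rm = TRUE))
      return(list(label = "inconsistent", n_offspring_informative = n_inf))
  }
  carrier_haps <- unique(haps[carry])
  noncarrier_haps <- unique(haps[!carry])
  consistent <- length(carrier_haps) == 1L &&
    !(carrier_haps %in% noncarrier_haps)
  list(label = if (consistent) "consistent" else "inconsistent",
       n_offspring_informative = n_inf)
}

#' Label all candidates of three-generation probands by transmission
#'
#' @param ds a \code{dnm_dataset} (uses pedigree, evidence and the
#'   per-offspring inheritance table).
#' @param cands candidate data.frame from \code{\link{extract_candidates}}.
#' @param config a \code{dnm_config}.
#' @return data.frame \code{proband}, \code{site_id}, \code{label},
#'   \code{n_offspring_informative}, one row per candidate whose proband
#'   heads a three-generation family.
#' @export
transmission_labels <- function(ds, cands, config = run_config()) {
  fams <- find_three_generation_families(ds$pedigree, config$min_offspring)
  if (!length(fams) || !nrow(cands))
    return(data.frame(proband = character(0), site_id = character(0),
                      label = character(0),
                      n_offspring_informative = integer(0),
                      stringsAsFactors = FALSE))
  fam_of <- stats::setNames(fams, vapply(fams, `[[`, "", "proband"))
  sub <- cands[cands$proband %in% names(fam_of), , drop = FALSE]
  out <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    fam <- fam_of[[sub$proband[i]]]
    off <- offspring_site_table(ds, fam$offspring, sub$site_id[i])
    res <- assess_transmission(off, x_site = is_x_chrom(sub$chrom[i]),
                               config = config)
    out[[i]] <- data.frame(proband = sub$proband[i], site_id = sub$site_id[i],
                           label = res$label,
                           n_offspring_informative = res$n_offspring_informative,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# offspring rows (hap + evidence) for one site; absent evidence -> missing,
# absent inheritance -> hap NA
offspring_site_table <- function(ds, offspring_ids, site, seg_rules = FALSE,
                                 config = run_config()) {
  ped <- ds$pedigree
  sex <- ped$records$sex; names(sex) <- ped$records$id
  inh <- ds$inheritance
  inh <- inh[inh$site_id == site & inh$offspring %in% offspring_ids, , drop = FALSE]
  ev <- ds$evidence
  ev <- ev[ev$site_id == site & ev$id %in% offspring_ids, , drop = FALSE]
  hap <- inh$proband_hap[match(offspring_ids, inh$offspring)]
  if (seg_rules && nrow(inh)) {
    m <- match(offspring_ids, inh$offspring)
    ok <- !is.na(m) & inh$seg_cm[m] >= config$min_segment_cm &
      inh$seg_markers[m] >= config$min_segment_markers
    hap[!ok] <- NA_character_
  }
  j <- match(offspring_ids, ev$id)
  data.frame(
    id = offspring_ids,
    sex = unname(sex[offspring_ids]),
    hap = hap,
    gt = ifelse(is.na(j), "missing", ev$gt[j]),
    ref_reads = ifelse(is.na(j), 0L, ev$ref_reads[j]),
    alt_reads = ifelse(is.na(j), 0L, ev$alt_reads[j]),
    depth = ifelse(is.na(j), 0L, ev$depth[j]),
    stringsAsFactors = FALSE)
}
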