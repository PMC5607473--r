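#' Allelic balance
#'
#' Fraction of reads supporting the alternative allele out of the reads
#' supporting the reference and alternative alleles combined.  Undefined
#' (\code{NA}) when no informative reads are present.
#'
#' @param ref_reads,alt_reads non-negative read counts (vectorized).
#' @return numeric vector of fractions in [0,1], \code{NA} where
#'   \code{ref_reads + alt_reads == 0}.
#' @examples
#' allelic_balance(10, 10)   # 0.5
#' allelic_balance(17, 3)    # 0.15
#' @export
allelic_balance <- function(ref_reads, alt_reads) {
  if (any(ref_reads < 0 | alt_reads < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  tot <- ref_reads + alt_reads
  ifelse(tot > 0, alt_reads / tot, NA_real_)
}

gt_carries_alt <- function(gt) gt %in% c("het", "hom_alt")

#' Count possible and likely carriers beyond an excluded set
#'
#' Possible carriers are individuals (outside \code{excluded}) whose called
#' genotype contains the alternative allele.  Likely carriers additionally
#' satisfy depth strictly over 12, allelic-balance deviation from 0.5
#' strictly below 0.25, and genotype quality strictly over 20.
#'
#' @param site_evidence data.frame of evidence rows at one site (columns
#'   \code{id}, \code{gt}, \code{ref_reads}, \code{alt_reads}, \code{depth},
#'   \code{gq}).
#' @param excluded character vector of ids excused from the count
#'   (the descendants of the proband's parent pair).
#' @param config a \code{dnm_config}.
#' @return list with \code{n_possible}, \code{n_likely} and the id vectors
#'   \code{possible}, \code{likely}.
#' @export
classify_carriers <- function(site_evidence, excluded, config = run_config()) {
  ev <- site_evidence[gt_carries_alt(site_evidence$gt) &
                        !(site_evidence$id %in% excluded), , drop = FALSE]
  if (!nrow(ev))
    return(list(n_possible = 0L, n_likely = 0L,
                possible = character(0), likely = character(0)))
  ab <- allelic_balance(ev$ref_reads, ev$alt_reads)
  likely <- ev$depth > config$likely_min_depth &
    !is.na(ab) & abs(ab - 0.5) < config$likely_ab_dev &
    ev$gq > config$likely_min_gq
  list(n_possible = nrow(ev), n_likely = sum(likely),
       possible = ev$id, likely = ev$id[likely])
}

is_x_chrom <- function(chrom) chrom %in% c("X", "chrX")

#' Extract de novo mutation candidates from trio evidence
#'
#' Scans every trio (proband with both sequenced parents, mean coverage
#' strictly over 20x) and retains the variants satisfying all of:
#' \itemize{
#'   \item the proband carries the alternative allele (hom-alt calls with
#'     more than one reference-supporting read are rejected; at X sites a
#'     male proband is treated as hemizygous, so any alt call with more
#'     than one reference read is rejected);
#'   \item each parent has depth >= 12 (>= 6 for the father at X sites of
#'     male probands), at most one alt-supporting read, and allelic
#'     balance <= 0.05;
#'   \item proband depth >= 12 and allelic balance >= 0.15;
#'   \item at most 10 possible and 3 likely carriers beyond the
#'     descendants of the parent pair;
#'   \item mean soft-clipped fraction of reads covering the site <= 10%.
#' }
#' Candidates whose parental evidence is absent, or whose proband allelic
#' balance is undefined, are not evaluable and are counted in the
#' \code{"skipped"} attribute of the result.
#'
#' @param ds a \code{dnm_dataset} (see \code{\link{load_dataset}} /
#'   \code{\link{simulate_dataset}}).
#' @param config a \code{dnm_config}.
#' @param excluded_probands ids to skip (e.g. samples failing lane or
#'   contamination QC).
#' @return data.frame of candidates, one row per retained (proband, site):
#'   identifiers, site fields, proband evidence (\code{proband_ab},
#'   read/orientation counts, \code{softclip_frac}), and the carrier counts
#'   \code{n_possible_outside}, \code{n_likely_outside}.
#' @export
extract_candidates <- function(ds, config = run_config(),
                               excluded_probands = character(0)) {
  ped <- ds$pedigree
  trios <- find_trios(ped)
  cov <- ds$samples
  covered <- cov$id[!is.na(cov$mean_coverage) &
                      cov$mean_coverage > config$min_proband_coverage]
  trios <- trios[trios$proband %in% covered &
                   !(trios$proband %in% excluded_probands), , drop = FALSE]
  ev <- ds$evidence
  ev_by_site <- split(seq_len(nrow(ev)), ev$site_id)
  site_of <- ds$variants
  rownames(site_of) <- site_of$site_id
  sex <- ped$records$sex; names(sex) <- ped$records$id
  key <- paste(ev$site_id, ev$id, sep = "\r")
  row_of <- seq_len(nrow(ev)); names(row_of) <- key

  out <- list(); skipped <- 0L
  for (t in seq_len(nrow(trios))) {
    pid <- trios$proband[t]; fid <- trios$father[t]; mid <- trios$mother[t]
    excl <- descendants_of_pair(ped, fid, mid)
    prow <- ev[ev$id == pid & gt_carries_alt(ev$gt), , drop = FALSE]
    for (i in seq_len(nrow(prow))) {
      p <- prow[i, ]
      site <- site_of[p$site_id, ]
      x_male <- is_x_chrom(site$chrom) && identical(unname(sex[pid]), "male")
      pab <- allelic_balance(p$ref_reads, p$alt_reads)
      if (is.na(pab)) { skipped <- skipped + 1L; next }
      fe <- ev[row_of[paste(p$site_id, fid, sep = "\r")], , drop = FALSE]
      me <- ev[row_of[paste(p$site_id, mid, sep = "\r")], , drop = FALSE]
      if (!nrow(fe) || is.na(fe$id[1]) || !nrow(me) || is.na(me$id[1])) {
        skipped <- skipped + 1L; next
      }
      # proband genotype rules
      if (p$gt == "hom_alt" || x_male) {
        if (p$ref_reads > config$max_homalt_ref_reads) next
      }
      if (p$depth < config$min_proband_depth) next
      if (pab < config$min_proband_ab) next
      # parental rules
      f_min_depth <- if (x_male) config$min_parent_depth_x_father else
        config$min_parent_depth
      if (fe$depth < f_min_depth || me$depth < config$min_parent_depth) next
      if (fe$alt_reads > config$max_parent_alt ||
          me$alt_reads > config$max_parent_alt) next
      fab <- allelic_balance(fe$ref_reads, fe$alt_reads)
      mab <- allelic_balance(me$ref_reads, me$alt_reads)
      if (!is.na(fab) && fab > config$max_parent_ab) next
      if (!is.na(mab) && mab > config$max_parent_ab) next
      # site-level soft clipping (proband reads covering the candidate)
      if (p$softclip_frac > config$max_site_softclip) next
      # outside-carrier counts
      cc <- classify_carriers(ev[ev_by_site[[p$site_id]], , drop = FALSE],
                              excl, config)
      if (cc$n_possible > config$max_possible_carriers ||
          cc$n_likely > config$max_likely_carriers) next
      out[[length(out) + 1L]] <- data.frame(
        proband = pid, father = fid, mother = mid,
        site_id = p$site_id, chrom = site$chrom, pos = site$pos,
        ref = site$ref, alt = site$alt, is_snp = site$is_snp,
        gatk_pass = site$gatk_pass,
        proband_gt = p$gt, proband_depth = p$depth,
        proband_ref = p$ref_reads, proband_alt = p$alt_reads,
        proband_ab = pab,
        f1r2_alt = p$f1r2_alt, f2r1_alt = p$f2r1_alt,
        softclip_frac = p$softclip_frac,
        n_possible_outside = cc$n_possible,
        n_likely_outside = cc$n_likely,
        stringsAsFactors = FALSE)
    }
  }
  cands <- if (length(out)) do.call(rbind, out) else empty_candidates()
  cands <- cands[order(cands$proband, cands$site_id), , drop = FALSE]
  rownames(cands) <- NULL
  attr(cands, "skipped") <- skipped
  cands
}

empty_candidates <- function() {
  data.frame(proband = character(0), father = character(0),
             mother = character(0), site_id = character(0),
             chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), is_snp = logical(0), gatk_pass = logical(0),
             proband_gt = character(0), proband_depth = integer(0),
             proband_ref = integer(0), proband_alt = integer(0),
             proband_ab = numeric(0), f1r2_alt = integer(0),
             f2r1_alt = integer(0), softclip_frac = numeric(0),
             n_possible_outside = integer(0), n_likely_outside = integer(0),
             stringsAsFactors = FALSE)
}

#' Remove probands exceeding genome-wide quality bounds
#'
#' Probands with more than 10% average soft clipping per read, more than
#' 1.5% average N fraction in the read alignment, or more than 300 DNM
#' candidates are dropped together with all their candidates.
#'
#' @param cands candidate data.frame from \code{\link{extract_candidates}}.
#' @param sample_metrics data.frame with \code{id}, \code{mean_softclip},
#'   \code{mean_nfrac} (genome-wide per-proband averages).
#' @param config a \code{dnm_config}.
#' @return list with \code{candidates} (retained rows) and
#'   \code{excluded_probands} (data.frame id/reason).
#' @export
filter_probands <- function(cands, sample_metrics, config = run_config()) {
  counts <- table(cands$proband)
  probands <- unique(cands$proband)
  sm <- sample_metrics[match(probands, sample_metrics$id), , drop = FALSE]
  reasons <- character(0); bad <- character(0)
  for (i in seq_along(probands)) {
    pid <- probands[i]; why <- character(0)
    if (!is.na(sm$mean_softclip[i]) &&
        sm$mean_softclip[i] > config$proband_max_softclip)
      why <- c(why, "mean_softclip")
    if (!is.na(sm$mean_nfrac[i]) &&
        sm$mean_nfrac[i] > config$proband_max_nfrac)
      why <- c(why, "mean_nfrac")
    if (counts[[pid]] > config$proband_max_candidates)
      why <- c(why, "n_candidates")
    if (length(why)) { bad <- c(bad, pid); reasons <- c(reasons, paste(why, collapse = ",")) }
  }
  list(candidates = cands[!(cands$proband %in% bad), , drop = FALSE],
       excluded_probands = data.frame(id = bad, reason = reasons,
                                      stringsAsFactors = FALSE))
}
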