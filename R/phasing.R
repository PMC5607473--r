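phase_call <- function(origin, method, support = list()) {
  list(origin = origin, method = method, support = support)
}

#' Parent-of-origin phasing by three-generation haplotype sharing
#'
#' Each eligible offspring votes: a DNM-allele carrier on the proband's
#' paternal haplotype (or a non-carrier on the maternal haplotype)
#' supports a paternal origin, and symmetrically for maternal.  An
#' offspring is eligible only when the shared segment covering the site
#' spans at least 0.8 cM and 200 consecutive panel markers; its carrier
#' status follows the transmission-assay missingness rules.  Unanimous
#' votes give the origin; conflicting votes or no eligible voter give
#' \code{"unphased"}.
#'
#' @param offspring data.frame as for \code{\link{assess_transmission}},
#'   plus \code{seg_cm} and \code{seg_markers} for the shared segment
#'   covering the site.
#' @param config a \code{dnm_config}.
#' @return a phase call: list with \code{origin} (\code{"paternal"},
#'   \code{"maternal"} or \code{"unphased"}), \code{method =
#'   "three_gen"}, and per-origin vote counts in \code{support}.
#' @export
phase_by_three_gen <- function(offspring, config = run_config()) {
  if (!nrow(offspring))
    return(phase_call("unphased", "three_gen",
                      list(paternal = 0L, maternal = 0L)))
  status <- offspring_carrier_status(offspring$gt, offspring$ref_reads,
                                     offspring$alt_reads, offspring$depth,
                                     config)
  eligible <- !is.na(status) & !is.na(offspring$hap) &
    !is.na(offspring$seg_cm) & !is.na(offspring$seg_markers) &
    offspring$seg_cm >= config$min_segment_cm &
    offspring$seg_markers >= config$min_segment_markers
  hap <- offspring$hap[eligible]; carry <- status[eligible]
  # carrier on hap H -> origin H; non-carrier on hap H -> the other origin
  votes <- ifelse(carry, hap,
                  ifelse(hap == "paternal", "maternal", "paternal"))
  sup <- list(paternal = sum(votes == "paternal"),
              maternal = sum(votes == "maternal"))
  origin <- if (length(votes) && length(unique(votes)) == 1L)
    votes[[1L]] else "unphased"
  phase_call(origin, "three_gen", sup)
}

#' Parent-of-origin phasing by read-pair tracing
#'
#' Read pairs physically linking the DNM alt allele to phased marker
#' alleles of known parental origin assign the DNM to a parental
#' chromosome.  Only alt-allele-bearing pairs vote; pairs involving the
#' reference allele, pairs supporting three or more haplotypes
#' (\code{n_multi}) and markers of unresolved origin never contribute.
#' The DNM is phased only when one side has support of at least
#' \code{min_read_support} pairs and the other side has none.
#'
#' @param pair_counts data.frame of read-pair count rows for one DNM
#'   (proband, site): columns \code{marker_site}, \code{n_alt_allele1},
#'   \code{n_alt_allele2}, \code{n_ref_allele1}, \code{n_ref_allele2},
#'   \code{n_multi}.
#' @param marker_phase data.frame giving the proband's marker phase:
#'   columns \code{marker_site}, \code{paternal_allele} (1 or 2; allele
#'   on the proband's paternal chromosome).  Markers absent from this
#'   table are dropped as unresolved.
#' @param config a \code{dnm_config}.
#' @return a phase call with \code{method = "read_pair"} and the summed
#'   per-parent alt-linked pair counts in \code{support}.
#' @export
phase_by_read_tracing <- function(pair_counts, marker_phase,
                                  config = run_config()) {
  m <- match(pair_counts$marker_site, marker_phase$marker_site)
  keep <- !is.na(m)
  pc <- pair_counts[keep, , drop = FALSE]
  pat_allele <- marker_phase$paternal_allele[m[keep]]
  pat <- sum(ifelse(pat_allele == 1L, pc$n_alt_allele1, pc$n_alt_allele2))
  mat <- sum(ifelse(pat_allele == 1L, pc$n_alt_allele2, pc$n_alt_allele1))
  origin <- "unphased"
  if (pat >= config$min_read_support && mat == 0) origin <- "paternal"
  if (mat >= config$min_read_support && pat == 0) origin <- "maternal"
  phase_call(origin, "read_pair", list(paternal = pat, maternal = mat))
}

#' Consensus of the two phasing methods
#'
#' Both methods phased and agreeing gives that origin; both phased and
#' disagreeing gives \code{"discordant"} (excluded from the phased set
#' but counted); exactly one phased gives its origin; neither phased
#' gives \code{"unphased"}.
#'
#' @param a phase call from \code{\link{phase_by_three_gen}}.
#' @param b phase call from \code{\link{phase_by_read_tracing}}.
#' @return a phase call with \code{method = "consensus"}; its support
#'   records which methods phased.
#' @export
consensus_phase <- function(a, b) {
  pa <- a$origin %in% c("paternal", "maternal")
  pb <- b$origin %in% c("paternal", "maternal")
  origin <- if (pa && pb) {
    if (a$origin == b$origin) a$origin else "discordant"
  } else if (pa) a$origin else if (pb) b$origin else "unphased"
  phase_call(origin, "consensus",
             list(three_gen = a$origin, read_pair = b$origin))
}

#' Phase a set of high-quality DNMs
#'
#' Runs both phasing methods and the consensus for every candidate row.
#'
#' @param ds a \code{dnm_dataset}.
#' @param cands candidate data.frame (typically the high-quality subset).
#' @param config a \code{dnm_config}.
#' @return data.frame with one row per candidate: \code{proband},
#'   \code{site_id}, \code{three_gen}, \code{read_pair} (per-method
#'   origins), \code{origin} (consensus) and \code{method}
#'   (\code{"three_gen"}, \code{"read_pair"}, \code{"both"},
#'   \code{"none"}).
#' @export
phase_dnms <- function(ds, cands, config = run_config()) {
  fams <- find_three_generation_families(ds$pedigree, config$min_offspring)
  fam_of <- stats::setNames(fams, vapply(fams, `[[`, "", "proband"))
  pc_all <- ds$pair_counts
  mp_all <- ds$marker_phase
  n <- nrow(cands)
  tg <- rp <- cons <- method <- character(n)
  for (i in seq_len(n)) {
    pid <- cands$proband[i]; site <- cands$site_id[i]
    a <- if (!is.null(fam_of[[pid]])) {
      off <- offspring_site_table(ds, fam_of[[pid]]$offspring, site)
      inh <- ds$inheritance
      inh <- inh[inh$site_id == site, , drop = FALSE]
      j <- match(off$id, inh$offspring)
      off$seg_cm <- inh$seg_cm[j]; off$seg_markers <- inh$seg_markers[j]
      phase_by_three_gen(off, config)
    } else phase_call("unphased", "three_gen",
                      list(paternal = 0L, maternal = 0L))
    pc <- pc_all[pc_all$proband == pid & pc_all$dnm_site == site, , drop = FALSE]
    mp <- mp_all[mp_all$id == pid, , drop = FALSE]
    if (nrow(pc) && nrow(mp)) {
      site_pos <- cands$pos[i]; site_chrom <- cands$chrom[i]
      if (all(c("marker_chrom", "marker_pos") %in% names(mp))) {
        near <- mp[mp$marker_chrom == site_chrom &
                     abs(mp$marker_pos - site_pos) <= config$pair_window, ,
                   drop = FALSE]
      } else near <- mp
      b <- phase_by_read_tracing(pc, near, config)
    } else b <- phase_call("unphased", "read_pair",
                           list(paternal = 0L, maternal = 0L))
    cc <- consensus_phase(a, b)
    tg[i] <- a$origin; rp[i] <- b$origin; cons[i] <- cc$origin
    pa <- a$origin %in% c("paternal", "maternal")
    pb <- b$origin %in% c("paternal", "maternal")
    method[i] <- if (pa && pb) "both" else if (pa) "three_gen" else
      if (pb) "read_pair" else "none"
  }
  data.frame(proband = cands$proband, site_id = cands$site_id,
             three_gen = tg, read_pair = rp, origin = cons,
             method = method, stringsAsFactors = FALSE)
}

#' Summary table of the phased DNMs
#'
#' Counts and fractions (of all high-quality DNMs) for the sets phased by
#' three-generation sharing, by read-pair tracing, by both methods, the
#' discordant overlap, and the consensus.  The consensus obeys the set
#' identity \code{consensus = three_gen + read_pair - both - discordant}.
#'
#' @param phases data.frame from \code{\link{phase_dnms}} (columns
#'   \code{three_gen}, \code{read_pair}, \code{origin}).
#' @param n_dnms total number of high-quality DNMs the fractions refer to.
#' @return data.frame \code{set}, \code{count}, \code{fraction}.
#' @export
summarize_phasing <- function(phases, n_dnms) {
  if (n_dnms == 0)
    return(data.frame(set = character(0), count = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  ph <- c("paternal", "maternal")
  n_tg <- sum(phases$three_gen %in% ph)
  n_rp <- sum(phases$read_pair %in% ph)
  n_both <- sum(phases$three_gen %in% ph & phases$read_pair %in% ph)
  n_disc <- sum(phases$origin == "discordant")
  n_cons <- sum(phases$origin %in% ph)
  counts <- c(three_gen = n_tg, read_pair = n_rp, both = n_both,
              discordant = n_disc, consensus = n_cons)
  data.frame(set = names(counts), count = as.integer(counts),
             fraction = as.numeric(counts) / n_dnms,
             stringsAsFactors = FALSE)
}
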