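#' Evaluate per-lane sequencing metrics against the QC rule set
#'
#' A lane fails when any rule trips.  Bounds are applied with the
#' documented strict inequality directions: mean base quality below 25,
#' percent duplicates above 50, mean N per read above 30, percent
#' MAPQ<20 above 11, any of the four unmapped percentages above 40, or a
#' chip-concordance mismatch rate above 2%.
#'
#' @param m a one-row data.frame (or named list) with fields
#'   \code{mean_base_quality}, \code{pct_duplicates}, \code{mean_n_per_read},
#'   \code{pct_mapq_lt20}, \code{pct_unmapped}, \code{pct_both_unmapped},
#'   \code{pct_first_unmapped}, \code{pct_second_unmapped},
#'   \code{chip_mismatch_rate} (a fraction).
#' @param config a \code{dnm_config}.
#' @return list with \code{pass} (logical) and \code{failed} (character
#'   vector naming every violated metric).  A missing metric value is an
#'   error, never a silent pass.
#' @examples
#' m <- list(mean_base_quality = 35, pct_duplicates = 10,
#'   mean_n_per_read = 1, pct_mapq_lt20 = 3, pct_unmapped = 2,
#'   pct_both_unmapped = 1, pct_first_unmapped = 1, pct_second_unmapped = 1,
#'   chip_mismatch_rate = 0.001)
#' evaluate_lane_metrics(m)$pass
#' @export
evaluate_lane_metrics <- function(m, config = run_config()) {
  rules <- lane_rules(config)
  failed <- character(0)
  for (r in rules) {
    v <- m[[r$field]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop("lane metric '", r$field, "' is missing; refusing to evaluate")
    if (r$dir == "lt") { if (v < r$bound) failed <- c(failed, r$field) }
    else               { if (v > r$bound) failed <- c(failed, r$field) }
  }
  list(pass = length(failed) == 0L, failed = failed)
}

# the nine lane rules; dir = "lt" fails values strictly below the bound,
# dir = "gt" strictly above
lane_rules <- function(config) {
  list(
    list(field = "mean_base_quality",   dir = "lt", bound = config$lane_min_base_quality),
    list(field = "pct_duplicates",      dir = "gt", bound = config$lane_max_pct_duplicates),
    list(field = "mean_n_per_read",     dir = "gt", bound = config$lane_max_n_per_read),
    list(field = "pct_mapq_lt20",       dir = "gt", bound = config$lane_max_pct_mapq_lt20),
    list(field = "pct_unmapped",        dir = "gt", bound = config$lane_max_pct_unmapped),
    list(field = "pct_both_unmapped",   dir = "gt", bound = config$lane_max_pct_unmapped),
    list(field = "pct_first_unmapped",  dir = "gt", bound = config$lane_max_pct_unmapped),
    list(field = "pct_second_unmapped", dir = "gt", bound = config$lane_max_pct_unmapped),
    list(field = "chip_mismatch_rate",  dir = "gt", bound = config$max_chip_mismatch)
  )
}

#' Chip-concordance mismatch rate
#'
#' Rate of pileup bases disagreeing with the chip genotype at sites where
#' the sample is chip-homozygous: mismatching bases divided by all
#' chip-typed bases.
#'
#' @param base_counts integer matrix, one row per chip-homozygous site,
#'   columns \code{A}, \code{C}, \code{G}, \code{T}: pileup base counts.
#' @param chip_alleles character vector (one per site) giving the
#'   chip-homozygous allele.
#' @return list with \code{rate} (fraction in [0,1]), \code{n_bases} and
#'   \code{defined} (FALSE with \code{rate = NA} when no chip-typed bases).
#' @export
chip_mismatch_rate <- function(base_counts, chip_alleles) {
  base_counts <- as.matrix(base_counts)
  stopifnot(ncol(base_counts) == 4L, nrow(base_counts) == length(chip_alleles),
            all(chip_alleles %in% c("A", "C", "G", "T")))
  if (any(base_counts < 0)) stop("negative base counts")
  colnames(base_counts) <- toupper(colnames(base_counts))
  total <- sum(base_counts)
  if (total == 0)
    return(list(rate = NA_real_, n_bases = 0L, defined = FALSE))
  match_n <- sum(base_counts[cbind(seq_along(chip_alleles),
                                   match(chip_alleles, colnames(base_counts)))])
  list(rate = (total - match_n) / total, n_bases = total, defined = TRUE)
}

#' Contamination surrogate from heterozygous marker pairs
#'
#' Fraction of heterozygous SNP marker pairs for which two or more read
#' pairs support a third haplotype; an excess indicates DNA from more than
#' one individual.  Samples above the bound (default 0.1%) are excluded.
#'
#' @param n_snp_pairs number of evaluated heterozygous marker pairs (> 0).
#' @param n_pairs_third_hap_ge2 number of those pairs with >= 2 read pairs
#'   supporting a third haplotype.
#' @param config a \code{dnm_config} (uses \code{max_contamination}).
#' @return list with \code{fraction} and \code{exclude}.
#' @export
contamination_fraction <- function(n_snp_pairs, n_pairs_third_hap_ge2,
                                   config = run_config()) {
  if (length(n_snp_pairs) != 1L || is.na(n_snp_pairs) || n_snp_pairs <= 0)
    stop("contamination surrogate undefined: n_snp_pairs must be positive")
  if (n_pairs_third_hap_ge2 < 0 || n_pairs_third_hap_ge2 > n_snp_pairs)
    stop("n_pairs_third_hap_ge2 must be in [0, n_snp_pairs]")
  f <- n_pairs_third_hap_ge2 / n_snp_pairs
  list(fraction = f, exclude = f > config$max_contamination)
}

#' Imputation information of a variant
#'
#' Variance-ratio measure of imputation quality: the observed variance of
#' the imputed expected allele counts (one dosage per haplotype, each in
#' [0,1]) divided by the binomial variance p(1-p) of the true allele
#' count.  Perfect imputation (dosages equal to the true 0/1 alleles)
#' gives 1; frequency-only imputation (all dosages equal to p) gives 0.
#' The observed variance is the population variance (divide by n), the
#' natural large-n estimator.
#'
#' @param dosages numeric vector of per-haplotype expected allele counts,
#'   each in [0,1]; at least 2 values.
#' @param p allele frequency, strictly inside (0,1).
#' @param tolerance slack above 1 allowed before clipping (sampling noise
#'   can push the ratio slightly over 1).
#' @return list with \code{info} (clipped to [0, 1]), \code{raw} (the
#'   unclipped ratio) and \code{flagged_over_one}.
#' @examples
#' imputation_info(c(0, 1, 0, 1), p = 0.5)$info     # perfect: 1
#' imputation_info(rep(0.3, 10), p = 0.3)$info      # uninformative: 0
#' @export
imputation_info <- function(dosages, p, tolerance = 1e-8) {
  if (length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("imputation information undefined for allele frequency p = ", p)
  if (length(dosages) < 2L) stop("need at least 2 dosages")
  if (any(dosages < 0 | dosages > 1)) stop("dosages must lie in [0, 1]")
  v <- mean((dosages - mean(dosages))^2)
  raw <- v / (p * (1 - p))
  flagged <- raw > 1 + tolerance
  list(info = min(max(raw, 0), 1), raw = raw, flagged_over_one = flagged)
}

#' Apply lane and contamination QC to a simulated or loaded dataset
#'
#' @param lane_metrics data.frame with a \code{sample_id} column and the
#'   nine lane-metric fields (one row per lane).
#' @param het_pair_support optional data.frame with \code{sample_id},
#'   \code{n_snp_pairs}, \code{n_pairs_third_hap_ge2}.
#' @param config a \code{dnm_config}.
#' @return list with \code{excluded_samples} (character), \code{lane_fail}
#'   (data.frame lane/sample/failed rules) and \code{contamination}
#'   (data.frame per sample).  A sample is excluded when any of its lanes
#'   fails or its contamination surrogate exceeds the bound.
#' @export
sample_qc <- function(lane_metrics, het_pair_support = NULL,
                      config = run_config()) {
  excluded <- character(0)
  fail_rows <- list()
  if (!is.null(lane_metrics) && nrow(lane_metrics)) {
    for (i in seq_len(nrow(lane_metrics))) {
      res <- evaluate_lane_metrics(lane_metrics[i, ], config)
      if (!res$pass) {
        excluded <- c(excluded, lane_metrics$sample_id[i])
        fail_rows[[length(fail_rows) + 1L]] <- data.frame(
          sample_id = lane_metrics$sample_id[i],
          lane_id = if ("lane_id" %in% names(lane_metrics))
            lane_metrics$lane_id[i] else NA_character_,
          failed = paste(res$failed, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  contam <- NULL
  if (!is.null(het_pair_support) && nrow(het_pair_support)) {
    frac <- numeric(nrow(het_pair_support)); excl <- logical(nrow(het_pair_support))
    for (i in seq_len(nrow(het_pair_support))) {
      r <- contamination_fraction(het_pair_support$n_snp_pairs[i],
                                  het_pair_support$n_pairs_third_hap_ge2[i],
                                  config)
      frac[i] <- r$fraction; excl[i] <- r$exclude
    }
    contam <- data.frame(sample_id = het_pair_support$sample_id,
                         fraction = frac, exclude = excl,
                         stringsAsFactors = FALSE)
    excluded <- c(excluded, contam$sample_id[contam$exclude])
  }
  list(excluded_samples = sort(unique(excluded)),
       lane_fail = if (length(fail_rows)) do.call(rbind, fail_rows) else
         data.frame(sample_id = character(0), lane_id = character(0),
                    failed = character(0), stringsAsFactors = FALSE),
       contamination = contam)
}
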