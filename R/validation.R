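#' Monozygotic-twin concordance of a proband's DNMs
#'
#' Verifies the presence or absence of each high-quality DNM of a proband
#' in its monozygotic co-twin.  Twin calls are treated as missing below
#' 10 reads of depth; heterozygous twin calls are additionally treated as
#' missing unless supported by at least 2 alt reads with allelic balance
#' of at least 0.1.  A DNM is verifiable when the twin call is
#' non-missing, and discordant when the verifiable twin call lacks the
#' DNM allele (hom-alt twin calls count as concordant carriers).
#'
#' @param ds a \code{dnm_dataset}.
#' @param proband a proband id registered in an MZ twin group.
#' @param dnm_sites site ids of the proband's high-quality DNMs.
#' @param config a \code{dnm_config}.
#' @return data.frame (one row): \code{proband}, \code{twin},
#'   \code{n_dnms}, \code{n_verifiable}, \code{n_discordant},
#'   \code{discordance} (\code{NA} when nothing is verifiable).
#' @export
twin_concordance <- function(ds, proband, dnm_sites, config = run_config()) {
  tw <- twin_of(ds$pedigree, proband)
  if (is.na(tw))
    stop("proband ", proband, " is not registered in an MZ twin group")
  ev <- ds$evidence
  ev <- ev[ev$id == tw & ev$site_id %in% dnm_sites, , drop = FALSE]
  j <- match(dnm_sites, ev$site_id)
  gt <- ifelse(is.na(j), "missing", ev$gt[j])
  depth <- ifelse(is.na(j), 0L, ev$depth[j])
  refr <- ifelse(is.na(j), 0L, ev$ref_reads[j])
  altr <- ifelse(is.na(j), 0L, ev$alt_reads[j])
  ab <- allelic_balance(refr, altr)
  missing <- gt == "missing" | depth < config$offspring_min_depth
  het_bad <- gt == "het" & (altr < config$offspring_min_alt |
                              is.na(ab) | ab < config$offspring_min_ab)
  verifiable <- !missing & !het_bad
  carrier <- gt_carries_alt(gt)
  n_ver <- sum(verifiable)
  n_dis <- sum(verifiable & !carrier)
  data.frame(proband = proband, twin = tw,
             n_dnms = length(dnm_sites), n_verifiable = n_ver,
             n_discordant = n_dis,
             discordance = if (n_ver > 0) n_dis / n_ver else NA_real_,
             stringsAsFactors = FALSE)
}

#' Twin concordance for every twin proband in a call set
#'
#' @param ds a \code{dnm_dataset}.
#' @param hq_calls data.frame of high-quality DNMs (\code{proband},
#'   \code{site_id}).
#' @param config a \code{dnm_config}.
#' @return list with \code{per_twin} (one row per twin proband, as in
#'   \code{\link{twin_concordance}}), \code{pooled_discordance}
#'   (count-weighted over all verifiable DNMs) and
#'   \code{mean_discordance} (unweighted mean of per-twin fractions).
#' @export
twin_validation <- function(ds, hq_calls, config = run_config()) {
  df <- ds$pedigree$records
  twins <- df$id[!is.na(df$twin_group)]
  probands <- intersect(unique(hq_calls$proband), twins)
  rows <- lapply(probands, function(p)
    twin_concordance(ds, p, hq_calls$site_id[hq_calls$proband == p], config))
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(proband = character(0), twin = character(0),
               n_dnms = integer(0), n_verifiable = integer(0),
               n_discordant = integer(0), discordance = numeric(0),
               stringsAsFactors = FALSE)
  nv <- sum(per$n_verifiable)
  list(per_twin = per,
       pooled_discordance = if (nv > 0) sum(per$n_discordant) / nv else NA_real_,
       mean_discordance = if (nrow(per))
         mean(per$discordance, na.rm = TRUE) else NA_real_)
}

#' Variant summary table
#'
#' Counts variants stratified by type (SNP / indel) and allele structure
#' (biallelic / non-biallelic), each with the number passing the GATK
#' filters, the number with phase score above 0.8 and the number with
#' imputation information above 0.8.  "Total" rows sum SNPs and indels.
#'
#' @param variants data.frame with \code{is_snp}, \code{multiallelic}
#'   (logical) and optionally \code{gatk_pass}, \code{phase_score},
#'   \code{impute_info}.
#' @param threshold score threshold for the phase / imputation columns
#'   (default 0.8, strict).
#' @return data.frame \code{variant_type}, \code{allele}, \code{total},
#'   \code{gatk_pass}, \code{phase_pass}, \code{imputation_pass}
#'   (\code{NA} columns when the annotation is absent).
#' @export
variant_summary <- function(variants, threshold = 0.8) {
  cnt <- function(sub) {
    c(total = nrow(sub),
      gatk_pass = if ("gatk_pass" %in% names(sub))
        sum(sub$gatk_pass, na.rm = TRUE) else NA_integer_,
      phase_pass = if ("phase_score" %in% names(sub))
        sum(sub$phase_score > threshold, na.rm = TRUE) else NA_integer_,
      imputation_pass = if ("impute_info" %in% names(sub))
        sum(sub$impute_info > threshold, na.rm = TRUE) else NA_integer_)
  }
  rows <- list()
  for (type in c("Indel", "SNP")) for (al in c("Biallelic", "Non-biallelic")) {
    sub <- variants[(variants$is_snp == (type == "SNP")) &
                      (variants$multiallelic == (al == "Non-biallelic")), ,
                    drop = FALSE]
    rows[[length(rows) + 1L]] <-
      data.frame(variant_type = type, allele = al, t(cnt(sub)),
                 stringsAsFactors = FALSE)
  }
  for (al in c("Biallelic", "Non-biallelic")) {
    sub <- variants[variants$multiallelic == (al == "Non-biallelic"), ,
                    drop = FALSE]
    rows[[length(rows) + 1L]] <-
      data.frame(variant_type = "Total", allele = al, t(cnt(sub)),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Agreement between the two phasing methods
#'
#' @param phases data.frame from \code{\link{phase_dnms}}.
#' @return list with \code{n_both} (DNMs phased by both methods),
#'   \code{n_discordant}, \code{discrepancy} (their ratio; \code{NA} and
#'   flagged undefined when no DNM was phased by both methods).
#' @export
phase_comparison <- function(phases) {
  ph <- c("paternal", "maternal")
  n_both <- sum(phases$three_gen %in% ph & phases$read_pair %in% ph)
  n_disc <- sum(phases$three_gen %in% ph & phases$read_pair %in% ph &
                  phases$three_gen != phases$read_pair)
  list(n_both = n_both, n_discordant = n_disc,
       discrepancy = if (n_both > 0) n_disc / n_both else NA_real_,
       defined = n_both > 0)
}
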