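#' Run the full DNM pipeline
#'
#' Executes, in order: sample QC (lane metrics and contamination
#' surrogate), candidate extraction with proband-level exclusions,
#' transmission labeling in three-generation families, fitting of the
#' transmission-calibrated GAM and scoring of all candidates,
#' parent-of-origin phasing of the high-quality DNMs (three-generation
#' sharing, read-pair tracing, consensus), monozygotic-twin validation
#' and summary tables.  Given the same dataset and configuration the
#' pipeline is deterministic.
#'
#' @param ds a \code{dnm_dataset}.
#' @param config a \code{dnm_config}.
#' @return object of class \code{dnm_result}: \code{report} (counts per
#'   stage), the scored \code{candidates} table (with \code{response},
#'   \code{high_quality}), transmission \code{labels}, the fitted
#'   \code{model}, \code{phases}, \code{phase_summary},
#'   \code{phase_comparison}, \code{twin} validation,
#'   \code{variant_summary}, QC exclusions and the configuration.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(sim_config(n_families = 12, seed = 7))
#' res <- run_pipeline(ds)
#' res$report
#' }
#' @export
run_pipeline <- function(ds, config = run_config()) {
  stopifnot(inherits(ds, "dnm_dataset"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  qc <- stage("sample_qc",
              sample_qc(ds$lane_metrics, ds$het_pair_support, config))
  cands <- stage("extract_candidates",
                 extract_candidates(ds, config, qc$excluded_samples))
  fp <- stage("filter_probands", filter_probands(cands, ds$samples, config))
  cands <- fp$candidates
  report <- c(n_samples = nrow(ds$pedigree$records),
              n_qc_excluded_samples = length(qc$excluded_samples),
              n_candidates_raw = nrow(cands) + 0L,
              n_probands_excluded = nrow(fp$excluded_probands))
  if (!nrow(cands)) {
    report <- c(report, n_labeled = 0L, n_high_quality = 0L, n_phased = 0L)
    return(structure(list(
      report = report, candidates = cands, labels = NULL, model = NULL,
      phases = NULL, phase_summary = NULL, phase_comparison = NULL,
      twin = NULL, variant_summary = variant_summary(ds$variants),
      qc = qc, excluded_probands = fp$excluded_probands,
      config = config, seed = if (!is.null(ds$sim)) ds$sim$seed else NA),
      class = "dnm_result"))
  }
  labels <- stage("transmission", transmission_labels(ds, cands, config))
  feats <- gam_features(cands)
  lab_vec <- labels$label[match(paste(cands$proband, cands$site_id),
                                paste(labels$proband, labels$site_id))]
  model <- stage("gam_fit",
                 fit_transmission_gam(feats, ifelse(is.na(lab_vec),
                                                    "unevaluable", lab_vec),
                                      config))
  scores <- stage("gam_score", score_candidates(model, feats))
  cands <- cbind(cands, scores)
  hq <- cands[cands$high_quality, , drop = FALSE]
  phases <- stage("phasing", phase_dnms(ds, hq, config))
  psum <- summarize_phasing(phases, nrow(hq))
  pcmp <- phase_comparison(phases)
  twin <- stage("twin_validation",
                twin_validation(ds, hq[, c("proband", "site_id")], config))
  report <- c(report,
              n_labeled = sum(lab_vec %in% c("consistent", "inconsistent"),
                              na.rm = TRUE),
              n_high_quality = nrow(hq),
              n_phased = sum(phases$origin %in% c("paternal", "maternal")))
  structure(list(
    report = report, candidates = cands, labels = labels, model = model,
    phases = phases, phase_summary = psum, phase_comparison = pcmp,
    twin = twin, variant_summary = variant_summary(ds$variants),
    qc = qc, excluded_probands = fp$excluded_probands, config = config,
    seed = if (!is.null(ds$sim)) ds$sim$seed else NA),
    class = "dnm_result")
}

#' @export
print.dnm_result <- function(x, ...) {
  cat("DNM pipeline result\n")
  for (nm in names(x$report))
    cat(sprintf("  %-26s %d\n", nm, x$report[[nm]]))
  if (!is.null(x$phase_comparison) && x$phase_comparison$defined)
    cat(sprintf("  phase-method discrepancy:  %.2f%% (%d of %d)\n",
                100 * x$phase_comparison$discrepancy,
                x$phase_comparison$n_discordant, x$phase_comparison$n_both))
  if (!is.null(x$twin) && !is.na(x$twin$pooled_discordance))
    cat(sprintf("  MZ twin discordance:       %.2f%% pooled\n",
                100 * x$twin$pooled_discordance))
  invisible(x)
}
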