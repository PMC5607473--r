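#' Pipeline run configuration
#'
#' Builds the configuration object holding every tunable threshold of the
#' DNM pipeline.  Defaults reproduce the published calling procedure, so
#' \code{run_pipeline(ds, run_config())} applies the standard filters.
#' Fractions are on [0,1]; depths are read counts; the GAM cutoff is a
#' posterior-response threshold on (0,1).
#'
#' Filter semantics follow the printed inequality directions exactly:
#' bounds documented as "minimum" are inclusive (\code{>=}), bounds
#' documented as "over"/"greater than" are strict (\code{>}), and
#' "maximum" bounds are inclusive (\code{<=}).
#'
#' @param ... named overrides of any default listed below.
#' @return An object of class \code{dnm_config} (a named list).
#'
#' @section Candidate extraction:
#' \describe{
#'   \item{min_proband_coverage}{proband mean genome coverage must exceed
#'     this (strict; default 20).}
#'   \item{min_proband_depth}{minimum site depth in the proband (12).}
#'   \item{min_proband_ab}{minimum proband allelic balance (0.15).}
#'   \item{max_homalt_ref_reads}{maximum reference-supporting reads allowed
#'     for a hom-alt proband call (1).}
#'   \item{min_parent_depth}{minimum parental site depth, autosomes (12).}
#'   \item{min_parent_depth_x_father}{minimum paternal depth at X sites of
#'     male probands (6; the father is hemizygous there).}
#'   \item{max_parent_alt}{maximum alt-supporting reads in a parent (1).}
#'   \item{max_parent_ab}{maximum parental allelic balance (0.05).}
#'   \item{max_possible_carriers}{maximum possible carriers beyond the
#'     descendants of the parent pair (10).}
#'   \item{max_likely_carriers}{maximum likely carriers beyond the
#'     descendants of the parent pair (3).}
#'   \item{max_site_softclip}{maximum mean soft-clipped read fraction over
#'     reads covering the candidate (0.10).}
#' }
#'
#' @section Likely-carrier definition:
#' depth strictly over \code{likely_min_depth} (12), allelic-balance
#' deviation from 0.5 strictly below \code{likely_ab_dev} (0.25), genotype
#' quality strictly over \code{likely_min_gq} (20).
#'
#' @section Proband-level exclusions:
#' \code{proband_max_softclip} (0.10), \code{proband_max_nfrac} (0.015) and
#' \code{proband_max_candidates} (300): probands exceeding any bound are
#' dropped with all their candidates.
#'
#' @section Transmission assay and twin checks:
#' offspring (or twin) calls are treated as missing below
#' \code{offspring_min_depth} (10) reads; alt-supporting calls additionally
#' require \code{offspring_min_alt} (2) alt reads and allelic balance of at
#' least \code{offspring_min_ab} (0.1).  \code{min_offspring} (2) offspring
#' on distinct proband haplotypes are needed for an evaluable label.
#'
#' @section GAM scoring:
#' \code{gam_cutoff} (0.8): candidates are high quality when the fitted
#' response is strictly greater than the cutoff.
#'
#' @section Phasing:
#' three-generation phasing requires the shared segment to span at least
#' \code{min_segment_cm} (0.8) cM and \code{min_segment_markers} (200)
#' consecutive panel markers.  Read-pair tracing considers phased markers
#' within \code{pair_window} (5000) bp of the DNM, requires at least
#' \code{min_read_support} (1) supporting pairs and zero pairs supporting
#' the opposite parent.
#'
#' @section Sample QC:
#' lane-metric bounds (\code{lane_*}), the chip-concordance mismatch bound
#' \code{max_chip_mismatch} (0.02) and the contamination-surrogate bound
#' \code{max_contamination} (0.001); \code{relationship_threshold} (0.45)
#' is the autosomal haplotype-sharing fraction confirming a parent-child
#' link.
#'
#' @examples
#' cfg <- run_config(gam_cutoff = 0.9)
#' cfg$gam_cutoff
#' @export
run_config <- function(...) {
  cfg <- list(
    # candidate extraction
    min_proband_coverage = 20,      # strict >
    min_proband_depth    = 12,      # >=
    min_proband_ab       = 0.15,    # >=
    max_homalt_ref_reads = 1,       # <=
    min_parent_depth     = 12,      # >=
    min_parent_depth_x_father = 6,  # >=
    max_parent_alt       = 1,       # <=
    max_parent_ab        = 0.05,    # <=
    max_possible_carriers = 10,     # <=
    max_likely_carriers  = 3,       # <=
    max_site_softclip    = 0.10,    # <=
    # likely-carrier definition (all strict)
    likely_min_depth = 12,
    likely_ab_dev    = 0.25,
    likely_min_gq    = 20,
    # proband-level exclusions (all strict >)
    proband_max_softclip   = 0.10,
    proband_max_nfrac      = 0.015,
    proband_max_candidates = 300,
    # transmission assay / twin validation
    min_offspring      = 2,
    offspring_min_depth = 10,   # >=
    offspring_min_alt   = 2,    # >=
    offspring_min_ab    = 0.1,  # >=
    # GAM
    gam_cutoff = 0.8,           # strict >
    gam_k      = 10,
    # phasing
    min_segment_cm      = 0.8,  # >=
    min_segment_markers = 200,  # >=
    pair_window         = 5000, # <= bp
    min_read_support    = 1,    # >=
    # sample QC: lane-metric bounds (fail when violated, strict as printed)
    lane_min_base_quality   = 25,   # fail if < 25
    lane_max_pct_duplicates = 50,   # fail if > 50
    lane_max_n_per_read     = 30,   # fail if > 30
    lane_max_pct_mapq_lt20  = 11,   # fail if > 11
    lane_max_pct_unmapped   = 40,   # fail if > 40 (all four unmapped rules)
    max_chip_mismatch  = 0.02,      # fail if > 2%
    max_contamination  = 0.001,     # exclude if > 0.1%
    relationship_threshold = 0.45,
    # imputation information
    info_tolerance = 1e-8,
    seed = NA_integer_
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  frac <- c("min_proband_ab", "max_parent_ab", "max_site_softclip",
            "likely_ab_dev", "proband_max_softclip", "proband_max_nfrac",
            "offspring_min_ab", "gam_cutoff", "max_chip_mismatch",
            "max_contamination", "relationship_threshold")
  for (f in frac) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("configuration field '", f, "' must be a fraction in [0, 1]")
  }
  structure(cfg, class = "dnm_config")
}

#' @export
print.dnm_config <- function(x, ...) {
  cat("<dnm_config> (", length(x), " fields)\n", sep = "")
  nm <- names(x)
  for (i in seq_along(x))
    cat(sprintf("  %-26s %s\n", nm[i], format(x[[i]])))
  invisible(x)
}

#' Read or write a pipeline configuration as YAML
#'
#' Unknown fields are rejected; absent fields keep their defaults.
#'
#' @param path file path of the YAML configuration.
#' @return \code{read_run_config} returns a \code{dnm_config};
#'   \code{write_run_config} returns \code{path} invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a \code{dnm_config} object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "dnm_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
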