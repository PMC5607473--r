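#' Assemble classifier features for DNM candidates
#'
#' The four covariates of the transmission-calibrated classifier: the
#' proband allelic balance, the oxoG strand-bias (FoxoG) metric, the
#' count of possible carriers beyond the descendants of the parent pair
#' (Trio-NPOSS), and the binary GATK filter status.
#'
#' @param cands candidate data.frame from \code{\link{extract_candidates}}.
#' @return data.frame \code{proband_ab}, \code{foxog}, \code{nposs},
#'   \code{gatk}, aligned with \code{cands} rows.
#' @export
gam_features <- function(cands) {
  data.frame(
    proband_ab = cands$proband_ab,
    foxog = foxog_metric(cands$ref, cands$alt, cands$f1r2_alt,
                         cands$f2r1_alt),
    nposs = cands$n_possible_outside,
    gatk = as.integer(cands$gatk_pass),
    stringsAsFactors = FALSE)
}

#' Fit the transmission-calibrated GAM classifier
#'
#' Fits a binomial generalized additive model (logit link) of the
#' transmission label (1 = consistent, 0 = inconsistent) on penalized
#' cubic-regression-spline smooths of proband allelic balance, FoxoG and
#' Trio-NPOSS, plus a linear binary GATK-filter term.  Smoothing
#' parameters are selected by generalized cross-validation.  A smooth
#' term's basis dimension is reduced when its covariate has fewer unique
#' values than the basis requires; covariates with fewer than four unique
#' values enter linearly.
#'
#' @param features data.frame from \code{\link{gam_features}} (rows with
#'   label \code{"unevaluable"} are dropped before fitting).
#' @param labels character vector of transmission labels aligned with
#'   \code{features}.
#' @param config a \code{dnm_config} (uses \code{gam_cutoff},
#'   \code{gam_k}).
#' @return object of class \code{transmission_gam}: the mgcv fit, the
#'   response cutoff, training covariate ranges and training diagnostics.
#' @seealso \code{\link{score_candidates}}
#' @export
fit_transmission_gam <- function(features, labels, config = run_config()) {
  keep <- labels %in% c("consistent", "inconsistent")
  df <- features[keep, , drop = FALSE]
  df$y <- as.integer(labels[keep] == "consistent")
  if (!nrow(df) || length(unique(df$y)) < 2L)
    stop("cannot fit the transmission GAM: training labels contain a ",
         "single class")
  if (nrow(df) < 50L)
    warning("only ", nrow(df), " labeled candidates; the fit may be unstable")
  terms <- vapply(c("proband_ab", "foxog", "nposs"), function(v) {
    u <- length(unique(df[[v]]))
    if (u < 4L) return(v)
    k <- min(config$gam_k, u - 1L)
    sprintf("s(%s, bs = \"cr\", k = %d)", v, k)
  }, "")
  rhs <- paste(c(terms, "gatk"), collapse = " + ")
  fit <- mgcv::gam(stats::as.formula(paste("y ~", rhs)),
                   family = stats::binomial(), data = df,
                   method = "GCV.Cp",
                   control = mgcv::gam.control(maxit = 400))
  structure(list(
    fit = fit,
    cutoff = config$gam_cutoff,
    n_train = nrow(df),
    n_consistent = sum(df$y == 1L),
    ranges = lapply(df[c("proband_ab", "foxog", "nposs")], range),
    deviance_explained = 1 - fit$deviance / fit$null.deviance,
    edf = sum(fit$edf)
  ), class = "transmission_gam")
}

#' @export
print.transmission_gam <- function(x, ...) {
  cat("Transmission-calibrated GAM classifier\n")
  cat(sprintf("  training candidates: %d (%d consistent, %d inconsistent)\n",
              x$n_train, x$n_consistent, x$n_train - x$n_consistent))
  cat(sprintf("  deviance explained:  %.1f%%   effective dof: %.1f\n",
              100 * x$deviance_explained, x$edf))
  cat(sprintf("  high-quality cutoff: response > %g\n", x$cutoff))
  invisible(x)
}

#' @export
summary.transmission_gam <- function(object, ...) {
  print(object)
  cat("\n")
  print(summary(object$fit))
  invisible(object)
}

#' @export
coef.transmission_gam <- function(object, ...) stats::coef(object$fit)

#' Predict the GAM response for new candidates
#'
#' @param object a \code{transmission_gam}.
#' @param newdata feature data.frame (see \code{\link{gam_features}}).
#' @param ... unused.
#' @return numeric vector of responses in (0,1).
#' @export
predict.transmission_gam <- function(object, newdata, ...) {
  as.numeric(mgcv::predict.gam(object$fit, newdata = newdata,
                               type = "response"))
}

#' @export
plot.transmission_gam <- function(x, which = c("response", "smooths"), ...) {
  which <- match.arg(which)
  if (which == "smooths") return(invisible(plot(x$fit, pages = 1, ...)))
  r <- stats::fitted(x$fit)
  graphics::hist(r, breaks = 50, main = "GAM response (training candidates)",
                 xlab = "response", ...)
  graphics::abline(v = x$cutoff, col = "red", lwd = 2)
  invisible(x)
}

is_high_quality <- function(response, cutoff) response > cutoff

#' Score candidates and flag high-quality DNMs
#'
#' Predicts the GAM response for every candidate; a candidate is high
#' quality when its response is strictly greater than the cutoff.
#' Candidates with a covariate outside the training range are still
#' scored but flagged as extrapolated.
#'
#' @param model a \code{transmission_gam}.
#' @param features feature data.frame (see \code{\link{gam_features}}).
#' @param cutoff response threshold; defaults to the model's.
#' @return data.frame \code{response}, \code{high_quality},
#'   \code{extrapolated}.
#' @export
score_candidates <- function(model, features, cutoff = model$cutoff) {
  stopifnot(inherits(model, "transmission_gam"))
  resp <- predict(model, features)
  extra <- rep(FALSE, nrow(features))
  for (v in names(model$ranges)) {
    rg <- model$ranges[[v]]
    extra <- extra | features[[v]] < rg[1] | features[[v]] > rg[2]
  }
  data.frame(response = resp,
             high_quality = is_high_quality(resp, cutoff),
             extrapolated = extra)
}
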