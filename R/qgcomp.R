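#' Quantize exposures into q quantile scores
#'
#' Each analyte is mapped to integer scores 0 … q−1 using its empirical
#' quantile cutpoints (quartiles by default). Cutpoints are returned so
#' replicate refits reuse the full-sample binning. Ties at a cutpoint
#' fall in the lower bin (left-open intervals), making scores invariant
#' to any strictly monotone transform of the raw concentrations.
#'
#' @param exposures data.frame/matrix of raw exposure values.
#' @param q number of quantile groups (default 4).
#' @param cutpoints optional list of per-analyte interior cutpoints to
#'   reuse (as produced by a previous call).
#' @return object of class `quantized_exposures`: `scores` (data.frame
#'   of integers), `cutpoints`, `q`.
#' @export
quantize <- function(exposures, q = 4, cutpoints = NULL) {
  exposures <- as.data.frame(exposures)
  if (q < 2) stop_pfasmix("q must be >= 2")
  if (anyNA(exposures)) stop_pfasmix("exposures must be complete")
  if (q > nrow(exposures)) stop_pfasmix("q exceeds the number of records")
  nm <- names(exposures)
  if (is.null(cutpoints)) {
    cutpoints <- lapply(exposures, function(x) {
      if (length(unique(x)) < 2L) {
        stop_pfasmix("constant analyte: quantiles undefined")
      }
      cp <- unique(stats::quantile(x, probs = seq_len(q - 1) / q,
                                   names = FALSE, type = 7))
      cp
    })
    names(cutpoints) <- nm
  }
  scores <- as.data.frame(
    lapply(nm, function(a) {
      # (−Inf, c1], (c1, c2], … : ties at a cutpoint go to the lower bin
      findInterval(exposures[[a]], cutpoints[[a]], left.open = TRUE)
    })
  )
  names(scores) <- nm
  structure(list(scores = scores, cutpoints = cutpoints, q = q),
            class = "quantized_exposures")
}

#' Quantile g-computation of a joint mixture effect
#'
#' Regresses the outcome on the quantized exposures plus covariates via
#' the survey-weighted GLM engine and reports the joint mixture effect
#' Ψ as the sum of the quantized-exposure coefficients — the effect of
#' a simultaneous one-quantile increase in every exposure. Positive and
#' negative weights decompose Ψ: each weight is a coefficient's share
#' of the summed coefficients in its direction, so weights in the same
#' direction sum to 1. Variance of Ψ comes from replicate refits with
#' the quantile cutpoints held fixed at their full-sample values (or
#' from the sandwich covariance when the design has no replicates).
#'
#' This is the conditional ("sum of coefficients") estimator; for a
#' log-link model exp(Ψ) is therefore a conditional prevalence ratio.
#'
#' @param data data.frame with outcome, exposures and covariates.
#' @param outcome outcome column name.
#' @param exposures character vector of exposure column names (raw
#'   concentrations; quantization is rank-based so any monotone
#'   transform yields identical results).
#' @param covariates character vector of adjustment covariates.
#' @param family `"gaussian"` or `"poisson"`.
#' @param design a [survey_design()].
#' @param q number of quantiles (default 4).
#' @param ci_level confidence level (default 0.95).
#' @return object of class `qgcomp_fit`.
#' @export
fit_qgcomp <- function(data, outcome, exposures, covariates = character(),
                       family = c("gaussian", "poisson"), design, q = 4,
                       ci_level = 0.95) {
  family <- match.arg(family)
  if (length(exposures) == 0L) stop_pfasmix("exposure set is empty")
  qx <- quantize(data[, exposures, drop = FALSE], q = q)

  score_names <- paste0("q_", exposures)
  dd <- data
  dd[score_names] <- qx$scores
  rhs <- paste(c(score_names, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))

  fit <- fit_weighted_glm(fml, dd, family = family, design = design,
                          ci_level = ci_level)

  beta <- fit$coefficients[score_names]
  names(beta) <- exposures
  psi <- sum(beta)

  if (fit$B >= 1L) {
    rep_psi <- rowSums(fit$replicate_estimates[, score_names, drop = FALSE])
    var_psi <- replicate_variance(psi, rep_psi, design$scale)
  } else {
    # sandwich covariance of the summed coefficients
    g <- refit_for_vcov(fml, dd, family, design)
    vc <- sandwich::vcovHC(g, type = "HC0")
    idx <- match(score_names, colnames(vc))
    var_psi <- sum(vc[idx, idx])
    rep_psi <- NULL
  }
  se_psi <- sqrt(var_psi)
  zq <- fit$z_quantile

  pos <- beta[beta > 0]
  neg <- beta[beta < 0]
  w_pos <- if (length(pos)) pos / sum(pos) else numeric(0)
  w_neg <- if (length(neg)) neg / sum(neg) else numeric(0)

  structure(list(
    psi = psi,
    se = se_psi,
    ci_lower = psi - zq * se_psi,
    ci_upper = psi + zq * se_psi,
    ci_level = ci_level,
    coefficients = beta,
    weights_positive = w_pos,
    weights_negative = w_neg,
    family = family,
    q = q,
    cutpoints = qx$cutpoints,
    replicate_psi = rep_psi,
    glm_fit = fit,
    n = fit$n,
    B = fit$B,
    estimator = "conditional sum-of-coefficients"
  ), class = "qgcomp_fit")
}

refit_for_vcov <- function(fml, dd, family, design) {
  fam <- if (family == "gaussian") stats::gaussian()
         else stats::quasipoisson("log")
  dd$.w <- design$weights
  eval(bquote(stats::glm(.(fml), data = dd, weights = .w, family = fam,
                         control = stats::glm.control(epsilon = 1e-8,
                                                      maxit = 100))))
}

#' @export
print.qgcomp_fit <- function(x, ...) {
  cat("quantile g-computation (", x$estimator, ", q = ", x$q,
      ", family = ", x$family, ", n = ", x$n, ", B = ", x$B, ")\n", sep = "")
  cat(sprintf("psi = %.4f  (%.0f%% CI %.4f, %.4f)\n",
              x$psi, 100 * x$ci_level, x$ci_lower, x$ci_upper))
  if (x$family == "poisson") {
    cat(sprintf("PR  = %.3f  (%.3f, %.3f)\n", exp(x$psi),
                exp(x$ci_lower), exp(x$ci_upper)))
  }
  if (length(x$weights_positive)) {
    cat("positive weights:",
        paste(names(x$weights_positive),
              sprintf("%.3f", x$weights_positive), collapse = ", "), "\n")
  }
  if (length(x$weights_negative)) {
    cat("negative weights:",
        paste(names(x$weights_negative),
              sprintf("%.3f", x$weights_negative), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize a mixture fit as one reporting row
#'
#' Emits the quantity the result tables print: a prevalence ratio for a
#' binary outcome, a mean difference for the CMRS, or a percent
#' difference for a log2-transformed risk factor — with its 95% CI and
#' the positive/negative weight of every analyte (zero when the analyte
#' is not in that direction's set).
#'
#' @param fit a [fit_qgcomp()] result.
#' @param outcome_kind `"binary"`, `"cmrs"` or `"log2cmrf"`.
#' @param analyte_order canonical ordering for the weight columns.
#' @return one-row data.frame.
#' @export
summarize_mixture <- function(fit,
                              outcome_kind = c("binary", "cmrs", "log2cmrf"),
                              analyte_order = names(fit$coefficients)) {
  outcome_kind <- match.arg(outcome_kind)
  stopifnot(inherits(fit, "qgcomp_fit"))
  tr <- switch(outcome_kind,
    binary   = list(est = exp(fit$psi), lo = exp(fit$ci_lower),
                    hi = exp(fit$ci_upper), type = "PR"),
    cmrs     = list(est = fit$psi, lo = fit$ci_lower,
                    hi = fit$ci_upper, type = "mean_difference"),
    log2cmrf = list(est = back_transform_percent(fit$psi),
                    lo = back_transform_percent(fit$ci_lower),
                    hi = back_transform_percent(fit$ci_upper),
                    type = "percent_difference")
  )
  row <- data.frame(
    estimate_type = tr$type, estimate = tr$est,
    lcl = tr$lo, ucl = tr$hi,
    psi = fit$psi, se = fit$se, n = fit$n, B = fit$B,
    stringsAsFactors = FALSE
  )
  for (a in analyte_order) {
    row[[paste0("w_pos_", a)]] <-
      if (a %in% names(fit$weights_positive)) fit$weights_positive[[a]] else 0
    row[[paste0("w_neg_", a)]] <-
      if (a %in% names(fit$weights_negative)) fit$weights_negative[[a]] else 0
  }
  row
}
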