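#' Survey design: main weight plus bootstrap replicate weights
#'
#' Holds the main analysis weight and an n × B matrix of replicate
#' weights, together with the variance-combination rule: the variance
#' of an estimator is `scale/B` times the sum of squared deviations of
#' the replicate estimates about the full-sample estimate.
#'
#' @param weights positive main analysis weights.
#' @param replicates n × B matrix of positive replicate weights, or
#'   `NULL` for a design without replicates (robust sandwich variance
#'   is then used by the modelling functions).
#' @param scale variance scale factor (default 1, i.e. mean squared
#'   deviation; no Fay adjustment).
#' @return object of class `survey_design`.
#' @export
survey_design <- function(weights, replicates = NULL, scale = 1) {
  weights <- as.numeric(weights)
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop_pfasmix("all main weights must be positive and finite")
  }
  if (!is.null(replicates)) {
    replicates <- as.matrix(replicates)
    if (nrow(replicates) != length(weights)) {
      stop_pfasmix("replicate weight matrix must have one row per record")
    }
    if (any(replicates < 0)) stop_pfasmix("replicate weights must be >= 0")
  }
  structure(list(weights = weights, replicates = replicates,
                 scale = scale,
                 n = length(weights),
                 B = if (is.null(replicates)) 0L else ncol(replicates)),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("survey_design: n =", x$n, ", B =", x$B,
      "replicate weights, variance scale =", x$scale, "\n")
  invisible(x)
}

subset_design <- function(design, idx) {
  survey_design(design$weights[idx],
                if (is.null(design$replicates)) NULL
                else design$replicates[idx, , drop = FALSE],
                design$scale)
}

#' Rao–Wu–Yue rescaling bootstrap replicate weights
#'
#' Resamples `n_sites − 1` collection sites with replacement within the
#' (single) stratum and rescales each record's weight by
#' `m_s · n_sites / (n_sites − 1)`, where `m_s` counts how often the
#' record's site was drawn — so every replicate total matches the
#' main-weight total in expectation. Deterministic given `seed`.
#'
#' @param cohort data.frame with `site` and `weight` columns.
#' @param n_replicates number of replicate weight vectors B.
#' @param seed integer seed.
#' @param resample set `FALSE` for the degenerate test mode in which
#'   every replicate equals the main weights (replicate variance 0).
#' @return a [survey_design()].
#' @export
generate_replicate_weights <- function(cohort, n_replicates, seed,
                                       resample = TRUE) {
  if (is.null(cohort$site) || is.null(cohort$weight)) {
    stop_pfasmix("cohort must carry 'site' and 'weight' columns")
  }
  if (n_replicates < 1L) stop_pfasmix("n_replicates must be >= 1")
  w <- cohort$weight
  if (!resample) {
    rep_w <- matrix(w, length(w), n_replicates)
    return(survey_design(w, rep_w))
  }
  sites <- sort(unique(cohort$site))
  S <- length(sites)
  if (S < 2L) stop_pfasmix("bootstrap undefined with fewer than 2 sites")
  site_idx <- match(cohort$site, sites)
  rep_w <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(b) {
      draw <- sample.int(S, S - 1L, replace = TRUE)
      m <- tabulate(draw, nbins = S)
      w * (m[site_idx] * S / (S - 1L))
    }, numeric(length(w)))
  })
  survey_design(w, rep_w)
}

#' Replicate-weight variance of an estimator
#'
#' Implements the design's variance-combination rule:
#' `scale/B · Σ_b (θ_b − θ_full)²`.
#'
#' @param full_estimate full-sample point estimate (scalar or vector).
#' @param replicate_estimates vector (scalar estimator) or B × p matrix
#'   of replicate estimates.
#' @param scale variance scale factor (default 1).
#' @return variance (scalar or per-column vector).
#' @export
replicate_variance <- function(full_estimate, replicate_estimates,
                               scale = 1) {
  if (is.matrix(replicate_estimates)) {
    B <- nrow(replicate_estimates)
    dev <- sweep(replicate_estimates, 2, full_estimate)
    (scale / B) * colSums(dev^2)
  } else {
    B <- length(replicate_estimates)
    (scale / B) * sum((replicate_estimates - full_estimate)^2)
  }
}

#' Survey-weighted generalized linear model with replicate-weight or
#' robust variance
#'
#' Fits the model by iteratively reweighted least squares using the
#' design's main weights, then refits once per replicate weight vector;
#' standard errors come from the replicate-variance rule. With a
#' `poisson` family on a binary outcome this is the modified Poisson
#' prevalence-ratio estimator: the variance is never the model-based
#' Poisson variance — when the design carries no replicates (B = 0) a
#' robust (HC0 sandwich) variance is used instead.
#'
#' Rows with any missing model variable are removed (listwise deletion)
#' and counted in `n_dropped`; complete-case subsetting of covariates
#' should normally happen upstream.
#'
#' @param formula model formula.
#' @param data data.frame aligned with the design.
#' @param family `"gaussian"` (identity link) or `"poisson"` (log link).
#' @param design a [survey_design()] with one weight per row of `data`.
#' @param ci_level confidence level (default 0.95, Wald on the link
#'   scale with the normal quantile).
#' @return object of class `pfas_glm` with coefficients, SEs, CIs,
#'   replicate estimates and convergence diagnostics.
#' @export
fit_weighted_glm <- function(formula, data, family = c("gaussian", "poisson"),
                             design, ci_level = 0.95) {
  family <- match.arg(family)
  stopifnot(inherits(design, "survey_design"))
  if (nrow(data) != design$n) {
    stop_pfasmix("data rows (", nrow(data), ") and design size (",
                 design$n, ") differ")
  }

  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  cc <- stats::complete.cases(mf)
  n_dropped <- sum(!cc)
  if (n_dropped > 0L) {
    message("listwise deletion dropped ", n_dropped, " incomplete row(s)")
    mf <- mf[cc, , drop = FALSE]
    design <- subset_design(design, cc)
  }
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_pfasmix("rank-deficient model matrix; collinear term(s): ",
                 paste(aliased, collapse = ", "))
  }

  fam <- if (family == "gaussian") {
    stats::gaussian()
  } else {
    # quasipoisson gives the same IRLS coefficients as poisson but
    # without the non-integer-response warning on binary outcomes;
    # its dispersion is irrelevant because variance is robust/replicate.
    stats::quasipoisson(link = "log")
  }
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)

  full <- glm_fit_engine(X, y, design$weights, fam, ctrl)
  if (!full$converged) {
    stop_pfasmix("IRLS did not converge in ", ctrl$maxit,
                 " iterations (deviance ", signif(full$deviance, 6), ")")
  }
  coefs <- full$coefficients

  fitted_gt1 <- FALSE
  if (family == "poisson" && all(y %in% c(0, 1))) {
    fitted_gt1 <- any(full$fitted.values > 1)
    if (fitted_gt1) {
      warning("modified Poisson: ", sum(full$fitted.values > 1),
              " fitted probabilit(ies) exceed 1", call. = FALSE)
    }
  }

  B <- design$B
  if (B >= 1L) {
    rep_est <- t(vapply(seq_len(B), function(b) {
      glm_fit_engine(X, y, design$replicates[, b], fam, ctrl,
                     start = coefs)$coefficients
    }, numeric(length(coefs))))
    colnames(rep_est) <- names(coefs)
    variance <- replicate_variance(coefs, rep_est, design$scale)
    vcov_type <- "replicate"
  } else {
    dd <- data[cc, , drop = FALSE]
    dd$.w <- design$weights
    g <- eval(bquote(stats::glm(.(formula), data = dd, weights = .w,
                                family = fam, control = ctrl)))
    vc <- sandwich::vcovHC(g, type = "HC0")
    variance <- diag(vc)[names(coefs)]
    rep_est <- NULL
    vcov_type <- "sandwich_HC0"
  }

  se <- sqrt(variance)
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(list(
    coefficients = coefs,
    se = se,
    ci_lower = coefs - zq * se,
    ci_upper = coefs + zq * se,
    ci_level = ci_level,
    z_quantile = zq,
    replicate_estimates = rep_est,
    vcov_type = vcov_type,
    family = family,
    formula = formula,
    n = length(y),
    n_dropped = n_dropped,
    B = B,
    converged = full$converged,
    fitted_gt1 = fitted_gt1,
    model_matrix_names = colnames(X)
  ), class = "pfas_glm")
}

# Single weighted fit: weighted least squares for gaussian (exact, one
# step), IRLS via glm.fit otherwise. `start` warm-starts replicate
# refits.
glm_fit_engine <- function(X, y, w, fam, ctrl, start = NULL) {
  if (fam$family == "gaussian" && fam$link == "identity") {
    fit <- stats::lm.wfit(X, y, w)
    mu <- drop(X %*% fit$coefficients)
    return(list(coefficients = fit$coefficients, fitted.values = mu,
                deviance = sum(w * (y - mu)^2), converged = TRUE))
  }
  g <- stats::glm.fit(X, y, weights = w, family = fam, control = ctrl,
                      start = start)
  list(coefficients = g$coefficients, fitted.values = g$fitted.values,
       deviance = g$deviance, converged = g$converged)
}

#' @export
print.pfas_glm <- function(x, ...) {
  cat("survey-weighted", x$family, "GLM  (n =", x$n,
      ", variance:", x$vcov_type,
      if (x$B > 0) paste0(", B = ", x$B), ")\n")
  print(data.frame(estimate = x$coefficients, se = x$se,
                   lower = x$ci_lower, upper = x$ci_upper))
  invisible(x)
}

#' @export
coef.pfas_glm <- function(object, ...) object$coefficients

#' Prevalence ratio for a model term
#'
#' Exponentiates a coefficient (and its Wald CI) from a log-link
#' modified Poisson fit. For a log2-transformed exposure the PR is per
#' two-fold increase in concentration.
#'
#' @param fit a `pfas_glm` with `family = "poisson"`.
#' @param term coefficient name.
#' @return list with `pr`, `lower`, `upper`, `log_pr`, `se`.
#' @export
estimate_pr <- function(fit, term) {
  stopifnot(inherits(fit, "pfas_glm"))
  if (fit$family != "poisson") {
    stop_pfasmix("prevalence ratios require a log-link (poisson) fit")
  }
  if (!term %in% names(fit$coefficients)) {
    stop_pfasmix("term '", term, "' not in model (have: ",
                 paste(names(fit$coefficients), collapse = ", "), ")")
  }
  b <- fit$coefficients[[term]]
  list(pr = exp(b),
       lower = exp(fit$ci_lower[[term]]),
       upper = exp(fit$ci_upper[[term]]),
       log_pr = b,
       se = fit$se[[term]])
}
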