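#' Exposure panel: per-analyte concentrations with LOD metadata
#'
#' Bundles raw concentrations, per-analyte (or per-record) limits of
#' detection, non-detect flags and, after [impute_panel()], imputed
#' concentrations and fitted lognormal parameters. Non-detect
#' concentrations are stored as `NA` until imputation fills them in with
#' draws from a left-truncated lognormal below the LOD.
#'
#' @param conc data.frame or matrix of concentrations (µg/L), one column
#'   per analyte. Non-detect cells may be `NA`.
#' @param lod scalar, per-analyte named vector, or matrix of the same
#'   shape as `conc` (per-record LODs, e.g. cycle-specific), in µg/L.
#' @param nondetect optional logical matrix flagging censored cells; by
#'   default any `NA` in `conc` is treated as a non-detect.
#' @return An object of class `exposure_panel` with elements `conc`,
#'   `lod`, `nondetect`, `analytes`, `detection`, and (after fitting)
#'   `params` and `imputed`.
#' @export
exposure_panel <- function(conc, lod, nondetect = NULL) {
  conc <- as.data.frame(conc)
  analytes <- names(conc)
  if (length(analytes) == 0L) stop_pfasmix("panel has no analytes")
  n <- nrow(conc)

  lod_mat <- if (is.matrix(lod) || is.data.frame(lod)) {
    as.matrix(lod)
  } else if (length(lod) == 1L) {
    matrix(lod, n, length(analytes), dimnames = list(NULL, analytes))
  } else {
    if (is.null(names(lod))) names(lod) <- analytes
    if (!all(analytes %in% names(lod))) {
      stop_pfasmix("lod must be named for every analyte")
    }
    matrix(rep(lod[analytes], each = n), n, length(analytes),
           dimnames = list(NULL, analytes))
  }
  if (any(lod_mat < 0)) stop_pfasmix("LOD values must be >= 0")

  if (is.null(nondetect)) {
    nondetect <- is.na(as.matrix(conc))
  } else {
    nondetect <- as.matrix(nondetect)
  }
  colnames(nondetect) <- analytes

  detected <- !nondetect
  bad <- as.matrix(conc)[detected]
  if (any(!is.na(bad) & bad <= 0)) {
    stop_pfasmix("detected concentrations must be > 0")
  }

  structure(
    list(
      conc = conc,
      lod = lod_mat,
      nondetect = nondetect,
      analytes = analytes,
      detection = colMeans(detected),
      params = NULL,
      imputed = NULL
    ),
    class = "exposure_panel"
  )
}

#' @export
print.exposure_panel <- function(x, ...) {
  cat("exposure_panel:", nrow(x$conc), "records,",
      length(x$analytes), "analytes\n")
  df <- data.frame(
    analyte = x$analytes,
    detection = round(100 * x$detection, 1),
    lod = apply(x$lod, 2, function(v) paste(unique(signif(v, 3)), collapse = "/"))
  )
  print(df, row.names = FALSE)
  if (!is.null(x$params)) cat("lognormal fill-in parameters fitted\n")
  invisible(x)
}

#' Drop analytes detected in fewer than a threshold fraction of samples
#'
#' Retention uses an inclusive boundary: an analyte detected in exactly
#' `threshold` of samples is kept.
#'
#' @param panel an [exposure_panel()].
#' @param threshold minimum detection frequency (default 0.70).
#' @return The filtered panel; dropped analytes and their detection
#'   frequencies are recorded in `attr(, "dropped")` and messaged.
#' @export
filter_by_detection <- function(panel, threshold = 0.70) {
  stopifnot(inherits(panel, "exposure_panel"))
  keep <- panel$detection >= threshold
  if (!any(keep)) {
    stop_pfasmix("no analyte meets the detection threshold of ", threshold)
  }
  dropped <- data.frame(
    analyte = panel$analytes[!keep],
    detection = unname(panel$detection[!keep])
  )
  if (nrow(dropped) > 0L) {
    message("dropping ", nrow(dropped), " analyte(s) below ",
            round(100 * threshold, 1), "% detection: ",
            paste0(dropped$analyte, " (",
                   round(100 * dropped$detection, 1), "%)",
                   collapse = ", "))
  }
  out <- exposure_panel(
    panel$conc[, keep, drop = FALSE],
    panel$lod[, keep, drop = FALSE],
    panel$nondetect[, keep, drop = FALSE]
  )
  attr(out, "dropped") <- dropped
  out
}

#' Maximum-likelihood fit of a lognormal under left-censoring at the LOD
#'
#' Detected values contribute the lognormal density; non-detects
#' contribute the CDF at their LOD. With zero non-detects the fit
#' reduces to the closed-form MLE (mean and population SD of the logs).
#'
#' @param values concentrations (µg/L); censored entries may be `NA`.
#' @param nondetect logical vector of non-detect flags.
#' @param lod scalar or per-record LOD (µg/L).
#' @return list with `log_mean`, `log_sd`, `converged`, `n_detected`,
#'   `n_censored`.
#' @export
fit_censored_lognormal <- function(values, nondetect, lod) {
  nondetect <- as.logical(nondetect)
  n <- length(values)
  if (length(lod) == 1L) lod <- rep(lod, n)
  det <- which(!nondetect)
  cen <- which(nondetect)
  if (length(det) < 10L) {
    stop_pfasmix("need at least 10 detected values to fit (have ",
                 length(det), ")")
  }
  x <- values[det]
  if (any(is.na(x)) || any(x <= 0)) {
    stop_pfasmix("detected values must be positive and non-missing")
  }
  lx <- log(x)
  s0 <- sqrt(mean((lx - mean(lx))^2))
  if (s0 <= 0) {
    stop_pfasmix("degenerate data: detected values have zero log-variance")
  }

  if (length(cen) == 0L) {
    return(list(log_mean = mean(lx), log_sd = s0, converged = TRUE,
                n_detected = length(det), n_censored = 0L))
  }

  llod <- log(lod[cen])
  nll <- function(par) {
    mu <- par[1]
    s <- exp(par[2])
    -(sum(stats::dnorm(lx, mu, s, log = TRUE)) +
        sum(stats::pnorm(llod, mu, s, log.p = TRUE)))
  }
  fit <- stats::optim(c(mean(lx), log(s0 * 1.2)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    stop_pfasmix("censored lognormal MLE did not converge (optim code ",
                 fit$convergence, ", message: ",
                 fit$message %||% "none", ")")
  }
  list(log_mean = fit$par[1], log_sd = exp(fit$par[2]), converged = TRUE,
       n_detected = length(det), n_censored = length(cen))
}

#' Single "fill-in" imputation of non-detects from a truncated lognormal
#'
#' Each non-detect is replaced by one draw from the fitted lognormal
#' truncated to (0, LOD), via inverse-CDF sampling; detected values are
#' returned unchanged, bit for bit. Deterministic given `seed`.
#'
#' @param values concentrations (µg/L), censored entries may be `NA`.
#' @param nondetect logical non-detect flags.
#' @param lod scalar or per-record LOD (µg/L).
#' @param params fit from [fit_censored_lognormal()].
#' @param seed integer seed for the imputation draws.
#' @return numeric vector with non-detects filled in below their LOD.
#' @export
fill_in_impute <- function(values, nondetect, lod, params, seed) {
  if (is.null(params$log_mean) || is.null(params$log_sd)) {
    stop_pfasmix("params must come from fit_censored_lognormal()")
  }
  nondetect <- as.logical(nondetect)
  cen <- which(nondetect)
  out <- values
  if (length(cen) == 0L) return(out)
  if (length(lod) == 1L) lod <- rep(lod, length(values))
  p_lod <- stats::plnorm(lod[cen], params$log_mean, params$log_sd)
  u <- with_seed(seed, stats::runif(length(cen)))
  out[cen] <- stats::qlnorm(u * p_lod, params$log_mean, params$log_sd)
  # guard against qlnorm rounding exactly to the boundary
  out[cen] <- pmin(out[cen], lod[cen] * (1 - 1e-12))
  out
}

#' Fit and impute every analyte in a panel
#'
#' Fits the left-censored lognormal per analyte and fills in all
#' non-detects. Each analyte uses its own deterministic sub-stream of
#' `seed`, so adding or dropping an analyte does not perturb the draws
#' of the others.
#'
#' @param panel an [exposure_panel()].
#' @param seed integer seed.
#' @return the panel with `$imputed` (data.frame of complete
#'   concentrations) and `$params` (per-analyte fits, including the
#'   sub-seed used) populated.
#' @export
impute_panel <- function(panel, seed) {
  stopifnot(inherits(panel, "exposure_panel"))
  imputed <- panel$conc
  params <- vector("list", length(panel$analytes))
  names(params) <- panel$analytes
  for (j in seq_along(panel$analytes)) {
    a <- panel$analytes[j]
    fit <- fit_censored_lognormal(panel$conc[[a]], panel$nondetect[, a],
                                  panel$lod[, a])
    sub <- derive_seed(seed, j)
    imputed[[a]] <- fill_in_impute(panel$conc[[a]], panel$nondetect[, a],
                                   panel$lod[, a], fit, sub)
    fit$seed <- sub
    fit$lod <- unique(panel$lod[, a])
    fit$detection <- panel$detection[[a]]
    params[[a]] <- fit
  }
  panel$imputed <- imputed
  panel$params <- params
  panel
}

#' log2-transformed exposures and the summed-PFAS composite
#'
#' `log2_exposures()` returns per-analyte log2 concentrations;
#' `sum_pfas()` sums the (imputed) concentrations on the original µg/L
#' scale — the composite is log2-transformed only when it enters a
#' model.
#'
#' @param panel an imputed [exposure_panel()].
#' @return data.frame of log2 values, or a numeric vector of summed
#'   concentrations.
#' @export
log2_exposures <- function(panel) {
  x <- imputed_conc(panel)
  if (any(as.matrix(x) <= 0, na.rm = TRUE) || anyNA(x)) {
    stop_pfasmix("nonpositive or missing value reached log2 transform; ",
                 "imputation contract violated")
  }
  as.data.frame(lapply(x, log2))
}

#' @rdname log2_exposures
#' @export
sum_pfas <- function(panel) {
  x <- imputed_conc(panel)
  if (any(as.matrix(x) <= 0, na.rm = TRUE) || anyNA(x)) {
    stop_pfasmix("nonpositive or missing value in summed exposures; ",
                 "imputation contract violated")
  }
  rowSums(as.matrix(x))
}

imputed_conc <- function(panel) {
  stopifnot(inherits(panel, "exposure_panel"))
  if (!is.null(panel$imputed)) panel$imputed else panel$conc
}

#' Write imputation provenance as a sidecar metadata file
#'
#' @param panel an imputed panel.
#' @param path file to write (CSV).
#' @export
write_imputation_metadata <- function(panel, path) {
  stopifnot(inherits(panel, "exposure_panel"), !is.null(panel$params))
  meta <- do.call(rbind, lapply(panel$analytes, function(a) {
    p <- panel$params[[a]]
    data.frame(analyte = a,
               lod = paste(signif(p$lod, 6), collapse = ";"),
               detection = p$detection,
               log_mean = p$log_mean, log_sd = p$log_sd,
               n_detected = p$n_detected, n_censored = p$n_censored,
               seed = p$seed)
  }))
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(meta)
}
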