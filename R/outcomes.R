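#' Clinical threshold registry for the metabolic syndrome criteria
#'
#' Returns the harmonized adult thresholds used by [classify_mets()],
#' read from the versioned registry shipped in `inst/extdata/`
#' (`mets_thresholds_v1.csv`). Thresholds are stored in SI units:
#' cm for waist circumference, mmol/L for lipids and glucose, mmHg for
#' blood pressure, percent for HbA1c.
#'
#' @param version registry version (default "v1").
#' @return data.frame with columns `criterion`, `group`, `threshold`,
#'   `direction` ("ge" or "lt") and `unit`.
#' @export
mets_thresholds <- function(version = "v1") {
  path <- system.file("extdata",
                      paste0("mets_thresholds_", version, ".csv"),
                      package = "pfasmix")
  if (!nzchar(path)) stop_pfasmix("unknown threshold registry version: ", version)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

threshold_of <- function(reg, criterion, group) {
  row <- reg[reg$criterion == criterion & reg$group == group, ]
  if (nrow(row) != 1L) {
    stop_pfasmix("threshold registry has no unique entry for ",
                 criterion, "/", group)
  }
  row$threshold
}

#' Classify metabolic syndrome from measured criteria, medications and
#' prior diagnoses
#'
#' MetS is positive when three or more of five criteria are met:
#' central obesity (waist circumference, with lower cut-offs for Asian
#' ethnicity), elevated triglycerides, reduced HDL cholesterol
#' (sex-specific), elevated blood pressure (systolic and/or diastolic),
#' and hyperglycemia (HbA1c by default, substituting fasting glucose).
#' Each criterion is also met when the corresponding medication is
#' taken, and the blood-pressure / glycemia criteria additionally when
#' a prior hypertension / type-2-diabetes diagnosis is reported. All
#' threshold comparisons are inclusive for "≥"-type criteria and strict
#' for the "<"-type HDL criterion.
#'
#' @param data data.frame with columns `sex` ("male"/"female"),
#'   `asian` (logical), `wc`, `tg`, `hdl`, `sbp`, `dbp`, `hba1c`
#'   (and `glu` when `glycemia = "glucose"`), plus logical flags
#'   `med_lipid`, `med_bp`, `med_diabetes`, `dx_htn`, `dx_t2d`.
#' @param thresholds registry from [mets_thresholds()].
#' @param glycemia which glycemia measure drives the fifth criterion;
#'   `"hba1c"` (default) or `"glucose"` (non-fasting serum glucose,
#'   auxiliary only — never a CMRS component).
#' @return data.frame of the five criterion booleans, `n_criteria` and
#'   `mets`.
#' @export
classify_mets <- function(data, thresholds = mets_thresholds(),
                          glycemia = c("hba1c", "glucose")) {
  glycemia <- match.arg(glycemia)
  need <- c("sex", "asian", "wc", "tg", "hdl", "sbp", "dbp",
            if (glycemia == "hba1c") "hba1c" else "glu",
            "med_lipid", "med_bp", "med_diabetes", "dx_htn", "dx_t2d")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_pfasmix("missing columns: ", paste(miss, collapse = ", "))
  sub <- data[, need]
  if (anyNA(sub)) {
    stop_pfasmix("classify_mets requires complete cases; ",
                 sum(!stats::complete.cases(sub)),
                 " record(s) have missing inputs — exclude them upstream")
  }
  male <- data$sex == "male"
  asian <- as.logical(data$asian)
  reg <- thresholds

  wc_cut <- ifelse(male,
                   ifelse(asian, threshold_of(reg, "wc", "male_asian"),
                          threshold_of(reg, "wc", "male")),
                   ifelse(asian, threshold_of(reg, "wc", "female_asian"),
                          threshold_of(reg, "wc", "female")))
  hdl_cut <- ifelse(male, threshold_of(reg, "hdl", "male"),
                    threshold_of(reg, "hdl", "female"))

  wc_high <- data$wc >= wc_cut
  tg_high <- data$tg >= threshold_of(reg, "tg", "all") | data$med_lipid
  hdl_low <- data$hdl < hdl_cut | data$med_lipid
  bp_high <- data$sbp >= threshold_of(reg, "sbp", "all") |
    data$dbp >= threshold_of(reg, "dbp", "all") |
    data$med_bp | data$dx_htn
  glyc_high <- if (glycemia == "hba1c") {
    data$hba1c >= threshold_of(reg, "hba1c", "all")
  } else {
    data$glu >= threshold_of(reg, "glu", "all")
  }
  glyc_high <- glyc_high | data$med_diabetes | data$dx_t2d

  n_criteria <- wc_high + tg_high + hdl_low + bp_high + glyc_high
  data.frame(wc_high = wc_high, tg_high = tg_high, hdl_low = hdl_low,
             bp_high = bp_high, glyc_high = glyc_high,
             n_criteria = n_criteria, mets = n_criteria >= 3L)
}

#' Age- and sex-standardized residual Z-scores for a cardiometabolic
#' risk factor
#'
#' Fits a (survey-weighted) linear regression of the risk factor on age
#' (linear) and sex, and returns residuals scaled by their weighted SD,
#' so the returned Z-scores have weighted mean 0 and weighted SD 1 in
#' the standardization sample.
#'
#' @param values numeric risk-factor measurements (complete).
#' @param age age in years.
#' @param sex factor/character with two levels.
#' @param weights survey weights; `NULL` for unweighted standardization.
#' @return numeric vector of Z-scores.
#' @export
standardize_cmrf <- function(values, age, sex, weights = NULL) {
  n <- length(values)
  if (n < 50L) stop_pfasmix("standardization needs n >= 50 (have ", n, ")")
  if (anyNA(values) || anyNA(age) || anyNA(sex)) {
    stop_pfasmix("standardize_cmrf requires complete inputs")
  }
  w <- if (is.null(weights)) rep(1, n) else weights
  X <- stats::model.matrix(~ age + sex,
                           data.frame(age = age, sex = as.factor(sex)))
  fit <- stats::lm.wfit(X, values, w)
  r <- fit$residuals
  s <- sqrt(sum(w * r^2) / sum(w))
  if (s < 1e-10) {
    stop_pfasmix("zero residual variance: risk factor is an exact ",
                 "function of age and sex")
  }
  r / s
}

#' Continuous cardiometabolic risk score (CMRS)
#'
#' Combines five standardized risk-factor Z-scores. The mean-arterial-
#' pressure Z-score is zMAP = zDBP + (zSBP − zDBP)/3; HDL enters with a
#' negative sign for its protective effect; the sum is divided by the
#' square root of the number of risk factors (5) to preserve the
#' Z-score scale.
#'
#' @param z data.frame (or list) with `zWC`, `zHbA1c`, `zTG`, `zHDL`,
#'   and either `zMAP` or both `zSBP` and `zDBP`.
#' @return data.frame with `zMAP` and `cmrs`.
#' @export
compute_cmrs <- function(z) {
  zmap <- if (!is.null(z$zMAP)) {
    z$zMAP
  } else {
    if (is.null(z$zSBP) || is.null(z$zDBP)) {
      stop_pfasmix("need zMAP or both zSBP and zDBP")
    }
    z$zDBP + (z$zSBP - z$zDBP) / 3
  }
  for (nm in c("zWC", "zHbA1c", "zTG", "zHDL")) {
    if (is.null(z[[nm]])) stop_pfasmix("missing Z-score: ", nm)
  }
  n_cmrf <- 5
  cmrs <- (z$zWC + z$zHbA1c + z$zTG - z$zHDL + zmap) / sqrt(n_cmrf)
  data.frame(zMAP = zmap, cmrs = cmrs)
}

#' Back-transform a log2-scale coefficient to a percent difference
#'
#' A coefficient `beta` from a model of a log2-transformed outcome is
#' reported as the percent difference (2^beta − 1) · 100 per one-unit
#' increase of the predictor. [percent_to_log2()] is the exact inverse.
#'
#' @param beta coefficient on the log2 scale.
#' @return percent difference.
#' @export
back_transform_percent <- function(beta) {
  stopifnot(all(is.finite(beta)))
  (2^beta - 1) * 100
}

#' @rdname back_transform_percent
#' @param pct percent difference.
#' @export
percent_to_log2 <- function(pct) log2(1 + pct / 100)

#' Derive all analysis outcomes on a cohort table
#'
#' Adds the MetS classification (criterion booleans, count, `mets`),
#' the standardized Z-scores of the five CMRS components, `zMAP` and
#' `cmrs` to a cohort table. Standardization is survey-weighted by
#' default (using the `weight` column) and computed on the supplied
#' (analytic) sample.
#'
#' @param cohort cohort data.frame (see [generate_cohort()] for the
#'   column schema).
#' @param weighted use survey-weighted standardization (default TRUE).
#' @param glycemia glycemia measure for the MetS classifier.
#' @return the cohort with outcome columns appended.
#' @export
derive_outcomes <- function(cohort, weighted = TRUE,
                            glycemia = c("hba1c", "glucose")) {
  glycemia <- match.arg(glycemia)
  cls <- classify_mets(cohort, glycemia = glycemia)
  w <- if (weighted) cohort$weight else NULL
  z <- data.frame(
    zWC    = standardize_cmrf(cohort$wc,    cohort$age, cohort$sex, w),
    zHbA1c = standardize_cmrf(cohort$hba1c, cohort$age, cohort$sex, w),
    zTG    = standardize_cmrf(cohort$tg,    cohort$age, cohort$sex, w),
    zHDL   = standardize_cmrf(cohort$hdl,   cohort$age, cohort$sex, w),
    zSBP   = standardize_cmrf(cohort$sbp,   cohort$age, cohort$sex, w),
    zDBP   = standardize_cmrf(cohort$dbp,   cohort$age, cohort$sex, w)
  )
  cm <- compute_cmrs(z)
  out <- cbind(cohort, cls, z, cm)
  # cbind drops non-standard attributes; keep the pipeline's metadata
  for (a in c("panel", "truth", "detection", "lod", "schema")) {
    attr(out, a) <- attr(cohort, a)
  }
  out
}
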