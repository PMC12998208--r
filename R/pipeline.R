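#' Build the covariate adjustment set for a model
#'
#' Encodes the adjustment rules of the analysis: a base set of
#' sociodemographic and lifestyle covariates plus survey cycle; age is
#' added except for CMRS models (whose components are already age- and
#' sex-standardized); sex is added only in total-population models;
#' female-only models additionally adjust for parity.
#'
#' @param outcome outcome name (`"mets"`, `"cmrs"`, or a risk factor
#'   such as `"hba1c"`).
#' @param stratum `"total"`, `"males"` or `"females"`.
#' @return character vector of covariate column names.
#' @export
build_adjustment_set <- function(outcome, stratum) {
  if (!stratum %in% c("total", "males", "females")) {
    stop_pfasmix("unknown stratum: ", stratum)
  }
  base <- c("ethnicity", "education", "smoking", "marital",
            "country_of_birth", "mvpa", "fish", "cycle")
  covs <- base
  if (outcome != "cmrs") {
    covs <- c("age", covs)
    if (stratum == "total") covs <- c(covs, "sex")
  }
  if (stratum == "females") covs <- c(covs, "parity")
  covs
}

med_rule_for <- function(outcome) {
  switch(outcome,
         tg = , hdl = "med_lipid",
         sbp = , dbp = "med_bp",
         glu = , hba1c = "med_diabetes",
         cmrs = c("med_lipid", "med_bp", "med_diabetes"),
         NULL)
}

#' Apply participant exclusions for a model, with an audit trail
#'
#' Pregnant participants and those with type-1 diabetes are always
#' excluded. When `exclude_medicated` is `TRUE`, users of the
#' medication class matched to the outcome are also excluded
#' (lipid-lowering for TG/HDL, antihypertensive for SBP/DBP, diabetes
#' medication for GLU/HbA1c; all three classes for the CMRS sensitivity
#' variant). Audit counts are incremental — each rule counts only rows
#' not already removed by an earlier rule — so they sum to the total
#' removed with no double counting.
#'
#' @param cohort cohort data.frame.
#' @param outcome outcome name (drives the medication rule).
#' @param exclude_medicated apply the medication-class exclusion.
#' @return list with `data` (the analytic subset), `keep` (logical row
#'   filter) and `audit` (named counts).
#' @export
apply_exclusions <- function(cohort, outcome, exclude_medicated = FALSE) {
  n_in <- nrow(cohort)
  drop_preg <- cohort$pregnant %in% TRUE
  drop_t1d <- !drop_preg & cohort$t1d %in% TRUE
  drop_med <- rep(FALSE, n_in)
  if (exclude_medicated) {
    rule <- med_rule_for(outcome)
    if (!is.null(rule)) {
      med <- Reduce(`|`, lapply(rule, function(r) cohort[[r]] %in% TRUE))
      drop_med <- !drop_preg & !drop_t1d & med
    }
  }
  keep <- !(drop_preg | drop_t1d | drop_med)
  audit <- c(n_in = n_in,
             dropped_pregnant = sum(drop_preg),
             dropped_t1d = sum(drop_t1d),
             dropped_medication = sum(drop_med),
             n_out = sum(keep))
  list(data = cohort[keep, , drop = FALSE], keep = keep, audit = audit)
}

#' Impute and transform the PFAS exposures of a cohort table
#'
#' Builds an [exposure_panel()] from the cohort's analyte columns,
#' applies the detection-frequency retention rule, fits the
#' left-censored lognormal per retained analyte, fills in non-detects,
#' and writes back imputed concentrations plus `log2_<analyte>`
#' columns, the summed-PFAS composite `sum_pfas` (µg/L) and its log2
#' transform `log2_sum_pfas`.
#'
#' @param cohort cohort with analyte columns and `nd_*` flags (e.g.
#'   from [censor_below_lod()]).
#' @param lod named per-analyte LOD vector; defaults to the cohort's
#'   `lod` attribute, falling back to [default_pfas_params()].
#' @param threshold detection-frequency retention threshold.
#' @param seed integer seed for the imputation draws.
#' @return the cohort with imputed/transformed exposure columns; the
#'   fitted panel is attached as attribute `panel`.
#' @export
prepare_exposures <- function(cohort, lod = NULL, threshold = 0.70,
                              seed = 1L) {
  dp <- default_pfas_params()
  analytes <- intersect(dp$analyte, names(cohort))
  if (length(analytes) == 0L) stop_pfasmix("cohort has no analyte columns")
  if (is.null(lod)) {
    lod <- attr(cohort, "lod") %||%
      stats::setNames(dp$lod, dp$analyte)[analytes]
  }
  nd <- sapply(paste0("nd_", analytes), function(cn) {
    cohort[[cn]] %||% rep(FALSE, nrow(cohort))
  })
  colnames(nd) <- analytes
  panel <- exposure_panel(cohort[, analytes, drop = FALSE],
                          lod[analytes], nd)
  panel <- filter_by_detection(panel, threshold)
  panel <- impute_panel(panel, seed)

  kept <- panel$analytes
  cohort[kept] <- panel$imputed
  l2 <- log2_exposures(panel)
  names(l2) <- paste0("log2_", kept)
  cohort[names(l2)] <- l2
  cohort$sum_pfas <- sum_pfas(panel)
  cohort$log2_sum_pfas <- log2(cohort$sum_pfas)
  attr(cohort, "panel") <- panel
  cohort
}

term_of <- function(cov) if (cov == "cycle") "factor(cycle)" else cov

battery_outcomes <- function() {
  c("mets", "cmrs", "wc", "tg", "hdl", "sbp", "dbp", "hba1c")
}

outcome_kind <- function(outcome) {
  switch(outcome, mets = "binary", cmrs = "cmrs", "log2cmrf")
}

#' Run the full battery of mixture and single-pollutant models
#'
#' For every stratum (total, males, females) and outcome, fits one
#' quantile-g-computation mixture model, one survey-weighted model per
#' individual analyte (log2-transformed), and one summed-PFAS model —
#' the modified Poisson prevalence-ratio engine for metabolic syndrome
#' and the gaussian engine for CMRS (raw scale) and each risk factor
#' (log2 scale, reported as percent difference). For the six
#' medication-linked risk factors the primary variant excludes users of
#' the matched medication class; an everyone-included complement is
#' always emitted as a named sensitivity variant (and conversely the
#' CMRS gains a medication-excluded sensitivity variant).
#'
#' @param cohort prepared cohort: exposures imputed
#'   ([prepare_exposures()]) and outcomes derived ([derive_outcomes()]).
#' @param design a [survey_design()] aligned to `cohort` rows.
#' @param outcomes outcomes to model (default the standard eight).
#' @param strata strata to run (default all three).
#' @param q number of exposure quantiles (default 4: quartiles).
#' @param analytes analyte columns forming the mixture.
#' @return object of class `pfas_battery`: `results` (tidy data.frame,
#'   one row per model), `audit` (per-model exclusion counts) and
#'   `metadata`.
#' @export
run_battery <- function(cohort, design, outcomes = battery_outcomes(),
                        strata = c("total", "males", "females"), q = 4,
                        analytes = intersect(default_pfas_params()$analyte,
                                             names(cohort))) {
  stopifnot(inherits(design, "survey_design"),
            nrow(cohort) == design$n)
  if ("mets" %in% outcomes && !"mets" %in% names(cohort)) {
    stop_pfasmix("cohort lacks derived outcomes; run derive_outcomes() first")
  }
  results <- list()
  audits <- list()
  failures <- character(0)

  for (stratum in strata) {
    in_stratum <- switch(stratum,
                         total = rep(TRUE, nrow(cohort)),
                         males = cohort$sex == "male",
                         females = cohort$sex == "female")
    for (outcome in outcomes) {
      covs <- build_adjustment_set(outcome, stratum)
      miss <- setdiff(covs, names(cohort))
      if (length(miss)) {
        stop_pfasmix("stratum '", stratum, "', outcome '", outcome,
                     "': missing covariate column(s): ",
                     paste(miss, collapse = ", "))
      }
      variants <- battery_variants(outcome)
      for (variant in names(variants)) {
        med_excl <- variants[[variant]]
        sub0 <- cohort[in_stratum, , drop = FALSE]
        des0 <- subset_design(design, which(in_stratum))
        excl <- apply_exclusions(sub0, outcome, med_excl)
        dd <- excl$data
        des1 <- subset_design(des0, which(excl$keep))

        model_vars <- c(outcome, covs, analytes,
                        paste0("log2_", analytes), "log2_sum_pfas")
        cc <- stats::complete.cases(dd[, model_vars, drop = FALSE])
        n_incomplete <- sum(!cc)
        dd <- dd[cc, , drop = FALSE]
        des1 <- subset_design(des1, which(cc))

        audit <- c(stratum = stratum, outcome = outcome,
                   variant = variant, excl$audit,
                   dropped_incomplete = n_incomplete,
                   n_model = nrow(dd))
        audits[[length(audits) + 1L]] <- audit

        family <- if (outcome == "mets") "poisson" else "gaussian"
        kind <- outcome_kind(outcome)
        dd$.y <- switch(kind,
                        binary = as.integer(dd$mets),
                        cmrs = dd$cmrs,
                        log2cmrf = log2(dd[[outcome]]))
        cov_terms <- vapply(covs, term_of, character(1))

        mk_row <- function(engine, analyte_label, expr) {
          res <- tryCatch(expr, error = function(e) e)
          if (inherits(res, "error")) {
            failures <<- c(failures, paste0(
              stratum, "/", outcome, "/", variant, "/", engine, "/",
              analyte_label, ": ", conditionMessage(res)))
            return(NULL)
          }
          cbind(data.frame(stratum = stratum, outcome = outcome,
                           variant = variant, engine = engine,
                           analyte = analyte_label,
                           stringsAsFactors = FALSE),
                res)
        }

        rows <- list(
          mk_row("qgcomp", "mixture",
                 qgcomp_row(dd, covs = cov_terms, analytes = analytes,
                            family = family, design = des1, q = q,
                            kind = kind)),
          mk_row("sum_pfas", "sum5pfas",
                 single_row(dd, "log2_sum_pfas", cov_terms, family,
                            des1, kind))
        )
        for (a in analytes) {
          rows[[length(rows) + 1L]] <- mk_row(
            "single", toupper(a),
            single_row(dd, paste0("log2_", a), cov_terms, family,
                       des1, kind))
        }
        results <- c(results, Filter(Negate(is.null), rows))
      }
    }
  }

  results_df <- do.call(rbind, lapply(results, pad_row,
                                      analytes = analytes))
  results_df$model_id <- sprintf("M%03d", seq_len(nrow(results_df)))
  audit_df <- as.data.frame(do.call(rbind, audits),
                            stringsAsFactors = FALSE)
  for (cn in setdiff(names(audit_df), c("stratum", "outcome", "variant"))) {
    audit_df[[cn]] <- as.integer(audit_df[[cn]])
  }
  structure(list(
    results = results_df,
    audit = audit_df,
    failures = failures,
    metadata = list(
      package_version = as.character(utils::packageVersion("pfasmix")),
      q = q, B = design$B, outcomes = outcomes, strata = strata,
      analytes = analytes,
      estimator = "conditional sum-of-coefficients qgcomp",
      glycemia = "hba1c",
      variance = if (design$B > 0) "bootstrap replicate weights"
                 else "robust sandwich (HC0)"
    )
  ), class = "pfas_battery")
}

battery_variants <- function(outcome) {
  if (outcome == "mets") {
    list(main = FALSE)
  } else if (outcome == "cmrs") {
    list(main = FALSE, med_excluded = TRUE)
  } else {
    # medication-linked risk factors: exclusion is the primary variant
    list(main = TRUE, all_included = FALSE)
  }
}

qgcomp_row <- function(dd, covs, analytes, family, design, q, kind) {
  fit <- fit_qgcomp(dd, ".y", exposures = analytes, covariates = covs,
                    family = family, design = design, q = q)
  summarize_mixture(fit, kind, analyte_order = analytes)
}

single_row <- function(dd, exposure, covs, family, design, kind) {
  fml <- stats::as.formula(paste(".y ~", paste(c(exposure, covs),
                                               collapse = " + ")))
  fit <- fit_weighted_glm(fml, dd, family = family, design = design)
  b <- fit$coefficients[[exposure]]
  lo <- fit$ci_lower[[exposure]]
  hi <- fit$ci_upper[[exposure]]
  tr <- switch(kind,
    binary = list(est = exp(b), lo = exp(lo), hi = exp(hi), type = "PR"),
    cmrs = list(est = b, lo = lo, hi = hi, type = "mean_difference"),
    log2cmrf = list(est = back_transform_percent(b),
                    lo = back_transform_percent(lo),
                    hi = back_transform_percent(hi),
                    type = "percent_difference"))
  data.frame(estimate_type = tr$type, estimate = tr$est, lcl = tr$lo,
             ucl = tr$hi, psi = b, se = fit$se[[exposure]], n = fit$n,
             B = fit$B, stringsAsFactors = FALSE)
}

# qgcomp rows carry weight columns; pad the others with NA so rbind works
pad_row <- function(row, analytes) {
  wcols <- c(paste0("w_pos_", analytes), paste0("w_neg_", analytes))
  for (cn in wcols) if (is.null(row[[cn]])) row[[cn]] <- NA_real_
  row[, c("stratum", "outcome", "variant", "engine", "analyte",
          "estimate_type", "estimate", "lcl", "ucl", "psi", "se",
          "n", "B", wcols)]
}

#' @export
print.pfas_battery <- function(x, ...) {
  cat("pfas_battery:", nrow(x$results), "model rows (",
      sum(x$results$variant == "main"), "primary ),",
      length(x$failures), "failure(s)\n")
  invisible(x)
}

#' Write a battery result bundle to disk
#'
#' Emits `results.csv` (tidy model rows in the shape of the result
#' tables), `audit.csv` (per-model exclusion accounting),
#' `metadata.json` and, on failures, `failures.txt`. Output is
#' byte-reproducible for a fixed cohort/design.
#'
#' @param battery a [run_battery()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_battery <- function(battery, dir) {
  stopifnot(inherits(battery, "pfas_battery"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(battery$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(battery$audit, file.path(dir, "audit.csv"),
                   row.names = FALSE)
  jsonlite::write_json(battery$metadata,
                       file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(battery$failures)) {
    writeLines(battery$failures, file.path(dir, "failures.txt"))
  }
  invisible(dir)
}

#' End-to-end pipeline: simulate, censor, impute, derive, fit, report
#'
#' Runs the whole chain on a synthetic cohort: generation with known
#' ground truth, LOD censoring, detection filtering and fill-in
#' imputation, outcome derivation, replicate-weight construction, the
#' full model battery, and (optionally) the result bundle on disk.
#' Fully deterministic given `seed`.
#'
#' @param config a [cohort_config()]; its own seed is overridden by a
#'   sub-stream of `seed`.
#' @param seed master seed for the run.
#' @param outdir if non-NULL, [write_battery()] target directory.
#' @param q exposure quantiles for the mixture models.
#' @return the `pfas_battery`, with the prepared cohort and design
#'   attached as attributes `cohort` and `design`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L,
                         outdir = NULL, q = 4) {
  config$seed <- derive_seed(seed, 1L)
  cohort <- generate_cohort(config)
  cohort <- censor_below_lod(
    cohort, stats::setNames(config$pfas$lod, config$pfas$analyte))
  cohort <- prepare_exposures(cohort, seed = derive_seed(seed, 2L))
  cohort <- derive_outcomes(cohort)
  design <- generate_replicate_weights(cohort, config$n_replicates,
                                       seed = derive_seed(seed, 3L))
  battery <- run_battery(cohort, design, q = q)
  if (!is.null(outdir)) write_battery(battery, outdir)
  attr(battery, "cohort") <- cohort
  attr(battery, "design") <- design
  battery
}
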