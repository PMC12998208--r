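# Shared fixture builders: all data is generated in code at test time.

# a MetS classifier record with every input at a harmless level
base_record <- function(...) {
  rec <- data.frame(
    sex = "male", asian = FALSE,
    wc = 90, tg = 1.0, hdl = 1.5, sbp = 115, dbp = 70, hba1c = 5.0,
    glu = 5.0,
    med_lipid = FALSE, med_bp = FALSE, med_diabetes = FALSE,
    dx_htn = FALSE, dx_t2d = FALSE,
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  rec
}

# small iid regression dataset with known coefficients
toy_regression <- function(n = 200, beta = c(1, 0.5), seed = 1,
                           weight_cv = 0.3) {
  set.seed(seed)
  x <- rnorm(n)
  y <- beta[1] + beta[2] * x + rnorm(n)
  w <- rlnorm(n, sdlog = sqrt(log(1 + weight_cv^2)))
  data.frame(x = x, y = y, w = w)
}

# default-config cohort, censored + imputed + outcomes derived, quietly
prepared_cohort <- function(n = 2000, seed = 1, ...) {
  cfg <- cohort_config(n_participants = n, seed = seed, ...)
  co <- suppressMessages(generate_cohort(cfg))
  co <- suppressMessages(censor_below_lod(
    co, stats::setNames(cfg$pfas$lod, cfg$pfas$analyte)))
  co <- suppressMessages(prepare_exposures(co, seed = seed + 1000L))
  derive_outcomes(co)
}

pfas_names <- function() default_pfas_params()$analyte
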