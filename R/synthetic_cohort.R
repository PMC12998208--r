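#' Canonical PFAS analyte set and marginal parameters
#'
#' Five plasma PFAS with sex-specific geometric means (µg/L),
#' geometric SDs and limits of detection typical of a general adult
#' population: males carry higher concentrations, most analytes are
#' detected in > 95% of samples, and PFDA sits close to its LOD with
#' roughly 18% non-detects.
#'
#' @return data.frame with one row per analyte.
#' @export
default_pfas_params <- function() {
  data.frame(
    analyte = c("pfoa", "pfos", "pfhxs", "pfda", "pfna"),
    label = c("PFOA", "PFOS", "PFHxS", "PFDA", "PFNA"),
    gm_male = c(2.0, 5.2, 1.6, 0.20, 0.60),
    gm_female = c(1.6, 3.2, 0.8, 0.18, 0.50),
    gsd = c(1.7, 2.0, 2.2, 1.9, 1.8),
    lod = c(0.08, 0.30, 0.10, 0.105, 0.09),
    stringsAsFactors = FALSE
  )
}

#' Default between-analyte Spearman correlation target
#'
#' Moderate-to-strong rank correlations (0.3–0.8), strongest within the
#' long-chain carboxylates (PFDA–PFNA) and the legacy pair PFOA–PFOS.
#'
#' @return symmetric 5 × 5 matrix with unit diagonal.
#' @export
default_spearman <- function() {
  a <- c("pfoa", "pfos", "pfhxs", "pfda", "pfna")
  m <- diag(5)
  dimnames(m) <- list(a, a)
  set_pair <- function(i, j, v) {
    m[i, j] <<- v
    m[j, i] <<- v
  }
  set_pair("pfoa", "pfos", 0.70)
  set_pair("pfoa", "pfhxs", 0.60)
  set_pair("pfoa", "pfda", 0.40)
  set_pair("pfoa", "pfna", 0.60)
  set_pair("pfos", "pfhxs", 0.65)
  set_pair("pfos", "pfda", 0.50)
  set_pair("pfos", "pfna", 0.60)
  set_pair("pfhxs", "pfda", 0.30)
  set_pair("pfhxs", "pfna", 0.45)
  set_pair("pfda", "pfna", 0.70)
  m
}

# Per-outcome marginal targets on the natural scale (population means /
# SDs by sex) and a default age slope on the log2 modelling scale.
# share_latent is the fraction of log2-scale SD carried by the shared
# "metabolic risk" factor that correlates the risk factors within a
# person (negative loading for the protective HDL). Means are
# calibrated jointly so the emergent MetS prevalence under the default
# configuration sits near the 27% target (medication and diagnosis
# flags are independent of the measurements here, so the measured tails
# must be leaner than the survey-table means they are derived from).
default_cmrf_params <- function() {
  data.frame(
    outcome = c("wc", "tg", "hdl", "glu", "sbp", "dbp", "hba1c"),
    mean_male   = c(90.4, 1.38, 1.37, 5.22, 107.5, 69.2, 5.25),
    mean_female = c(84.7, 1.15, 1.68, 4.91, 105.7, 65.5, 5.17),
    sd_male     = c(14.0, 0.76, 0.36, 1.08, 14, 9, 0.67),
    sd_female   = c(16.3, 0.65, 0.43, 1.29, 17, 11, 0.73),
    age_coef    = c(0.0020, 0.0030, 0.0000, 0.0015, 0.0025, 0.0010, 0.0020),
    share_latent = c(0.55, 0.55, -0.45, 0.55, 0.55, 0.55, 0.55),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic survey cohort generator
#'
#' Collects every data-generating parameter: sample size, sex-specific
#' lognormal PFAS marginals with a rank-correlation target, ground-truth
#' joint mixture effects per outcome (on the log2 modelling scale, per
#' one-quartile increase in all exposures), per-analyte shares of that
#' effect, medication/diagnosis prevalences, and the survey design
#' (cluster count, replicate weights). Defaults emulate a pooled
#' multi-cycle national health-measures sample of adults aged 20–79.
#'
#' @param n_participants number of participants.
#' @param seed integer RNG seed; the generator is fully deterministic
#'   given the config and seed.
#' @param sex_fraction_female proportion female.
#' @param pfas data.frame as [default_pfas_params()].
#' @param spearman_target symmetric positive-semidefinite rank-
#'   correlation matrix for the PFAS copula.
#' @param true_psi named vector of ground-truth joint effects per
#'   outcome (`wc`, `tg`, `hdl`, `glu`, `sbp`, `dbp`, `hba1c`), on the
#'   log2 scale of that outcome per one-quartile increase in all
#'   exposures. Default all zero (null mixture effect).
#' @param true_weights named per-analyte shares of the joint effect;
#'   nonnegative, summing to 1.
#' @param covariate_effects optional list: per outcome, a named vector
#'   of log2-scale coefficients for `age` (per year, centered at 50),
#'   `smoking` (ever vs never), `fish` (per meal/month, centered at 8)
#'   and `mvpa` (per min/day, centered at 23); unspecified outcomes
#'   keep the default age slopes.
#' @param noise_sd optional named vector overriding the residual SD of
#'   an outcome on its log2 modelling scale.
#' @param med_prevalence named vector: probabilities of lipid-lowering,
#'   antihypertensive and diabetes medication use.
#' @param dx_prevalence named vector: prior hypertension and type-2-
#'   diabetes diagnosis probabilities.
#' @param n_sites number of collection-site clusters (single stratum).
#' @param n_replicates number of bootstrap replicate weights B.
#' @param weight_cv coefficient of variation of the survey weights.
#' @return validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 2000,
                          seed = 1L,
                          sex_fraction_female = 0.52,
                          pfas = default_pfas_params(),
                          spearman_target = default_spearman(),
                          true_psi = NULL,
                          true_weights = NULL,
                          covariate_effects = NULL,
                          noise_sd = NULL,
                          med_prevalence = c(lipid = 0.20, bp = 0.21,
                                             diabetes = 0.07),
                          dx_prevalence = c(htn = 0.14, t2d = 0.05),
                          n_sites = 16L,
                          n_replicates = 500L,
                          weight_cv = 0.3) {
  analytes <- pfas$analyte
  outcomes <- default_cmrf_params()$outcome
  if (is.null(true_psi)) {
    true_psi <- stats::setNames(rep(0, length(outcomes)), outcomes)
  } else {
    full <- stats::setNames(rep(0, length(outcomes)), outcomes)
    bad <- setdiff(names(true_psi), outcomes)
    if (length(bad)) stop_pfasmix("unknown outcome(s) in true_psi: ",
                                  paste(bad, collapse = ", "))
    full[names(true_psi)] <- true_psi
    true_psi <- full
  }
  if (is.null(true_weights)) {
    true_weights <- stats::setNames(rep(1 / length(analytes),
                                        length(analytes)), analytes)
  }
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    sex_fraction_female = sex_fraction_female,
    pfas = pfas,
    spearman_target = spearman_target,
    true_psi = true_psi,
    true_weights = true_weights,
    covariate_effects = covariate_effects,
    noise_sd = noise_sd,
    med_prevalence = med_prevalence,
    dx_prevalence = dx_prevalence,
    n_sites = as.integer(n_sites),
    n_replicates = as.integer(n_replicates),
    weight_cv = weight_cv
  ), class = "cohort_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  p <- cfg$pfas
  if (any(p$gm_male <= 0) || any(p$gm_female <= 0) || any(p$gsd <= 0) ||
      any(p$lod < 0)) {
    stop_pfasmix("PFAS geometric means and GSDs must be > 0, LODs >= 0")
  }
  S <- cfg$spearman_target
  if (!isTRUE(all.equal(S, t(S))) || any(abs(diag(S) - 1) > 1e-12)) {
    stop_pfasmix("spearman_target must be symmetric with unit diagonal")
  }
  P <- spearman_to_pearson(S)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_pfasmix("spearman_target is not positive semidefinite after the ",
                 "Gaussian-copula conversion (min eigenvalue ",
                 signif(min(ev), 4), ")")
  }
  if (any(cfg$true_weights < 0) ||
      abs(sum(cfg$true_weights) - 1) > 1e-8) {
    stop_pfasmix("true_weights must be nonnegative and sum to 1")
  }
  probs <- c(cfg$sex_fraction_female, cfg$med_prevalence,
             cfg$dx_prevalence)
  if (any(probs < 0) || any(probs > 1)) {
    stop_pfasmix("all prevalences/proportions must be in [0, 1]")
  }
  if (cfg$n_replicates < 1L) stop_pfasmix("n_replicates must be >= 1")
  if (cfg$n_sites < 2L) stop_pfasmix("n_sites must be >= 2")
  invisible(cfg)
}

# Gaussian-copula conversion: Pearson correlation reproducing a target
# Spearman correlation for continuous marginals.
spearman_to_pearson <- function(S) 2 * sin(pi * S / 6)

#' Generate a synthetic survey cohort with known ground truth
#'
#' Draws correlated lognormal PFAS exposures through a Gaussian copula
#' (rank correlations converge to `spearman_target`), sociodemographic
#' covariates with realistic marginals, and continuous cardiometabolic
#' risk factors from a linear model on the quantized joint exposure
#' index — so the quantile-g-computation estimand equals `true_psi`
#' exactly. Metabolic syndrome status is NOT drawn directly: it emerges
#' from applying [classify_mets()] to the generated measurements and
#' medication/diagnosis flags, and lands near the calibrated target
#' prevalence of ~27% under the default configuration.
#'
#' @param config a [cohort_config()].
#' @return data.frame (one row per participant) following the schema in
#'   `inst/extdata/cohort_schema_v1.csv`, with an attribute `truth`
#'   carrying the generating `psi`, `weights` and the per-participant
#'   joint exposure index.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_participants
  p <- cfg$pfas
  analytes <- p$analyte

  # --- design + demographics -------------------------------------------
  sex <- ifelse(stats::runif(n) < cfg$sex_fraction_female,
                "female", "male")
  female <- sex == "female"
  age <- qtrunc_norm(stats::runif(n), 49.8, 15.5, 20, 79)
  cycle <- sample(c(2L, 5L, 6L), n, replace = TRUE,
                  prob = c(0.31, 0.37, 0.32))
  ethnicity <- ifelse(stats::runif(n) < 0.77, "white", "other")
  asian <- ethnicity == "other" & stats::runif(n) < 0.40
  education <- sample(c("elementary", "secondary", "postsecondary"), n,
                      replace = TRUE, prob = c(0.06, 0.25, 0.69))
  marital <- sample(c("married", "widowed_sep_div", "single"), n,
                    replace = TRUE, prob = c(0.66, 0.09, 0.25))
  smoking <- ifelse(stats::runif(n) < 0.81, "never", "ever")
  country_of_birth <- ifelse(stats::runif(n) < 0.70, "canada", "foreign")
  parity <- ifelse(female,
                   sample(c("0", "1", "2", "3plus"), n, replace = TRUE,
                          prob = c(0.32, 0.12, 0.39, 0.17)),
                   NA_character_)
  fish <- stats::rlnorm(n, meanlog = log(7.67) - 0.917^2 / 2, sdlog = 0.917)
  mvpa <- stats::rlnorm(n, meanlog = log(22.7) - 0.880^2 / 2, sdlog = 0.880)
  pregnant <- female & stats::runif(n) < 0.02
  t1d <- stats::runif(n) < 0.005
  site <- sample.int(cfg$n_sites, n, replace = TRUE)
  wcv <- cfg$weight_cv
  sdw <- sqrt(log(1 + wcv^2))
  weight <- stats::rlnorm(n, meanlog = log(1000) - sdw^2 / 2, sdlog = sdw)

  # --- PFAS via Gaussian copula ----------------------------------------
  P <- spearman_to_pearson(cfg$spearman_target[analytes, analytes])
  ev <- eigen(P, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  Z <- matrix(stats::rnorm(n * length(analytes)), n) %*% L
  U <- stats::pnorm(Z)
  conc <- matrix(NA_real_, n, length(analytes),
                 dimnames = list(NULL, analytes))
  for (j in seq_along(analytes)) {
    gm <- ifelse(female, p$gm_female[j], p$gm_male[j])
    conc[, j] <- stats::qlnorm(U[, j], meanlog = log(gm),
                               sdlog = log(p$gsd[j]))
  }

  # --- quantized joint exposure index ----------------------------------
  qx <- quantize(as.data.frame(conc), q = 4)
  w <- cfg$true_weights[analytes]
  index <- as.numeric(as.matrix(qx$scores) %*% w)

  # --- continuous cardiometabolic risk factors -------------------------
  latent <- stats::rnorm(n)
  cmrf <- default_cmrf_params()
  out <- data.frame(row.names = seq_len(n))
  for (k in seq_len(nrow(cmrf))) {
    o <- cmrf$outcome[k]
    mean_s <- ifelse(female, cmrf$mean_female[k], cmrf$mean_male[k])
    sd_s <- ifelse(female, cmrf$sd_female[k], cmrf$sd_male[k])
    sd_ln <- sqrt(log(1 + (sd_s / mean_s)^2))
    sd_l2 <- sd_ln / log(2)
    mu_l2 <- log2(mean_s) - sd_ln^2 / (2 * log(2))

    eff <- c(age = cmrf$age_coef[k], smoking = 0, fish = 0, mvpa = 0)
    user <- cfg$covariate_effects[[o]]
    if (!is.null(user)) eff[names(user)] <- user
    lin <- eff[["age"]] * (age - 50) +
      eff[["smoking"]] * (smoking == "ever") +
      eff[["fish"]] * (fish - 8) +
      eff[["mvpa"]] * (mvpa - 23)

    lam <- cmrf$share_latent[k] * sd_l2
    var_resid <- sd_l2^2 - lam^2 - eff[["age"]]^2 * 15.5^2
    sd_resid <- sqrt(pmax(var_resid, (0.25 * sd_l2)^2))
    if (!is.null(cfg$noise_sd) && o %in% names(cfg$noise_sd)) {
      sd_resid <- cfg$noise_sd[[o]]
    }
    l2 <- mu_l2 + lin + cfg$true_psi[[o]] * index + lam * latent +
      stats::rnorm(n, sd = sd_resid)
    out[[o]] <- 2^l2
  }

  # --- medication and diagnosis flags ----------------------------------
  med_lipid <- stats::runif(n) < cfg$med_prevalence[["lipid"]]
  med_bp <- stats::runif(n) < cfg$med_prevalence[["bp"]]
  med_diabetes <- stats::runif(n) < cfg$med_prevalence[["diabetes"]]
  dx_htn <- stats::runif(n) < cfg$dx_prevalence[["htn"]]
  dx_t2d <- stats::runif(n) < cfg$dx_prevalence[["t2d"]]

  cohort <- data.frame(
    id = seq_len(n), cycle = cycle, age = age, sex = sex,
    ethnicity = ethnicity, asian = asian, education = education,
    marital = marital, smoking = smoking,
    country_of_birth = country_of_birth, parity = parity,
    fish = fish, mvpa = mvpa, pregnant = pregnant, t1d = t1d,
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(conc))
  for (a in analytes) cohort[[paste0("nd_", a)]] <- FALSE
  cohort <- cbind(cohort, out)
  cohort$med_lipid <- med_lipid
  cohort$med_bp <- med_bp
  cohort$med_diabetes <- med_diabetes
  cohort$dx_htn <- dx_htn
  cohort$dx_t2d <- dx_t2d
  cohort$site <- site
  cohort$weight <- weight

  attr(cohort, "truth") <- list(
    psi = cfg$true_psi,
    weights = cfg$true_weights,
    index = index,
    cutpoints = qx$cutpoints
  )
  attr(cohort, "schema") <- "cohort_schema_v1"
  cohort
}

# inverse-CDF truncated normal
qtrunc_norm <- function(u, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + u * (pu - pl), mean, sd)
}

#' Censor PFAS concentrations below their limits of detection
#'
#' Flags every concentration below its analyte's LOD as a non-detect
#' and masks the stored value (`NA`), mimicking what a laboratory
#' reports; detection frequencies are attached as an attribute and
#' messaged.
#'
#' @param cohort a cohort table from [generate_cohort()].
#' @param lod named per-analyte LOD vector (µg/L); defaults to the LODs
#'   of [default_pfas_params()] for the analyte columns present.
#' @return the cohort with masked concentrations, updated `nd_*` flags
#'   and attribute `detection`.
#' @export
censor_below_lod <- function(cohort, lod = NULL) {
  dp <- default_pfas_params()
  analytes <- intersect(dp$analyte, names(cohort))
  if (is.null(lod)) {
    lod <- stats::setNames(dp$lod, dp$analyte)[analytes]
  }
  detection <- numeric(length(analytes))
  names(detection) <- analytes
  for (a in analytes) {
    nd <- cohort[[a]] < lod[[a]]
    detection[[a]] <- mean(!nd)
    cohort[[paste0("nd_", a)]] <- nd
    cohort[[a]][nd] <- NA_real_
  }
  message("detection frequencies: ",
          paste0(analytes, " ", round(100 * detection, 1), "%",
                 collapse = ", "))
  attr(cohort, "detection") <- detection
  attr(cohort, "lod") <- lod
  cohort
}

#' Write / read a generator configuration as structured text (YAML)
#'
#' Round-trips every field of a [cohort_config()], including the PFAS
#' marginal table and the Spearman target matrix, so a simulation is
#' fully described by one human-editable text file.
#'
#' @param config a [cohort_config()].
#' @param path YAML file path.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_pfasmix("the 'yaml' package is required for config files")
  }
  x <- unclass(config)
  x$pfas <- as.list(config$pfas)
  S <- config$spearman_target
  x$spearman_target <- list(analytes = colnames(S),
                            rows = apply(S, 1, as.numeric,
                                         simplify = FALSE))
  # yaml serializes named atomic vectors as plain sequences; keep the
  # names by converting to maps
  for (f in c("true_psi", "true_weights", "med_prevalence",
              "dx_prevalence", "noise_sd")) {
    if (!is.null(x[[f]])) x[[f]] <- as.list(x[[f]])
  }
  if (!is.null(x$covariate_effects)) {
    x$covariate_effects <- lapply(x$covariate_effects, as.list)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_pfasmix("the 'yaml' package is required for config files")
  }
  x <- yaml::read_yaml(path)
  S <- do.call(rbind, lapply(x$spearman_target$rows, as.numeric))
  dimnames(S) <- list(x$spearman_target$analytes,
                      x$spearman_target$analytes)
  cohort_config(
    n_participants = x$n_participants,
    seed = x$seed,
    sex_fraction_female = x$sex_fraction_female,
    pfas = as.data.frame(x$pfas, stringsAsFactors = FALSE),
    spearman_target = S,
    true_psi = unlist(x$true_psi),
    true_weights = unlist(x$true_weights),
    covariate_effects = lapply(x$covariate_effects, unlist),
    noise_sd = if (length(x$noise_sd)) unlist(x$noise_sd) else NULL,
    med_prevalence = unlist(x$med_prevalence),
    dx_prevalence = unlist(x$dx_prevalence),
    n_sites = x$n_sites,
    n_replicates = x$n_replicates,
    weight_cv = x$weight_cv
  )
}

#' Write / read a cohort table as CSV under the versioned schema
#'
#' @param cohort cohort data.frame.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(x, "schema") <- "cohort_schema_v1"
  x
}
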