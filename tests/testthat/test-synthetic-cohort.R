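test_that("generation is deterministic given config and seed", {
  cfg <- cohort_config(n_participants = 300, seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  # byte-for-byte after canonical serialization
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, f1)
  write_cohort(c2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  c3 <- generate_cohort(cohort_config(n_participants = 300, seed = 43))
  expect_false(identical(c1$pfoa, c3$pfoa))
})

test_that("sex-specific geometric means match their targets within 3%", {
  co <- generate_cohort(cohort_config(n_participants = 20000, seed = 7))
  p <- default_pfas_params()
  for (j in seq_len(nrow(p))) {
    a <- p$analyte[j]
    gm_m <- exp(mean(log(co[[a]][co$sex == "male"])))
    gm_f <- exp(mean(log(co[[a]][co$sex == "female"])))
    expect_lt(abs(gm_m - p$gm_male[j]) / p$gm_male[j], 0.03)
    expect_lt(abs(gm_f - p$gm_female[j]) / p$gm_female[j], 0.03)
  }
  # log-scale SD matches log(GSD)
  expect_equal(sd(log(co$pfos[co$sex == "male"])), log(2.0),
               tolerance = 0.03)
})

test_that("copula reproduces the Spearman target; identity gives independence", {
  # the copula acts within sex; the sex-specific geometric-mean shift
  # adds a little extra pooled rank correlation on top, so fidelity is
  # checked within strata and the pooled matrix only for plausibility
  co <- generate_cohort(cohort_config(n_participants = 50000, seed = 11))
  for (s in c("male", "female")) {
    emp <- cor(co[co$sex == s, pfas_names()], method = "spearman")
    expect_lt(max(abs(emp - default_spearman())), 0.03)
  }
  pooled <- cor(co[, pfas_names()], method = "spearman")
  expect_gt(min(pooled[upper.tri(pooled)]), 0.25)
  expect_lt(max(pooled[upper.tri(pooled)]), 0.85)

  id <- diag(5)
  dimnames(id) <- list(pfas_names(), pfas_names())
  co0 <- generate_cohort(cohort_config(n_participants = 10000, seed = 13,
                                       spearman_target = id))
  for (s in c("male", "female")) {
    emp0 <- cor(co0[co0$sex == s, pfas_names()], method = "spearman")
    expect_lt(max(abs(emp0[upper.tri(emp0)])), 0.05)
  }
})

test_that("non-positive-semidefinite correlation targets are rejected with a diagnostic", {
  bad <- diag(5)
  dimnames(bad) <- list(pfas_names(), pfas_names())
  bad[1, 2] <- bad[2, 1] <- 0.9
  bad[1, 3] <- bad[3, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- -0.9
  expect_error(cohort_config(spearman_target = bad),
               "positive semidefinite")
  asym <- default_spearman()
  asym[1, 2] <- 0.2
  expect_error(cohort_config(spearman_target = asym), "symmetric")
})

test_that("under a null mixture effect the exposure index is unrelated to the outcomes", {
  co <- generate_cohort(cohort_config(n_participants = 10000, seed = 17))
  idx <- attr(co, "truth")$index
  for (o in c("wc", "tg", "hba1c")) {
    # partial rank correlation given the generating covariates
    r_o <- resid(lm(log2(co[[o]]) ~ age + sex, co))
    r_i <- resid(lm(idx ~ age + sex, co))
    expect_lt(abs(cor(r_o, r_i, method = "spearman")), 0.05)
  }
})

test_that("a configured mixture effect shifts the outcome by psi per index unit", {
  cfg <- cohort_config(n_participants = 20000, seed = 19,
                       true_psi = c(hba1c = 0.25),
                       noise_sd = c(hba1c = 0.5))
  co <- generate_cohort(cfg)
  idx <- attr(co, "truth")$index
  b <- coef(lm(log2(co$hba1c) ~ idx + age + sex, co))[["idx"]]
  expect_equal(b, 0.25, tolerance = 0.02)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(true_weights = c(pfoa = 0.7, pfos = 0.7,
                                              pfhxs = -0.4, pfda = 0,
                                              pfna = 0)),
               "nonnegative")
  expect_error(cohort_config(med_prevalence = c(lipid = 1.2, bp = 0.2,
                                                diabetes = 0.1)),
               "prevalences")
  expect_error(cohort_config(n_replicates = 0), "n_replicates")
  expect_error(cohort_config(true_psi = c(bogus = 1)), "unknown outcome")
  bad_pfas <- default_pfas_params()
  bad_pfas$gsd[2] <- -1
  expect_error(cohort_config(pfas = bad_pfas), "GSDs")
})

test_that("cohort marginals land near their configured prevalences", {
  co <- generate_cohort(cohort_config(n_participants = 20000, seed = 23))
  expect_lt(abs(mean(co$sex == "female") - 0.52), 0.02)
  expect_lt(abs(mean(co$med_lipid) - 0.20), 0.02)
  expect_lt(abs(mean(co$med_bp) - 0.21), 0.02)
  expect_lt(abs(mean(co$med_diabetes) - 0.07), 0.01)
  expect_true(all(co$age >= 20 & co$age <= 79))
  expect_true(all(co$weight > 0))
  expect_true(all(as.matrix(co[, c("wc", "tg", "hdl", "glu", "sbp",
                                   "dbp", "hba1c")]) > 0))
  expect_true(all(is.na(co$parity[co$sex == "male"])))
})

test_that("LOD censoring masks values, sets flags and reports detection", {
  co <- generate_cohort(cohort_config(n_participants = 10000, seed = 29))
  cen <- suppressMessages(censor_below_lod(co))
  det <- attr(cen, "detection")
  # PFDA LOD sits near the 18th percentile: ~82% detected
  expect_equal(unname(det["pfda"]), 0.82, tolerance = 0.02)
  expect_true(all(det[c("pfoa", "pfos", "pfhxs", "pfna")] > 0.95))
  expect_true(all(is.na(cen$pfda[cen$nd_pfda])))
  expect_identical(cen$pfda[!cen$nd_pfda], co$pfda[!cen$nd_pfda])

  # zero LOD: everything detected; huge LOD: nothing detected
  lod0 <- setNames(rep(0, 5), pfas_names())
  expect_equal(unname(attr(suppressMessages(censor_below_lod(co, lod0)),
                           "detection")), rep(1, 5))
  lodInf <- setNames(rep(1e6, 5), pfas_names())
  expect_equal(unname(attr(suppressMessages(censor_below_lod(co, lodInf)),
                           "detection")), rep(0, 5))
})

test_that("a config round-trips through its YAML representation", {
  skip_if_not_installed("yaml")
  cfg <- cohort_config(n_participants = 123, seed = 9,
                       true_psi = c(hba1c = 0.1, wc = -0.05),
                       noise_sd = c(hba1c = 0.4),
                       covariate_effects = list(tg = c(age = 0.001)))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, f)
  back <- read_cohort_config(f)
  expect_equal(back$true_psi, cfg$true_psi)
  expect_equal(back$spearman_target, cfg$spearman_target)
  expect_equal(back$pfas, cfg$pfas)
  expect_equal(back$noise_sd, cfg$noise_sd)
  # identical cohorts from the round-tripped config
  expect_identical(generate_cohort(cfg), generate_cohort(back))
})

test_that("emergent MetS prevalence sits near the 27% target", {
  co <- prepared_cohort(n = 20000, seed = 31)
  expect_gt(mean(co$mets), 0.24)
  expect_lt(mean(co$mets), 0.30)
})
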