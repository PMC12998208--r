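test_that("MetS classifier reproduces the clinical rule on worked examples", {
  # white male with central obesity, high TG, low HDL only
  r <- base_record(wc = 103, tg = 1.8, hdl = 0.9, sbp = 125, dbp = 80,
                   hba1c = 5.5)
  out <- classify_mets(r)
  expect_true(out$wc_high && out$tg_high && out$hdl_low)
  expect_false(out$bp_high || out$glyc_high)
  expect_equal(out$n_criteria, 3)
  expect_true(out$mets)

  # Asian female WC threshold is 80 cm, inclusive
  expect_true(classify_mets(base_record(sex = "female", asian = TRUE,
                                        wc = 81))$wc_high)
  expect_true(classify_mets(base_record(sex = "female", asian = TRUE,
                                        wc = 80))$wc_high)
  expect_false(classify_mets(base_record(sex = "female", asian = TRUE,
                                         wc = 79))$wc_high)

  # every measure just under threshold, no medication: zero criteria
  eps <- 1e-9
  r0 <- base_record(wc = 102 - eps, tg = 1.7 - eps, hdl = 1.0,
                    sbp = 130 - eps, dbp = 85 - eps, hba1c = 5.7 - eps)
  expect_equal(classify_mets(r0)$n_criteria, 0)
  expect_false(classify_mets(r0)$mets)
})

test_that("threshold boundaries are inclusive for >= criteria and strict for HDL", {
  expect_true(classify_mets(base_record(wc = 102))$wc_high)
  expect_true(classify_mets(base_record(sex = "female", wc = 88))$wc_high)
  expect_true(classify_mets(base_record(asian = TRUE, wc = 90))$wc_high)
  expect_true(classify_mets(base_record(tg = 1.7))$tg_high)
  expect_false(classify_mets(base_record(hdl = 1.0))$hdl_low)   # strict <
  expect_true(classify_mets(base_record(hdl = 1.0 - 1e-9))$hdl_low)
  expect_false(classify_mets(base_record(sex = "female",
                                         hdl = 1.3))$hdl_low)
  expect_true(classify_mets(base_record(sbp = 130))$bp_high)
  expect_true(classify_mets(base_record(dbp = 85))$bp_high)
  expect_true(classify_mets(base_record(hba1c = 5.7))$glyc_high)
})

test_that("medication and diagnosis flags satisfy their criteria", {
  expect_true(classify_mets(base_record(med_lipid = TRUE))$tg_high)
  expect_true(classify_mets(base_record(med_lipid = TRUE))$hdl_low)
  expect_true(classify_mets(base_record(med_bp = TRUE))$bp_high)
  expect_true(classify_mets(base_record(dx_htn = TRUE))$bp_high)
  expect_true(classify_mets(base_record(med_diabetes = TRUE))$glyc_high)
  expect_true(classify_mets(base_record(dx_t2d = TRUE))$glyc_high)
})

test_that("classifier aggregate equals the brute-force >=3-of-5 rule on all 32 patterns", {
  grid <- expand.grid(wc = c(FALSE, TRUE), tg = c(FALSE, TRUE),
                      hdl = c(FALSE, TRUE), bp = c(FALSE, TRUE),
                      glyc = c(FALSE, TRUE))
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    base_record(wc = if (g$wc) 103 else 95,
                tg = if (g$tg) 1.8 else 1.0,
                hdl = if (g$hdl) 0.9 else 1.2,
                sbp = if (g$bp) 135 else 120,
                hba1c = if (g$glyc) 5.9 else 5.2)
  }))
  out <- classify_mets(recs)
  truth <- rowSums(grid) >= 3
  expect_identical(out$mets, unname(truth))
  expect_identical(out$n_criteria, as.integer(rowSums(grid)))
  expect_equal(sum(out$mets), 16)  # half of the 32 patterns
})

test_that("classifier refuses incomplete records", {
  r <- base_record()
  r$tg <- NA
  expect_error(classify_mets(r), "complete")
})

test_that("CMRF standardization yields weighted mean 0, SD 1 residual Z-scores", {
  set.seed(5)
  n <- 500
  age <- runif(n, 20, 79)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  w <- rlnorm(n, sdlog = 0.3)
  y <- 80 + 0.2 * age + 3 * (sex == "male") + rnorm(n, sd = 8)
  z <- standardize_cmrf(y, age, sex, w)
  expect_equal(wtd_m <- sum(w * z) / sum(w), 0, tolerance = 1e-10)
  expect_equal(sqrt(sum(w * z^2) / sum(w)), 1, tolerance = 1e-10)

  # outcome independent of age/sex with equal weights: Z converges to
  # the plain standard score (regression slopes -> 0)
  y2 <- rnorm(20000)
  z2 <- standardize_cmrf(y2, runif(20000, 20, 79),
                         sample(c("male", "female"), 20000, TRUE),
                         weights = NULL)
  std <- (y2 - mean(y2)) / sqrt(mean((y2 - mean(y2))^2))
  expect_lt(max(abs(z2 - std)), 0.05)

  # exact linear function of age: zero residual variance is an error
  expect_error(standardize_cmrf(2 + 3 * age, age, sex), "variance")
  expect_error(standardize_cmrf(y[1:20], age[1:20], sex[1:20]), "n >= 50")
})

test_that("CMRS follows its formula: zMAP combination, HDL sign, sqrt-5 scaling", {
  z0 <- data.frame(zWC = 0, zHbA1c = 0, zTG = 0, zHDL = 0,
                   zSBP = 0, zDBP = 0)
  expect_equal(compute_cmrs(z0)$cmrs, 0)

  z1 <- data.frame(zWC = 1, zHbA1c = 1, zTG = 1, zHDL = 1,
                   zSBP = 1, zDBP = 1)
  out <- compute_cmrs(z1)
  expect_equal(out$zMAP, 1)
  expect_equal(out$cmrs, 3 / sqrt(5))

  # raising zHDL by delta lowers the score by exactly delta/sqrt(5)
  delta <- 0.37
  z2 <- z1
  z2$zHDL <- z1$zHDL + delta
  expect_equal(compute_cmrs(z2)$cmrs, out$cmrs - delta / sqrt(5))

  # zMAP = zDBP + (zSBP - zDBP)/3
  z3 <- data.frame(zWC = 0, zHbA1c = 0, zTG = 0, zHDL = 0,
                   zSBP = 3, zDBP = 0)
  expect_equal(compute_cmrs(z3)$zMAP, 1)
  expect_error(compute_cmrs(data.frame(zWC = 1)), "zMAP|zSBP")
})

test_that("log2 back-transform and its inverse are exact", {
  expect_equal(back_transform_percent(0), 0)
  expect_equal(back_transform_percent(1), 100)
  expect_equal(back_transform_percent(-1), -50)
  expect_equal(back_transform_percent(0.0166), (2^0.0166 - 1) * 100)
  for (b in c(-2, -0.3, 0, 0.017, 1.5)) {
    expect_equal(percent_to_log2(back_transform_percent(b)), b,
                 tolerance = 1e-12)
  }
})

test_that("derived outcomes on synthetic data are internally consistent", {
  co <- prepared_cohort(n = 1500, seed = 3)
  # z-scores are weighted-standardized on the analytic sample
  for (zc in c("zWC", "zTG", "zHDL")) {
    expect_equal(sum(co$weight * co[[zc]]) / sum(co$weight), 0,
                 tolerance = 1e-8)
  }
  expect_equal(co$cmrs,
               (co$zWC + co$zHbA1c + co$zTG - co$zHDL + co$zMAP) / sqrt(5))
  # swapping the glycemia criterion moves prevalence by < 2 points
  p_hba1c <- mean(co$mets)
  p_glu <- mean(derive_outcomes(co[, setdiff(names(co),
    c("wc_high","tg_high","hdl_low","bp_high","glyc_high",
      "n_criteria","mets","zWC","zHbA1c","zTG","zHDL","zSBP","zDBP",
      "zMAP","cmrs"))], glycemia = "glucose")$mets)
  expect_lt(abs(p_hba1c - p_glu), 0.02)
})
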