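test_that("parent profile matches closed-form peak and area oracles", {
  p <- pk_params(ka = 1.0, ke = 0.1, v_f = 1, dose = 1000)
  expect_identical(simulate_parent(p, 0), 0)

  tmax_cf <- log(p$ka / p$ke) / (p$ka - p$ke)   # = ln(10)/0.9
  grid <- seq(0, 20, by = 1e-4)
  tmax_grid <- grid[which.max(simulate_parent(p, grid))]
  expect_equal(tmax_grid, tmax_cf, tolerance = 1e-3)
  expect_equal(tmax_cf, 2.5584, tolerance = 1e-4)

  auc_quad <- quad_auc(function(t) simulate_parent(p, t), 500)
  expect_equal(auc_quad, p$dose / (p$v_f * p$ke), tolerance = 1e-3)  # 10000
})

test_that("equal-rate absorption/elimination uses the analytic limit", {
  k <- 0.3
  t <- c(0.5, 1, 2, 5, 10, 30)
  p_eq <- pk_params(ka = k, ke = k, v_f = 100, dose = 1e5)
  expect_equal(simulate_parent(p_eq, t),
               p_eq$dose * k * t / p_eq$v_f * exp(-k * t), tolerance = 1e-12)
  # continuity: the general branch just outside the tolerance agrees
  p_near <- pk_params(ka = k * (1 + 1e-5), ke = k, v_f = 100, dose = 1e5)
  expect_equal(simulate_parent(p_near, t), simulate_parent(p_eq, t),
               tolerance = 1e-4)
})

test_that("metabolite cascade satisfies its area identities", {
  expect_equal(simulate_metabolite(pk_params(1, 0.2, 10, 1e4), c(0, 1, 5)),
               c(0, 0, 0))

  # fm = 1, same volume and rate: metabolite area equals parent area
  p1 <- pk_params(ka = 1, ke = 0.1, v_f = 50, dose = 1e5,
                  fm = 1, kem = 0.1, vm_f = 50)
  expect_equal(quad_auc(function(t) simulate_metabolite(p1, t), 1000),
               p1$dose / (p1$v_f * p1$ke), tolerance = 1e-3)

  p2 <- pk_params(ka = 1, ke = 0.2, v_f = 50, dose = 1e5,
                  fm = 0.5, kem = 0.05, vm_f = 80)
  expect_equal(quad_auc(function(t) simulate_metabolite(p2, t), 1000),
               p2$fm * p2$dose / (p2$vm_f * p2$kem), tolerance = 1e-3)
})

test_that("metabolite area scales linearly in the formation fraction", {
  base <- list(ka = 1.2, ke = 0.15, v_f = 40, dose = 1e5, kem = 0.06, vm_f = 70)
  auc_at <- function(fm) {
    p <- pk_params(base$ka, base$ke, base$v_f, base$dose, fm, base$kem, base$vm_f)
    quad_auc(function(t) simulate_metabolite(p, t), 1000)
  }
  expect_equal(auc_at(0.6), 2 * auc_at(0.3), tolerance = 1e-6)
})

test_that("near-equal metabolite rate pairs fall back to analytic limits", {
  t <- c(1, 5, 20, 60)
  for (rates in list(c(1, 1, 0.05), c(1, 0.2, 0.2), c(0.3, 0.3, 0.3))) {
    p_eq <- pk_params(rates[1], rates[2], 50, 1e5, 0.5, rates[3], 50)
    jit <- rates * (1 + c(0, 1e-5, 2e-5))
    p_near <- pk_params(jit[1], jit[2], 50, 1e5, 0.5, jit[3], 50)
    expect_equal(simulate_metabolite(p_eq, t), simulate_metabolite(p_near, t),
                 tolerance = 1e-3)
    expect_true(all(is.finite(simulate_metabolite(p_eq, t))))
  }
})

test_that("assay noise honours its moments and censoring contract", {
  set.seed(11)
  clean <- add_assay_noise(c(5, 50), noise_cv = 0, noise_sd_add = 0, lloq = 0)
  expect_equal(clean$measured, c(5, 50))
  expect_false(any(clean$blq))

  zero <- add_assay_noise(0, noise_cv = 0.1, noise_sd_add = 0, lloq = 1)
  expect_true(zero$blq)
  expect_identical(zero$reported, 0)

  mc <- add_assay_noise(rep(100, 10000), noise_cv = 0.05, noise_sd_add = 0,
                        lloq = 0)
  expect_equal(100 * sd(mc$measured) / mean(mc$measured), 5, tolerance = 0.1)

  expect_error(add_assay_noise(10, -0.1, 0, 0))
  # BLQ reported value censored, measurement retained
  set.seed(12)
  low <- add_assay_noise(rep(1, 200), noise_cv = 0.5, noise_sd_add = 0, lloq = 1)
  expect_true(all(low$reported[low$blq] == 0))
  expect_true(all(low$measured[low$blq] < 1))
})

test_that("simulated study has the design's shape and is seed-reproducible", {
  bp <- default_base_params()
  ds <- simulate_study(study_design(seed = 7), bp)
  df <- profiles_to_df(ds)
  # 5 parent profiles (group I) + 5x2 (group II) + 5x3 (group III)
  expect_equal(length(ds$profiles), 30)
  expect_true(all(table(df$subject_id, df$analyte) %in% c(0, 10)))
  counts <- table(unique(df[c("subject_id", "analyte", "group")])$group)
  expect_equal(as.integer(counts[c("I", "II", "III")]), c(5, 10, 15))

  ds2 <- simulate_study(study_design(seed = 7), bp)
  expect_identical(profiles_to_df(ds2), df)
  ds3 <- simulate_study(study_design(seed = 8), bp)
  expect_false(identical(profiles_to_df(ds3), df))
})

test_that("zero variability collapses a group to identical animals", {
  bp <- default_base_params()
  ds <- simulate_study(study_design(noise_cv = 0, iiv_cv = 0, seed = 3), bp)
  df <- profiles_to_df(ds)
  tam <- df[df$group == "II" & df$analyte == "TAM", ]
  concs <- split(tam$conc_ng_per_mL, tam$subject_id)
  for (i in seq_along(concs)[-1]) expect_identical(concs[[i]], concs[[1]])
})

test_that("noise-free terminal log-slope recovers ke to 4 significant figures", {
  bp <- default_base_params()
  for (an in c("DSV", "TAM")) {
    p <- bp[[an]]
    t <- c(24, 48, 96)   # far past tmax so absorption has fully decayed
    slope <- coef(lm(log(simulate_parent(p, t)) ~ t))[[2]]
    expect_equal(-slope, p$ke, tolerance = 1e-4)
  }
})

test_that("interaction effect scales the victim's exposure in the combo arm", {
  bp <- default_base_params()
  d0 <- study_design(noise_cv = 0, iiv_cv = 0, seed = 5)
  ds1 <- simulate_study(d0, bp, ddi_effect("TAM", f_scale = 1))
  ds2 <- simulate_study(d0, bp, ddi_effect("TAM", f_scale = 2))
  pick <- function(ds, g, an) {
    p <- Filter(function(x) x$group == g & x$analyte == an, ds$profiles)[[1]]
    p$concs
  }
  expect_equal(pick(ds2, "III", "TAM"), 2 * pick(ds1, "III", "TAM"))
  # single-administration arm untouched
  expect_identical(pick(ds2, "II", "TAM"), pick(ds1, "II", "TAM"))
})

test_that("calibration batches expose truth, stage attenuation and noise", {
  set.seed(21)
  b <- simulate_calibration_batch(slope = 0.9565, intercept = 0.0147,
                                  levels = c(0.1, 0.5, 1, 5, 25, 100, 250, 500),
                                  replicates = 1, noise_cv = 0,
                                  stage_factors = c(pre = 1, post = 1, neat = 1))
  d <- b[b$stage == "pre", ]
  cv <- fit_calibration(d$level, d$response / d$is_response)
  expect_equal(cv$slope_b, 0.9565, tolerance = 1e-12)
  expect_equal(cv$intercept_a, 0.0147, tolerance = 1e-12)

  b2 <- simulate_calibration_batch(1, 0, levels = 100, replicates = 4,
                                   noise_cv = 0,
                                   stage_factors = c(pre = 0.95, post = 1, neat = 1))
  expect_equal(extraction_recovery(b2$response[b2$stage == "pre"],
                                   b2$response[b2$stage == "post"]), 95)

  set.seed(22)
  b3 <- simulate_calibration_batch(1, 0, levels = 100, replicates = 2000,
                                   noise_cv = 0.02,
                                   stage_factors = c(pre = 1))
  r <- b3$response[b3$stage == "pre"]
  expect_equal(100 * sd(r) / mean(r), 2, tolerance = 0.15)
})
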