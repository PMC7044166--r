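test_that("accuracy/precision matches hand arithmetic exactly", {
  exact <- accuracy_precision(rep(20, 6), 20)
  expect_equal(exact$recovery_pct, 100)
  expect_equal(exact$er_pct, 0)
  expect_equal(exact$rsd_pct, 0)

  # replicate set built to a printed-style summary: mean 19.486 on nominal 20
  found <- make_replicates(19.486, 2.06, 18)
  ap <- accuracy_precision(found, 20)
  expect_equal(ap$recovery_pct, 97.43)
  expect_equal(ap$er_pct, -2.57)
  expect_equal(ap$rsd_pct, 2.06)

  set.seed(41)
  for (i in 1:5) {
    x <- rlnorm(6, 3, 0.2); nom <- 20
    ap <- accuracy_precision(x, nom)
    expect_equal(ap$recovery_pct, 100 * mean(x) / nom, tolerance = 1e-12)
    expect_equal(ap$er_pct, 100 * (mean(x) - nom) / nom, tolerance = 1e-12)
    expect_equal(ap$rsd_pct, 100 * sd(x) / mean(x), tolerance = 1e-12)
  }
  expect_error(accuracy_precision(5, 10), "2 replicates")
  expect_true(is.na(accuracy_precision(c(0, 0), 10)$rsd_pct))
})

test_that("RSD converges to the generating CV (Monte-Carlo)", {
  set.seed(42)
  found <- 100 * (1 + rnorm(1e4, 0, 0.05))
  expect_equal(accuracy_precision(found, 100)$rsd_pct, 5, tolerance = 0.5)
})

test_that("recovery and matrix effect are ratio-of-means with a paired option", {
  expect_equal(extraction_recovery(c(10, 12), c(10, 12)), 100)
  post <- c(98, 101, 103, 99)
  expect_equal(extraction_recovery(0.9 * post, post), 90)
  expect_equal(extraction_recovery(93.82, 100), 93.82)

  expect_equal(matrix_effect(c(5, 6), c(5, 6)), 100)
  neat <- c(200, 210, 195)
  expect_equal(matrix_effect(1.0145 * neat, neat), 101.45)

  set.seed(43)
  a <- runif(6, 80, 120); b <- runif(6, 80, 120)
  expect_equal(extraction_recovery(a, b), 100 * mean(a) / mean(b))
  expect_equal(extraction_recovery(a, b, mode = "mean_of_ratios"),
               100 * mean(a / b))
  expect_error(extraction_recovery(a, rep(0, 6)), "zero")
  # invariance to common rescaling of both response sets
  expect_equal(extraction_recovery(7 * a, 7 * b), extraction_recovery(a, b))
})

test_that("selectivity thresholds are inclusive and blank-zero is vacuous", {
  expect_true(selectivity_check(1, 5, 20, 1)$passed)        # boundary
  expect_false(selectivity_check(1, 4.9, 100, 1)$passed)
  expect_true(selectivity_check(0, 0.1, 1, 0)$passed)
  expect_false(selectivity_check(1, 100, 19.9, 1)$passed)   # IS side fails
  expect_error(selectivity_check(-1, 5, 20, 1))
})

test_that("carryover limits are strict inequalities", {
  expect_true(carryover_check(0, 0, 100, 1000)$passed)
  expect_true(carryover_check(19, 40, 100, 1000)$passed)
  expect_false(carryover_check(25, 40, 100, 1000)$passed)
  expect_false(carryover_check(20, 40, 100, 1000)$passed)   # exactly 20%: fail
  expect_false(carryover_check(10, 50, 100, 1000)$passed)   # IS at 5%: fail
})

test_that("stability passes within 100 +/- 15", {
  expect_true(stability_recovery(rep(50, 6), 50, "bench")$passed)
  rec <- stability_recovery(make_replicates(0.9851 * 60, 0.49, 6), 60,
                            "freeze-thaw, 3 cycles")
  expect_equal(rec$value, 98.51, tolerance = 1e-10)
  expect_true(rec$passed)
  expect_false(stability_recovery(rep(0.84 * 60, 3), 60, "bench")$passed)
})

test_that("dilution integrity passes on |Er| <= 15", {
  expect_true(dilution_integrity(rep(2000, 6), 2000)$passed)
  rec <- dilution_integrity(make_replicates(1994.8, 3.96, 6), 2000)
  expect_equal(rec$value, 99.74)
  expect_true(rec$passed)
  expect_false(dilution_integrity(rep(0.84 * 2000, 3), 2000)$passed)
})

# a coherent battery dataset built to known summaries
battery_fixture <- function(er_interday = -2.57) {
  qc <- function(nom, er, rsd, n) data.frame(
    analyte = "DSV", nominal = nom,
    found = make_replicates(nom * (1 + er / 100), rsd, n))
  list(
    qc_intraday = rbind(qc(20, -1.40, 1.19, 6), qc(60, -2.78, 1.92, 6)),
    qc_interday = rbind(qc(20, er_interday, 2.06, 18), qc(60, -1.35, 1.89, 18)),
    recovery = data.frame(
      analyte = "DSV", level = 500,
      stage = rep(c("pre", "post", "neat"), each = 2),
      response = c(0.963 * c(99, 101), c(99, 101), c(99, 101) / 0.9365)),
    selectivity = data.frame(analyte = "DSV", blank_signal = 1,
                             lloq_signal = 8, is_signal = 500,
                             is_blank_signal = 2),
    carryover = data.frame(analyte = "DSV", blank_peak = 1, is_blank_peak = 5,
                           lloq_response = 10, is_response = 500),
    dilution = data.frame(analyte = "DSV", nominal = 2000, factor = 5,
                          found = make_replicates(1994.8, 3.96, 6)),
    stability = data.frame(analyte = "DSV", condition = "freeze-thaw",
                           nominal = 60,
                           found = make_replicates(0.9851 * 60, 0.49, 6)))
}

test_that("the validation battery aggregates records and verdicts", {
  recs <- run_validation_battery(battery_fixture())
  expect_true(attr(recs, "verdict"))
  expect_setequal(
    unique(recs$metric),
    c("precision_intraday", "precision_interday", "recovery",
      "matrix_effect", "selectivity", "carryover", "dilution_integrity",
      "stability"))
  inter <- recs[recs$metric == "precision_interday" & recs$level == "20", ]
  expect_equal(inter$value, 97.43)
  expect_equal(inter$dispersion, 2.06)

  # pushing one metric past its limit flips the verdict (the 20 ng/mL level
  # is the LLOQ, so its inclusive limit is +/- 20%)
  bad <- run_validation_battery(battery_fixture(er_interday = -25))
  expect_false(attr(bad, "verdict"))
  expect_false(bad$passed[bad$metric == "precision_interday" &
                            bad$level == "20"])
})

test_that("a missing stage reports not-evaluable without aborting", {
  ds <- battery_fixture()
  ds$recovery <- ds$recovery[ds$recovery$stage != "neat", ]
  ds$stability <- NULL
  recs <- run_validation_battery(ds)
  expect_false("matrix_effect" %in%
                 recs$metric[!is.na(recs$value)])
  st <- recs[recs$metric == "stability", ]
  expect_equal(st$note, "not evaluable")
  expect_true("precision_intraday" %in% recs$metric)
})

test_that("loosening policy limits never flips pass to fail", {
  ds <- battery_fixture()
  tight <- run_validation_battery(ds, acceptance_policy(limit_lloq = 15,
                                                        limit_other = 10))
  loose <- run_validation_battery(ds, acceptance_policy(limit_lloq = 25,
                                                        limit_other = 20))
  both <- !is.na(tight$passed) & !is.na(loose$passed)
  expect_true(all(!tight$passed[both] | loose$passed[both]))
})
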