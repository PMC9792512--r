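test_that("suppression fold is the control/treated ratio of mean cell ratios", {
  cells <- function(jf, mt = 1000, bjf = 50, bmt = 30) {
    data.frame(jf_mean = jf + bjf, mturq_mean = mt + bmt,
               background_jf = bjf, background_mturq = bmt)
  }
  same <- suppression_fold(cells(c(400, 600)), cells(c(400, 600)))
  expect_equal(same$fold, 1)
  tenx <- suppression_fold(cells(c(40, 60)), cells(c(400, 600)))
  expect_equal(tenx$fold, 10)
  # common gain on both channels of every cell cancels
  gained <- suppression_fold(cells(c(40, 60) * 3, mt = 3000, bjf = 150,
                                   bmt = 90),
                             cells(c(400, 600) * 3, mt = 3000, bjf = 150,
                                   bmt = 90))
  expect_equal(gained$fold, 10)
  # a cell whose background-subtracted mTurq is non-positive is excluded
  bad <- cells(c(40, 60))
  bad$mturq_mean[1] <- 10
  out <- suppression_fold(bad, cells(c(400, 600)))
  expect_identical(out$n_excluded, 1L)
  expect_length(out$treated_ratios, 1)
})

test_that("FM release applies the baseline floor and responder threshold", {
  tr <- data.frame(bouton_id = c("a", "b"), baseline_mean = 800,
                   load_value = 1000, unload_value = c(400, 900))
  out <- fm_release(tr)
  expect_equal(out$boutons$fraction_released, c(0.6, 0.1))
  expect_identical(out$boutons$responder, c(TRUE, FALSE))
  expect_equal(out$responder_percent, 50)

  fx <- simulate_assay_fixtures(1)$fm
  res <- fm_release(fx$traces)
  expect_identical(res$n_excluded_baseline, fx$truth$n_excluded_baseline)
  expect_identical(nrow(res$boutons), fx$truth$n_analyzed)
  expect_identical(sum(res$boutons$responder), fx$truth$n_responders)

  # responder percentage is monotone non-increasing in the threshold
  pcts <- vapply(c(0, 0.1, 0.15, 0.3, 0.7),
                 function(th) fm_release(fx$traces,
                                         responder_threshold = th)$responder_percent,
                 numeric(1))
  expect_true(all(diff(pcts) <= 0))
  # fractions are at most 1, and in [0, 1] when unload <= load
  expect_true(all(res$boutons$fraction_released <= 1))
})

test_that("viability is the live fraction averaged over fields", {
  expect_equal(viability_ratio(data.frame(n_calcein = 90, n_pi = 10))$mean,
               0.9)
  expect_equal(viability_ratio(data.frame(n_calcein = 50, n_pi = 0))$mean, 1)
  fields <- data.frame(n_calcein = c(9, 8, 10), n_pi = c(1, 2, 0))
  out <- viability_ratio(fields)
  expect_equal(out$mean, 0.9)
  expect_equal(out$sem, sd(c(0.9, 0.8, 1.0)) / sqrt(3))
  skip <- viability_ratio(rbind(fields, data.frame(n_calcein = 0, n_pi = 0)))
  expect_identical(skip$n_skipped, 1L)
  expect_equal(skip$mean, 0.9)
  expect_error(viability_ratio(data.frame(n_calcein = 0, n_pi = 0)),
               "positive total")
})

test_that("activity normalization divides by the baseline mean", {
  expect_equal(activity_normalize(rep(4, 200)), rep(1, 200))
  expect_equal(activity_normalize(c(10, 10, 10, 5, 15), baseline_bins = 1:3),
               c(1, 1, 1, 0.5, 1.5))
  halves <- c(rep(10, 180), rep(5, 60))
  expect_equal(unique(activity_normalize(halves)[181:240]), 0.5)
  expect_error(activity_normalize(c(0, 0, 5), baseline_bins = 1:2),
               "not positive")
})

test_that("paired slope test contrasts pre and post windows", {
  flat <- lapply(1:4, function(i) rep(1, 100) + (1:100) * 0.001)
  out <- activity_slope_test(flat, 1:50, 51:100)
  expect_equal(out$p_value, 1)
  expect_equal(out$t_statistic, 0)
  single <- activity_slope_test(flat[1], 1:50, 51:100)
  expect_true(is.na(single$p_value))

  # planted post-window drift is detected in nearly every simulation
  detected <- 0
  for (s in 1:100) {
    set.seed(9000 + s)
    series <- lapply(1:10, function(i) {
      c(100 + rnorm(100, 0, 3), 100 - 0.2 * (1:100) + rnorm(100, 0, 3))
    })
    p <- activity_slope_test(series, 1:100, 101:200)$p_value
    if (!is.na(p) && p < 0.05) detected <- detected + 1
  }
  expect_gte(detected, 90)
})

test_that("flux normalization anchors at the fifth baseline cycle", {
  fx <- simulate_assay_fixtures(1)$flux
  out <- flux_normalize(fx$values, fx$background_wells)
  expect_identical(sum(out$flags$increased_after_oligomycin),
                   fx$truth$n_flagged_oligo)
  expect_identical(sum(!out$flags$excluded), fx$truth$n_clean)
  # retained wells are exactly 100% at the 5th baseline cycle
  expect_true(all(out$normalized[, 5] == 100))
  # textbook well reads 100/60/180/20% of baseline
  clean <- out$normalized[1, ]
  expect_equal(unname(clean[c(5, 10, 15, 20)]), c(100, 60, 180, 20))

  # a well identical to background has non-positive reference: excluded
  plate <- fx$values
  plate <- rbind(plate, DEAD = rep(10, 20))
  out2 <- flux_normalize(plate, fx$background_wells)
  expect_identical(out2$n_excluded_nonpositive_baseline, 1L)
})
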