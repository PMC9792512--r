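test_that("generators are reproducible under a seed and vary across seeds", {
  a <- simulate_silac(n_proteins = 20, seed = 5)
  b <- simulate_silac(n_proteins = 20, seed = 5)
  c <- simulate_silac(n_proteins = 20, seed = 6)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$records$ratio_hm, c$records$ratio_hm))

  t1 <- simulate_trajectories(n_cells = 2, puncta_per_cell = 5,
                              duration_h = 6, seed = 5)
  t2 <- simulate_trajectories(n_cells = 2, puncta_per_cell = 5,
                              duration_h = 6, seed = 5)
  expect_identical(t1$trajectories, t2$trajectories)
})

test_that("noise-free peptide ratios equal the kinetic model exactly", {
  sim <- simulate_silac(n_proteins = 15, noise_sigma_log2 = 0,
                        offset_sd_log2 = 0, seed = 2)
  truth_key <- paste(sim$truth_log2$protein_id, sim$truth_log2$timepoint_h)
  rec_key <- paste(sim$records$protein_id, sim$records$timepoint_h)
  expected <- sim$truth_log2$true_log2[match(rec_key, truth_key)]
  expect_equal(log2(sim$records$ratio_hm), expected, tolerance = 1e-12)

  null_sim <- simulate_silac(n_proteins = 10, k_true = 1, seed = 2)
  expect_true(all(null_sim$truth_log2$true_log2 == 0))
})

test_that("planted half-lives and accelerated subsets are honored", {
  sim <- simulate_silac(t_half_days = c(0.5, 0.5, 5), k_true = 0.0255,
                        noise_sigma_log2 = 0, offset_sd_log2 = 0,
                        n_reference = 0, seed = 4)
  expect_equal(sim$truth$t_half_days, c(0.5, 0.5, 5))
  acc <- simulate_silac(n_proteins = 200, accelerated_fraction = 0.3,
                        gamma = 5, noise_sigma_log2 = 0, offset_sd_log2 = 0,
                        n_reference = 0, seed = 4)
  planted <- acc$truth$accelerated
  expect_gt(sum(planted), 0)
  tl8 <- acc$truth_log2[acc$truth_log2$timepoint_h == 8, ]
  tl8 <- tl8[match(acc$truth$protein_id, tl8$protein_id), ]
  manual <- expected_log2_ratio(
    acc$truth$t_half_days / ifelse(planted, 5, 1), acc$config$k_true, 8
  )
  expect_equal(tl8$true_log2, manual, tolerance = 1e-12)
})

test_that("peptide noise is lognormal around model truth", {
  sim <- simulate_silac(n_proteins = 150, peptides_mean = 20,
                        noise_sigma_log2 = 0.2, offset_sd_log2 = 0.1,
                        seed = 11)
  truth_key <- paste(sim$truth_log2$protein_id, sim$truth_log2$timepoint_h)
  rec_key <- paste(sim$records$protein_id, sim$records$timepoint_h)
  off_key <- paste(sim$offsets$experiment_id, sim$offsets$timepoint_h)
  rec_off <- paste(sim$records$experiment_id, sim$records$timepoint_h)
  resid <- log2(sim$records$ratio_hm) -
    sim$truth_log2$true_log2[match(rec_key, truth_key)] -
    sim$offsets$offset_log2[match(rec_off, off_key)]
  expect_gt(length(resid), 10000)
  ks <- suppressWarnings(stats::ks.test(resid / 0.2, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("trajectory autocorrelation matches the mean-reverting process", {
  sim <- simulate_trajectories(n_cells = 100, puncta_per_cell = 100,
                               duration_h = 12, tau_c = 12, sigma_log = 0.2,
                               seed = 13)
  tr <- sim$trajectories
  wide <- matrix(tr$fluorescence[order(tr$timepoint_h, tr$punctum_id)],
                 ncol = 13)
  logw <- log(wide)
  n <- nrow(logw)
  for (delta in c(1, 6, 12)) {
    r <- cor(logw[, 1], logw[, 1 + delta])
    rho <- exp(-delta / 12)
    se <- (1 - rho^2) / sqrt(n)
    expect_lt(abs(r - rho), 3 * se)
  }
})

test_that("post-onset elimination follows the constant hazard", {
  sim <- simulate_trajectories(n_cells = 50, puncta_per_cell = 100,
                               duration_h = 48, treatment_onset_h = 24,
                               elimination_hazard = 0.02, seed = 19)
  survived <- is.na(sim$truth$eliminated_at_h)
  p_expected <- exp(-0.02 * 24)
  se <- sqrt(p_expected * (1 - p_expected) / 5000)
  expect_lt(abs(mean(survived) - p_expected), 3 * se)
  # eliminated puncta report NA from their elimination time on
  gone <- sim$truth$punctum_id[!survived][1]
  tr <- sim$trajectories[sim$trajectories$punctum_id == gone, ]
  t_elim <- sim$truth$eliminated_at_h[sim$truth$punctum_id == gone]
  expect_true(all(is.na(tr$fluorescence[tr$timepoint_h >= t_elim])))
  expect_true(all(!is.na(tr$fluorescence[tr$timepoint_h < t_elim])))
})

test_that("assay fixtures plant their advertised ground truth", {
  fx <- simulate_assay_fixtures(3)
  sup <- suppression_fold(fx$suppression$treated, fx$suppression$control)
  expect_equal(sup$fold, fx$suppression$truth$fold, tolerance = 0.05)
  expect_identical(sup$n_excluded, fx$suppression$truth$n_excluded)
  expect_identical(viability_ratio(fx$viability$counts)$n_skipped,
                   fx$viability$truth$n_skipped)
})
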