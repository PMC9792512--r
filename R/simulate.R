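#' Seeded synthetic-data generators
#'
#' Generators for every input the analysis consumes, with known ground truth:
#' peptide-level SILAC ratio tables produced by first-order decay under
#' suppressed synthesis, mean-reverting puncta fluorescence trajectories with
#' a treatment-onset change, planted-spot images for the detection tests and
#' small per-assay fixtures exercising each exclusion rule.
#'
#' All generators take a single integer `seed`; internally each random
#' component draws from its own named substream derived from that seed, so
#' adding a component does not perturb the draws of the others.
#'
#' @name synthetic_data
NULL

# Deterministic per-component seed derived from the root seed and a stream
# name; kept well below 2^31.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 65521L
  (abs(as.integer(seed %% 1000003L)) * 2017L + h * 31L) %% 2147483629L
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(substream_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  force(expr)
}

#' Simulate a dynamic-SILAC peptide ratio table
#'
#' Each protein gets a half-life drawn from a lognormal distribution
#' (spanning the days-to-weeks regime typical of neuronal proteins, with a
#' short-lived tail); its true log2(H/M) trajectory follows the first-order
#' kinetic model at the configured `k_true`. Peptide-level measurements add
#' a per-experiment-and-time-point mixing offset (the quantity reference
#' normalization removes) and lognormal peptide noise. A planted set of
#' long-lived reference proteins (half-lives of 100-200 days, hence
#' essentially flat over 8 h) and an optional accelerated-degradation subset
#' (degradation rate multiplied by `gamma` under treatment) are included.
#'
#' @param n_proteins Number of non-reference proteins.
#' @param k_true True fractional synthesis rate under the inhibitor.
#' @param halflife_median_days,halflife_sdlog Lognormal half-life
#'   distribution (median in days, log-scale SD).
#' @param timepoints_h Sampling times in hours (must include 0 for the
#'   downstream pipeline).
#' @param n_experiments Number of biological repeats.
#' @param peptides_mean Mean peptides per protein x experiment x time point
#'   (shifted Poisson: `1 + Poisson(peptides_mean - 1)`, so at least one).
#' @param noise_sigma_log2 Per-peptide measurement noise SD in log2 units.
#' @param offset_sd_log2 SD of the per-experiment x time point mixing
#'   offsets (log2 units); 0 disables them.
#' @param n_reference Number of planted long-lived reference proteins
#'   (ids `REF1`, `REF2`, ...).
#' @param accelerated_fraction Fraction of non-reference proteins whose
#'   degradation is accelerated under treatment.
#' @param gamma Degradation-rate multiplier for the accelerated subset.
#' @param t_half_days Optional vector of planted half-lives (days), one per
#'   protein, bypassing the lognormal draw; its length overrides
#'   `n_proteins`.
#' @param seed Root seed.
#' @return List with `records` (peptide table: `protein_id`,
#'   `experiment_id`, `timepoint_h`, `ratio_hm`, `peptide_id`), `truth`
#'   (per protein: `t_half_days`, `is_reference`, `accelerated`),
#'   `truth_log2` (per protein x time point: `true_log2`), `offsets`
#'   (per experiment x time point) and the configuration echo `config`.
#' @export
simulate_silac <- function(n_proteins = 2000, k_true = 1 / 39.2,
                           halflife_median_days = 5, halflife_sdlog = 1,
                           timepoints_h = c(0, 2, 4, 8), n_experiments = 5,
                           peptides_mean = 10, noise_sigma_log2 = 0.2,
                           offset_sd_log2 = 0.1, n_reference = 7,
                           accelerated_fraction = 0, gamma = 1,
                           t_half_days = NULL, seed = 1) {
  stopifnot(n_proteins >= 1, k_true >= 0, k_true <= 1, peptides_mean >= 1,
            accelerated_fraction >= 0, accelerated_fraction <= 1, gamma >= 1)
  if (!is.null(t_half_days)) {
    stopifnot(all(t_half_days > 0))
    n_proteins <- length(t_half_days)
  }
  t_half <- if (!is.null(t_half_days)) {
    t_half_days
  } else {
    with_substream(seed, "halflives", {
      stats::rlnorm(n_proteins, meanlog = log(halflife_median_days),
                    sdlog = halflife_sdlog)
    })
  }
  ref_t_half <- if (n_reference > 0) {
    with_substream(seed, "reference", stats::runif(n_reference, 100, 200))
  } else {
    numeric(0)
  }
  accelerated <- with_substream(seed, "accelerated", {
    stats::runif(n_proteins) < accelerated_fraction
  })
  ids <- sprintf("P%05d", seq_len(n_proteins))
  # planted reference proteins carry the real reference-set names (so the
  # default normalization works on simulated tables), extended if more than
  # seven are requested
  ref_ids <- utils::head(c(default_reference_proteins(),
                           paste0("REF", seq_len(max(0, n_reference - 7)))),
                         n_reference)
  truth <- data.frame(
    protein_id = c(ids, ref_ids),
    t_half_days = c(t_half, ref_t_half),
    is_reference = c(rep(FALSE, n_proteins), rep(TRUE, n_reference)),
    accelerated = c(accelerated, rep(FALSE, n_reference)),
    stringsAsFactors = FALSE
  )
  # accelerated degradation = beta multiplied by gamma = half-life / gamma
  eff_t_half <- truth$t_half_days / ifelse(truth$accelerated, gamma, 1)
  truth_log2 <- expand.grid(protein_id = truth$protein_id,
                            timepoint_h = timepoints_h,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  truth_log2$true_log2 <- expected_log2_ratio(
    eff_t_half[match(truth_log2$protein_id, truth$protein_id)],
    k_true, truth_log2$timepoint_h
  )
  exp_ids <- paste0("E", seq_len(n_experiments))
  offsets <- expand.grid(experiment_id = exp_ids, timepoint_h = timepoints_h,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  offsets$offset_log2 <- if (offset_sd_log2 > 0) {
    with_substream(seed, "offsets",
                   stats::rnorm(nrow(offsets), 0, offset_sd_log2))
  } else {
    rep(0, nrow(offsets))
  }

  grid <- expand.grid(protein_id = truth$protein_id,
                      experiment_id = exp_ids, timepoint_h = timepoints_h,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_pep <- with_substream(seed, "peptide_counts", {
    1L + stats::rpois(nrow(grid), peptides_mean - 1)
  })
  rows <- rep(seq_len(nrow(grid)), n_pep)
  records <- grid[rows, , drop = FALSE]
  key_t <- paste(records$protein_id, records$timepoint_h)
  tl_key <- paste(truth_log2$protein_id, truth_log2$timepoint_h)
  true_part <- truth_log2$true_log2[match(key_t, tl_key)]
  off_key <- paste(records$experiment_id, records$timepoint_h)
  o_key <- paste(offsets$experiment_id, offsets$timepoint_h)
  offset_part <- offsets$offset_log2[match(off_key, o_key)]
  noise <- if (noise_sigma_log2 > 0) {
    with_substream(seed, "peptide_noise",
                   stats::rnorm(nrow(records), 0, noise_sigma_log2))
  } else {
    rep(0, nrow(records))
  }
  records$ratio_hm <- 2^(true_part + offset_part + noise)
  records$peptide_id <- paste0(
    "pep_", stats::ave(seq_len(nrow(records)),
                       paste(records$protein_id, records$experiment_id,
                             records$timepoint_h),
                       FUN = seq_along)
  )
  rownames(records) <- NULL
  list(records = records, truth = truth, truth_log2 = truth_log2,
       offsets = offsets,
       config = list(n_proteins = n_proteins, k_true = k_true,
                     halflife_median_days = halflife_median_days,
                     halflife_sdlog = halflife_sdlog,
                     timepoints_h = timepoints_h,
                     n_experiments = n_experiments,
                     peptides_mean = peptides_mean,
                     noise_sigma_log2 = noise_sigma_log2,
                     offset_sd_log2 = offset_sd_log2,
                     n_reference = n_reference,
                     accelerated_fraction = accelerated_fraction,
                     gamma = gamma, seed = seed))
}

#' Simulate mean-reverting puncta fluorescence trajectories
#'
#' Each punctum's log fluorescence follows a stationary Ornstein-Uhlenbeck
#' (mean-reverting) process with reversion time scale `tau_c` and stationary
#' SD `sigma_log`, discretized at the sampling interval; fluorescence is its
#' exponential times a per-cell gain. The lag-\eqn{\Delta} autocorrelation of
#' the log process is \eqn{e^{-\Delta/\tau_c}}, so the population
#' \eqn{R^2(\Delta)} of the tenacity regression is \eqn{e^{-2\Delta/\tau_c}}.
#' From `treatment_onset_h` the innovation SD is multiplied by
#' `volatility_multiplier`, a downward drift `drift_per_h` (log units/hour)
#' is applied, and puncta are eliminated with constant hazard
#' `elimination_hazard` (per hour); eliminated puncta report `NA` from the
#' elimination time on.
#'
#' @param n_cells,puncta_per_cell Number of cells and puncta per cell.
#' @param interval_h Sampling interval (hours).
#' @param duration_h Total duration (hours); samples at `0, interval_h, ...,
#'   duration_h`.
#' @param tau_c Mean-reversion time scale (hours).
#' @param sigma_log Stationary SD of log fluorescence.
#' @param mean_fluorescence Median punctum fluorescence (AU) before gains.
#' @param cell_gain_sdlog Log-scale SD of per-cell gains (0 = identical
#'   cells).
#' @param treatment_onset_h Onset of the treatment regime (set beyond
#'   `duration_h` for an untreated run).
#' @param volatility_multiplier Innovation-SD multiplier after onset.
#' @param drift_per_h Downward drift of log fluorescence per hour after
#'   onset.
#' @param elimination_hazard Per-hour elimination probability rate after
#'   onset.
#' @param condition Label copied into the trajectory table.
#' @param seed Root seed.
#' @return List with `trajectories` (long data frame `cell_id`,
#'   `punctum_id`, `condition`, `timepoint_h`, `fluorescence`), `truth`
#'   (per punctum: `cell_id`, `gain`, `eliminated_at_h` or `NA`) and
#'   `config`.
#' @export
simulate_trajectories <- function(n_cells = 10, puncta_per_cell = 50,
                                  interval_h = 1, duration_h = 48,
                                  tau_c = 12, sigma_log = 0.2,
                                  mean_fluorescence = 1000,
                                  cell_gain_sdlog = 0,
                                  treatment_onset_h = Inf,
                                  volatility_multiplier = 1,
                                  drift_per_h = 0, elimination_hazard = 0,
                                  condition = "control", seed = 1) {
  stopifnot(tau_c > 0, sigma_log >= 0, interval_h > 0,
            volatility_multiplier >= 0, elimination_hazard >= 0)
  times <- seq(0, duration_h, by = interval_h)
  n_steps <- length(times)
  n_puncta <- n_cells * puncta_per_cell
  phi <- exp(-interval_h / tau_c)
  innov_sd <- sigma_log * sqrt(1 - phi^2)
  mu <- log(mean_fluorescence)

  x <- matrix(NA_real_, n_puncta, n_steps)
  x[, 1] <- with_substream(seed, "initial",
                           stats::rnorm(n_puncta, mu, sigma_log))
  innov <- with_substream(seed, "innovations", {
    matrix(stats::rnorm(n_puncta * (n_steps - 1)), n_puncta, n_steps - 1)
  })
  elim_u <- with_substream(seed, "elimination", {
    matrix(stats::runif(n_puncta * (n_steps - 1)), n_puncta, n_steps - 1)
  })
  gains <- if (cell_gain_sdlog > 0) {
    with_substream(seed, "gains", stats::rlnorm(n_cells, 0, cell_gain_sdlog))
  } else {
    rep(1, n_cells)
  }

  eliminated_at <- rep(NA_real_, n_puncta)
  alive <- rep(TRUE, n_puncta)
  for (s in seq_len(n_steps - 1)) {
    treated <- times[s + 1] > treatment_onset_h
    sd_s <- innov_sd * if (treated) volatility_multiplier else 1
    drift <- if (treated) drift_per_h * interval_h else 0
    x[, s + 1] <- mu + phi * (x[, s] - mu) - drift + sd_s * innov[, s]
    if (treated && elimination_hazard > 0) {
      p_elim <- 1 - exp(-elimination_hazard * interval_h)
      dying <- alive & (elim_u[, s] < p_elim)
      eliminated_at[dying] <- times[s + 1]
      alive[dying] <- FALSE
    }
    x[!alive, s + 1] <- NA_real_
  }

  cell_of <- rep(seq_len(n_cells), each = puncta_per_cell)
  fluor <- exp(x) * gains[cell_of]
  punctum_ids <- sprintf("c%03d_p%03d", cell_of,
                         rep(seq_len(puncta_per_cell), times = n_cells))
  trajectories <- data.frame(
    cell_id = sprintf("c%03d", rep(cell_of, times = n_steps)),
    punctum_id = rep(punctum_ids, times = n_steps),
    condition = condition,
    timepoint_h = rep(times, each = n_puncta),
    fluorescence = as.vector(fluor),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    punctum_id = punctum_ids, cell_id = sprintf("c%03d", cell_of),
    gain = gains[cell_of], eliminated_at_h = eliminated_at,
    stringsAsFactors = FALSE
  )
  list(trajectories = trajectories, truth = truth,
       config = list(n_cells = n_cells, puncta_per_cell = puncta_per_cell,
                     interval_h = interval_h, duration_h = duration_h,
                     tau_c = tau_c, sigma_log = sigma_log,
                     mean_fluorescence = mean_fluorescence,
                     cell_gain_sdlog = cell_gain_sdlog,
                     treatment_onset_h = treatment_onset_h,
                     volatility_multiplier = volatility_multiplier,
                     drift_per_h = drift_per_h,
                     elimination_hazard = elimination_hazard,
                     condition = condition, seed = seed))
}

#' Simulate an image with planted Gaussian spots
#'
#' Spots are placed by rejection sampling with a minimum pairwise separation
#' and a border margin, rendered as isotropic Gaussian profiles, and
#' corrupted with additive Gaussian pixel noise. The signal-to-noise ratio is
#' amplitude / noise SD.
#'
#' @param n_spots Number of spots.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param amplitude Peak amplitude of each spot (AU).
#' @param sigma_px Spot width (pixels).
#' @param snr Signal-to-noise ratio; noise SD is `amplitude / snr`
#'   (`Inf` = noiseless).
#' @param min_separation Minimum center-to-center distance (pixels).
#' @param margin Minimum distance of centers from the border (pixels).
#' @param background Constant background level (AU).
#' @param seed Root seed.
#' @return List with `image` (matrix) and `centers` (data frame `row`,
#'   `col`, `amplitude`).
#' @export
simulate_spot_image <- function(n_spots = 50, dim = c(256, 256),
                                amplitude = 200, sigma_px = 1.5, snr = 10,
                                min_separation = 12, margin = 10,
                                background = 100, seed = 1) {
  centers <- with_substream(seed, "centers", {
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(pts) < n_spots && tries < 20000) {
      cand <- c(stats::runif(1, margin + 1, dim[1] - margin),
                stats::runif(1, margin + 1, dim[2] - margin))
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
            min_separation) {
        pts <- rbind(pts, cand)
      }
      tries <- tries + 1
    }
    if (nrow(pts) < n_spots) {
      stop("could not place the requested spots; reduce n_spots or ",
           "min_separation", call. = FALSE)
    }
    round(pts)
  })
  img <- matrix(background, dim[1], dim[2])
  support <- ceiling(4 * sigma_px)
  for (i in seq_len(n_spots)) {
    r0 <- centers[i, 1]
    c0 <- centers[i, 2]
    rr <- max(1, r0 - support):min(dim[1], r0 + support)
    cc <- max(1, c0 - support):min(dim[2], c0 + support)
    prof <- amplitude *
      outer(exp(-((rr - r0)^2) / (2 * sigma_px^2)),
            exp(-((cc - c0)^2) / (2 * sigma_px^2)))
    img[rr, cc] <- img[rr, cc] + prof
  }
  if (is.finite(snr)) {
    noise <- with_substream(seed, "pixel_noise", {
      matrix(stats::rnorm(prod(dim), 0, amplitude / snr), dim[1], dim[2])
    })
    img <- img + noise
  }
  list(image = img,
       centers = data.frame(row = centers[, 1], col = centers[, 2],
                            amplitude = amplitude))
}

#' Deterministic small fixtures for the functional assays
#'
#' Produces one small fixture per assay, each exercising the assay's
#' exclusion rules with planted ground truth: a suppression fixture with a
#' known fold and one unusable cell, an FM fixture with sub-600-AU boutons
#' and known responder status, a viability fixture with a zero-total field,
#' an activity fixture with a planted post-treatment downward drift, and a
#' flux plate with textbook-shaped wells plus one oligomycin-increase well.
#'
#' @param seed Root seed.
#' @return Named list `suppression`, `fm`, `viability`, `activity`, `flux`;
#'   each element carries its input tables and a `truth` list.
#' @export
simulate_assay_fixtures <- function(seed = 1) {
  # --- suppression: planted fold of 10, one cell with non-positive mTurq
  n <- 20
  noise <- with_substream(seed, "suppression", stats::rnorm(2 * n, 0, 0.02))
  control <- data.frame(
    cell_id = paste0("ctl", seq_len(n)),
    jf_mean = 1000 * (1 + noise[seq_len(n)]) + 50,
    mturq_mean = 1000 + 30, background_jf = 50, background_mturq = 30
  )
  treated <- data.frame(
    cell_id = paste0("trt", seq_len(n)),
    jf_mean = 100 * (1 + noise[n + seq_len(n)]) + 50,
    mturq_mean = 1000 + 30, background_jf = 50, background_mturq = 30
  )
  treated$mturq_mean[n] <- 10  # below its background: must be excluded
  suppression <- list(treated = treated, control = control,
                      truth = list(fold = 10, n_excluded = 1L))

  # --- FM: 10 boutons, 3 below the 600 AU baseline floor, known responders
  fm_traces <- data.frame(
    bouton_id = paste0("b", 1:10),
    baseline_mean = c(500, 500, 500, rep(800, 7)),
    load_value = c(rep(1000, 10)),
    unload_value = c(400, 400, 400, 400, 300, 500, 850, 900, 200, 100)
  )
  # analyzed boutons 4-10: fractions .6 .7 .5 .15 .10 .8 .9 -> 5 responders
  fm <- list(traces = fm_traces,
             truth = list(n_excluded_baseline = 3L, n_analyzed = 7L,
                          n_responders = 5L))

  # --- viability: 3 informative fields plus one empty field
  viability <- list(
    counts = data.frame(field_id = paste0("f", 1:4),
                        n_calcein = c(9, 8, 10, 0), n_pi = c(1, 2, 0, 0)),
    truth = list(mean = 0.9, n_skipped = 1L)
  )

  # --- activity: 8 experiments, flat pre-window, drifting post-window
  n_bins <- 360
  activity_series <- with_substream(seed, "activity", {
    lapply(seq_len(8), function(i) {
      base <- 100 + stats::rnorm(n_bins, 0, 5)
      drift <- c(rep(0, 180), -0.05 * seq_len(180))
      pmax(base + drift, 0)
    })
  })
  activity <- list(series = activity_series,
                   pre_window = 1:180, post_window = 181:360,
                   truth = list(drift_per_bin = -0.05))

  # --- flux: 4 textbook wells, 1 oligomycin-increase well, 3 background
  baseline <- rep(100, 5); oligo <- rep(60, 5)
  fccp <- rep(180, 5); rot <- rep(20, 5)
  good <- c(baseline, oligo, fccp, rot)
  bad_oligo <- c(baseline, rep(120, 5), fccp, rot)
  bg <- rep(10, 20)
  samples <- rbind(good, good, good, good, bad_oligo) + 10
  plate <- rbind(samples, bg, bg, bg)
  rownames(plate) <- c(paste0("W", 1:5), paste0("BG", 1:3))
  flux <- list(values = plate, background_wells = paste0("BG", 1:3),
               truth = list(n_flagged_oligo = 1L, n_clean = 4L))

  list(suppression = suppression, fm = fm, viability = viability,
       activity = activity, flux = flux)
}
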