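#' Quantification of functional assay readouts
#'
#' Procedures for the functional readouts that accompany the proteomic and
#' imaging analyses: fold suppression of protein synthesis from a two-channel
#' reporter-dilution assay, FM dye destaining (synaptic vesicle recycling),
#' calcein/PI viability counts, multielectrode-array spike-rate series, and
#' extracellular flux (OCR/ECAR) plate normalization with its exclusion
#' rules.
#'
#' @name functional_assays
NULL

#' Fold suppression of protein synthesis from reporter fluorescence
#'
#' Each cell expressing the HaloTag reporter contributes a background-
#' subtracted ratio of newly synthesized reporter (JF ligand channel) to
#' total reporter (mTurquoise2 channel). The fold suppression is the mean
#' control ratio divided by the mean treated ratio; its reciprocal is the
#' fractional synthesis rate `k` fed to the kinetic model (see
#' [k_from_fold_suppression()]).
#'
#' @param treated,control Data frames with columns `jf_mean`, `mturq_mean`,
#'   `background_jf`, `background_mturq`, one row per cell.
#' @return List with `fold`, per-group cell ratios (`treated_ratios`,
#'   `control_ratios`) and `n_excluded` (cells whose background-subtracted
#'   mTurquoise signal was not positive).
#' @export
suppression_fold <- function(treated, control) {
  cell_ratios <- function(d) {
    stopifnot(all(c("jf_mean", "mturq_mean", "background_jf",
                    "background_mturq") %in% names(d)))
    if (nrow(d) == 0) stop("empty cell table", call. = FALSE)
    denom <- d$mturq_mean - d$background_mturq
    ok <- denom > 0
    list(ratios = (d$jf_mean - d$background_jf)[ok] / denom[ok],
         n_excluded = sum(!ok))
  }
  tr <- cell_ratios(treated)
  ct <- cell_ratios(control)
  if (length(tr$ratios) == 0 || length(ct$ratios) == 0) {
    stop("no analyzable cells in one of the groups", call. = FALSE)
  }
  list(fold = mean(ct$ratios) / mean(tr$ratios),
       treated_ratios = tr$ratios, control_ratios = ct$ratios,
       n_excluded = tr$n_excluded + ct$n_excluded)
}

#' FM dye fractional release and responder classification
#'
#' Boutons whose mean baseline fluorescence falls below `baseline_min`
#' (600 AU by default) are excluded as unreliable. For the rest, the
#' fraction of dye released by the unloading stimulus is
#' `(load - unload) / load`; boutons releasing more than
#' `responder_threshold` (15%) are classified as responders — smaller
#' reductions are within the range attributable to washout and
#' photobleaching.
#'
#' @param traces Data frame with `bouton_id`, `load_value`, `unload_value`
#'   and either a `baseline_mean` column or a list-column `baseline_values`.
#' @param baseline_min Minimum mean baseline fluorescence (AU).
#' @param responder_threshold Minimum fractional release counted as a
#'   response.
#' @return List with `boutons` (per analyzed bouton: `fraction_released`,
#'   `responder`), `n_excluded_baseline`, `n_excluded_zero_load`,
#'   `responder_percent` and `mean_fraction_released`.
#' @export
fm_release <- function(traces, baseline_min = 600,
                       responder_threshold = 0.15) {
  stopifnot(all(c("bouton_id", "load_value", "unload_value") %in%
                  names(traces)))
  if ("baseline_mean" %in% names(traces)) {
    base <- traces$baseline_mean
  } else if ("baseline_values" %in% names(traces)) {
    base <- vapply(traces$baseline_values, mean, numeric(1))
  } else {
    stop("traces need a baseline_mean or baseline_values column",
         call. = FALSE)
  }
  keep <- base >= baseline_min
  n_excl_base <- sum(!keep)
  d <- traces[keep, , drop = FALSE]
  zero_load <- d$load_value == 0
  n_excl_zero <- sum(zero_load)
  d <- d[!zero_load, , drop = FALSE]
  frac <- (d$load_value - d$unload_value) / d$load_value
  responder <- frac > responder_threshold
  list(
    boutons = data.frame(bouton_id = d$bouton_id,
                         fraction_released = frac, responder = responder,
                         stringsAsFactors = FALSE),
    n_excluded_baseline = n_excl_base,
    n_excluded_zero_load = n_excl_zero,
    responder_percent = if (length(frac)) 100 * mean(responder) else NA_real_,
    mean_fraction_released = if (length(frac)) mean(frac) else NA_real_
  )
}

#' Cell viability from calcein / propidium-iodide counts
#'
#' Per field of view, viability is the number of calcein-positive (live)
#' cells over the total count (live + PI-positive); fields with no cells are
#' skipped and counted.
#'
#' @param counts Data frame with `n_calcein` and `n_pi` per field of view.
#' @return List with `per_field` fractions, `mean`, `sem` (SD over fields /
#'   sqrt(number of fields)) and `n_skipped`.
#' @export
viability_ratio <- function(counts) {
  stopifnot(all(c("n_calcein", "n_pi") %in% names(counts)))
  if (any(counts$n_calcein < 0) || any(counts$n_pi < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  total <- counts$n_calcein + counts$n_pi
  ok <- total > 0
  if (!any(ok)) stop("no field with a positive total count", call. = FALSE)
  frac <- counts$n_calcein[ok] / total[ok]
  list(per_field = frac, mean = mean(frac),
       sem = if (sum(ok) > 1) stats::sd(frac) / sqrt(sum(ok)) else NA_real_,
       n_skipped = sum(!ok))
}

#' Normalize a spike-rate series to its baseline window
#'
#' Spike counts accumulated in uniform (1-minute) bins are divided by the
#' mean count over the baseline window — the first 3 hours of recording in
#' acute experiments, or the first 24 hours in perfused long-term
#' experiments.
#'
#' @param counts Numeric vector of spike counts per bin.
#' @param baseline_bins Indices of the baseline window (default: first 180
#'   bins, i.e. 3 h of 1-minute bins).
#' @return Normalized rate series.
#' @export
activity_normalize <- function(counts, baseline_bins = seq_len(180)) {
  stopifnot(length(baseline_bins) >= 1,
            max(baseline_bins) <= length(counts))
  if (any(counts < 0)) stop("spike counts must be non-negative", call. = FALSE)
  m <- mean(counts[baseline_bins])
  if (!is.finite(m) || m <= 0) {
    stop("baseline mean spike rate is not positive", call. = FALSE)
  }
  counts / m
}

ols_slope <- function(y, x = seq_along(y)) {
  fit <- stats::lm.fit(cbind(1, x), y)
  unname(fit$coefficients[2])
}

#' Paired comparison of activity slopes before and after treatment
#'
#' Fits an ordinary least-squares line to each experiment's normalized
#' activity series separately over the pre- and post-treatment windows and
#' compares the slopes by a two-sided paired t-test across experiments.
#'
#' @param experiments List of normalized rate series (one per experiment).
#' @param pre_window,post_window Index vectors into each series.
#' @return List with `slopes` (data frame `pre`, `post` per experiment),
#'   `p_value` (`NA` with fewer than 2 experiments) and `t_statistic`.
#' @export
activity_slope_test <- function(experiments, pre_window, post_window) {
  stopifnot(is.list(experiments), length(experiments) >= 1)
  slopes <- t(vapply(experiments, function(s) {
    stopifnot(max(pre_window) <= length(s), max(post_window) <= length(s))
    c(pre = ols_slope(s[pre_window], pre_window),
      post = ols_slope(s[post_window], post_window))
  }, numeric(2)))
  slopes <- as.data.frame(slopes)
  if (nrow(slopes) < 2) {
    return(list(slopes = slopes, p_value = NA_real_, t_statistic = NA_real_))
  }
  diffs <- slopes$post - slopes$pre
  if (stats::sd(diffs) == 0) {
    # identical slope changes in every experiment: no variance to test
    return(list(slopes = slopes,
                p_value = if (abs(mean(diffs)) < 1e-12) 1 else NA_real_,
                t_statistic = 0))
  }
  tt <- stats::t.test(slopes$post, slopes$pre, paired = TRUE)
  list(slopes = slopes, p_value = tt$p.value,
       t_statistic = unname(tt$statistic))
}

#' Normalize an extracellular flux plate and flag failed wells
#'
#' Per measurement cycle, the mean of the background (cell-free perimeter)
#' wells is subtracted from every sample well; each well is then divided by
#' its own fifth baseline measurement (the most stable baseline cycle) and
#' expressed as percent of baseline. Wells with pharmacological delivery
#' failures are flagged: increased OCR after oligomycin (post-oligomycin
#' mean above the baseline mean), no FCCP response (post-FCCP mean not above
#' `fccp_factor` times the post-oligomycin mean) or no rotenone/antimycin-A
#' response (post-Rot/AA mean not below the post-FCCP mean).
#'
#' @param values Numeric matrix, wells x measurement cycles.
#' @param background_wells Indices (or row names) of the cell-free
#'   background wells.
#' @param cycles Named list of index vectors into the cycle axis:
#'   `baseline`, `oligomycin`, `fccp`, `rot_aa` (any of the injection
#'   windows may be omitted, disabling the corresponding flag).
#' @param baseline_reference Which baseline cycle anchors the 100% level
#'   (default the fifth).
#' @param fccp_factor Required ratio of post-FCCP to post-oligomycin OCR for
#'   a well to count as FCCP-responsive.
#' @return List with `normalized` (percent-of-baseline matrix for retained
#'   sample wells), `flags` (data frame of per-well exclusion flags) and
#'   `n_excluded_nonpositive_baseline`.
#' @export
flux_normalize <- function(values, background_wells,
                           cycles = list(baseline = 1:5, oligomycin = 6:10,
                                         fccp = 11:15, rot_aa = 16:20),
                           baseline_reference = 5, fccp_factor = 1.1) {
  stopifnot(is.matrix(values), length(cycles$baseline) >= baseline_reference)
  if (is.character(background_wells)) {
    background_wells <- match(background_wells, rownames(values))
  }
  stopifnot(length(background_wells) >= 1,
            all(background_wells %in% seq_len(nrow(values))))
  sample_wells <- setdiff(seq_len(nrow(values)), background_wells)
  bg <- colMeans(values[background_wells, , drop = FALSE])
  corrected <- sweep(values[sample_wells, , drop = FALSE], 2, bg)
  ref_cycle <- cycles$baseline[baseline_reference]
  ref <- corrected[, ref_cycle]
  ok <- ref > 0
  n_bad <- sum(!ok)
  corrected <- corrected[ok, , drop = FALSE]
  normalized <- 100 * corrected / corrected[, ref_cycle]
  win_mean <- function(m, idx) rowMeans(m[, idx, drop = FALSE])
  base_mean <- win_mean(normalized, cycles$baseline)
  flags <- data.frame(well = sample_wells[ok])
  if (!is.null(cycles$oligomycin)) {
    oligo <- win_mean(normalized, cycles$oligomycin)
    flags$increased_after_oligomycin <- oligo > base_mean
  }
  if (!is.null(cycles$fccp) && !is.null(cycles$oligomycin)) {
    fccp <- win_mean(normalized, cycles$fccp)
    flags$no_fccp_response <- fccp <= fccp_factor * oligo
  }
  if (!is.null(cycles$rot_aa) && !is.null(cycles$fccp)) {
    rot <- win_mean(normalized, cycles$rot_aa)
    flags$no_rot_aa_response <- rot >= fccp
  }
  flag_cols <- setdiff(names(flags), "well")
  flags$excluded <- if (length(flag_cols)) {
    Reduce(`|`, flags[flag_cols])
  } else {
    rep(FALSE, nrow(flags))
  }
  list(normalized = normalized, flags = flags,
       n_excluded_nonpositive_baseline = n_bad)
}
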