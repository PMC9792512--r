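#' Synapse tenacity from tracked puncta trajectories
#'
#' Individual fluorescently tagged postsynaptic puncta (e.g. PSD-95:EGFP or
#' mCherry:Gephyrin clusters) are tracked at hourly intervals. Tenacity — the
#' capacity of each synapse to preserve its molecular "size" — is quantified
#' by regressing, across puncta, the normalized fluorescence at increasing
#' time intervals \eqn{\Delta} on the fluorescence at the start of an analysis
#' window, and following the coefficient of determination \eqn{R^2(\Delta)}.
#' A fast-decaying \eqn{R^2} curve means synaptic configurations reshuffle
#' quickly.
#'
#' Trajectories are long data frames with columns `cell_id`, `punctum_id`,
#' `condition` (optional label), `timepoint_h`, `fluorescence`.
#'
#' @name tenacity
NULL

#' Smooth a fluorescence series with a centered moving average
#'
#' A 3-point (3-hour, at hourly sampling) low-pass box filter by default;
#' series ends use the shrunken window of available samples rather than
#' padding, so no data are invented at the edges.
#'
#' @param values Numeric series sampled at uniform intervals.
#' @param width Odd window width in samples, `>= 1`.
#' @return Smoothed series of the same length.
#' @examples
#' smooth_trajectory(c(0, 3, 0, 3, 0))  # 1.5 1 2 1 1.5
#' @export
smooth_trajectory <- function(values, width = 3) {
  stopifnot(width >= 1, width %% 2 == 1)
  n <- length(values)
  if (width > n) stop("smoothing width exceeds series length", call. = FALSE)
  half <- (width - 1) %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(values[lo:hi])
  }, numeric(1))
}

#' Normalize puncta trajectories per cell
#'
#' Divides every punctum's series by the mean fluorescence of that punctum's
#' cell at `reference_time` (mean over the cell's puncta). This removes
#' cell-to-cell differences in reporter expression level so puncta from
#' different neurons and experiments can be pooled.
#'
#' @param trajectories Long trajectory data frame (see [tenacity]).
#' @param reference_time Time point (hours) whose per-cell mean defines the
#'   normalization constant.
#' @return The trajectories with `fluorescence` rescaled.
#' @export
normalize_per_cell <- function(trajectories, reference_time) {
  stopifnot(all(c("cell_id", "punctum_id", "timepoint_h", "fluorescence")
                %in% names(trajectories)))
  ref <- trajectories[trajectories$timepoint_h == reference_time, ]
  if (nrow(ref) == 0) {
    stop("no samples at reference_time = ", reference_time, call. = FALSE)
  }
  cell_means <- tapply(ref$fluorescence, ref$cell_id, mean)
  cells <- unique(trajectories$cell_id)
  missing <- setdiff(as.character(cells), names(cell_means))
  bad <- c(missing, names(cell_means)[!is.finite(cell_means) | cell_means <= 0])
  if (length(bad)) {
    stop("cell(s) without a positive reference mean: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  out <- trajectories
  out$fluorescence <- out$fluorescence /
    as.numeric(cell_means[as.character(out$cell_id)])
  out
}

#' R-squared decay curve over increasing time intervals
#'
#' For each interval `delta` (in samples, converted to hours via the sampling
#' step), fits an ordinary least-squares line of the puncta values at
#' `window_start + delta` on the values at `window_start`, across puncta, and
#' records slope, intercept and \eqn{R^2}. Smoothing and per-cell
#' normalization are expected to have been applied beforehand (smooth, then
#' normalize, then regress); \eqn{R^2} itself is invariant to any common
#' affine rescaling of the trajectories.
#'
#' @param trajectories Long trajectory data frame (see [tenacity]).
#' @param window_start Start of the analysis window (hours).
#' @param window_length Window length in hours (default one day).
#' @param label Optional window label copied into the output.
#' @return Data frame with one row per `delta_h`: `slope`, `intercept`,
#'   `r_squared`, `n` (puncta with complete pairs). Rows are `NA` when the
#'   start values have zero variance or fewer than 3 puncta are available.
#' @export
tenacity_curve <- function(trajectories, window_start, window_length = 24,
                           label = NULL) {
  stopifnot(all(c("punctum_id", "timepoint_h", "fluorescence")
                %in% names(trajectories)))
  times <- sort(unique(trajectories$timepoint_h))
  if (length(times) < 2) stop("need at least 2 time points", call. = FALSE)
  step <- unique(round(diff(times), 9))
  if (length(step) != 1) {
    stop("trajectories are not uniformly sampled", call. = FALSE)
  }
  if (!any(abs(times - window_start) < 1e-9)) {
    stop("window_start is not a sampled time point", call. = FALSE)
  }
  dt <- data.table::as.data.table(
    trajectories[, c("punctum_id", "timepoint_h", "fluorescence")]
  )
  wide <- data.table::dcast(dt, punctum_id ~ timepoint_h,
                            value.var = "fluorescence")
  mat <- as.matrix(wide[, -1])
  colnames(mat) <- names(wide)[-1]
  t0_col <- which(abs(as.numeric(colnames(mat)) - window_start) < 1e-9)
  x <- mat[, t0_col]
  deltas <- seq_len(floor(window_length / step))
  out <- data.frame(
    window = if (is.null(label)) sprintf("%g h", window_start) else label,
    delta_h = deltas * step, slope = NA_real_, intercept = NA_real_,
    r_squared = NA_real_, n = 0L, stringsAsFactors = FALSE
  )
  for (i in seq_along(deltas)) {
    target <- window_start + deltas[i] * step
    col <- which(abs(as.numeric(colnames(mat)) - target) < 1e-9)
    if (length(col) != 1) next
    y <- mat[, col]
    ok <- is.finite(x) & is.finite(y)
    out$n[i] <- sum(ok)
    if (sum(ok) < 3 || stats::var(x[ok]) == 0) next
    fit <- stats::lm.fit(cbind(1, x[ok]), y[ok])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y[ok] - mean(y[ok]))^2)
    out$slope[i] <- fit$coefficients[2]
    out$intercept[i] <- fit$coefficients[1]
    out$r_squared[i] <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  }
  out
}
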