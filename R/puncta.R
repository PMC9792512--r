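#' Puncta detection and fixed-ROI measurement
#'
#' Fluorescent puncta (synaptic specializations) are detected on maximal
#' intensity projections by band-pass filtering with a Mexican-hat kernel and
#' taking strict local fluorescence maxima within a 5-pixel radius, then
#' measured by centering a fixed square region of interest (9 x 9 pixels by
#' default, ~1.4 um x 1.4 um) on each punctum and averaging pixel
#' intensities. Images are numeric matrices indexed `[row, column]`
#' (1-based, R convention).
#'
#' @name puncta
NULL

# Separable Gaussian blur with replicate-edge padding. Row/column passes are
# implemented as sums of clamped index shifts, which keeps edge handling
# explicit (no wrap-around) and the result deterministic.
gaussian_blur <- function(image, sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pass <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    acc <- 0
    for (j in -radius:radius) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      acc <- acc + k[j + radius + 1] *
        (if (along_rows) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
    }
    acc
  }
  pass(pass(image, TRUE), FALSE)
}

#' Mexican-hat (difference-of-Gaussians) band-pass filter
#'
#' Approximates the Mexican-hat kernel as the difference of two Gaussian
#' blurs, suppressing both pixel noise (below `sigma_inner`) and slowly
#' varying background (above `sigma_outer`).
#'
#' @param image Numeric matrix of intensities.
#' @param sigma_inner,sigma_outer Standard deviations (pixels) of the center
#'   and surround Gaussians; `sigma_inner < sigma_outer`.
#' @return Filtered matrix of the same dimensions.
#' @export
mexican_hat <- function(image, sigma_inner = 1.5, sigma_outer = 3) {
  stopifnot(is.matrix(image), sigma_inner > 0, sigma_outer > sigma_inner)
  gaussian_blur(image, sigma_inner) - gaussian_blur(image, sigma_outer)
}

disk_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g <- g[g$dr^2 + g$dc^2 <= radius^2 & !(g$dr == 0 & g$dc == 0), ]
  g
}

#' Detect puncta as local maxima of the Mexican-hat-filtered image
#'
#' A pixel is a detection when its filtered value exceeds `threshold` and is
#' a strict maximum within `radius` pixels (Euclidean); exact ties within the
#' radius are broken by keeping the lexicographically smallest (row, column)
#' coordinate, so output is deterministic. Detections are returned in
#' row-major order.
#'
#' @param image Numeric matrix of intensities.
#' @param radius Local-maximum suppression radius in pixels.
#' @param sigma_inner,sigma_outer Mexican-hat filter scales (see
#'   [mexican_hat()]).
#' @param threshold Intensity threshold on the filtered image; defaults to
#'   mean + 3 SD of the filtered image.
#' @return Data frame `row`, `col`, `filtered_value`; zero rows when nothing
#'   is detected.
#' @export
detect_puncta <- function(image, radius = 5, sigma_inner = 1.5,
                          sigma_outer = 3, threshold = NULL) {
  f <- mexican_hat(image, sigma_inner, sigma_outer)
  if (is.null(threshold)) threshold <- mean(f) + 3 * stats::sd(f)
  nr <- nrow(f)
  nc <- ncol(f)
  # pad with -Inf so border pixels only compete with in-bounds neighbours
  pad <- matrix(-Inf, nr + 2 * radius, nc + 2 * radius)
  pad[radius + seq_len(nr), radius + seq_len(nc)] <- f
  keep <- f > threshold
  offs <- disk_offsets(radius)
  for (i in seq_len(nrow(offs))) {
    if (!any(keep)) break
    dr <- offs$dr[i]
    dc <- offs$dc[i]
    neigh <- pad[radius + dr + seq_len(nr), radius + dc + seq_len(nc)]
    # neighbour with larger value kills the pixel; an equal-valued neighbour
    # kills it only if that neighbour precedes it lexicographically
    lex_prior <- dr < 0 || (dr == 0 && dc < 0)
    keep <- keep & (f > neigh | (f == neigh & !lex_prior))
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    return(data.frame(row = integer(0), col = integer(0),
                      filtered_value = numeric(0)))
  }
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  ord <- order(rows, cols)
  data.frame(row = rows[ord], col = cols[ord],
             filtered_value = f[idx][ord])
}

#' Measure puncta intensities in fixed square ROIs
#'
#' Centers a `roi` x `roi` pixel region of interest on each detection and
#' reports the mean pixel intensity of the raw image within it. ROIs
#' extending past the image border are clipped to the available pixels and
#' flagged. ROIs containing any pixel at or above `saturation` are flagged
#' excluded (measurements near detector saturation are unreliable).
#'
#' @param image Numeric matrix of intensities.
#' @param centers Data frame with `row`, `col` (e.g. from
#'   [detect_puncta()]).
#' @param roi ROI side length in pixels (odd; the center pixel plus
#'   `(roi - 1) / 2` on each side).
#' @param saturation Saturation intensity cutoff, or `NULL` to disable.
#' @return `centers` with added `roi_mean`, `clipped`,
#'   `excluded_saturation`.
#' @export
measure_puncta <- function(image, centers, roi = 9, saturation = NULL) {
  stopifnot(roi >= 1, roi %% 2 == 1)
  half <- (roi - 1) %/% 2
  n <- nrow(centers)
  roi_mean <- numeric(n)
  clipped <- logical(n)
  excluded <- logical(n)
  for (i in seq_len(n)) {
    r <- centers$row[i]
    c <- centers$col[i]
    rlo <- max(1, r - half); rhi <- min(nrow(image), r + half)
    clo <- max(1, c - half); chi <- min(ncol(image), c + half)
    clipped[i] <- (rhi - rlo + 1 < roi) || (chi - clo + 1 < roi)
    px <- image[rlo:rhi, clo:chi]
    roi_mean[i] <- mean(px)
    excluded[i] <- !is.null(saturation) && any(px >= saturation)
  }
  out <- centers
  out$roi_mean <- roi_mean
  out$clipped <- clipped
  out$excluded_saturation <- excluded
  out
}

#' Normalized puncta count and fluorescence time course
#'
#' Detects and measures puncta in each image of a time series and reports
#' the counts and mean punctum fluorescence per time point, normalized to a
#' reference time point.
#'
#' @param images List of numeric matrices, one per time point.
#' @param normalization_index Index of the reference time point.
#' @param roi,saturation Passed to [measure_puncta()].
#' @param ... Passed to [detect_puncta()].
#' @return Data frame per time point: `n_puncta`, `mean_fluorescence`,
#'   `norm_count`, `norm_fluorescence`.
#' @export
puncta_timecourse <- function(images, normalization_index = 1, roi = 9,
                              saturation = NULL, ...) {
  stopifnot(length(images) >= 1,
            normalization_index %in% seq_along(images))
  per_tp <- lapply(images, function(img) {
    det <- detect_puncta(img, ...)
    meas <- measure_puncta(img, det, roi = roi, saturation = saturation)
    meas <- meas[!meas$excluded_saturation, , drop = FALSE]
    data.frame(n_puncta = nrow(meas),
               mean_fluorescence = if (nrow(meas)) mean(meas$roi_mean)
                                   else NA_real_)
  })
  out <- do.call(rbind, per_tp)
  out <- cbind(timepoint = seq_along(images), out)
  ref <- out[normalization_index, ]
  if (ref$n_puncta == 0) {
    stop("no puncta detected at the normalization time point", call. = FALSE)
  }
  out$norm_count <- out$n_puncta / ref$n_puncta
  out$norm_fluorescence <- out$mean_fluorescence / ref$mean_fluorescence
  rownames(out) <- NULL
  out
}
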