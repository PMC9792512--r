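#' First-order protein loss kinetics under partial synthesis suppression
#'
#' A protein pool at steady state is synthesized at a fixed (zero-order) rate
#' and degraded as a first-order reaction with rate constant
#' \eqn{\beta = 1/\tau}, where \eqn{\tau = t_{1/2}/\ln 2} (about
#' \eqn{1.44 \cdot t_{1/2}}). When a protein synthesis inhibitor reduces the
#' synthesis rate to a fraction \eqn{k \in [0, 1]} of its nominal value while
#' leaving degradation untouched, the residual fraction
#' \eqn{C' = C/C_0} relaxes from 1 toward the new steady state \eqn{k}:
#' \deqn{C'(t) = (1 - k)\,e^{-\beta t} + k.}
#' In a dynamic-SILAC design \eqn{C'(t)} is the expected (normalized) H/M
#' ratio, so \eqn{\log_2 C'(t)} is directly comparable to measured
#' \eqn{\log_2(H/M)} values.
#'
#' Half-lives are accepted in days (the unit half-life catalogs use) and
#' converted internally to hours, the unit of inhibitor exposure times.
#'
#' @name kinetics
NULL

HOURS_PER_DAY <- 24

#' Construct validated kinetic parameters
#'
#' @param t_half_days Protein half-life in days; positive, may be `Inf`
#'   (a protein that is not degraded on the experiment's time scale).
#' @param k Fractional synthesis rate in the presence of the inhibitor,
#'   in `[0, 1]`. `k = 1` means no suppression, `k = 0` complete shutdown.
#' @return A list of class `kinetic_params` with elements `t_half_days`,
#'   `tau_days` (= t_half / ln 2), `beta_per_day`, `beta_per_hour`, `k`.
#' @examples
#' kinetic_params(1, k = 1 / 39.2)
#' @export
kinetic_params <- function(t_half_days, k) {
  stopifnot(length(t_half_days) == 1, length(k) == 1)
  if (!is.numeric(t_half_days) || is.na(t_half_days) || t_half_days <= 0) {
    stop("t_half_days must be positive (Inf allowed)", call. = FALSE)
  }
  if (!is.numeric(k) || is.na(k) || k < 0 || k > 1) {
    stop("k must lie in [0, 1]", call. = FALSE)
  }
  tau <- t_half_days / log(2)
  structure(
    list(
      t_half_days = t_half_days,
      tau_days = tau,
      beta_per_day = 1 / tau,
      beta_per_hour = 1 / (tau * HOURS_PER_DAY),
      k = k
    ),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "Kinetic parameters: t1/2 = %g d, tau = 1.44*t1/2 = %g d, k = %g\n",
    x$t_half_days, x$tau_days, x$k
  ))
  invisible(x)
}

#' Degradation time constant from half-life
#'
#' \eqn{\tau = 1/\beta = t_{1/2}/\ln 2}. The exact constant
#' \eqn{1/\ln 2 = 1.4427...} is used; 1.44 is its familiar 3-significant-figure
#' rounding.
#'
#' @param t_half_days Half-life in days (vectorized); positive, `Inf` allowed.
#' @return Time constant in days.
#' @examples
#' tau_from_halflife(1)     # 1.4427
#' tau_from_halflife(Inf)   # Inf
#' @export
tau_from_halflife <- function(t_half_days) {
  if (any(is.na(t_half_days)) || any(t_half_days <= 0)) {
    stop("t_half_days must be positive (Inf allowed)", call. = FALSE)
  }
  t_half_days / log(2)
}

#' Degradation rate constant (per hour) from half-life in days
#'
#' @inheritParams tau_from_halflife
#' @return \eqn{\beta} in 1/hours.
#' @export
beta_per_hour <- function(t_half_days) {
  log(2) / (t_half_days * HOURS_PER_DAY)
}

#' Fractional synthesis rate from a measured fold suppression
#'
#' A PSI measured to reduce protein synthesis `fold`-fold leaves a fractional
#' synthesis rate `k = 1/fold`. The fold suppressions measured for the three
#' inhibitors in the reporter-dilution assay were 39.2 (cycloheximide),
#' 4.17 (anisomycin) and 1.93 (puromycin).
#'
#' @param fold Fold reduction in synthesis rate, `>= 1` (vectorized).
#' @return `k` in `(0, 1]`.
#' @examples
#' k_from_fold_suppression(39.2)  # ~0.0255, cycloheximide
#' @export
k_from_fold_suppression <- function(fold) {
  if (any(is.na(fold)) || any(fold < 1)) {
    stop("fold suppression must be >= 1", call. = FALSE)
  }
  1 / fold
}

#' Residual protein fraction C'(t) after inhibitor addition
#'
#' Closed-form solution of \eqn{dC'/dt = \beta k - \beta C'}, \eqn{C'(0) = 1}:
#' \eqn{C'(t) = (1-k) e^{-\beta t} + k}. Monotone non-increasing in `t`,
#' equal to 1 at `t = 0`, tending to the new steady state `k` as
#' `t` grows.
#'
#' @param t_half_days Half-life in days (recycled against `t_hours`).
#' @param k Fractional synthesis rate under the inhibitor, in `[0, 1]`.
#' @param t_hours Time since inhibitor addition, hours, `>= 0`.
#' @return Residual fraction in `(0, 1]` (in `[k, 1]` for `k > 0`).
#' @examples
#' residual_fraction(1, k = 0, t_hours = 24)  # one half-life: 0.5
#' @export
residual_fraction <- function(t_half_days, k, t_hours) {
  if (any(is.na(t_hours)) || any(t_hours < 0)) {
    stop("t_hours must be non-negative", call. = FALSE)
  }
  if (any(is.na(t_half_days)) || any(t_half_days <= 0)) {
    stop("t_half_days must be positive (Inf allowed)", call. = FALSE)
  }
  if (any(is.na(k)) || any(k < 0) || any(k > 1)) {
    stop("k must lie in [0, 1]", call. = FALSE)
  }
  beta <- beta_per_hour(t_half_days)
  (1 - k) * exp(-beta * t_hours) + k
}

#' Expected log2(H/M) ratio under the kinetic model
#'
#' \eqn{\log_2(H/M) = \log_2\!\big((1-k) e^{-\beta t} + k\big)}; 0 at
#' `t = 0`, tending to \eqn{\log_2 k} at long times (`-Inf` when `k = 0`).
#'
#' @inheritParams residual_fraction
#' @return Expected log2 ratio, `<= 0`.
#' @examples
#' expected_log2_ratio(1, k = 0, t_hours = 24)  # exactly -1
#' @export
expected_log2_ratio <- function(t_half_days, k, t_hours) {
  log2(residual_fraction(t_half_days, k, t_hours))
}

#' Estimate the fractional synthesis rate k from measured log2 ratios
#'
#' Least-squares fit of the kinetic model to a set of measurements
#' `(t_half, t, measured log2 ratio)` over `k` in `[0, 1]`:
#' minimizes \eqn{\sum_i (y_i - \log_2 C'(t_i; t_{1/2,i}, k))^2} with
#' [stats::optimize()]. The model is identifiable only when some measurements
#' have `t > 0` and finite half-lives.
#'
#' @param t_half_days Half-lives (days), one per measurement.
#' @param t_hours Exposure times (hours), one per measurement.
#' @param log2_ratio Measured log2(H/M) values.
#' @param tol Convergence tolerance passed to [stats::optimize()].
#' @return A list with `k` (the estimate), `rss` (residual sum of squares),
#'   and `n` (number of measurements used). Rows with missing values are
#'   dropped.
#' @export
estimate_k <- function(t_half_days, t_hours, log2_ratio, tol = 1e-9) {
  n <- length(log2_ratio)
  stopifnot(length(t_half_days) == n, length(t_hours) == n)
  keep <- stats::complete.cases(t_half_days, t_hours, log2_ratio)
  t_half_days <- t_half_days[keep]
  t_hours <- t_hours[keep]
  log2_ratio <- log2_ratio[keep]
  if (length(log2_ratio) < 2) {
    stop("need at least 2 complete measurements to estimate k", call. = FALSE)
  }
  informative <- t_hours > 0 & is.finite(t_half_days)
  if (!any(informative)) {
    stop("k is unidentifiable: no measurement with t > 0 and finite half-life",
         call. = FALSE)
  }
  sse <- function(k) {
    sum((log2_ratio - expected_log2_ratio(t_half_days, k, t_hours))^2)
  }
  # optimize() can miss a minimum at the boundary of the search interval,
  # so both endpoints are checked explicitly.
  opt <- stats::optimize(sse, interval = c(0, 1), tol = tol)
  cand_k <- c(opt$minimum, 0, 1)
  cand_sse <- c(opt$objective, sse(0), sse(1))
  best <- which.min(cand_sse)
  list(k = cand_k[best], rss = cand_sse[best], n = length(log2_ratio))
}
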