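# Independent oracles used across the test files. These stay independent of
# the code paths they check: the decay oracle integrates the governing ODE
# numerically instead of using the closed form, the k oracle is a dense grid
# search instead of a 1-D optimizer, and the matching oracle is a greedy
# assignment against planted ground truth.

# Fixed-step 4th-order (RK4) integration of dC'/dt = beta*k - beta*C',
# C'(0) = 1, with step <= 0.001 h, via deSolve.
integrate_residual <- function(t_half_days, k, t_hours, step = 0.001) {
  beta <- log(2) / (t_half_days * 24)
  if (all(t_hours == 0)) return(rep(1, length(t_hours)))
  times <- sort(unique(c(0, t_hours)))
  sol <- deSolve::ode(
    y = c(C = 1), times = times,
    func = function(t, y, p) list(p["beta"] * p["k"] - p["beta"] * y),
    parms = c(beta = beta, k = k),
    method = "rk4", hini = step, maxsteps = 1e6
  )
  unname(sol[match(t_hours, sol[, "time"]), "C"])
}

# Dense grid search over k at the stated resolution.
grid_search_k <- function(t_half_days, t_hours, log2_ratio,
                          resolution = 1e-4) {
  ks <- seq(0, 1, by = resolution)
  beta <- log(2) / (t_half_days * 24)
  decay <- exp(-beta * t_hours)
  sse <- vapply(ks, function(k) {
    sum((log2_ratio - log2((1 - k) * decay + k))^2)
  }, numeric(1))
  ks[which.min(sse)]
}

# Exact two-sided permutation test on the difference of group means over all
# splits of the pooled values into the two observed group sizes.
permutation_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  idx <- utils::combn(n, length(x))
  obs <- abs(mean(x) - mean(y))
  stats <- apply(idx, 2, function(i) {
    abs(mean(pooled[i]) - mean(pooled[-i]))
  })
  mean(stats >= obs - 1e-12)
}

# Greedy matching of detections to ground-truth centers within a radius;
# each truth center is matched at most once.
match_detections <- function(detected, truth, radius = 2) {
  used <- rep(FALSE, nrow(truth))
  matched <- 0L
  for (i in seq_len(nrow(detected))) {
    d2 <- (truth$row - detected$row[i])^2 + (truth$col - detected$col[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= radius^2) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(recall = matched / nrow(truth),
       precision = if (nrow(detected)) matched / nrow(detected) else 0)
}

# Peptide table for the stringent-filter fixture: per protein, peptide
# counts split over experiments so that (total peptides, experiments) are
# exactly as requested.
make_filter_fixture <- function() {
  spec <- list(
    A = c(2, 2, 1),          # (5, 3)  keep
    B = c(2, 1, 1),          # (4, 3)  drop: too few peptides
    C = c(4, 3),             # (7, 2)  drop: too few experiments
    D = c(2, 2, 2, 2, 2)     # (10, 5) keep
  )
  rows <- lapply(names(spec), function(p) {
    counts <- spec[[p]]
    do.call(rbind, lapply(seq_along(counts), function(e) {
      data.frame(protein_id = p, experiment_id = paste0("E", e),
                 timepoint_h = 8,
                 ratio_hm = rep(0.8, counts[e]),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
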