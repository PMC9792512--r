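make_records <- function(log2_by_cell) {
  # log2_by_cell: data frame protein, experiment, timepoint, list of log2s
  do.call(rbind, lapply(seq_len(nrow(log2_by_cell)), function(i) {
    vals <- log2_by_cell$log2[[i]]
    data.frame(protein_id = log2_by_cell$protein[i],
               experiment_id = log2_by_cell$experiment[i],
               timepoint_h = log2_by_cell$timepoint[i],
               ratio_hm = 2^vals, stringsAsFactors = FALSE)
  }))
}

test_that("peptide aggregation takes the median log2 ratio per cell", {
  rec <- make_records(data.frame(
    protein = c("A", "B"), experiment = "E1", timepoint = 8,
    log2 = I(list(c(-1.0, -0.5, -0.3), c(-0.2)))
  ))
  agg <- aggregate_peptides(rec)
  expect_equal(agg$log2_ratio[agg$protein_id == "A"], -0.5)
  expect_equal(agg$log2_ratio[agg$protein_id == "B"], -0.2)
  expect_equal(agg$n_peptides, c(3L, 1L))

  set.seed(11)
  vals <- -1 + rnorm(7, 0, 0.1)
  agg2 <- aggregate_peptides(make_records(data.frame(
    protein = "C", experiment = "E1", timepoint = 4, log2 = I(list(vals))
  )))
  expect_equal(agg2$log2_ratio, sort(vals)[4])  # explicit sort-and-middle
  expect_lt(abs(agg2$log2_ratio - (-1)), 0.12)
  expect_error(aggregate_peptides(rec[0, ]), "empty")
})

test_that("reference normalization subtracts the per-cell reference median", {
  # all reference proteins at H/M = 2: every log2 ratio drops by 1
  rec <- data.frame(
    protein_id = c("R1", "R2", "A"), experiment_id = "E1", timepoint_h = 2,
    ratio_hm = c(2, 2, 1)
  )
  norm <- normalize_to_reference(aggregate_peptides(rec), c("R1", "R2"))
  expect_equal(norm$log2_ratio[norm$protein_id == "A"], -1)
  expect_equal(norm$log2_ratio[norm$protein_id == "R1"], 0)

  # references with zero median leave the table unchanged
  rec2 <- data.frame(
    protein_id = c("R1", "R2", "A"), experiment_id = "E1", timepoint_h = 2,
    ratio_hm = c(2^0.1, 2^-0.1, 0.5)
  )
  norm2 <- normalize_to_reference(aggregate_peptides(rec2), c("R1", "R2"))
  expect_equal(norm2$log2_ratio[norm2$protein_id == "A"], -1)
})

test_that("normalization removes arbitrary per-experiment mixing offsets", {
  with_off <- simulate_silac(n_proteins = 40, n_experiments = 3,
                             offset_sd_log2 = 0.4, seed = 7)
  no_off <- simulate_silac(n_proteins = 40, n_experiments = 3,
                           offset_sd_log2 = 0, seed = 7)
  refs <- default_reference_proteins()
  n1 <- normalize_to_reference(aggregate_peptides(with_off$records), refs)
  n2 <- normalize_to_reference(aggregate_peptides(no_off$records), refs)
  expect_lt(max(abs(n1$log2_ratio - n2$log2_ratio)), 1e-12)
})

test_that("normalization reports unusable reference sets", {
  rec <- data.frame(protein_id = c("A", "R1"), experiment_id = "E1",
                    timepoint_h = c(2, 4), ratio_hm = 1)
  agg <- aggregate_peptides(rec)
  # R1 measured only at 4 h: the 2 h cell has no reference
  expect_error(normalize_to_reference(agg, "R1"), "E1 @ 2")
  expect_warning(
    normalize_to_reference(aggregate_peptides(
      data.frame(protein_id = c("A", "R1"), experiment_id = "E1",
                 timepoint_h = 2, ratio_hm = 1)
    ), c("R1", "R9")),
    "R9"
  )
  expect_error(normalize_to_reference(agg, "R9"), "none of the reference")
})

test_that("the stringent filter applies both thresholds per protein x timepoint", {
  agg <- aggregate_peptides(make_filter_fixture())
  kept <- filter_stringent(agg, min_peptides = 5, min_experiments = 3)
  expect_setequal(unique(kept$protein_id), c("A", "D"))
  expect_identical(nrow(filter_stringent(agg[0, ])), 0L)

  # brute-force recount oracle on a simulated proteome
  sim <- simulate_silac(n_proteins = 120, n_experiments = 5,
                        peptides_mean = 3, seed = 9)
  agg2 <- aggregate_peptides(sim$records)
  kept2 <- filter_stringent(agg2, 12, 4)
  oracle_keep <- by(agg2, list(agg2$protein_id, agg2$timepoint_h),
                    function(d) {
                      sum(d$n_peptides) >= 12 && nrow(d) >= 4
                    })
  surviving_groups <- nrow(unique(kept2[, c("protein_id", "timepoint_h")]))
  expect_identical(surviving_groups, sum(unlist(oracle_keep)))
})

two_group_estimates <- function(vals0, vals8, protein = "A") {
  data.frame(
    protein_id = protein,
    experiment_id = paste0("E", seq_along(c(vals0, vals8))),
    timepoint_h = rep(c(0, 8), c(length(vals0), length(vals8))),
    log2_ratio = c(vals0, vals8), n_peptides = 5L
  )
}

test_that("volcano flags strong losses and matches a permutation oracle", {
  v0 <- c(0.00, 0.05, -0.05, 0.02, -0.02)
  v8 <- c(-1.0, -0.9, -1.1, -1.05, -0.95)
  filler <- data.frame(  # extra proteins so the t0 SD is defined
    protein_id = rep(paste0("F", 1:5), each = 2),
    experiment_id = "E1",
    timepoint_h = rep(c(0, 8), 5),
    log2_ratio = rep(c(0.01, -0.03, 0.02, -0.01, 0.0), each = 2),
    n_peptides = 5L
  )
  est <- rbind(two_group_estimates(v0, v8), filler)
  v <- volcano(est, test_timepoints = 8)
  a_row <- v$records[v$records$protein_id == "A", ]
  expect_lt(a_row$p_value, 1e-5)
  expect_true(a_row$passes_significance)
  expect_equal(a_row$log2_fc, mean(v8) - mean(v0))
  # the exact permutation test agrees the split is as extreme as possible
  expect_equal(permutation_p(v8, v0), 2 / choose(10, 5))
})

test_that("volcano magnitude rule is two SD of the t0 population", {
  set.seed(21)
  m0 <- rnorm(40)
  m0 <- (m0 - mean(m0)) / sd(m0) * 0.26  # population SD exactly 0.26
  est <- data.frame(
    protein_id = rep(paste0("P", 1:40), 2),
    experiment_id = "E1",
    timepoint_h = rep(c(0, 8), each = 40),
    log2_ratio = c(m0, m0), n_peptides = 5L
  )
  v <- volcano(est, test_timepoints = 8)
  expect_equal(v$magnitude_threshold, 0.52, tolerance = 1e-12)
  # the threshold corresponds to a ~30% reduction in H/M
  expect_equal(round(2^(-v$magnitude_threshold), 2), 0.70)
  # identical values at t and t0: zero fold change, below magnitude
  expect_true(all(v$records$log2_fc == 0))
  expect_false(any(v$records$passes_magnitude))
})

test_that("volcano handles missing repeats and baseline self-comparison", {
  est <- two_group_estimates(c(0, 0.1), -0.5)  # single 8 h repeat
  v <- volcano(est, test_timepoints = 8)
  expect_true(is.na(v$records$p_value))
  expect_false(v$records$passes_significance)
  # t0 against itself: exact zeros
  sim <- simulate_silac(n_proteins = 30, seed = 3)
  agg <- aggregate_peptides(sim$records)
  v0 <- volcano(agg, test_timepoints = 0)
  expect_true(all(v0$records$log2_fc == 0))
})

test_that("hit_4and8 requires passing both rules at both later timepoints", {
  mk <- function(p, fc4, fc8) {
    data.frame(protein_id = p,
               experiment_id = rep(paste0("E", 1:5), 3),
               timepoint_h = rep(c(0, 4, 8), each = 5),
               log2_ratio = c(rnorm(5, 0, 0.01), rnorm(5, fc4, 0.01),
                              rnorm(5, fc8, 0.01)),
               n_peptides = 5L)
  }
  set.seed(31)
  est <- rbind(mk("HIT", -1, -1.2), mk("LATE", 0, -1.1),
               mk("FLAT", 0.002, -0.001))
  v <- volcano(est, test_timepoints = c(4, 8))
  expect_identical(v$hit_4and8_ids, "HIT")
  hit_rows <- v$records[v$records$protein_id == "HIT", ]
  expect_true(all(hit_rows$klass == "hit_4and8"))
  late8 <- v$records[v$records$protein_id == "LATE" &
                       v$records$timepoint_h == 8, ]
  expect_identical(late8$klass, "significant")
})

test_that("model comparison is perfectly correlated on noise-free data", {
  sim <- simulate_silac(n_proteins = 60, k_true = 0.0255,
                        noise_sigma_log2 = 0, offset_sd_log2 = 0,
                        n_reference = 0, seed = 5)
  agg <- aggregate_peptides(sim$records)
  hl <- sim$truth[, c("protein_id", "t_half_days")]
  cmp <- compare_to_model(agg, hl, k = 0.0255)
  ok <- !is.na(cmp$correlations$r)
  expect_true(any(ok))
  expect_true(all(abs(cmp$correlations$r[ok] - 1) < 1e-9))
  expect_equal(cmp$n_missing_halflife, 0)
  expect_lt(max(abs(cmp$table$mean_log2 - cmp$table$expected_log2)), 1e-12)
})

test_that("ranks are ascending by loss with average-rank ties", {
  est <- data.frame(protein_id = c("A", "B", "C"), experiment_id = "E1",
                    timepoint_h = 2, log2_ratio = c(-2, -1, 0),
                    n_peptides = 5L)
  rk <- rank_proteins(est, timepoints = 2)
  expect_equal(rk$ranks$mean_rank[match(c("A", "B", "C"),
                                        rk$ranks$protein_id)], c(1, 2, 3))
  est$log2_ratio <- c(-1, -1, 0)
  rk2 <- rank_proteins(est, timepoints = 2)
  expect_equal(rk2$ranks$mean_rank[match(c("A", "B", "C"),
                                         rk2$ranks$protein_id)],
               c(1.5, 1.5, 3))
})

test_that("multi-timepoint ranks equal the brute-force mean of sorted ranks", {
  set.seed(41)
  ids <- paste0("P", 1:25)
  est <- do.call(rbind, lapply(c(2, 4, 8), function(tp) {
    data.frame(protein_id = ids, experiment_id = "E1", timepoint_h = tp,
               log2_ratio = sample(seq(-2, 2, length.out = 25)),
               n_peptides = 5L)
  }))
  rk <- rank_proteins(est)
  oracle <- sapply(ids, function(p) {
    mean(sapply(c(2, 4, 8), function(tp) {
      d <- est[est$timepoint_h == tp, ]
      which(d$protein_id[order(d$log2_ratio)] == p)
    }))
  })
  expect_equal(rk$ranks$mean_rank[match(ids, rk$ranks$protein_id)],
               unname(oracle))
  expect_equal(rk$ranks$log10_rank, log10(rk$ranks$mean_rank))

  # invariance under a strictly monotone transform of the values
  est2 <- est
  est2$log2_ratio <- tanh(est2$log2_ratio) * 3 + 1
  rk2 <- rank_proteins(est2)
  expect_equal(rk$ranks$mean_rank[match(ids, rk$ranks$protein_id)],
               rk2$ranks$mean_rank[match(ids, rk2$ranks$protein_id)])
})

test_that("group rank summaries cover whole-set, disjoint and planted groups", {
  set.seed(51)
  ids <- paste0("P", 1:30)
  est <- data.frame(protein_id = ids, experiment_id = "E1", timepoint_h = 2,
                    log2_ratio = rnorm(30), n_peptides = 5L)
  rk <- rank_proteins(est, timepoints = 2)
  gs <- group_rank_summary(rk$ranks, list(all = ids, none = c("X1", "X2")))
  expect_equal(gs$summary$mean_log10_rank[gs$summary$group == "all"],
               mean(log10(1:30)))
  expect_identical(gs$summary$n_members[gs$summary$group == "none"], 0L)
  expect_true(is.na(gs$summary$mean_log10_rank[gs$summary$group == "none"]))
})

test_that("a planted fast-decay group ranks above the proteome average", {
  hits <- 0
  for (s in 1:50) {
    sim <- simulate_silac(n_proteins = 100, n_experiments = 2,
                          peptides_mean = 5, accelerated_fraction = 0.1,
                          gamma = 8, n_reference = 0, seed = 6000 + s)
    agg <- aggregate_peptides(sim$records)
    rk <- rank_proteins(agg)
    planted <- sim$truth$protein_id[sim$truth$accelerated]
    if (length(planted) < 2) next
    gs <- group_rank_summary(rk$ranks, list(fast = planted))
    if (gs$summary$mean_log10_rank < mean(rk$ranks$log10_rank)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 47)
})

test_that("enrichment terms are post-filtered by the three rules", {
  terms <- data.frame(
    term_id = paste0("GO:", 1:10),
    term_name = letters[1:10],
    fold_enrichment_0 = c(3, rep(NA, 9)),            # term 1: t0-enriched
    fold_enrichment_2 = c(5, 10, 8, 7, 6, 5, 4, 3, NA, 2),
    fold_enrichment_4 = c(5, 10, NA, 5, 3, 3, 1, 2, NA, 1),
    fold_enrichment_8 = c(5, NA, 7, NA, NA, NA, NA, NA, 4, NA)
  )
  # eligible terms 2..8, 10 have sums {20, 15, 12, 9, 8, 5, 5, 3}
  kept <- filter_enrichment_terms(terms)
  expect_setequal(kept$term_id, c("GO:2", "GO:3"))
  expect_equal(kept$sum_fold_enrichment, c(20, 15))
  # single-timepoint term 9 and t0 term 1 are gone even at top_fraction = 1
  all_kept <- filter_enrichment_terms(terms, top_fraction = 1)
  expect_false(any(c("GO:1", "GO:9") %in% all_kept$term_id))

  fixture <- data.frame(
    term_id = paste0("T", 1:8), term_name = paste0("t", 1:8),
    fold_enrichment_0 = NA_real_,
    fold_enrichment_2 = c(10, 7, 6, 6, 4, 4, 2, 1),
    fold_enrichment_4 = c(10, 8, 7, 6, 5, 4, 3, 2),
    fold_enrichment_8 = NA_real_
  )
  fixture$fold_enrichment_8 <- c(0, 0, 0, 0, 0, 0, 0, 0)
  fixture$fold_enrichment_8 <- NA_real_
  # sums over present timepoints: {20, 15, 13, 12, 9, 8, 5, 3}
  kept8 <- filter_enrichment_terms(fixture, top_fraction = 0.25)
  expect_equal(kept8$sum_fold_enrichment, c(20, 15))
})
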