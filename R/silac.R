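#' Dynamic-SILAC loss pipeline
#'
#' Peptide-level H/M ratios from PSI-treated vs. time-matched control cultures
#' are aggregated to protein-level log2 ratios per experiment and time point,
#' normalized to a set of abundant long-lived reference proteins, filtered by
#' stringent peptide/experiment criteria, and classified on a volcano plot
#' (fold-change magnitude vs. t-test significance against the 0 h samples).
#' Downstream scoring compares measured losses to the kinetic model, ranks
#' proteins by loss, and summarizes ranks over annotation groups.
#'
#' Tables are plain data frames in long format. Peptide records carry
#' `protein_id`, `experiment_id`, `timepoint_h`, `ratio_hm` (> 0) and
#' optionally `peptide_id`. Protein estimates carry `protein_id`,
#' `experiment_id`, `timepoint_h`, `log2_ratio`, `n_peptides`.
#'
#' @name silac_pipeline
NULL

#' The seven abundant long-lived proteins used for reference normalization
#'
#' Versican (Vcan/Cspg2), Lamin-B1, Lamin-B2, Nup155, Nup205, Macro-H2A.1 and
#' Macro-H2A.2, all with half-lives of ~9-16 days, so their H/M ratios are
#' expected to stay at 1 over an 8-hour experiment and any departure reflects
#' a mixing offset.
#'
#' @return Character vector of the seven default reference protein ids.
#' @export
default_reference_proteins <- function() {
  c("Vcan", "Lmnb1", "Lmnb2", "Nup155", "Nup205", "Macroh2a1", "Macroh2a2")
}

check_peptide_records <- function(records) {
  required <- c("protein_id", "experiment_id", "timepoint_h", "ratio_hm")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("peptide records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) stop("peptide records are empty", call. = FALSE)
  if (any(!is.finite(records$ratio_hm)) || any(records$ratio_hm <= 0)) {
    stop("ratio_hm must be finite and > 0", call. = FALSE)
  }
  invisible(records)
}

#' Aggregate peptide H/M ratios to protein-level log2 ratios
#'
#' For every protein x experiment x time point, the combined log2 ratio is the
#' median of the peptide log2(H/M) ratios (robust to single-peptide outliers),
#' with the contributing peptide count recorded.
#'
#' @param records Data frame of peptide-level records (see
#'   [silac_pipeline]).
#' @return Data frame with columns `protein_id`, `experiment_id`,
#'   `timepoint_h`, `log2_ratio`, `n_peptides`, one row per
#'   protein x experiment x time point present in the input.
#' @export
aggregate_peptides <- function(records) {
  check_peptide_records(records)
  dt <- data.table::as.data.table(records)
  dt[, log2_hm := log2(ratio_hm)]
  out <- dt[, list(log2_ratio = stats::median(log2_hm),
                   n_peptides = .N),
            by = list(protein_id, experiment_id, timepoint_h)]
  data.table::setorder(out, protein_id, experiment_id, timepoint_h)
  data.table::setDF(out)
  out
}

#' Normalize protein estimates to long-lived reference proteins
#'
#' Subtracts, separately for each experiment x time point, the median
#' log2 ratio of the reference proteins from every protein's log2 ratio.
#' This removes per-sample mixing offsets (slight differences in the amounts
#' of treated and control material combined in each tube), under the premise
#' that the reference proteins are long-lived enough that their true ratio
#' is 1.
#'
#' @param estimates Protein estimates from [aggregate_peptides()].
#' @param reference_ids Character vector of reference protein ids; defaults to
#'   [default_reference_proteins()]. Ids absent from the table are dropped
#'   with a warning; an experiment x time point with no reference protein at
#'   all is an error.
#' @return The estimates with `log2_ratio` shifted; the per-cell offsets are
#'   attached as attribute `"offsets"` (a data frame).
#' @export
normalize_to_reference <- function(estimates,
                                   reference_ids = default_reference_proteins()) {
  stopifnot(length(reference_ids) >= 1)
  present <- intersect(reference_ids, unique(estimates$protein_id))
  absent <- setdiff(reference_ids, present)
  if (length(present) == 0) {
    stop("none of the reference proteins are present in the table",
         call. = FALSE)
  }
  if (length(absent)) {
    warning("reference protein(s) not found and ignored: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  dt <- data.table::as.data.table(estimates)
  refs <- dt[protein_id %in% present,
             list(offset = stats::median(log2_ratio)),
             by = list(experiment_id, timepoint_h)]
  merged <- merge(dt, refs, by = c("experiment_id", "timepoint_h"),
                  all.x = TRUE, sort = FALSE)
  bad <- merged[is.na(offset)]
  if (nrow(bad)) {
    cells <- unique(bad[, paste(experiment_id, timepoint_h, sep = " @ ")])
    stop("no reference protein measured in experiment x timepoint cell(s): ",
         paste0(cells, " h", collapse = "; "), call. = FALSE)
  }
  merged[, log2_ratio := log2_ratio - offset]
  offsets <- data.table::copy(refs)
  merged[, offset := NULL]
  data.table::setcolorder(merged, names(estimates))
  data.table::setorder(merged, protein_id, experiment_id, timepoint_h)
  data.table::setDF(merged)
  data.table::setDF(offsets)
  attr(merged, "offsets") <- offsets
  merged
}

#' Stringent inclusion filter on peptide and experiment counts
#'
#' Keeps, for each protein at each time point, only estimates supported by at
#' least `min_peptides` peptide ratios in total, drawn from at least
#' `min_experiments` experiments ("a minimum of 5 peptide pairs from at least
#' 3 experiments" in the original design).
#'
#' @param estimates Protein estimates (per experiment rows).
#' @param min_peptides Minimum total peptides per protein x time point.
#' @param min_experiments Minimum number of experiments per
#'   protein x time point.
#' @return The surviving rows of `estimates`.
#' @export
filter_stringent <- function(estimates, min_peptides = 5,
                             min_experiments = 3) {
  stopifnot(min_peptides >= 1, min_experiments >= 1)
  if (nrow(estimates) == 0) return(estimates)
  dt <- data.table::as.data.table(estimates)
  dt[, `:=`(n_peptides_total = sum(n_peptides), n_experiments = .N),
     by = list(protein_id, timepoint_h)]
  out <- dt[n_peptides_total >= min_peptides & n_experiments >= min_experiments]
  out[, c("n_peptides_total", "n_experiments") := NULL]
  data.table::setDF(out)
  out
}

#' Per-protein mean log2 ratios across experiments
#'
#' @param estimates Protein estimates (per experiment rows).
#' @return Data frame `protein_id`, `timepoint_h`, `mean_log2`,
#'   `n_experiments`.
#' @export
protein_means <- function(estimates) {
  dt <- data.table::as.data.table(estimates)
  out <- dt[, list(mean_log2 = mean(log2_ratio), n_experiments = .N),
            by = list(protein_id, timepoint_h)]
  data.table::setorder(out, protein_id, timepoint_h)
  data.table::setDF(out)
  out
}

volcano_p <- function(x, y, paired, var_equal) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  tryCatch({
    if (paired) {
      stats::t.test(x, y, paired = TRUE)$p.value
    } else {
      stats::t.test(x, y, var.equal = var_equal)$p.value
    }
  }, error = function(e) NA_real_)
}

#' Volcano classification of protein loss
#'
#' For each protein at each post-treatment time point, computes the log2 fold
#' change (mean over experiments at `t` minus mean at 0 h) and a two-sided
#' t-test p-value on the per-experiment values (`t` vs. 0 h; unequal-variance
#' by default, paired on `experiment_id` optionally). The magnitude threshold
#' is twice the standard deviation of the population of per-protein mean
#' log2 ratios at t = 0 — at that time point any departure from 0 is
#' measurement noise, so 2 SD bounds "biologically interesting" changes.
#'
#' @param estimates Protein estimates (per experiment rows), typically
#'   normalized and stringently filtered.
#' @param alpha Significance cutoff on the (raw, by default) p-value.
#' @param test_timepoints Post-treatment time points (hours) to test.
#' @param paired Pair samples by `experiment_id` instead of the two-sample
#'   test.
#' @param var_equal Pool the group variances (the default; exact at the
#'   small, equal group sizes of this design). `FALSE` gives the Welch
#'   unequal-variance test.
#' @param p_adjust Multiple-testing adjustment applied per time point
#'   (a [stats::p.adjust()] method); `"none"` by default, matching the raw
#'   p <= alpha rule.
#' @return List with `records` (data frame: `protein_id`, `timepoint_h`,
#'   `log2_fc`, `p_value`, `passes_magnitude`, `passes_significance`,
#'   `klass`), `magnitude_threshold` (2 SD in |log2| units), and `alpha`.
#'   `klass` is `"not_significant"` unless both flags hold, `"significant"`
#'   when they do, and `"hit_4and8"` at 4 h and 8 h for proteins passing both
#'   flags at both of those time points.
#' @export
volcano <- function(estimates, alpha = 0.05, test_timepoints = c(2, 4, 8),
                    paired = FALSE, var_equal = TRUE, p_adjust = "none") {
  dt <- data.table::as.data.table(estimates)
  base <- dt[timepoint_h == 0]
  if (nrow(base) == 0) stop("no t = 0 estimates present", call. = FALSE)
  base_means <- base[, list(m0 = mean(log2_ratio)), by = protein_id]
  threshold <- 2 * stats::sd(base_means$m0)

  rows <- list()
  for (tp in test_timepoints) {
    cur <- dt[timepoint_h == tp]
    if (nrow(cur) == 0) next
    proteins <- intersect(unique(cur$protein_id), unique(base$protein_id))
    cur <- cur[protein_id %in% proteins]
    b <- base[protein_id %in% proteins]
    cur_split <- split(cur$log2_ratio, cur$protein_id)
    cur_exp <- split(cur$experiment_id, cur$protein_id)
    b_split <- split(b$log2_ratio, b$protein_id)
    b_exp <- split(b$experiment_id, b$protein_id)
    ids <- names(cur_split)
    fc <- numeric(length(ids))
    pv <- numeric(length(ids))
    for (i in seq_along(ids)) {
      x <- cur_split[[i]]
      y <- b_split[[ids[i]]]
      if (paired) {
        common <- intersect(cur_exp[[i]], b_exp[[ids[i]]])
        x <- x[match(common, cur_exp[[i]])]
        y <- y[match(common, b_exp[[ids[i]]])]
      }
      fc[i] <- mean(cur_split[[i]]) - mean(b_split[[ids[i]]])
      pv[i] <- volcano_p(x, y, paired, var_equal)
    }
    pv <- stats::p.adjust(pv, method = p_adjust)
    rows[[as.character(tp)]] <- data.frame(
      protein_id = ids, timepoint_h = tp, log2_fc = fc, p_value = pv,
      stringsAsFactors = FALSE
    )
  }
  rec <- do.call(rbind, rows)
  if (is.null(rec)) stop("no post-treatment estimates to test", call. = FALSE)
  rec$passes_magnitude <- abs(rec$log2_fc) > threshold
  rec$passes_significance <- !is.na(rec$p_value) & rec$p_value <= alpha
  sig <- rec$passes_magnitude & rec$passes_significance
  hits_4 <- unique(rec$protein_id[sig & rec$timepoint_h == 4])
  hits_8 <- unique(rec$protein_id[sig & rec$timepoint_h == 8])
  hit_ids <- intersect(hits_4, hits_8)
  rec$klass <- ifelse(sig, "significant", "not_significant")
  rec$klass[sig & rec$protein_id %in% hit_ids &
              rec$timepoint_h %in% c(4, 8)] <- "hit_4and8"
  rownames(rec) <- NULL
  list(records = rec, magnitude_threshold = threshold, alpha = alpha,
       hit_4and8_ids = hit_ids)
}

#' Compare measured log2 ratios with kinetic-model expectations
#'
#' Joins per-protein mean log2 ratios with a half-life table, computes the
#' model expectation \eqn{\log_2 C'(t)} for each protein and time point, and
#' reports Pearson correlations between measured and expected values within
#' half-life strata (short-lived proteins change detectably within hours, so
#' correlations are computed for `t_half <=` each stratum bound).
#'
#' @param estimates Protein estimates (per experiment rows).
#' @param half_lives Data frame `protein_id`, `t_half_days` (all > 0).
#' @param k Fractional synthesis rate under the inhibitor.
#' @param timepoints Time points (hours) to evaluate.
#' @param strata Upper half-life bounds (days) defining correlation strata.
#' @return List with `table` (per protein x time point: measured, expected,
#'   `t_half_days`), `correlations` (per time point x stratum: `r`, `n`; `r`
#'   is `NA` when fewer than 3 proteins fall in the stratum) and
#'   `n_missing_halflife` (proteins skipped for lack of a half-life).
#' @export
compare_to_model <- function(estimates, half_lives, k,
                             timepoints = c(2, 4, 8), strata = c(2, 10)) {
  stopifnot(all(c("protein_id", "t_half_days") %in% names(half_lives)))
  if (any(half_lives$t_half_days <= 0)) {
    stop("half-lives must be positive", call. = FALSE)
  }
  means <- protein_means(estimates)
  means <- means[means$timepoint_h %in% timepoints, ]
  matched <- merge(means, half_lives[, c("protein_id", "t_half_days")],
                   by = "protein_id")
  n_missing <- length(setdiff(unique(means$protein_id),
                              unique(half_lives$protein_id)))
  matched$expected_log2 <- expected_log2_ratio(
    matched$t_half_days, k, matched$timepoint_h
  )
  cors <- expand.grid(timepoint_h = timepoints, stratum_max_days = strata)
  cors$r <- NA_real_
  cors$n <- 0L
  for (i in seq_len(nrow(cors))) {
    sub <- matched[matched$timepoint_h == cors$timepoint_h[i] &
                     matched$t_half_days <= cors$stratum_max_days[i], ]
    cors$n[i] <- nrow(sub)
    if (nrow(sub) >= 3 && stats::sd(sub$mean_log2) > 0 &&
        stats::sd(sub$expected_log2) > 0) {
      cors$r[i] <- stats::cor(sub$mean_log2, sub$expected_log2)
    }
  }
  list(table = matched, correlations = cors, n_missing_halflife = n_missing)
}

#' Rank proteins by loss and average ranks across time points
#'
#' Within each time point, proteins are ranked ascending by mean log2 ratio
#' (most strongly decreased = rank 1; ties get the average rank); each
#' protein's ranks are then averaged over the time points where it was
#' quantified, and reported on a log10 scale.
#'
#' @param estimates Protein estimates (per experiment rows).
#' @param timepoints Time points (hours) entering the rank average.
#' @param require_all Require a protein to be present at all `timepoints`
#'   (strict mode); otherwise the average runs over available time points.
#' @return List with `ranks` (data frame `protein_id`, `mean_rank`,
#'   `log10_rank`, `n_timepoints`) and `n_excluded` (proteins present in the
#'   input but at none of the ranked time points, or failing strict mode).
#' @export
rank_proteins <- function(estimates, timepoints = c(2, 4, 8),
                          require_all = FALSE) {
  means <- protein_means(estimates)
  means <- means[means$timepoint_h %in% timepoints, ]
  all_ids <- unique(protein_means(estimates)$protein_id)
  per_tp <- lapply(split(means, means$timepoint_h), function(d) {
    d$rank <- rank(d$mean_log2, ties.method = "average")
    d[, c("protein_id", "rank")]
  })
  long <- do.call(rbind, per_tp)
  agg <- stats::aggregate(rank ~ protein_id, data = long,
                          FUN = function(r) c(mean(r), length(r)))
  ranks <- data.frame(
    protein_id = agg$protein_id,
    mean_rank = agg$rank[, 1],
    n_timepoints = as.integer(agg$rank[, 2]),
    stringsAsFactors = FALSE
  )
  if (require_all) {
    ranks <- ranks[ranks$n_timepoints == length(timepoints), ]
  }
  ranks$log10_rank <- log10(ranks$mean_rank)
  ranks <- ranks[order(ranks$mean_rank, ranks$protein_id), ]
  rownames(ranks) <- NULL
  list(ranks = ranks, n_excluded = length(setdiff(all_ids, ranks$protein_id)))
}

#' Summarize loss ranks over annotation groups
#'
#' @param ranks The `ranks` data frame from [rank_proteins()].
#' @param groups Named list of character vectors (group name -> protein ids),
#'   e.g. synaptic categories. Proteins in several groups count in each.
#' @return List with `members` (per group x member: `log10_rank`) and
#'   `summary` (per group: `n_members`, `mean_log10_rank`; the mean is `NA`
#'   for a group with no ranked member).
#' @export
group_rank_summary <- function(ranks, groups) {
  stopifnot(is.list(groups), length(groups) >= 1,
            !is.null(names(groups)), all(nzchar(names(groups))))
  members <- lapply(names(groups), function(g) {
    hit <- ranks[ranks$protein_id %in% groups[[g]], ]
    if (nrow(hit) == 0) return(NULL)
    data.frame(group = g, protein_id = hit$protein_id,
               mean_rank = hit$mean_rank, log10_rank = hit$log10_rank,
               stringsAsFactors = FALSE)
  })
  members <- do.call(rbind, members)
  summary <- data.frame(
    group = names(groups),
    n_members = vapply(names(groups), function(g) {
      sum(ranks$protein_id %in% groups[[g]])
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  summary$mean_log10_rank <- vapply(names(groups), function(g) {
    r <- ranks$log10_rank[ranks$protein_id %in% groups[[g]]]
    if (length(r)) mean(r) else NA_real_
  }, numeric(1))
  rownames(summary) <- NULL
  list(members = members, summary = summary)
}

#' Post-filter enrichment terms from a ranked-list GO analysis
#'
#' Applies the selection used on externally computed enrichment tables:
#' terms already enriched in the control (t = 0) lists are excluded, terms
#' enriched at fewer than two of the 2/4/8 h time points are excluded, and of
#' the remainder the top fraction by summed fold enrichment (over 2/4/8 h) is
#' kept, with ties at the cut retained.
#'
#' @param terms Data frame with `term_id`, `term_name` and per-time-point
#'   fold-enrichment columns `fold_enrichment_0`, `fold_enrichment_2`,
#'   `fold_enrichment_4`, `fold_enrichment_8` (`NA` = not enriched there).
#' @param top_fraction Fraction of eligible terms to keep.
#' @return The kept rows with an added `sum_fold_enrichment` column, sorted
#'   decreasing.
#' @export
filter_enrichment_terms <- function(terms, top_fraction = 0.25) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  fe_cols <- paste0("fold_enrichment_", c(2, 4, 8))
  stopifnot(all(c("term_id", "fold_enrichment_0", fe_cols) %in% names(terms)))
  eligible <- terms[is.na(terms$fold_enrichment_0), ]
  fe <- as.matrix(eligible[, fe_cols])
  n_present <- rowSums(!is.na(fe))
  eligible <- eligible[n_present >= 2, , drop = FALSE]
  if (nrow(eligible) == 0) {
    eligible$sum_fold_enrichment <- numeric(0)
    return(eligible)
  }
  fe <- as.matrix(eligible[, fe_cols])
  eligible$sum_fold_enrichment <- rowSums(fe, na.rm = TRUE)
  n_keep <- ceiling(top_fraction * nrow(eligible))
  ord <- order(-eligible$sum_fold_enrichment)
  cutoff <- eligible$sum_fold_enrichment[ord[n_keep]]
  kept <- eligible[eligible$sum_fold_enrichment >= cutoff, , drop = FALSE]
  kept <- kept[order(-kept$sum_fold_enrichment), ]
  rownames(kept) <- NULL
  kept
}
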