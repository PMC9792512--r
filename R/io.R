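#' File formats and the end-to-end SILAC run
#'
#' All tables are UTF-8, header-first, with '.' as decimal separator; inputs
#' are tab-separated except where noted, and numeric outputs are written at
#' 6 significant digits so repeated runs diff cleanly.
#'
#' @name silac_io
NULL

#' Read a peptide-level SILAC ratio table
#'
#' Native dialect: tab-separated with columns `protein_id`, `experiment`,
#' `timepoint_h`, `ratio_hm`, plus optional `peptide_id` and `orientation`
#' (`"HM"` or `"MH"`; heavy and medium labels were used interchangeably
#' across experiments, so `"MH"` rows are inverted on read — ratios are
#' always stored as treated/control). MaxQuant evidence dialect: columns
#' `Proteins`, `Experiment`, `Ratio H/M` (plus a `Timepoint` column added at
#' export); the first id of a semicolon-separated protein group is taken.
#'
#' @param path File path.
#' @param dialect `"native"` or `"maxquant"`.
#' @return Data frame of validated peptide records (see
#'   [silac_pipeline]); malformed rows (non-positive or non-numeric
#'   ratio) are dropped with a warning naming their line numbers.
#' @export
read_silac_table <- function(path, dialect = c("native", "maxquant")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (dialect == "maxquant") {
    required <- c("Proteins", "Experiment", "Ratio H/M")
    missing <- setdiff(required, names(raw))
    if (length(missing)) {
      stop("column(s) missing from MaxQuant table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tp_col <- intersect(c("Timepoint", "timepoint_h"), names(raw))
    if (length(tp_col) == 0) {
      stop("column missing from MaxQuant table: Timepoint", call. = FALSE)
    }
    records <- data.frame(
      protein_id = vapply(strsplit(raw$Proteins, ";", fixed = TRUE),
                          `[`, character(1), 1),
      experiment_id = as.character(raw$Experiment),
      timepoint_h = as.numeric(raw[[tp_col[1]]]),
      ratio_hm = as.numeric(raw$`Ratio H/M`),
      stringsAsFactors = FALSE
    )
    if ("Sequence" %in% names(raw)) records$peptide_id <- raw$Sequence
  } else {
    required <- c("protein_id", "experiment", "timepoint_h", "ratio_hm")
    missing <- setdiff(required, names(raw))
    if (length(missing)) {
      stop("column(s) missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    records <- data.frame(
      protein_id = as.character(raw$protein_id),
      experiment_id = as.character(raw$experiment),
      timepoint_h = as.numeric(raw$timepoint_h),
      ratio_hm = suppressWarnings(as.numeric(raw$ratio_hm)),
      stringsAsFactors = FALSE
    )
    if ("peptide_id" %in% names(raw)) records$peptide_id <- raw$peptide_id
    if ("orientation" %in% names(raw)) {
      bad_orient <- !raw$orientation %in% c("HM", "MH")
      if (any(bad_orient)) {
        stop("invalid orientation value(s) on line(s): ",
             paste(which(bad_orient) + 1, collapse = ", "), call. = FALSE)
      }
      flip <- raw$orientation == "MH"
      records$ratio_hm[flip] <- 1 / records$ratio_hm[flip]
    }
  }
  bad <- !is.finite(records$ratio_hm) | records$ratio_hm <= 0 |
    is.na(records$timepoint_h)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) dropped (line(s) ",
            paste(utils::head(which(bad) + 1, 20), collapse = ", "), ")",
            call. = FALSE)
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no valid records in ", path, call. = FALSE)
  rownames(records) <- NULL
  records
}

#' Read a protein half-life table (CSV: protein_id, t_half_days)
#'
#' @param path File path.
#' @return Data frame `protein_id`, `t_half_days` (validated positive).
#' @export
read_halflife_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("protein_id", "t_half_days"), names(d))
  if (length(missing)) {
    stop("column(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d$t_half_days <- as.numeric(d$t_half_days)
  if (any(!is.finite(d$t_half_days) & !is.infinite(d$t_half_days)) ||
      any(d$t_half_days <= 0)) {
    stop("all half-lives must be positive", call. = FALSE)
  }
  d[, c("protein_id", "t_half_days")]
}

#' Read annotation groups (TSV: group_name, protein_id)
#'
#' @param path File path.
#' @return Named list of protein-id vectors, one element per group.
#' @export
read_annotation_groups <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("group_name", "protein_id"), names(d))
  if (length(missing)) {
    stop("column(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups <- split(d$protein_id, d$group_name)
  lapply(groups, unique)
}

#' Read an enrichment-term table
#'
#' TSV with `term_id`, `term_name`, then `fold_enrichment_<t>` (and
#' optionally `fdr_<t>`) columns per time point; empty cells mean the term
#' was not enriched at that time point.
#'
#' @param path File path.
#' @return Data frame suitable for [filter_enrichment_terms()].
#' @export
read_enrichment_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("term_id", "term_name", paste0("fold_enrichment_", c(0, 2, 4, 8)))
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop("column(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (cn in grep("^(fold_enrichment|fdr)_", names(d), value = TRUE)) {
    d[[cn]] <- suppressWarnings(as.numeric(d[[cn]]))
  }
  d
}

#' Read a puncta trajectory table
#'
#' CSV with `cell_id`, `punctum_id`, `condition`, `timepoint_h`,
#' `fluorescence_au`.
#'
#' @param path File path.
#' @return Long trajectory data frame (see [tenacity]).
#' @export
read_trajectory_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cell_id", "punctum_id", "condition", "timepoint_h",
              "fluorescence_au")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop("column(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data.frame(cell_id = as.character(d$cell_id),
             punctum_id = as.character(d$punctum_id),
             condition = as.character(d$condition),
             timepoint_h = as.numeric(d$timepoint_h),
             fluorescence = as.numeric(d$fluorescence_au),
             stringsAsFactors = FALSE)
}

#' Write a table as TSV with stable numeric formatting
#'
#' Tab-separated, UTF-8, '.' decimal separator, numeric columns at 6
#' significant digits — byte-identical across repeated runs of the same
#' analysis.
#'
#' @param x Data frame.
#' @param path Output path (parent directories created).
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  y <- x
  for (cn in names(y)) {
    if (is.numeric(y[[cn]]) && !is.integer(y[[cn]])) {
      y[[cn]] <- signif(y[[cn]], 6)
    }
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the dynamic-SILAC pipeline end to end
#'
#' Reads (or accepts) a peptide table, aggregates peptides to proteins,
#' normalizes to the reference proteins, applies the stringent filter, and
#' classifies proteins on the volcano; optionally compares to the kinetic
#' model, ranks proteins, and summarizes annotation groups. Writes
#' `volcano.tsv`, `estimates.tsv` and, when the corresponding inputs are
#' given, `model_compare.tsv`, `ranks.tsv`, `groups.tsv`, plus a
#' `run_summary.json` recording thresholds, per-stage counts and the full
#' configuration — enough to re-execute the run.
#'
#' @param records Peptide records data frame, or a path readable by
#'   [read_silac_table()].
#' @param out_dir Output directory (created). `NULL` skips writing.
#' @param reference_ids Reference proteins for normalization.
#' @param min_peptides,min_experiments Stringent-filter thresholds.
#' @param alpha Volcano significance cutoff.
#' @param k Fractional synthesis rate used for model comparison.
#' @param half_lives Optional half-life data frame or CSV path.
#' @param groups Optional annotation groups (named list or TSV path).
#' @param test_timepoints Post-treatment time points for the volcano.
#' @return List with `estimates` (normalized, filtered), `volcano`,
#'   `model_compare` (or `NULL`), `ranks`, `groups` (or `NULL`) and
#'   `summary`.
#' @export
run_pipeline <- function(records, out_dir = NULL,
                         reference_ids = default_reference_proteins(),
                         min_peptides = 5, min_experiments = 3,
                         alpha = 0.05, k = 1 / 39.2, half_lives = NULL,
                         groups = NULL, test_timepoints = c(2, 4, 8)) {
  if (is.character(records)) records <- read_silac_table(records)
  check_peptide_records(records)
  n_input <- nrow(records)
  aggregated <- aggregate_peptides(records)
  normalized <- normalize_to_reference(aggregated, reference_ids)
  filtered <- filter_stringent(normalized, min_peptides, min_experiments)
  if (nrow(filtered) == 0) {
    stop("no protein x time point passed the stringent filter", call. = FALSE)
  }
  vol <- volcano(filtered, alpha = alpha, test_timepoints = test_timepoints)

  if (is.character(half_lives)) half_lives <- read_halflife_table(half_lives)
  model_cmp <- if (!is.null(half_lives)) {
    compare_to_model(filtered, half_lives, k, timepoints = test_timepoints)
  }
  rk <- rank_proteins(filtered, timepoints = test_timepoints)
  if (is.character(groups)) groups <- read_annotation_groups(groups)
  grp <- if (!is.null(groups)) group_rank_summary(rk$ranks, groups)

  hits_per_tp <- table(factor(
    vol$records$timepoint_h[vol$records$passes_magnitude &
                              vol$records$passes_significance],
    levels = test_timepoints
  ))
  summary <- list(
    thresholds = list(min_peptides = min_peptides,
                      min_experiments = min_experiments, alpha = alpha,
                      magnitude_threshold_log2 = vol$magnitude_threshold,
                      k = k, test_timepoints = test_timepoints,
                      reference_ids = reference_ids),
    counts = list(
      input_records = n_input,
      aggregated = nrow(aggregated),
      post_filter = nrow(filtered),
      proteins_post_filter = length(unique(filtered$protein_id)),
      volcano_hits = as.list(stats::setNames(as.integer(hits_per_tp),
                                             names(hits_per_tp))),
      hits_4and8 = length(vol$hit_4and8_ids)
    ),
    software_version = as.character(utils::packageVersion("psilac"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ok <- FALSE
    on.exit(if (!ok) unlink(file.path(out_dir, c(
      "estimates.tsv", "volcano.tsv", "model_compare.tsv", "ranks.tsv",
      "groups.tsv", "run_summary.json"
    ))), add = TRUE)
    write_table_tsv(filtered, file.path(out_dir, "estimates.tsv"))
    write_table_tsv(vol$records, file.path(out_dir, "volcano.tsv"))
    if (!is.null(model_cmp)) {
      write_table_tsv(model_cmp$table, file.path(out_dir, "model_compare.tsv"))
    }
    write_table_tsv(rk$ranks, file.path(out_dir, "ranks.tsv"))
    if (!is.null(grp)) {
      write_table_tsv(grp$summary, file.path(out_dir, "groups.tsv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ok <- TRUE
  }
  list(estimates = filtered, volcano = vol, model_compare = model_cmp,
       ranks = rk, groups = grp, summary = summary)
}
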