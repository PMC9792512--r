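#!/usr/bin/env Rscript
# Generate every input the downstream analyses consume, with ground truth:
# a peptide-level dynamic-SILAC ratio table (5 experiments x 4 time points,
# cycloheximide-level suppression k = 1/39.2, including the seven long-lived
# reference proteins and a planted accelerated-degradation subset), a
# half-life catalog, annotation groups, and puncta trajectory tables for a
# control and a PSI-treated imaging session.

suppressMessages(library(psilac))
seed <- 42
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_silac(n_proteins = 2000, k_true = k_from_fold_suppression(39.2),
                      noise_sigma_log2 = 0.2, n_experiments = 5,
                      accelerated_fraction = 0.02, gamma = 4, seed = seed)
records <- sim$records
names(records)[names(records) == "experiment_id"] <- "experiment"
write_table_tsv(records, file.path(out, "silac_peptides.tsv"))
write_table_tsv(sim$truth, file.path(out, "ground_truth.tsv"))
write.csv(sim$truth[, c("protein_id", "t_half_days")],
          file.path(out, "halflives.csv"), row.names = FALSE, quote = FALSE)

groups <- rbind(
  data.frame(group_name = "accelerated_degradation",
             protein_id = sim$truth$protein_id[sim$truth$accelerated]),
  data.frame(group_name = "long_lived_reference",
             protein_id = sim$truth$protein_id[sim$truth$is_reference])
)
write_table_tsv(groups, file.path(out, "groups.tsv"))

for (cond in c("control", "psi")) {
  tr <- simulate_trajectories(
    n_cells = 30, puncta_per_cell = 60, duration_h = 48, tau_c = 12,
    sigma_log = 0.2, cell_gain_sdlog = 0.3,
    treatment_onset_h = 24,
    volatility_multiplier = if (cond == "psi") 2 else 1,
    drift_per_h = if (cond == "psi") 0.005 else 0,
    elimination_hazard = if (cond == "psi") 0.005 else 0,
    condition = cond, seed = seed + (cond == "psi")
  )
  d <- tr$trajectories
  names(d)[names(d) == "fluorescence"] <- "fluorescence_au"
  write.csv(d, file.path(out, sprintf("trajectories_%s.csv", cond)),
            row.names = FALSE, quote = FALSE)
}

cat("Simulated", nrow(records), "peptide ratio records for",
    nrow(sim$truth), "proteins (",
    sum(sim$truth$accelerated), "accelerated,",
    sum(sim$truth$is_reference), "reference ) and two trajectory sets.\n")
cat("Inputs written under", out, "\n")
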