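# psilac

Analyses of neuronal protein turnover and synaptic failure under acute
protein synthesis inhibition.

When protein synthesis in cultured cortical neurons is abruptly suppressed
with an inhibitor (PSI; cycloheximide, anisomycin), each protein's abundance
relaxes toward a new steady state at a rate set by its half-life. `psilac`
implements the computational analyses of such a study for researchers
working with dynamic-SILAC proteomics and long-term synapse imaging:

- **Kinetic model.** With degradation first-order
  (β = 1/τ, τ = t<sub>1/2</sub>/ln 2 ≈ 1.44·t<sub>1/2</sub>) and synthesis
  reduced to a fraction *k* of its nominal rate, the residual fraction is
  C′(t) = (1 − k)·e<sup>−βt</sup> + k, so the expected SILAC ratio is
  log₂(H/M) = log₂((1 − k)·e<sup>−βt</sup> + k). *k* is the reciprocal of
  the measured fold suppression (39.2 for cycloheximide → k ≈ 0.0255).
  Functions: `residual_fraction()`, `expected_log2_ratio()`,
  `k_from_fold_suppression()`, `estimate_k()`.
- **Dynamic-SILAC loss pipeline.** Peptide→protein aggregation (median
  log2 ratio), normalization to seven abundant long-lived reference
  proteins per experiment × time point, the stringent
  ≥5-peptides/≥3-experiments filter, volcano classification
  (|log₂FC| > 2·SD of the t = 0 population and t-test p ≤ 0.05 vs. 0 h),
  comparison with model expectations stratified by half-life, loss ranking
  and annotation-group summaries, and enrichment-term post-filtering.
  Functions: `aggregate_peptides()`, `normalize_to_reference()`,
  `filter_stringent()`, `volcano()`, `compare_to_model()`,
  `rank_proteins()`, `group_rank_summary()`, `filter_enrichment_terms()`,
  orchestrated by `run_pipeline()`.
- **Synaptic tenacity.** Tracked PSD-95/gephyrin puncta are smoothed
  (3-point filter), normalized per cell, and later fluorescence is
  regressed on window-start fluorescence across puncta; the decay of
  R²(Δ) with the interval Δ measures how fast synaptic configurations
  reshuffle. Includes Mexican-hat + local-maxima puncta detection and
  fixed-ROI measurement. Functions: `smooth_trajectory()`,
  `normalize_per_cell()`, `tenacity_curve()`, `detect_puncta()`,
  `measure_puncta()`, `puncta_timecourse()`.
- **Functional assays.** Synthesis-suppression fold from two-channel
  reporter fluorescence, FM dye destaining (600 AU baseline floor, >15%
  responder rule), calcein/PI viability, spike-rate normalization and
  paired slope tests, and flux-plate (OCR/ECAR) normalization with
  exclusion flags.
- **Synthetic data.** Seeded generators (`simulate_silac()`,
  `simulate_trajectories()`, `simulate_spot_image()`,
  `simulate_assay_fixtures()`) produce every input with known ground
  truth, which is how the package validates itself.

## Worked example

```r
library(psilac)

# cycloheximide suppresses synthesis 39.2-fold
k <- k_from_fold_suppression(39.2)           # 0.02551

# a protein with a 1-day half-life, 8 h after inhibitor addition
residual_fraction(1, k, 8)                   # 0.79896
expected_log2_ratio(1, k, 8)                 # -0.3238

# simulate a 5-experiment dynamic-SILAC study and run the pipeline
sim <- simulate_silac(n_proteins = 2000, k_true = k, seed = 42,
                      accelerated_fraction = 0.02, gamma = 4)
res <- run_pipeline(sim$records, out_dir = "results/silac",
                    half_lives = sim$truth[, c("protein_id", "t_half_days")],
                    k = k)
res$summary$counts
```

On the simulated study this prints (numbers from an actual run, seed 42):
401,677 input peptide records aggregated to 40,140 protein × experiment ×
time point estimates, all passing the stringent filter; a magnitude
threshold of 0.0706 log2 units; 178 / 282 / 547 volcano hits at 2 / 4 / 8 h;
and 228 proteins significant at both 4 and 8 h, 132 of which are planted
short-lived or accelerated-degradation proteins. Measured-vs-expected
correlations for short-lived proteins (t<sub>1/2</sub> ≤ 2 d) rise with
exposure: r = 0.83 (2 h), 0.89 (4 h), 0.91 (8 h) — the signature of signal
growing against fixed measurement noise.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate_inputs.R` … `06_functional_assays.R`); each is a thin driver
over the package functions that prints what it found and writes its tables
under `results/`.

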