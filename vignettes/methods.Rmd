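---
title: "Protein loss kinetics and synaptic failure under protein synthesis inhibition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein loss kinetics and synaptic failure under protein synthesis inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`psilac` implements the computational core of a study design in which
protein synthesis in cultured cortical neurons is abruptly suppressed with a
protein synthesis inhibitor (PSI; cycloheximide or anisomycin) and the
consequences are followed across several readouts: proteome-wide protein
loss measured by dynamic SILAC, destabilization of postsynaptic
specializations measured by long-term imaging of tagged PSD-95 and gephyrin
puncta, and functional assays (network spiking, FM dye recycling, viability,
extracellular flux). This vignette explains the models, the tunable
parameters, the synthetic-data generators the tests rely on, and the design
choices that were genuinely open.

## The first-order loss model

A protein pool at steady state is synthesized at a constant (zero-order)
rate and degraded in proportion to its amount (first-order, rate constant
$\beta = 1/\tau$ with $\tau = t_{1/2}/\ln 2 \approx 1.44\,t_{1/2}$). If an
inhibitor reduces the synthesis rate to a fraction $k \in [0, 1]$ of its
nominal value while leaving degradation untouched, the residual fraction
$C' = C/C_0$ obeys $dC'/dt = \beta k - \beta C'$ with $C'(0) = 1$, giving

$$C'(t) = (1 - k)\,e^{-\beta t} + k .$$

$C'$ decays from 1 toward the new steady state $k$. In the dynamic-SILAC
design, treated ("heavy"-labeled) and time-matched control
("medium"-labeled) extracts are mixed, so the measured H/M ratio of a
protein estimates $C'(t)$ and $\log_2(H/M)$ is compared directly with
$\log_2 C'(t)$.

Numerical conventions: the exact constant $1/\ln 2 = 1.4427\ldots$ is used
internally (1.44 is a display rounding); half-lives are accepted in days and
converted to hours ($\times 24$), the unit of inhibitor exposure; $k = 0$
with $t \to \infty$ yields a well-defined $-\infty$ on the log2 scale, not
an error. The closed form is verified in the test suite against fixed-step
RK4 integration of the governing equation (step $\le$ 0.001 h) to
$|\Delta| < 10^{-8}$ over a grid of half-lives (0.1–20 d), $k$ values
(0–1) and exposure times (0–48 h).

The measured fold suppressions feeding $k = 1/\text{fold}$ are 39.2
(cycloheximide), 4.17 (anisomycin) and 1.93 (puromycin); they are always
explicit parameters, never hard-coded.

`estimate_k()` inverts the model by least squares over $k \in [0, 1]$
(1-D golden-section search via `stats::optimize`, with both interval
endpoints checked). Identifiability requires measurements at $t > 0$ with
finite half-lives; data at $t = 0$ only are rejected. A practical caveat
established while characterizing the estimator: when per-measurement noise
is large (log2 SD 0.2) and half-lives follow the realistic lognormal
(median 5 d), the sum of squares is nearly flat in $k$ — the information
comes almost entirely from the rare short-lived proteins — so hundreds of
raw measurements do not pin $k$ to better than several tens of percent.
Aggregating peptides and experiments first (per-protein means, effective
noise $\approx 0.03$) makes recovery precise. Reference normalization
(below) re-introduces a common per-sample error of roughly 0.01–0.03 log2
units (the sampling noise of a 7-protein median), which again limits $k$
recovery from normalized tables; the package therefore characterizes $k$
recovery on aggregated, offset-free data and validates normalization by its
exact invariance property instead.

## The dynamic-SILAC pipeline

Inputs are peptide-level H/M ratios per protein, biological repeat
(experiment) and time point (0, 2, 4, 8 h by default). The stages, each an
exported function:

1. **Aggregation** (`aggregate_peptides`): the protein-level log2 ratio per
   experiment and time point is the *median* of the peptide log2 ratios.
   The source protocol only states that peptide ratios are "pooled"; the
   median was chosen for robustness to single-peptide outliers.
2. **Reference normalization** (`normalize_to_reference`): per experiment
   and time point, the median log2 ratio of seven abundant, exceptionally
   long-lived proteins (versican, lamin-B1/B2, Nup155, Nup205,
   macro-H2A.1/.2) is subtracted from every protein. Their half-lives
   (9–16 d) make their true change over 8 h negligible, so their measured
   ratio estimates the sample's mixing offset. Median vs. mean was
   unstated in the source; the median is used for the same robustness
   reason, and the choice is immaterial to the exact-invariance property
   (any constant per-cell offset cancels identically). A missing reference
   in some experiment × time point is an error naming the cell; partially
   resolvable reference sets warn.
3. **Stringent filtering** (`filter_stringent`): keep a protein at a time
   point only with $\ge 5$ peptide ratios in total from $\ge 3$
   experiments.
4. **Volcano classification** (`volcano`): the magnitude threshold is twice
   the SD of the population of per-protein mean log2 ratios at $t = 0$
   (where any departure from 0 is measurement noise); significance is a
   two-sided t-test of the per-experiment values at $t$ vs. 0 h with
   $p \le 0.05$, unadjusted (a Benjamini–Hochberg option exists but is off
   by default, matching the raw-p rule). Proteins passing both rules at
   both 4 h and 8 h are labeled `hit_4and8`. Increasing proteins are kept
   with positive fold change and simply rank at the bottom.
   *t-test variant:* the default pools the group variances. The
   unequal-variance (Welch) test was considered first, but at the design's
   group sizes (5 vs. 5) its Satterthwaite degrees of freedom are noisy
   and the test is measurably conservative (type-I error 0.044 over
   12,000 simulated null proteins vs. 0.0497 for the pooled test), so the
   pooled test — which is also what an unqualified "two-sided t-test"
   denotes — is the default; `var_equal = FALSE` and a paired mode
   (pairing on experiment id) are available. The pooling level for the
   $t=0$ SD (per-protein means, pooled over proteins) was also unstated
   and is documented in `?volcano`.
5. **Model comparison** (`compare_to_model`): Pearson correlation of
   measured vs. expected log2 ratios within half-life strata
   ($t_{1/2} \le 2$ d and $\le 10$ d), per time point. Correlations rise
   with exposure duration because the signal grows while measurement noise
   stays fixed; the test suite checks this ordering holds in at least
   95 of 100 simulations at the study's design size (2000 proteins, 5
   repeats, peptide noise 0.2 log2).
6. **Ranking and group scoring** (`rank_proteins`,
   `group_rank_summary`): ascending rank by mean log2 ratio per time point
   (most lost = rank 1, ties averaged), averaged over 2/4/8 h and reported
   as log10. Proteins missing a time point average over the available ones
   (a strict all-three mode exists); ranking is invariant under monotone
   transforms of the values.
7. **Enrichment-term post-filtering** (`filter_enrichment_terms`): applied
   to an externally computed enrichment table — terms enriched at $t = 0$
   are dropped, terms enriched at fewer than two of 2/4/8 h are dropped,
   and the top 25% by summed fold enrichment are kept (ties at the cut
   retained). Ontology-graph level filtering is out of scope.

## Synaptic tenacity

Tracked puncta series are smoothed with a centered 3-point moving average
(shrunken windows at the ends — no data are invented), normalized per cell
(each punctum divided by the mean fluorescence of its cell's puncta at the
window-start reference time, removing expression-level differences), and
then, for each interval $\Delta$, the values at $t_0 + \Delta$ are
regressed on the values at $t_0$ across puncta. $R^2(\Delta)$ measures how
much of the synaptic "size" configuration persists; the smoothed data are
used throughout the downstream analysis, and the window start is an
explicit parameter (one analysis normalizes to the 24 h point, another
within each 24-h window). $R^2$ is invariant to common affine rescaling,
degenerate windows (zero start variance, or fewer than 3 puncta) report an
absent value, and a destabilizing treatment lowers the whole curve.

The generator behind the tenacity tests is a stationary Ornstein–Uhlenbeck
process on log fluorescence (multiplicative dynamics) with reversion time
$\tau_c = 12$ h and stationary log-SD 0.2, for which the population
$R^2(\Delta)$ is $e^{-2\Delta/\tau_c}$; at these parameters the bias from
exponentiating the log process is well inside the Monte-Carlo band used by
the tests (10,000 puncta, three empirical SEs). Treatment onset multiplies
the innovation SD (volatility), optionally adds a downward drift and a
constant elimination hazard; the generator-match test uses raw (unsmoothed,
gain-free) values because smoothing would distort the autocorrelation being
checked.

## Puncta detection and measurement

Detection band-passes the image with a Mexican-hat filter and takes strict
local maxima within a 5-pixel radius above a threshold. The kernel is
implemented as a difference of Gaussians ($\sigma_{in} = 1.5$ px,
$\sigma_{out} = 3$ px — the source protocol names the filter but not its
parameters) via separable convolution with replicate-edge padding, which
keeps detection translation-equivariant up to the borders; the default
threshold is mean + 3 SD of the filtered image. Exact ties within the
radius keep the lexicographically smallest (row, column) coordinate so
output is deterministic; coordinates are 1-based (row, column), the R
convention. Measurement centers a fixed square ROI (9 × 9 px by default;
other assays in the protocol use 7 × 7 or 10 × 10, so the size is a
parameter) and reports the mean raw intensity; border ROIs are clipped and
flagged, and ROIs containing pixels at or above a configurable saturation
level are flagged excluded.

## Functional assays

Each quantification is a small, explicit rule set: background-subtracted
two-channel ratios and the control/treated fold (whose reciprocal is $k$);
FM destaining with the 600 AU baseline floor and the >15% responder rule
(dimming up to ~8–12% is attributable to washout and photobleaching);
calcein/PI live fractions averaged over fields with SEM; spike counts in
1-minute bins normalized to the first 3 h (or first 24 h for perfused
recordings) with per-window OLS slopes compared by a two-sided paired
t-test; and flux plates normalized per cycle to the cell-free perimeter
wells and anchored at 100% on each well's fifth baseline cycle, with wells
flagged for an OCR increase after oligomycin, no FCCP response (post-FCCP
mean not above 1.1 × the post-oligomycin mean — the source does not define
"failed to respond" numerically, so the factor is configurable) or no
rotenone/antimycin-A response. Background correction uses means over the
designated background wells/regions (plate-reader convention; configurable).
FM release kinetics, where needed, are summarized by a single-exponential
rate fit — an interpretation, since the source shows kinetics without
defining a scalar metric.

## Synthetic data: what it emulates, and what it does not

`simulate_silac` draws half-lives from a lognormal distribution with median
5 d and log-SD 1, spanning the days-to-weeks regime typical of neuronal
proteins with a short-lived tail; true log2 trajectories follow the model
at the configured $k$; peptide counts are shifted-Poisson (mean 10, at
least 1) per protein × experiment × time point; peptide noise is lognormal
(log2 SD 0.2); each experiment × time point carries an additive mixing
offset (SD 0.1 log2) that the reference normalization must remove; seven
planted reference proteins carry the real reference-set names and
half-lives of 100–200 d; and an optional accelerated subset has $\beta$
multiplied by $\gamma$ under treatment — mirroring the observation that a
few proteins are lost faster than their half-lives predict, without
asserting a mechanism. One root seed feeds named substreams per component,
so adding a generator does not perturb the others and identical seeds give
bit-identical outputs.

What the generators do *not* emulate: peptide-level missingness beyond
count sampling, isotope impurity, protein-inference ambiguity, image drift
or tracking errors, and non-stationarities of long recordings (the slight
slowing of configuration change over sessions seen in real data). Passing
tests therefore validate the pipeline's arithmetic and statistical behavior
under the stated model, not robustness to every artifact of real data.

## Problem sizes and determinism

The test suite and the acceptance script use: 2000 proteins × 5
experiments × 4 time points (≈ 400k peptide rows) for recovery and
correlation checks, 100-seed batches of 200 proteins for null calibration
(the fraction with $p \le 0.05$ must sit within three binomial SEs of
0.05) and of 20 planted $t_{1/2} = 0.5$ d proteins for power (>90% called
at 8 h at log2 noise 0.1), 10,000 puncta for the tenacity curves, and
50-spot fields at SNR 5 for detection (≥95% recall and precision against
planted centers). All tabular outputs are written at 6 significant digits
so repeated runs are byte-identical.

## Known limitations

- Degradation is strictly first-order and unchanged by the inhibitor;
  accelerated loss exists only in the generator's $\gamma$ factor, not as a
  fitted model.
- The normalization noise floor of a 7-protein reference set propagates
  into all downstream absolute log2 values (≈ 0.01–0.03 log2 per sample);
  quantities defined as within-sample contrasts are unaffected.
- Puncta tracking itself (drift, merges, splits) is out of scope; the
  tenacity analysis assumes trajectories are already correctly tracked for
  the full series.
- Enrichment computation is external; only the published post-filtering
  rules are implemented.
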