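---
title: "Outcome-stratified reference intervals for ICU laboratory values: methods"
author: "icuref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcome-stratified reference intervals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icuref)
```

## The procedure

`icuref` implements a cross-sectional comparison of intensive-care
laboratory value distributions against hospital reference intervals,
conditioned on patient outcome. The pipeline is:

1. **First-stay selection.** One stay per subject — the earliest `intime`,
   ties broken by smallest `stay_id` — restricted to adults. Using only
   first stays keeps observations independent across patients; later stays
   of the same patient are discarded entirely.
2. **Worst first-day values.** For each stay and panel test, the most
   clinically extreme measurement in the first-day window is kept: the
   minimum, the maximum, or both, per the test's configured direction
   (e.g. minimum for albumin, where depletion is the danger; maximum for
   lactate, where elevation is).
3. **Outcome stratification.** ICU deaths form the worst-outcome group.
   Survivors are ranked by length of stay (LOS) and split into quartiles;
   the first quartile — the shortest stays — is the best outcome. Five
   ordered groups: `Q1_BEST`, `Q2`, `Q3`, `Q4`, `DIED_WORST`.
4. **Divergence statistics.** Each feature's distribution (all ICU, best
   group, worst group) is compared with the instantiated hospital
   reference interval via the overlapping coefficient (OVL) and the Cohen
   standardized mean difference (SMD), with a one-sample Wilcoxon
   signed-rank test against the reference mean; best and worst groups are
   also compared with each other.
5. **Outcome profiles.** Across the (extreme-trimmed) lab-value axis, the
   per-bin relative proportions of the five groups — the stacked-chart
   view of how outcome likelihood shifts with the lab value.

## Instantiating a reference interval as a distribution

A hospital reference interval is by definition the central 95% of a
healthy population, but density-based comparison needs a full
distribution. The canonical construction of reference intervals assumes an
approximately Gaussian healthy cohort, so the package instantiates the
interval $(L, U)$ as $\mathcal{N}(\mu, \sigma^2)$ with $\mu = (L+U)/2$ and
$\sigma = (U-L)/(2\,z_{0.975})$, $z_{0.975} \approx 1.959964$ — the unique
normal whose central 95% reproduces the interval exactly (round-trip
verified to $10^{-9}$). Assumptions worth keeping in mind:

- The healthy population's true dispersion is unknowable from the interval
  alone; every reference-relative SMD inherits the equal-tail Gaussian
  reading. This is a modelling choice, not an empirical fact.
- For strictly positive analytes a log-normal instantiation is available
  (same mapping on the log scale). The default stays normal; when
  $L - 3\sigma < 0$ (e.g. lactate, 0.5–2.0 mmol/L) the *evaluated density*
  is truncated at zero and renormalized so no reference mass sits on
  impossible values, while reported means and quantiles remain those of
  the untruncated normal — the truncated mass is negligible whenever the
  flag triggers on a realistic interval, and keeping moments untruncated
  preserves the exact round-trip invariant.
- The reference side of OVL/SMD/Wilcoxon is used *analytically* (exact
  density on the grid, exact mean) rather than as a sampled cohort,
  removing a layer of Monte-Carlo noise. A sampled mode exists for parity
  checks; it matches the ICU sample size by default so that two-sample
  pooled SMD is comparable with the analytic equal-weight pooling
  $(\bar{x}-\mu)/\sqrt{(s_x^2+\sigma^2)/2}$.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `windowHours` | 24 | hours | "First day" read as a half-open 24 h window from ICU admission, the simplest defensible definition; some derivations add a pre-ICU buffer, hence configurable. |
| `adultAgeMin` | 18 | years | Conventional adult threshold. Masked-age sentinels (> 300 y, a deidentification artifact) are retained as adults. |
| `trim` | 0.025 | fraction/tail | Central-95% intervals exclude the extreme 2.5% per tail to resist outliers. |
| `profileTrim` | 0.05 | total fraction | Extreme values carried by < 5% of the population are excluded before profiling (too few points for stable proportions); read as symmetric 2.5% per tail to match the interval convention; asymmetric splits are accepted. |
| `nBins` | 20 | bins | Equal-width bins over the kept range; bin width is presentation-level and not critical. |
| `bandwidthRule` | Silverman | — | Gaussian kernel with rule-of-thumb bandwidth; Sheather–Jones or a fixed numeric bandwidth can be substituted. |
| `gridPoints` | 512 | points | KDE grid spanning data ± 3 bandwidths, clipped at 0 for non-negative analytes and renormalized (avoids spurious negative-value mass). |
| `minN` | 10 | stays | Minimum non-missing values before a density/OVL/SMD is attempted for a population. |

The lab panel (test ids, units, directions, reference intervals) is
configuration, not code; `defaultPanel()` carries a routine 16-test ICU
panel with standard adult reference ranges.

## Quantiles, ranks and tie-breaks

- All empirical quantiles use linear interpolation over the order
  statistics, position $1 + p(n-1)$ (`stats::quantile` type 7). Interval
  endpoints depend on the convention, so it is fixed and stated.
- Survivor quartiles use rank $r$ of $n$ mapped to $\lceil 4r/n \rceil$,
  with `(los_days, stay_id)` ordering so ties are deterministic and the
  assignment is invariant to input row order. Quartile sizes differ
  pairwise by at most one. With 35 515 survivors this rule yields a
  first-quartile group of exactly 8 878.
- Quartile cut-points are computed on all selected stays, before any
  per-test missingness exclusion (missingness is handled per test, not by
  dropping patients).
- ICU death during the stay defines the worst group; patients dying in
  hospital after ICU discharge count as survivors for grouping, because
  the stratification is on ICU mortality.
- No multiple-testing correction is applied: per-test p-values are
  reported as-is, as is conventional for this descriptive design.

## The synthetic cohort: what it states and what it omits

`generateCohort()` draws a cohort whose structure exercises every
downstream rule, with defaults chosen once as a realistic stated world:
ICU death probability 0.08; survivor LOS log-normal with median 2 days
(sdlog 1), death-group LOS from the same family with median 2.5 days
(right-skewed, as ICU LOS is); 25% of surviving patients receive a later
decoy stay whose events must be ignored; roughly three measurements per
measured test on the first day; per-test missingness mirroring ordering
practice (albumin 59%, lactate 40%, others ≤ 20%); ages uniform 18–89
with an optional masked-age sentinel (308 y); vasopressor/ventilation
covariate rates conditioned on death status. Group-conditional analyte
values are normal or log-normal with per-group location shifts expressed
in units of the latent-scale SD — the shift *is* the true SMD against
baseline, which is what makes parameter-recovery tests possible.

A single master seed drives everything, with per-analyte RNG substreams
derived from `(seed, test_id)`: adding an analyte to the panel never
perturbs another's draws, keeping regression fixtures stable.

The generator deliberately omits: physiological time-series dynamics,
inter-analyte correlation, unit heterogeneity, and any relationship
between a patient's lab values and their LOS *within* an outcome group.
A green test suite therefore establishes that the pipeline's mechanics
and estimators are correct on data with known truth — not that any
particular hospital's values will reproduce a published table, which
would require the original credential-gated source database.

## Numerical choices and degenerate inputs

- OVL integrates $\min(f_1, f_2)$ by trapezoid on the union grid, each
  density linearly interpolated and zero outside its own grid; the result
  is clipped to $[0,1]$. OVL is symmetric to machine precision.
- KDE requires ≥ 2 distinct values; degenerate (constant) samples are an
  error for densities but fine for intervals (`(c, c)`) and profiles
  (a degenerate kept range is padded by a relative $10^{-8}$ to form one
  bin).
- The Wilcoxon signed-rank path drops zero differences, uses mid-ranks,
  and switches from the exact distribution to the tie-corrected normal
  approximation above n = 25 (or whenever ties exist); an all-zero
  difference vector warns and returns p = 1.
- Pooled-SD of zero (both groups constant and equal) is an error, not a
  silent infinity.
- Empty profile bins are reported with zero counts and `NA` proportions
  rather than dropped, keeping bin edges stable across analytes.
- Pipeline outputs are byte-reproducible for identical config + seed;
  optional plot images are excluded from that guarantee.

## Known limitations

- Reference-relative SMDs depend on the Gaussian instantiation of the
  reference interval (above); with a heavy-tailed healthy population the
  true standardized difference would differ.
- No age- or sex-partitioned reference intervals, no unit conversion, no
  severity-score computation — covariates like a severity score enter
  only as optional descriptive columns.
- The mean OVL across comparisons is reported as mean plus IQR if
  summarized by the user; the package does not claim any particular
  summary convention beyond the per-feature table.
- Bootstrap confidence intervals for OVL and smoothing of proportion
  curves are extension hooks, not implemented.

```{r example, eval = FALSE}
# end-to-end run on a synthetic cohort
res <- runPipeline(list(synthetic = list(nPatients = 2000)),
                   outDir = "icuref_out")
head(res$divergence)
```
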