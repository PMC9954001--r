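---
title: "Scoring and synergy analysis of Cmax-anchored viability screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and synergy analysis of Cmax-anchored viability screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combiscreen)
```

# The screen and its quantities

combiscreen implements the analysis stack of a high-throughput drug screen
on patient-derived tumor cells (e.g. glioblastoma tumorspheres in 384-well
plates read with a luminescent viability assay). Each drug is tested on a
6-point serial-dilution ladder whose *top* dose equals the drug's clinically
reported maximum plasma concentration (Cmax), so that every tested exposure
is clinically reachable. Drug pairs are additionally tested in combination,
and the screen is summarized by three quantities:

1. **Drug score.** Raw well signals are divided by the mean vehicle signal
   of the same sample, giving viability fractions (vehicle = 1). The area
   under the viability-vs-log10(dose) curve is computed by the trapezoid
   rule, $\mathrm{AUC} = \sum_i \Delta X_i (Y_i + Y_{i+1})/2$, and mapped to
   a 0–100 scale by min–max normalization,
   $$\mathrm{score} = 100\left(1 - \frac{\mathrm{AUC} -
   \mathrm{AUC_{min}}}{\mathrm{AUC_{max}} - \mathrm{AUC_{min}}}\right),$$
   where 100 means every cell killed at every dose, 0 means no effect, and
   growth-stimulating drugs score below 0 (scores are never clipped).
2. **Combination index (CI).** Single-agent responses are fitted with the
   Chou median-effect model $f_a/(1-f_a) = (D/D_m)^m$ by ordinary least
   squares of $\log_{10}(f_a/(1-f_a))$ on $\log_{10} D$. For a measured
   combination point with doses $(d_a, d_b)$ and fraction affected $f_a$,
   $$\mathrm{CI} = \frac{d_a}{D_{x,a}(f_a)} + \frac{d_b}{D_{x,b}(f_a)},
   \qquad D_{x}(f_a) = D_m\left(\frac{f_a}{1-f_a}\right)^{1/m},$$
   with CI < 1 synergism, CI = 1 Loewe additivity, CI > 1 antagonism.
3. **Panel ranking.** Scores are assembled into a treatment × sample
   matrix and treatments are ranked by their mean score over tested
   samples; the headline ranking uses the 10% Cmax dose tier, which favors
   combinations that act at the lowest clinically relevant exposure.

The package also covers the expression analyses that typically follow such
a screen: a two-rule differentially-expressed-gene filter, max–min heatmap
gene selection, log2 + mean-centering + average-linkage (UPGMA)
clustering, and relative qPCR quantification by $2^{-\Delta\Delta C_T}$
with error propagation.

# The synthetic screen and its ground truth

No external data are required: the `simulate_*` generators produce plate
tables, expression matrices and Ct tables whose ground truth is known in
closed form, which is what the test suite exercises.

**Single agents** follow a four-parameter Hill curve
$v(d) = \mathrm{bottom} + (\mathrm{top} - \mathrm{bottom}) /
(1 + (d/\mathrm{EC_{50}})^h)$. For a fully efficacious inhibitor
(top = 1, bottom = 0) this is exactly the median-effect model with
$D_m = \mathrm{EC_{50}}$ and $m = h$, so both fitting routes can be checked
against the same planted parameters.

**Combinations** are built from a scaled Loewe construction: the
noise-free fraction affected at a dose pair solves
$$\psi\,\frac{d_a}{D_{x,a}(f_a)} + \psi\,\frac{d_b}{D_{x,b}(f_a)} = 1 .$$
By construction the CI recovered downstream equals $1/\psi$ at **every**
dose pair, giving an exact closed-form oracle: $\psi = 1$ plants pure
additivity, $\psi = 2$ plants CI = 0.5. The left-hand side is strictly
decreasing in $f_a$ from $+\infty$ to $\psi \cdot 0 - 1 < 0$, so a root
always exists in (0, 1); it is found with Brent's method (`uniroot`, a
guarded bisection refinement, tolerance 1e-12) on the interval
$[10^{-6}, 1-10^{-6}]$, and roots outside that interval — dose pairs that
saturate the assay's dynamic range — are clamped and flagged on the row.

**Noise** is multiplicative lognormal on viability with standard
deviation `noise_sd` on the log scale (median 1). Plate readouts are
positive and heteroscedastic, which an additive Gaussian model would
violate; 3–5% is typical for replicate luminescence reads and the default
panel noise is 0.05.

**Panel heterogeneity** is a per-sample lognormal multiplier (sd 0.3) on
each drug's EC50 only. Keeping the slope fixed keeps parameter-recovery
tests single-parameter and mirrors the common observation that potency
varies across patient samples more than curve shape. A configurable
fraction of (sample, treatment) cells is dropped entirely, mimicking the
"not tested" cells of real screening heatmaps.

# Numerical and design choices

* **Dose axis.** The trapezoid AUC uses $X = \log_{10}$ concentration:
  dose–response curves are conventionally displayed and analyzed on a log
  axis, and a serial dilution then has uniform $\Delta X$, which is what
  makes the printed trapezoid formula natural. A linear axis is available
  via `axis = "linear"`.
* **Dilution factor.** Half-log ($\sqrt{10} \approx 3.16$-fold) steps, six
  doses: a common choice for 6-point screens covering 2.5 decades below
  Cmax. The factor is an argument, not a constant.
* **Score anchors.** $\mathrm{AUC_{min}} = 0$ (viability 0 everywhere) and
  $\mathrm{AUC_{max}} = $ the log10-dose range (viability 1 everywhere).
  Theoretical anchors make scores comparable across plates and screens;
  per-screen empirical anchors (observed min/max AUC) are available via
  `anchors = "empirical"`.
* **AUC on measured points.** Scoring integrates the measured per-dose
  means, not a fitted curve; `fit_hill()` exists for EC50 reporting and
  for the synthetic round-trip. Negative viabilities are floored at 0
  *only* inside the AUC (full kill is the maximal effect the score can
  express); values above 1 are kept, so stimulation yields negative
  scores, and nothing is clipped elsewhere.
* **Hill fitting.** Levenberg–Marquardt (`minpack.lm::nls.lm`) on the
  log10-dose axis with EC50 parameterized as $\log_{10}\mathrm{EC_{50}}$,
  slope bounded to $[10^{-3}, 100]$ and $\log_{10}\mathrm{EC_{50}}$ to the
  data range ± 3 decades. With fewer than 4 distinct doses the asymptotes
  are fixed at the observed max/min; curves with viability range < 0.05
  are flagged flat and returned unconverged.
* **fa clamping.** The median-effect linearization diverges at $f_a \in
  \{0, 1\}$, so observed fractions are clamped to [0.01, 0.99]
  (configurable). Clamped points are excluded from median-effect
  regressions but still evaluated — flagged — in Fa–CI tables.
* **Additive band.** CI within ±0.05 of 1 is classified "additive" so
  that arithmetic noise cannot flip a label; the raw CI is always
  reported. A series is "synergistic overall" when the majority of its
  points classify as synergism (i.e. CI below the band), a definition
  that is stable when every point sits exactly at CI = 1.
* **Non-constant-ratio CI.** Each measured dose pair is evaluated at its
  own observed $f_a$; the screen combines fixed dose pairs rather than a
  constant-ratio dilution series, and the classical two-term (mutually
  exclusive) CI is the only variant implemented.
* **Ranking.** Unweighted mean over tested samples (median by flag),
  ranked descending; ties share the minimum rank and order
  lexicographically; treatments tested on fewer than `min_samples = 3`
  samples are listed but unranked, preventing single-sample winners.
* **DEG filter.** The per-gene test is a Welch two-sample t-test on log2
  intensities. The proprietary error model of the original microarray
  vendor software is not reproducible from its description, so an
  unequal-variance location test is the package's substitute — this is a
  deliberate, documented substitution, and it is why absolute p-values
  should not be expected to match any vendor pipeline. Rule 1 requires
  $|\log_2 \mathrm{FC}| \ge 1$ **and** p < 0.05 (Benjamini–Hochberg
  adjustment by flag, default off). Rule 2 handles undefined ratios: when
  one group has no positive, non-missing intensities the log2 ratio is
  `NA`, and the gene passes if the group mean intensities differ by at
  least 1000. "The two samples" is read as the two group means.
* **Clustering input.** "Data transformation" before mean-centering is
  read as log2, the near-universal convention for intensity data; UPGMA
  is delegated to `stats::hclust(method = "average")` and verified in the
  test suite against a brute-force $O(n^3)$ all-pairs implementation.
  Euclidean distance is the default; `1 - Pearson` is available, with
  zero-variance rows dropped (their correlation is undefined).
* **ΔΔCt error propagation.** The sd of $\Delta\Delta C_T$ is the
  quadrature sum of the four cell-mean standard errors
  $\sqrt{\sum_i s_i^2/n_i}$ — the standard spreadsheet convention — and is
  reported as the fold-change interval
  $[2^{-\Delta\Delta C_T - s}, 2^{-\Delta\Delta C_T + s}]$. The test
  suite checks it against a $10^5$-draw Monte-Carlo resampling of the
  replicate Cts.
* **Determinism.** Every generator takes an explicit integer seed and
  restores the caller's RNG state; identical seeds give bit-identical
  tables, and `run_pipeline()` is byte-deterministic given config + seed.

# Calibration conditions

The stochastic checks in the test suite run under fixed, realistic screen
conditions chosen once:

* CI calibration uses two drugs whose ladders bracket their EC50s well
  (Cmax = 10 × EC50) and six combination dose pairs spanning ratios
  0.25–8 around the pair of median-effect doses — the informative $f_a$
  range a Chou–Talalay experiment is designed to cover. CI estimation is
  intrinsically ill-conditioned at extreme fractions affected (a 3%
  viability error is a ~100% relative error in $f_a$ near 0), so pairs
  confined to very low or very high $f_a$ give noisy indices no analysis
  can rescue; the central estimate over 50 seeded replicates at
  `noise_sd = 0.03` recovers $1/\psi$ within ±0.05 for
  $\psi \in \{0.5, 1, 2\}$.
* Parameter recovery uses 200 seeded 6-point, 3-replicate runs at
  `noise_sd = 0.05`; EC50 is recovered within ±25% in well over 90% of
  runs.
* Ranking recovery uses 100 seeded panels of 10 samples × 12 treatments
  (7 single drugs + 5 combinations, one of them planted uniformly best)
  at the 10% Cmax tier with `noise_sd = 0.05`.
* Expression checks use 100-gene matrices with 5 samples per group
  (planted $\log_2\mathrm{FC} = 2$, $\sigma = 0.1$), 20 seeds for power
  and 100 seeds for the null rate.

# What the synthetic screen does and does not emulate

The generators reproduce the *statistical* structure the pipeline relies
on: Cmax-anchored ladders, vehicle wells, multiplicative noise,
between-sample potency variation, untested cells, planted fold changes
and Ct shifts. They deliberately do **not** model tumorsphere growth
kinetics, plate spatial effects (edge wells, drift), seeding-density
artifacts, pharmacokinetics beyond the Cmax anchor, or microarray
preprocessing (gridding, background, cross-array normalization). Passing
tests therefore demonstrate that the computations are correct and well
calibrated on data satisfying their assumptions — not that those
assumptions hold for any particular wet-lab dataset.

# Worked example

```{r example}
erlotinib <- drug_spec("erlotinib", cmax = 20, ec50 = 4)
mln0128   <- drug_spec("mln0128", cmax = 1, ec50 = 0.3, hill_slope = 1.2)
pair      <- combo_spec(erlotinib, mln0128, psi = 1.6)

pan <- simulate_panel(6, list(erlotinib, mln0128, pair),
                      seed = 11, noise_sd = 0.05)
curves <- normalize_viability(pan)
scored <- score_curves(curves)
ranking <- rank_treatments(build_score_matrix(scored, "10pct_cmax"),
                           min_samples = 3)
ranking

fit_e <- with(subset(curves, treatment_id == "erlotinib@cmax" &
                       sample_id == "S01"), {
  fa <- fraction_affected(viability)
  fit_median_effect(dose_a_um[!fa$clamped], fa$fa[!fa$clamped])
})
fit_m <- with(subset(curves, treatment_id == "mln0128@cmax" &
                       sample_id == "S01"), {
  fa <- fraction_affected(viability)
  fit_median_effect(dose_a_um[!fa$clamped], fa$fa[!fa$clamped])
})
combo_rows <- subset(curves, treatment_id == "erlotinib+mln0128@cmax" &
                       sample_id == "S01")
fa_ci_table(combo_rows, fit_e, fit_m)
```

# Known limitations

* The AUC/score depends on the dose ladder's range; scores from screens
  with different ladder widths are only comparable under the theoretical
  anchors and the same number of decades.
* Median-effect fits assume full-range inhibitors; partial inhibitors
  (bottom > 0) bias $(D_m, m)$ because $f_a$ is measured against vehicle,
  not against the drug's own span. The Hill fit reports the asymptotes
  needed to detect this.
* The Welch-test DEG filter is a substitute for an unpublished
  vendor error model; set `adjust = TRUE` for multiplicity control.
* CI values at clamped fractions affected are reported but should be
  treated as qualitative.
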