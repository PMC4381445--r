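---
title: "Calibration methods: NIR/PLS models for feedstock composition and reactivity"
author: "feedstockNIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedstockNIR)
```

# The problem

Near-infrared spectra of milled, dried biomass encode overtone and
combination vibrations of the organic bonds in cell-wall polymers.
Given a calibration population whose composition (glucan, xylan,
lignin, ash; wt% dry basis) and reactivity (glucose/xylose release in
g/g and glucan/xylan yield as a fraction of theoretical) have been
measured by primary wet-chemistry and bench assay methods, a
latent-variable regression maps preprocessed spectra onto those
constituents so that future samples need only a scan. This vignette
documents the modelling choices the package makes, the parameters that
matter, and what the synthetic test bed does and does not demonstrate.

# Preprocessing chain

Steps run in a fixed order; each addresses a distinct artifact:

1. **SNV** (per spectrum, mean 0 / SD 1, $n-1$ denominator). Removes
   multiplicative gain and constant additive offset from particle-size
   and packing scatter — exactly, for any distortion of the form
   $a\,x + b$ with $a > 0$.
2. **Savitzky–Golay first derivative** (2nd-order local polynomial,
   21-point window, reported per cm⁻¹). Removes residual smoothly
   varying baseline while smoothing: a degree-2 local fit reproduces
   quadratic band shapes exactly, and the 21-point window (~77 cm⁻¹ at
   3.857 cm⁻¹ spacing) is narrow relative to NIR band widths. Edge
   points without a full window are trimmed ((window−1)/2 = 10 points
   per side) rather than fitted asymmetrically: deterministic, and the
   subsequent range cut discards the edges anyway.
3. **Range restriction** to 4,000–8,998 cm⁻¹ (bounds inclusive; the
   stated range carries no endpoint semantics, and inclusivity is the
   convention that never silently drops a stated endpoint). The grid
   ends outside this window carry detector noise and water-vapour
   structure without compositional information.
4. **1/SD column weighting** (dimensionless, per wavenumber, sample SD).
   Gives every wavenumber equal leverage in the fit. Weights are
   *fitted on calibration spectra only* and reused verbatim for any new
   spectra; inside cross-validation they are refitted per fold so no
   information leaks from the held-out sample.

Whether SNV should use the population or sample SD is immaterial
downstream — PLS centers and weights columns — but the sample ($n-1$)
convention is used everywhere for consistency with the descriptive
statistics.

# PLS-1 / PLS-2

The regression is NIPALS with per-factor X-deflation, the classical
algorithm of chemometric packages. Both blocks are mean-centered before
weighting; predictions are returned in original units. PLS-1 (single
response) and PLS-2 (joint responses) share one code path — a
single-column response reduces the inner loop to the non-iterative
PLS-1 update. Numerical choices:

* inner-loop convergence: 1e-12 on the loading-weight vector, max 500
  iterations — far below any data-driven scale;
* deterministic sign convention: each loading-weight vector's
  largest-magnitude element is made positive, so serialized models are
  reproducible bit-for-bit;
* rank exhaustion (residual X or Y sum of squares below 1e-24 of its
  start, or a degenerate weight vector) stops extraction early with a
  note recorded in the model rather than fabricating factors;
* a constant response block returns the mean model (zero coefficients)
  explicitly.

Model-family conventions: the composition model is one PLS-2 over
glucan/xylan/lignin/ash with spectra weighted 1/SD and constituents
unweighted (they share a wt% scale). The reactivity family weights
constituents 1/SD in its PLS-2 pairs (release pairs span different
ranges than yield pairs) and uses PLS-1 for the sums GX.Release and
GX.Yield. Default factor caps: 9 for composition, 11/8/9/8 for the
reactivity models — generous relative to the 4–6 factors the
cross-validation typically selects on the synthetic bed.

# Cross-validation and factor choice

Leave-one-out cross-validation refits *everything* per fold — centers,
1/SD weights, the NIPALS sequence — and predicts the held-out sample at
every factor count 0..max (0 = mean model). Because NIPALS extracts
factors sequentially, truncating a max-factor fit reproduces the
smaller fits exactly, so the per-fold curves cost one fit each; the
result is verified in the tests to match a naive per-factor refit loop
bit-for-bit.

The number of factors is the smallest count whose cross-validated
explained Y-variance (averaged over the model's constituents, so a
PLS-2 model gets one factor count) lies within 0.5 percentage points of
its maximum. The literature's "judgement at the plateau" is thereby an
explicit, reproducible rule; a manual override can be passed downstream.

Summary statistics follow the predicted-versus-measured convention:
slope and intercept are the least-squares line of predicted (ordinate)
on measured (abscissa), and R² is the squared Pearson correlation.

# Sample selection and outlier screening

Kennard–Stone runs on the top two mean-centered PCA score dimensions of
the preprocessed (but unweighted) spectra: selection precedes model
development, where the 1/SD weighting belongs. Ties in the max–min
rule break to the lowest sample index, then lexicographic ID, making
the split deterministic and permutation-stable. Kennard–Stone
guarantees spectral coverage of the calibration set; it does *not*
guarantee that validation samples are interpolated, and no such claim
is tested.

Outlier screening fits a base model on the full calibration set and
normalizes each sample's absolute prediction error by the constituent's
RMSEC. For composition, the glucan/xylan/lignin errors are averaged and
compared to 1.5, with ash screened separately at the same cutoff (ash,
measured only indirectly by NIR, would otherwise dominate the average).
For reactivity models the cutoff is 2.0, applied per modeled
constituent (a sample is removed when any response of the model exceeds
it). Flagged samples are always removed and the model refit once —
discretionary exceptions are not reproducible, so the package makes
none. One consequence is a known bias: the single-constituent ash
screen removes the top ~13% of |error| under Gaussian residuals, so the
post-screen error estimates are computed on a truncated residual
distribution (~0.74 × SD for the ash screen). This is inherent in the
screening rule, and users comparing RMSECV before and after screening
should expect the drop.

# Reactivity arithmetic

Release is grams of monomeric sugar per gram dry biomass (the assay
loads 3.0 g in 30 mL of 1% sulfuric acid). Yields divide
anhydro-corrected release by the structural-carbohydrate base:
glucose→glucan 162.14/180.16, xylose→xylan 132.11/150.13 (repeat unit
over monomer), with sucrose contributing only its glucosyl moiety
(162.14/342.30) to the glucan base. The combined GX.Yield is a *pooled
ratio* — summed corrected releases over summed bases — not the sum of
the two component yields: a sum of two fractions could reach 2.0 and
would not be a yield; the pooled ratio stays on the same 0–1 scale and
equals 1 exactly when both components convert fully.

# The synthetic test bed

Because no spectral archive accompanies the methodology, the package
ships a generator that reproduces the *statistical structure* the
pipeline assumes, with every default fixed at the study conditions:

* **Population**: 279 samples; per-constituent truncated normals with
  mean/SD/min/max of glucan 33.2/6.3/21.4/47.8, xylan 17.8/3.4/9.5/28.7,
  lignin 15.2/3.8/6.7/29.0, ash 6.7/3.6/0.9/16.4 wt%. The generating
  center is adjusted so the *truncated* mean hits the stated mean; the
  truncation shrinks the SD by ~5–25% (ash most), which is accepted.
  Real feedstock populations are bimodal or skewed rather than normal;
  an optional two-component mixture per constituent is provided for
  stress tests, but the defaults do not claim those shapes.
* **Spectra**: Beer–Lambert mixtures of per-constituent Gaussian-band
  bases on the 3,300–12,000 cm⁻¹ grid at 3.857 cm⁻¹ spacing (so the
  range-reduction step is exercised non-trivially), with the unmodeled
  remainder of the dry mass carrying its own "other" basis; per-sample
  multiplicative (SD 0.05) and additive (SD 0.02 AU) scatter shared by
  both duplicate scans; instrument noise 5e-4 AU drawn independently
  per replicate. Duplicate averaging therefore reduces noise, and SNV
  removes the scatter exactly — by construction, as in the acquisition
  model it emulates.
* **Reference uncertainty**: the reported composition is the true value
  plus normal error with SD 1.1 (glucan), 0.7 (xylan), 0.75 (lignin),
  0.85 (ash) wt% — the wet-chemistry uncertainty that, in practice,
  sets the floor for RMSEC/RMSECV/RMSEP. These SDs were chosen once so
  that the *post-screening* cross-validation errors fall at the scale
  primary methods report (roughly 0.6–1.2 wt%), accounting for the
  truncation the deterministic screen introduces.
* **Reactivity**: release is linear in composition plus assay noise —
  G.Release = 0.035 + 0.008·glucan − 0.004·lignin + N(0, 0.02),
  X.Release = 0.009·xylan − 0.002·lignin + N(0, 0.015), clipped at 0 —
  the weakest structure under which a linear calibration can succeed,
  with lignin entering negatively (recalcitrance). The coefficients
  place the population means/SDs at ≈0.24/0.06 and ≈0.13/0.04 g/g.
  Yields are computed exactly from the simulated releases by the
  package's own yield arithmetic, so they are internally consistent.

What passing tests on this bed demonstrates: the pipeline recovers
constituents down to the reference-uncertainty floor, the screening
rule catches gross reference errors, and every stage is deterministic
and leakage-free. What it does not demonstrate: performance on real NIR
band structure (overlapping overtones, nonlinear detector response,
moisture interference), on non-normal populations, or on reactivity
whose relation to spectra is nonlinear. Yield models in particular are
ratios of noisy quantities and cross-validate substantially worse than
release models on the synthetic bed — a structural effect a linear
model cannot remove, mirroring the common observation that yield
calibrations carry roughly twice the uncertainty of release
calibrations.

# Problem sizes

The shipped tests run the complete study at its full scale — 279
samples, 245-sample Kennard–Stone selection, leave-one-out over the
~210 post-screen calibration samples at up to 9 factors — twice (the
second run verifies byte-identical artifacts), plus a 193/175-sample
reactivity configuration in the acceptance script. Property-style
checks (PLS-vs-least-squares, naive cross-validation loop, exhaustive
Kennard–Stone) use small random instances (n ≤ 40, p ≤ 10, 50–100
seeds) where brute-force oracles are exact.

# Known limitations

* Physical realism of the band bases is not attempted; the generator
  validates the statistics of the pipeline, not NIR spectroscopy.
* The outlier screen is deliberately non-discretionary; populations
  with heavy-tailed reference errors will lose more samples than an
  analyst reviewing each flag would remove.
* Factor selection encodes one plateau rule; analysts preferring the
  RMSECV minimum or a parsimony rule should pass their factor count
  explicitly.
* Kernel, sparse and nonlinear PLS variants, k-fold/venetian-blind
  cross-validation, and spectral outlier diagnostics (leverage,
  Hotelling T², Q residuals) are out of scope.
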