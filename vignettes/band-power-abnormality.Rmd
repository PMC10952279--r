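---
title: "Band-power abnormality mapping and surgical-failure markers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-power abnormality mapping and surgical-failure markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megmark)
```

## The model

`megmark` operates on parcellated, region-level MEG data: one interictal
resting-state time series per cortical region of interest, or precomputed
region × band relative power tables. The pipeline is

time series → Welch PSD → relative band power → normative z-map →
max-|z| abnormality map → resection markers → cohort statistics.

The core modelling assumption is that, conditional on region and band,
relative band power in healthy controls is approximately Gaussian, so that
the per-cell score $|z_{ij}| = |x_{ij} - \mu_{ij}| / \sigma_{ij}$ (patient
value $x$, control mean $\mu$ and SD $\sigma$) is interpretable on a common
scale across regions and bands. The per-region reduction
$\max_j |z_{ij}|$ deliberately keeps only the most deviant band: a region
is "abnormal" if *any* of its five band fractions is far from the healthy
norm. The price is a non-Gaussian null for the region score — the maximum
of five folded normals — which is why reference levels for region scores
come from the max-order-statistic law (below), never from a normal table.

## Spectral estimation

`welch_psd()` averages Hann-tapered, modified periodograms over sliding
windows. Parameters:

| parameter | default | units | rationale |
|---|---|---|---|
| `window_s` | 2 | s | 0.5 Hz resolution; resolves the 1 Hz lower band edge |
| `overlap_frac` | 0.5 | — | standard variance/efficiency compromise for Hann windows |

Choices the estimator fixes internally: a symmetric Hann taper and
per-window constant detrending (mean removal), both field defaults for
resting-state spectra; a final incomplete window is dropped, so results do
not depend on how much trailing signal fails to fill a hop. The one-sided
density is scaled by $1/(f_s \sum w^2)$ with interior bins doubled, the
convention under which summing `psd * df` recovers mean squared amplitude.

Band powers are the sum of PSD bins whose *center* lies in the band,
times the bin width, under a half-open $[low, high)$ convention. With
shared edges at 4, 8, 13 and 30 Hz, half-openness guarantees no bin is
counted twice, so the five relative powers sum to exactly 1. The same
half-open rule applies to the 47.5–52.5 Hz powerline notch inside gamma.
On a flat unit density this integration rule returns exactly the
effective bandwidths 3 : 4 : 5 : 17 : 45 — a closed-form identity the
test suite asserts.

"Total power" for normalization is the sum of the five band powers, not
an integral over the full recorded spectrum. The two differ in whether the
gamma notch and any residual power above 80 Hz count toward the
denominator; excluding both from numerator *and* denominator keeps the
five reported fractions an exact composition (rows sum to 1 within 1e-9,
enforced at construction and on file read). This is a design choice: the
alternative (full-spectrum denominator) would make the fractions depend on
out-of-band artifact power that the band scheme was designed to exclude.

## Normative and abnormality maps

`build_normative_map()` uses the *sample* standard deviation (denominator
$n-1$). Controls are a sample from the healthy population, and with
typical control cohorts (~70) the difference from the population
convention is ~0.7% of σ — far below between-site variability — but the
sample convention is the statistically defensible one and is fixed
throughout.

Degenerate cells with $\sigma = 0$ (possible with identical controls,
e.g. the zero-noise generator setting) yield $z = 0$ when the patient
matches the control mean and are a hard error otherwise: a silent
division by zero would inject infinities into the downstream rank
statistics, which is strictly worse than failing.

Ties in the per-region argmax band resolve to the lowest band index
(delta first), making maps bit-reproducible; the score itself is
unaffected. Regions labelled `unknown` by resection labelling stay in the
abnormality map — they are excluded only where resection status matters,
i.e. inside the three markers.

## Resection labelling and markers

Percent volume change is computed against the *pre-operative* volume,
$100(pre - post)/pre$: the pre-operative brain is the surgical referent.
Boundary conventions, chosen by literal reading of the labelling rule:
change must *exceed* 10% to count as resected, so exactly 10% is
`unknown`; exactly 1% is `spared`. Apparent volume growth is clamped to
0% with a warning — post-operative regional "growth" at registration
accuracy is noise, not regeneration.

`drs()` is the Mann–Whitney AUC of spared against resected abnormalities,
computed via midranks; ties count ½, matching the U-statistic convention.
It inherits the U-statistic's invariance under strictly increasing
transforms of the scores and the exact complement symmetry
$D_{RS}(\text{swapped labels}) = 1 - D_{RS}$, both asserted exactly in
tests against an exhaustive pair-count oracle. `acr()` satisfies the
complement identity $AC_R + AC_R^{\text{swapped}} = 100\%$ whenever no
region is unknown.

## Cohort statistics

**Mann–Whitney AUC and p.** `auc_mwu()` orients the AUC so values above
0.5 support the stated one-sided hypothesis. P-values are exact — complete
enumeration of group assignments over midranks, valid under ties — for
combined $n \le 20$, and tie-corrected normal with continuity correction
beyond. The cutoff places a 12-vs-20 style cohort just outside the exact
regime while keeping enumeration (choose(20, 10) ≈ 1.8 × 10⁵ subsets)
instant for anything smaller.

**Wilcoxon signed-rank.** Zero differences are dropped (standard
convention). For up to 25 nonzero differences the null distribution of
the positive-rank sum is computed by convolving its generating function
over doubled midranks — doubling makes tied midranks integer exponents, so
the computation stays exact under ties, where `stats::wilcox.test` would
silently fall back to an approximation. Beyond 25, tie-corrected normal
with continuity correction.

**Healthy max-|z| threshold.** `simulate_max_abs_z_threshold()` draws
`n_bands` (default 5) standard normals per iteration, keeps the maximum
absolute value, and returns the empirical $1-\alpha$ quantile over
`n_iter` (default 100,000) iterations. The closed form is
$t$ solving $(2\Phi(t) - 1)^{n\_bands} = 1 - \alpha$, i.e. 2.5688 for five
bands at 5%, conventionally quoted as 2.6; the simulation serves as the
operational definition and the closed form as its cross-check.

**Optimal ROC threshold.** Candidate cuts are midpoints between adjacent
sorted unique values plus ±∞; the returned cut maximizes Youden's
$J = TPR - FPR$ for detecting bad outcome in the marker's failure
direction. "Maximize true positives while minimizing false positives" is
ambiguous between Youden and closest-to-corner; Youden is the default
because it weighs sensitivity and specificity equally and is the common
operational reading, and `method = "closest"` exposes the alternative.
Ties on $J$ break toward the lowest FPR, then toward the more extreme cut
in the failure direction — when the data cannot justify flagging, the
flag should stay off. Degenerate all-equal inputs therefore return a cut
that flags nobody. Flag inequalities are strict (`<`, `>`): boundary
equality never flags.

## The synthetic-data generator

`generate_controls()` draws, per region and band, a latent Gaussian
(region-specific means drawn once per cohort around a broadly 1/f-like,
alpha-dominant band profile; per-subject noise SD `noise_sd`) and passes
each region's five latents through a softmax. This guarantees valid
compositions (rows in $[0,1]$, summing to 1) while keeping per-cell
z-scores against the control cohort approximately Gaussian at the chosen
noise scale. It is an *emulation* of the statistical structure the
pipeline consumes, not a biophysical MEG model: there is no forward/inverse
physics, no spatial correlation between neighbouring regions, no
age or site structure, and the "bands" have no spectral meaning inside
the generator. Passing tests on synthetic cohorts therefore demonstrates
the pipeline's statistical machinery, not its behaviour on real MEG.

Abnormalities are injected on the latent scale, into one band per
abnormal region, in units of `noise_sd` (`effect_size`, default 6 — a
clearly pathological deviation, chosen so that single-patient maps are
visually unambiguous at the default noise level). Scenarios encode the
three failure mechanisms plus a control case:

- `mislocalized`: focal abnormal set (`n_abnormal` = 6 regions at
  near-full effect); resection disjoint from it. Matching marker: low
  MA_R.
- `partial`: widespread graded field (`n_abnormal_diffuse` = 60 of 114
  regions with effects $\sim \text{effect} \times U(0,1)$, a
  core-to-penumbra gradient); the resection covers only the weakest-effect
  penumbra, sparing the core. Matching marker: D_RS above chance.
- `diffuse`: the same widespread field, but the resection covers the few
  *strongest* regions — well targeted yet a small fraction of the total
  load. Matching marker: low AC_R.
- `clean`: focal set, fully resected; good outcome.

The widespread-set size (60) was set during design so the scenarios
realize their mechanisms reliably: with a smaller field, the many normal
spared regions dilute the rank statistic and a partial resection no
longer sits above chance on D_RS in the large majority of replicates,
which would defeat the scenario's purpose as ground truth. Outcomes are
deterministic by scenario (bad for the three failure scenarios), then
flipped with probability `label_noise` (default 0.1) to mimic the
imperfect outcome separation of real cohorts. Default cohort shape — 114
regions, 70 controls, 12 good and 20 bad patients — mirrors a
mid-resolution parcellation study with a typical surgical cohort.
Everything is deterministic given the config seed.

## Problem sizes and tolerances in the test suite

The suite runs at desk scale by design: Welch cross-checks use seconds of
signal at tens of Hz against an $O(n^2)$ DFT oracle; rank-statistic
oracle checks use ≤ 50 regions over 100 random instances (exact
equality); the threshold simulation uses the full 100,000 iterations
(sub-second); mechanism-recovery uses a full default cohort plus 200
replicate patients per scenario and 100 per effect level on the dose
ladder (0, 2, 4, 6 σ). Composition identities assert to 1e-9; rank
identities exactly; Monte-Carlo checks use 2–3 standard-error bands.

## Known limitations

- Normative maps carry no age or site harmonization; maps built from one
  acquisition setup do not transfer to another.
- Each run is single-parcellation; region lists of any size work (68–448
  tested), but there is no cross-walk between parcellations.
- Thresholds from `unified_outcome_analysis()` are in-sample; they are
  descriptive of the analysed cohort, not validated cutoffs for new
  patients.
- The estimator assumes stationary, artifact-free region time series;
  sensor-level cleaning and source reconstruction are out of scope.
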