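---
title: "Network segregation, aging, and valence bias: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network segregation, aging, and valence bias: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segbias)
```

## The scientific question

Resting-state fMRI reveals a stable community structure of functional brain
networks. A network's *segregation* summarizes how much more strongly its
regions talk to each other than to the rest of the brain:

$$ S_k = \frac{\bar Z_w^{(k)} - \bar Z_b^{(k)}}{\bar Z_w^{(k)}}, $$

where $\bar Z_w^{(k)}$ is the mean Fisher-z correlation over all ROI pairs
inside network $k$ and $\bar Z_b^{(k)}$ the mean correlation of network-$k$
ROIs with all ROIs outside $k$. Segregation declines across adult aging.
*Valence bias* — the percentage of emotionally ambiguous faces and scenes a
person categorizes as positive — grows more positive with age. This package
implements the full analysis chain linking the two: behavioral scoring,
motion-aware time-series cleaning, connectivity and segregation metrics over
a 300-ROI / 14-network parcellation (12 networks after merging the two
somatomotor networks and dropping unassigned ROIs), and the lifespan
statistical models, including AIC backward elimination of DMN
between-network predictors with a forced age covariate, simple slopes, and
Johnson-Neyman moderation intervals.

## Pipeline stages and their fixed order

Per subject and run, processing is: filtered framewise displacement →
censor mask → demean/detrend → censor-aware nuisance regression →
interpolation of censored frames → 0.009–0.08 Hz band-pass → re-censoring →
frame-budget selection → Pearson correlation → Fisher z → negative-value
zeroing → network measures. The order is recorded in the provenance of
`clean_subject()` and asserted in tests.

Key parameters, their units and defaults:

| parameter | default | meaning |
|---|---|---|
| FD censoring threshold | 0.2 mm | frames above it are discarded |
| FD low-pass cutoff | 0.1 Hz | zero-phase 2nd-order Butterworth on the six realignment estimates before differencing |
| rotation radius | 50 mm | converts radians to mm of arc (standard convention; the conversion itself, not a fit parameter) |
| contiguity rule | 5 frames | retained segments shorter than this are dropped, within runs only |
| run rule | 50 frames | runs retaining fewer frames are dropped whole |
| frame budget | 800 frames | subjects below it are excluded; the *earliest* 800 retained frames are analyzed so data quantity is matched across subjects |
| pass band | 0.009–0.08 Hz | zero-phase 2nd-order Butterworth band-pass |
| accuracy cutoff | 0.60 | clear-trial accuracy below 60% excludes a subject behaviorally |
| alpha | 0.05 | two-sided; used for quadratic retention, interaction screening and the Johnson-Neyman critical t |

Nuisance regression uses the 24-parameter motion set (the six realignment
parameters, their backward differences, and the squares of current and
one-frame-lagged parameters) plus the global signal and two tissue signals —
27 columns. Coefficients are estimated on retained frames only, so
high-motion frames exert no leverage; a configuration flag restores
estimation on all frames for comparison. When no measured tissue signals
exist (as for synthetic cohorts), two white-noise proxy columns keep the
design shape; they remove only random degrees of freedom.

## Statistical models

Motion is controlled twice, deliberately with two different mechanisms:
the root-mean-square of FD is *residualized out* of every network measure
(segregation, within, between, and the DMN pairwise connectivities), while
age enters the valence-bias models as a *covariate*. Age models are fitted
on standardized age with an automatic quadratic term: the quadratic model is
reported only when its quadratic coefficient is significant at alpha (a
documented reading; pre-specifying quadratics per measure is also possible
via `quadratic = "on"/"off"`). Overall model p-values across the 12
per-network models are corrected with Benjamini–Hochberg FDR.

The valence-bias stage regresses bias on standardized age plus the 11 DMN
between-network connectivities and prunes the candidates by backward AIC
elimination with age forced in: at each step the candidate whose removal
most decreases AIC is dropped; ties break lexicographically so the trace is
deterministic. An optional change-in-estimate guard (retain a candidate
whose removal shifts any remaining coefficient by more than 20%) is
available but off by default; the exact augmentation rules of the original
selection procedure are not fully described, so plain AIC backward
elimination with forced covariates is the package's documented
approximation. Age moderation of each surviving predictor is screened one
interaction at a time; significant interactions are then retained jointly.
Simple slopes are evaluated at moderator values −1, 0 and +1 SD, and the
Johnson-Neyman boundaries solve
$(B_f + B_i a)^2 = t_{crit}^2 (V_f + a^2 V_i + 2 a C)$ by the quadratic
formula, with the significance region decided by direct testing rather than
sign conventions. The critical t uses the final model's residual degrees of
freedom at pointwise two-sided alpha = .05 (no multiplicity correction over
the moderator range, a documented choice). Extreme outliers are flagged by
the median ± 3 × IQR rule before the age models; the rule is config-exposed
because the original criterion is not stated.

Degenerate inputs fail loudly rather than silently: models refuse to fit
with n ≤ terms + 2, rank-deficient designs raise errors (nuisance designs
drop collinear columns with a warning instead, since censoring can make
motion columns collinear), and a network with non-positive mean within-z
yields an undefined segregation with a warning.

## What the synthetic cohort emulates

`generate_cohort()` draws subjects uniformly over 6–80 years and builds,
per subject, a latent factor model over the parcellation: each ROI loads on
its network factor, on one shared cross-network factor, and — for DMN, CO,
VAN and Reward ROIs — on pair-specific factors. Loadings are solved so the
population correlations hit the planted targets exactly, which guarantees a
valid covariance at any target. Planted structure:

* within-network correlation declines linearly with standardized age
  (default 0.40 at the mean age, −0.04 per SD of age), which induces the
  planted segregation decline; small fixed per-network offsets spread the
  14 networks over roughly 0.36–0.44;
* between-network correlation follows an inverted U in age
  (0.12 − 0.015·age_z² + 0.01·age_z);
* the DMN–CO, DMN–VAN and DMN–Reward couplings get subject-specific
  Fisher-z deviations (SD 0.15) that carry the behavioral effects;
* valence bias = 50 + 5·age_z + 25·d(CO) + 12·d(VAN) − 55·age_z·d(Reward)
  + N(0, 15), clipped to [0, 100];
* motion: a low-amplitude random-walk drift plus sustained 1.2–2.5 mm
  translation steps whose filtered-FD footprint exceeds 0.2 mm over about
  five frames per event; the event rate is U-shaped in age (children and
  older adults move more), so some young/old subjects genuinely fail the
  800-frame requirement;
* about 3% of subjects are simulated as behaviorally non-compliant
  (clear-trial accuracy below 60%).

Two calibration notes. First, the within/between magnitudes are
order-of-magnitude choices (the analyzed scale after global-signal
regression lands near within z ≈ 0.25–0.4, between z ≈ 0–0.1); they are
config-exposed, not asserted. Second, the bias gammas are expressed per
unit *planted* z-deviation, but the measurement chain shrinks deviations
substantially: global-signal regression centers between-network
correlations near zero and the negative-zeroing step then censors the lower
half of each deviation. The defaults above were calibrated once so that the
*measured* effects land near the reported real-data magnitudes (DMN–CO
t ≈ 2.2–2.7, age × DMN–Reward t ≈ −2 to −3.6 at n ≈ 250); they encode the
reported effect structure, not its raw coefficients.

Ambiguous-trial responses realize the planted bias as an exact positive
count at the task's 1/48 resolution with random placement (marginally, each
trial is positive with probability bias/100), so noiseless scoring recovers
the planted bias up to rounding; clear-trial responses are Bernoulli in the
planted accuracy.

What the generator does **not** emulate: hemodynamic autocorrelation and
spatial smoothness (factors are white in time), scanner-specific artifacts
beyond step motion, anatomical misregistration, and any non-Gaussian
behavior of real BOLD. Passing recovery tests therefore demonstrates that
the *pipeline* is correct and well-calibrated under the assumed generative
structure — not that the scientific findings would replicate in new data.

## Numerical choices

* Fisher z clips |r| at 1 − 1e−7 before `atanh` so duplicated ROIs stay
  finite; diagonals are excluded as NA.
* Negative z values are zeroed *after* the Fisher transform, entrywise,
  before any averaging; pairwise DMN–X means use the same thresholded
  matrix (an unthresholded variant is a config switch).
* Global segregation uses equally weighted per-network means,
  $S = (\bar W - \bar B)/\bar W$; the alternative mean of per-network
  $S_k$ is reported alongside as `mean_segregation`.
* Interpolation of censored frames is linear by default; a least-squares
  sinusoid reconstruction (`method = "spectral"`) is available.
* Censoring idempotence, threshold monotonicity, and the prefix property
  of frame-budget selection are asserted as properties in the test suite.
* All generators are pure functions of (spec, seed); child seeds are
  derived per subject and stream, and the caller's RNG state is restored.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen for a single-CPU run while
keeping every stage at realistic per-subject scale (1000 frames, 800-frame
budget): sign recovery of the three planted effects uses 10 seeded cohorts
of 250 subjects at 112 ROIs (8 per network) through the full pipeline;
CI coverage uses 200 cohorts of 250 subjects on the planted predictors
(coverage is a property of the estimator under the generative model —
measured predictors would attenuate coefficients by design); null
calibration pools 600 bias-model tests with 60 full-pipeline age-model
tests. The demo pipeline runs 24 subjects at the full 300-ROI parcellation.

## Known limitations

* Between-network connectivity after global-signal regression is centered
  near zero, so thresholded between-z values carry a censored floor; the
  package reports them as analyzed, but their absolute scale should not be
  compared with pipelines that skip global-signal regression.
* The AIC elimination is a greedy path, not an all-subsets search; with a
  purely interactive effect the main-effect candidate is legitimately
  dropped, so moderation questions about a specific pair should be asked
  of the final-form model directly.
* `fit_from_coefs()` reconstructs a model from printed coefficients with
  zero covariances unless supplied; slopes are exact but their standard
  errors at non-zero moderator values are approximations in that case.
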