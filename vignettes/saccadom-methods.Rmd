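---
title: "Saccadometry models and methods in saccadom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saccadometry models and methods in saccadom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
second-order model of saccade trajectories, the damping-ratio estimator
and its precision filter, the synthetic cohort generator, the univariate
mixed models, the multivariate classifiers, and the small-sample
cross-validation machinery — together with the numerical choices and
known limitations a maintainer should understand.

## The second-order model of a saccade

A horizontal saccade is modelled as the step response of a linear
second-order system with gain $A$ (degrees), damping ratio $\sigma$
(dimensionless) and natural frequency $\omega_0$ (rad/s):

$$
\hat\varphi(t) = H(t)\, A \, g(t;\sigma,\omega_0),
$$

where $g$ has three closed-form branches — underdamped ($\sigma<1$,
oscillatory overshoot), critically damped ($\sigma=1$) and overdamped
($\sigma>1$, monotone approach) — all starting at rest and converging to
1. Physiologically, low damping trades terminal accuracy (overshoot,
retinal slip) for speed; high damping does the opposite. The branches
are algebraically continuous at $\sigma=1$; numerically the critical
branch is evaluated only within $|\sigma-1|<10^{-6}$ because the open
branches are stable everywhere else (the cross-branch sup-norm
discrepancy near the boundary is below $10^{-6}$, tested).

Two identities validate the implementation independently of any fitting:
the asymptote equals $A$ for every branch, and the underdamped peak
overshoot equals $\exp(-\sigma\pi/\sqrt{1-\sigma^2})$.

## Damping-ratio estimation

`fit_second_order()` normalises the post-initiation samples by the
measured amplitude (net displacement, as a recording device would report
it) rather than the fitted plateau — the gain $A$ then remains free to
express over- or undershoot relative to the measured amplitude, and the
estimate of $(\sigma,\omega_0,\delta t)$ becomes exactly scale
equivariant. The residual

$$
\textstyle\sum_i \big(\varphi_{\mathrm{obs}}(t_i)-\hat\varphi(t_i-\delta t)\big)^2,
\qquad |\delta t|\le 5\ \mathrm{ms},
$$

is minimised by Levenberg–Marquardt least squares with a multi-start
grid $\sigma_0\in\{0.5,1,1.5\}\times\omega_{0,0}\in\{30,60,120\}$ rad/s,
because the underdamped and overdamped basins can each hold a local
minimum; ties in the final sum of squares break toward the smaller
$\sigma$. The time shift is a continuous bounded parameter (not a grid),
since its purpose is sub-sample alignment of the initiation time.
Parameter boxes are $A\in(0.05,3]$, $\sigma\in(0.05,5]$,
$\omega_0\in[5,500]$ rad/s. Implementation detail: the box-constrained
mode of the Levenberg–Marquardt solver is roughly twenty times slower
than the unconstrained mode, so the unconstrained solver runs first and
the constrained one is used only when the unconstrained optimum leaves
the box; solutions in the interior are identical. Exploration runs use a
coarse tolerance and the best start is polished at full tolerance; a
start that reproduces the data to machine precision ends the search.

The standard error of $\sigma$ comes from the linearised covariance
$s^2(J^\top J)^{-1}$ at the optimum ($J$ the residual Jacobian by
central differences, $s^2$ the residual variance). How the original
analysis computed this quantity is not documented anywhere we could
follow, so this choice is calibrated rather than asserted: across
noisy-replicate simulations the median reported SE falls within a factor
of two of the empirical spread of $\hat\sigma$ (tested). Fits are
flagged non-converged — and their SE set to $+\infty$, so the precision
filter always removes them — when the optimiser fails, the trajectory is
degenerate (constant), or $A$, $\sigma$ or $\omega_0$ lands on a box
bound. A $\delta t$ at its $\pm 5$ ms limit is *not* treated as failure:
that limit is part of the model definition, not a numerical guard.
`filter_by_sigma_se()` then excludes fits with SE strictly greater than
0.5, mirroring the strict-inequality convention used by the kinematic
quality-control filters.

## The synthetic cohort generator

No participant-level recordings are deposited for this protocol, so the
generator is a first-class, tested module that defines the study
conditions under which everything downstream is validated. It emulates a
step-paradigm saccadometry session: fixation at 0°, peripheral targets at
±10° chosen with equal probability, foreperiods drawn from an
exponential law truncated to 1.0–2.0 s (inverse-CDF sampling; the
rate→0 limit is uniform, tested), and eye position sampled every 5 ms
from 25 ms before initiation to 20 ms after the saccade ends by the
5°/s velocity criterion.

Defaults encode the effect structure the analyses are designed to
detect, with one value chosen per quantity and not revisited:

* **Latency** (shifted gamma, shape 9, right-skewed): control
  prosaccades 200 ms; PD +19 ms; correct antisaccades +120.9 ms
  (control) and +147.1 ms (PD) above prosaccades; antisaccade
  directional errors ≈ prosaccade +14 ms — consistent with their
  interpretation as failures to inhibit a reflexive prosaccade.
* **Damping ratio** (zero-truncated normal): control prosaccades 1.00,
  PD 1.05; antisaccades +0.06 (control) and +0.09 (PD); errors damped
  like prosaccades in PD (1.07) but closer to antisaccades in controls
  (1.03).
* **Amplitude**: 10° except correct antisaccades — controls overshoot
  (12.31°), PD do not (10.52°): a *relative* hypometria.
* **Antisaccade error rates** 0.25 (PD) vs 0.20 (control): group
  difference deliberately modest, in the range reported for older
  adults, since the error-rate comparison is expected to be
  non-significant at this cohort size.
* $\omega_0 = 60$ rad/s (no published value; chosen so 10° saccades
  last roughly 40–60 ms), measurement noise 0.15° per sample,
  between-participant random intercepts (20 ms, 0.08, 5 rad/s, 0.8°)
  and within-participant spreads (0.18, 8 rad/s, 1.5°) chosen so
  participant-level damping means span roughly 0.5–1.5.

What the generator deliberately does **not** model: blinks, head
movements, main-sequence amplitude–velocity coupling, vertical saccades,
prosaccade directional errors, and recording artifacts. One visible
consequence: the kinematic QC filters (latency outside 100–1000 ms,
amplitude > 40°, peak velocity > 1000 deg/s — all strict inequalities)
almost never fire on synthetic data, because the generator produces no
artifacts; the filters are therefore validated on constructed toy
inputs. Passing tests on synthetic cohorts shows the estimators and the
evaluation machinery are correct under the stated generative model; it
cannot show robustness to artifact structure real devices produce.

### Segmentation in the pipeline

The device that motivated this design detects saccades online; its
exported latency is the initiation time. The pipeline therefore segments
each trial at the reported latency, and the velocity-threshold detector
(`detect_saccade()`, first contiguous run of |v| > 5°/s) is provided for
clean or smoothed series. Thresholding raw differentiated positions at
5°/s is physically meaningless at 0.15° noise and 5 ms sampling (the
finite-difference noise floor is ≈20 deg/s), which is why detection is
not part of the default noisy-data path.

## Univariate mixed models

Each saccade metric is analysed at the saccade level with fixed effects
of group, response type (prosaccade correct, antisaccade error,
antisaccade correct) and their interaction, plus a participant random
intercept (`lme4`). Fixed effects are tested by likelihood-ratio tests
on nested maximum-likelihood fits. The Kenward–Roger small-sample
procedure was considered and deliberately not used: it is a heavy
correction whose target (denominator degrees of freedom for F-tests)
does not change the direction or approximate magnitude of any effect
here, and the LRT is exact in its own asymptotic frame; estimated
marginal means consequently use asymptotic (z) intervals. A Gamma GLMM
with identity link is available for right-skewed positive responses
(`family = "gamma"`), with a Gaussian fallback when it fails to
converge; the default analyses use the Gaussian LMM, which is robust to
moderate skew and kurtosis at these sample sizes (residual shape
diagnostics are reported with every fit). Amplitude is modelled on the
square-root scale and back-transformed. Pairwise contrasts cover the six
within-group task comparisons and the three within-task group
comparisons, Bonferroni-corrected over that family of nine — the family
reconstructs the comparisons the analysis reports; the original
correction denominator is not documented, so ours is stated explicitly.
The antisaccade error rate, one number per participant, is compared
between groups by the Mann–Whitney U test (midranks; normal
approximation with tie correction at these group sizes).

Calibration is tested, not assumed: under a null group effect the
group-test type-I error lands in [0.025, 0.075] at nominal 0.05 over 200
simulated datasets.

## Classifiers

Participants are summarised by 61 features: {median, Q1, Q3, IQR,
adjusted Fisher–Pearson skewness, adjusted excess kurtosis} × {fit MSE,
damping ratio, latency, amplitude, peak velocity} × {prosaccade,
antisaccade-correct}, plus the antisaccade error rate (directional
responses only in the denominator). Quantiles use linear interpolation
(R type 7); too-few or constant samples yield missing values, never
fabricated zeros. Antisaccade errors contribute only to the error rate.

**Logistic pipeline.** Missing features are imputed with training-fold
medians; each feature is Yeo-Johnson transformed (profile-ML $\lambda$
on $[-5,5]$, estimated on training data only; constant training columns
are dropped) and standardised; forward selection then ranks candidates
by estimated mutual information with the *residual* of the current
ridge-logistic model (first step: MI with the label itself), recording
stratified 5-fold CV ROC-AUC after each addition and stopping at the
first decrease — plus a plateau guard that stops after three additions
that fail to improve the running maximum, which bounds the search on
degenerate data where the CV-AUC trace is flat. The returned model uses
the prefix with maximal CV-AUC. MI uses equal-frequency binning
($\sqrt n$ bins, minimum 4) — a deliberately simple, small-n-robust
estimator; ties in selection break toward the lowest column index. The
ridge penalty is a single fixed value on the per-observation scale
(default 1), making the optimum invariant under dataset duplication;
no hyperparameter search is performed. The residual-MI step matters:
for an XOR-structured label neither parent feature carries marginal MI,
but once one parent enters the model the residual jointly encodes
(parent, label) and the second parent becomes near-deterministically
selectable — while the *linear* model's CV-AUC cannot reward the pair,
which is exactly why the nonlinear forest is the comparison model.

**Random forest.** 400 probability trees (`ranger`), seeded,
single-threaded for reproducibility, Gini impurity importances.

**Feature importance** is ranked over 75 random overlapping subsets of
2/3 of participants: logistic features by the proportion of subset fits
whose forward selection retained them, forest features by mean impurity
decrease (normalised to sum to 1).

## Evaluation

**TLPO-CV.** For every unordered pair of participants the model is
trained on the remaining $n-2$ — all preprocessing nested inside the
trainer, so the pipeline never sees the held-out pair — and the
higher-scored member wins (ties half each). Ranking by total wins gives
an ROC whose area equals the Mann–Whitney statistic of the win scores
($U/(n_+n_-)$, ties half — the tie convention keeps the identity exact).
Per-pair trainer seeds derive deterministically from the master seed and
pair index, so the $n(n-1)/2$ fits (1,275 of 49 participants at
$n=51$) are reproducible and order-independent. A trainer failure flags
the pair (half-win each) rather than aborting. Confidence intervals for
TLPO-CV AUC are an open problem and are not provided.

**5×2cv combined F-test.** Five seeded, class-stratified 50/50 splits;
each half serves once as training set; $p_{ij}$ is the test-fold AUC
difference between the two classifiers, computed from raw probabilities
within each fold. With per-replication variances $s_i^2$, the statistic
$F=\sum_{ij}p_{ij}^2 / (2\sum_i s_i^2)$ is referred to $F(10,5)$. All
differences exactly zero (identical classifiers) is reported as a
degenerate case with $p=1$, not as an F value. One practical caveat the
tests document: with very small cohorts the fold AUCs are so discrete
that the F approximation turns conservative; at the cohort scale this
package targets (~50 participants) its empirical size lies within
[0.02, 0.09] over 500 null runs (tested).

## Problem sizes used in the test suite

The suite validates at reduced scale, chosen as the smallest sizes at
which each property is decisively measurable: noiseless recovery over
the $\sigma\times\omega_0$ design grid; 500 noisy replicates for bias
and SE calibration; 200 null mixed-model simulations; 500 null 5×2
runs at 26+26; 100 XOR selection runs at $n=200$; direction-recovery
over 50 cohorts of 12+13 participants × 40 trials/task; one full-scale
TLPO combinatorics check at $n=51$; and the chance-level check as a
mean over 60 small null cohorts, because a single cohort's null AUC
fluctuates with the Mann–Whitney SD (≈0.17 at $n=12$) and only the
mean is informative at the ±0.05 level. `scripts/acceptance.R` runs the
full default-scale study (51 participants × 200 trials).

## Known limitations

* The generator's variance components are configuration, not estimates:
  no public data exist to fit them against.
* The damping-ratio SE is a linearisation; its factor-of-two calibration
  is an empirical property under the generator, not a guarantee.
* The Gamma-identity GLMM can fail to converge on unbalanced data; the
  documented fallback is the Gaussian LMM.
* QC filters are validated on constructed inputs only (see above).
* Classification metrics on synthetic cohorts reflect the configured
  effect sizes and should not be read as expected performance on any
  real cohort.
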