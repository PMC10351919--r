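---
title: "Modeling credit assignment and neural state representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling credit assignment and neural state representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credassign)
```

## The problem

In an iterated investment game a participant repeatedly chooses how much of
$10 to entrust to one of four stimuli (social partners, or reward-matched
slot machines).  The investment is quadrupled and the stimulus returns a
pre-scheduled fraction between 0 and 50% of that amount, so a return rate
above 0.25 is a net gain.  Because trials with the four stimuli are
randomly interleaved, an outcome arrives temporally adjacent to decisions
about *other* stimuli.  Learning well therefore requires *structural credit
assignment*: attributing each outcome to the stimulus that caused it rather
than smearing it across whatever else is currently in play.  This package
implements a reinforcement-learning model family that measures how
precisely an agent assigns credit, the behavioral regressions that
fingerprint credit spreading, and the representational similarity analyses
(RSA) that relate credit assignment to the fidelity of multivoxel state
representations — all exercised end-to-end on synthetic data.

## The model family

Every model shares a sigmoid policy readout and a Gaussian choice density.
With expected value $V_{t,j}$ for stimulus $j$ on trial $t$,

$$\widehat{inv}_t = \frac{\text{max investment}}{1 + e^{-m\,(V_{t,j} - \text{bias})}},$$

and the probability of each discrete option ($0, 2.50, \dots, 10$) falls
off as a normal density around $\widehat{inv}_t$ with $\sigma = 1$ (fixed),
renormalized over the options on each trial.  The likelihood of a
participant-task is the product of these probabilities over non-missed
trials; fitting minimizes the summed negative log probability.

Learning is error-driven: $\delta_t = r_t - V_{t,j}$ where $r_t$ is the
returned amount.  The variants differ in the update:

* **baseline** — Rescorla–Wagner, $V_{t+1,j} = V_{t,j} + a\,\delta_t$
  (4 free parameters: $a$, prior, $m$, bias).
* **vlr_ca** — valenced learning rates ($a^+$ on $\delta \ge 0$, $a^-$
  otherwise) plus a credit-assignment parameter $CA \in [0,1]$: the engaged
  stimulus receives $a\,\delta\,CA$ and each of the $n-1$ others receives
  $a\,\delta\,(1-CA)/(n-1)$ (6 parameters).
* **vlr_vca** — separate $CA^+$ and $CA^-$ for positive vs negative
  prediction errors (7 parameters).
* **vlr_decay** — full credit to the engaged stimulus while unengaged
  values relax toward the prior at rate $\gamma$ (6 parameters),
  attributing errors to forgetting rather than misattribution.

$CA = 1$ is perfect credit assignment; smaller values spread credit.  Note
that the *equal-share* point — every stimulus receiving the same update, a
true single-state learner — is $CA = 1/n$, not $CA = 0$: at $CA = 0$ the
engaged stimulus gets nothing while the others absorb everything, which
actually *inverts* discrimination.  The package's simulation tests assert
this corrected geometry.

Ties at $\delta = 0$ route to the positive branch (measure-zero under
continuous schedules).  Missed trials contribute no likelihood and trigger
no update; whether values should instead decay through a missed trial is
unknowable from the task description, and freezing is the minimal choice.
Rewards enter $\delta$ as the displayed returned amount, not the net gain;
the prior and bias parameters absorb the scale difference.

## Fitting, comparison, validation

`fit_ca_model()` performs bounded maximum likelihood with L-BFGS-B from 20
(default) uniform-random starts inside the bounds (rates and fractions on
$[0,1]$; $m \in (0.01, 5]$; prior, bias $\in [0, 20]$, the maximum possible
return).  The likelihood trial loop and its central-difference gradient run
in compiled code; an R-language straight-line reference implementation
built from the exported update primitives serves as an oracle in the test
suite.  Choice probabilities are floored at $10^{-12}$ before the log.
Model comparison uses $AIC = 2k + 2\,\mathrm{NLL}$ per participant-task,
with $\Delta AIC$ relative to each participant's best model and a
fewer-parameters tie-break.

The validation suite mirrors the standard protocol: `confusability_study()`
simulates agents per generative model with uniformly sampled parameters,
refits every candidate, and classifies by AIC, reporting forward
(row-normalized) and inverse (column-normalized) confusion matrices;
`parameter_recovery()` reports Spearman correlations between generative and
recovered parameters; `posterior_predictive()` compares per-condition
learning curves of refitted simulations against the fitted data.

**A caution discovered by these tools.**  With parameters drawn uniformly
over wide ranges, a large fraction of the simulated agents produce almost
no behavioral variance: when $|prior - bias| \cdot m$ is large the sigmoid
policy saturates, and an agent predicted to invest $0 earns $0, driving its
values to an absorbing floor.  Such agents carry no parameter information,
so the forward confusion matrix leans heavily toward the baseline model
(the AIC penalty buys nothing on inert behavior) and the pooled recovery
correlations for the CA parameters fall short of what recovery among
behaviorally variable, genuinely spreading agents would suggest.  The
inverse confusion matrix remains diagonal-dominant in every column (the
acceptance script reports both diagonals).  We deliberately did not
restrict the sampler after observing this: the package reports the
protocol's behavior as it is, and the test suite documents the two affected
checks as known-failing under these conditions.

The sampler used for simulation studies draws learning rates from
$[0.05, 1]$, CA and decay fractions from $[0, 1]$, prior and bias from the
investable $[0, 10]$ scale, and $m$ from $[0.2, 3]$ (below $\approx 0.2$
the policy is essentially flat on a $10 value scale).  These ranges were
fixed once, on behavioral-realism grounds, before any acceptance
measurement.

## The synthetic task environment

The generator reproduces the study conditions: 2 tasks × 4 stimuli × 15
trials per stimulus; investments in $2.50 steps; multiplier 4; return rates
in $[0, 0.5]$.  The exact preselected rate lists are not printed in the
source description, so the defaults are constructed to match its
qualitative contract — high: 15 rates evenly spaced on $[0.30, 0.50]$
(always a net gain); low: $[0, 0.20]$ (always a loss); neutral:
$[0.22, 0.28]$ (near break-even); random: $[0, 0.50]$ with mean 0.25 —
identical across participants with seed-randomized ordering, and
overridable through `task_config()`.  Interleaving draws unconstrained
random shuffles and rejects any with a same-stimulus gap above 15 trials,
which yields the right-skewed gap profile (mode 1–5) without further
mechanism.  Returns are rounded to whole cents at generation time.

## Lagged regressions

`build_lagged_design()` regresses each investment on the returns of the
three most recent *relevant* trials (same stimulus) and three most recent
*irrelevant* trials (immediately preceding, any stimulus), each crossed
with task — 13 coefficients including the intercept.  Missed trials are
excluded as responses and skipped as lag sources; rows lacking a full lag
history are dropped listwise.  Whether "irrelevant lag n" should exclude
same-stimulus trials is ambiguous; the default counts the immediately
preceding trials irrespective of identity, with a switch
(`irrelevant_excludes_relevant`).  On simulated cohorts the design behaves
as the theory predicts: perfect-CA agents show a relevant-lag recency
gradient and irrelevant slopes indistinguishable from zero, while CA = 0.2
agents leak the immediately preceding irrelevant outcome into their
choices.  The valence-split variant (four lag-1 models for
relevant/irrelevant × gain/loss) is verified with planted constructions;
we found that cohort-level gain-vs-loss slope contrasts are not a reliable
fingerprint of valenced learning rates in this generative family, because
gain subsets are range-restricted near the investment ceiling.

## Synthetic voxel patterns

`generate_patterns()` builds, per task phase (choice, feedback), trial
patterns
$s_{\text{phase}} \cdot u_{\text{stim}} + v \cdot V_t \cdot w + \varepsilon_t$
with orthonormal random stimulus prototypes $u$, a value direction $w$, and
AR(1) trial noise (coefficient $\rho$) of stationary SD
$\sigma_{\text{noise}}$ — the autocorrelation gives the RSA nuisance
regressor something real to absorb.  Feedback prototypes are
$\kappa\,u^{\text{choice}} + \sqrt{1-\kappa^2}\,u^\perp$, so $\kappa$ *is*
the expected cross-phase prototype correlation.  Because prototypes are
unit-norm, the expected same-stimulus pattern correlation is
$s^2/(s^2 + n_{\text{vox}}\sigma^2)$ — an analytic oracle used in the
tests, and the reason planted-signal simulations over large regions scale
the signal by $\sqrt{n_{\text{vox}}}$ to hold per-voxel amplitude fixed.
What the generator does *not* emulate: HRF convolution, BOLD time series,
motion, physiological noise, spatial smoothness within regions.  Passing
tests therefore certify the analysis pipeline's statistical behavior, not
performance on real fMRI.

## RSA

`neural_rdm()` computes correlation distances ($1 - r$) between trial
patterns with trials nested within stimulus.  Hypothesis matrices: identity
(0 within stimulus, 1 between), expected value ($|V_i - V_j|$ — the
minimal monotone choice, since only "controlling for expected value" is
stated), and autocorrelation ($|i - j|$ in trial indices).
`rdm_regression()` z-scores the strict lower triangles (z-scoring, not
Fisher transformation — distances exceed 1, and standardization makes betas
comparable across participants) and fits OLS.  Searchlights use identity +
autocorrelation; ROI analyses add the value predictor, which is withheld
from searchlights to avoid collinearity with identity.  Noise normalization
divides each voxel by its residual SD (univariate; estimated from the
coefficients when no residuals are available).  The searchlight places a
9 mm sphere at every in-mask voxel (edge spheres truncated at the mask, no
padding) and stores the identity t-statistic; a test asserts center-wise
equality with the standalone ROI pipeline.  The valence-split RSA z-scores
prediction errors within participant and splits at the z-scored sign —
note this re-centers any non-constant series, so both subsets stay
populated by construction (that is the split's stated purpose); subsets
missing a stimulus or with fewer than 2 trials of one are flagged.

Under the null (AR(1) noise patterns, no identity structure) the identity
t-test rejects at close to the nominal 5% rate over 500 replicates, despite
the mild dependence between distance pairs sharing a trial; the identity
beta rises monotonically with planted signal strength.

## Cross-timepoint RSA

Within each stimulus, trials alternate by occurrence parity into odd/even
halves; per half, per phase, voxelwise condition means form a voxel ×
(stimulus × phase) matrix.  The cross-timepoint matrix is
$1 - r(\text{even}_a, \text{odd}_b)$ over all condition pairs (8 × 8 for 4
stimuli).  The two cross-phase quadrants are converted to similarities and
correlated (Pearson) with a same-stimulus indicator, both quadrants
concatenated — so a stronger shared identity code across choice and
feedback yields a larger positive score.  Whether to correlate distances or
similarities is only a sign convention; similarity was fixed so that
"more shared code" is positive.  The score is ≈ 0 at $\kappa = 0$,
approaches 1 at $\kappa = 1$ with low noise, increases monotonically in
$\kappa$, and agrees with a straight-line brute-force recomputation to
$10^{-10}$.

## Group inference

`sign_flip_permutation()` thresholds the one-sample t map at a one-sided
cluster-forming threshold, labels clusters under 26-connectivity (a common
default; 6-connectivity available), and compares observed cluster sizes to
the permutation null of the maximum cluster size under random sign flips
of subject maps, retaining clusters with family-wise $p < 0.05$.  With the
maximum cluster *size* as the statistic, small grids at stringent forming
thresholds make the null distribution highly discrete and the test
conservative; the calibration study therefore uses a 12³ grid, 12 subjects
and a 0.05 forming threshold, where the empirical family-wise rate sits
near the nominal level (and never above it — the permutation test is valid
by construction).  Conjunction masks, spherical ROI extraction around peaks
and the brain–behavior regression (ROI effect ~ CA, optionally + learning
rate, with an ROI indicator for pooled fits) complete the second level.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → fit/compare → lagged regressions → ROI
RSA (+ valence split) → cross-timepoint RSA → group regression from one
JSON-serializable config, with per-stage seeds derived deterministically
from the global seed, stage outputs as CSV, a manifest with the config
hash, and resume semantics (a deleted stage reruns itself and everything
downstream).  The default test-scale configuration uses 8 participants and
flat 40-voxel patterns.  The packaged simulation studies use 25 agents per
model for confusability, 50 for recovery, 100-agent cohorts for the lagged
fingerprints, 500 replicates for RSA calibration, a 20³ grid with a planted
8³ region for searchlight localization, and 150 replicates × 500
permutations for the group calibration — sizes chosen so the whole suite
runs on one CPU in minutes while keeping Monte-Carlo error well below the
asserted margins.

## Known limitations

* The preselected return-rate lists are reconstructions of the described
  reward structure, not the originals.
* Uniform parameter sampling over wide ranges produces behaviorally inert
  agents (see the validation caution above); conclusions about model
  separability at 60 trials depend strongly on the sampled population.
* The synthetic voxel generator abstracts away everything hemodynamic;
  noise normalization consequently estimates residual SDs from the
  coefficients themselves.
* Group inference implements a generic sign-flip cluster permutation, not
  any specific neuroimaging package's variant (no variance smoothing, no
  TFCE, sequential peak/cluster filters only as masks).
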