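---
title: "Methods: simulating and recovering reward and efficacy effects on cognitive control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and recovering reward and efficacy effects on cognitive control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcontrol)
```

## The scientific problem

How much mental effort a person invests in a task depends not only on the
reward at stake but on whether their effort actually determines the outcome
— its *efficacy*. Expected-value-of-control (EVC) theory formalizes this:
a candidate control intensity $u \in [0, 1]$ is worth its expected payoff
minus its effort cost, and the allocated intensity is the maximizer

$$u^\* = \arg\max_u \; \underbrace{R\,[E\,P(u) + (1-E)\,r_0] + v\,P(u)}_{\text{payoff}}
\;-\; \underbrace{c\,u^2}_{\text{cost}},$$

where $R$ is the reward magnitude, $E$ the efficacy (probability that the
outcome is performance-determined), $P(u)$ the probability of a fast and
accurate response, $r_0$ the reward rate on non-contingent trials, $v$ a
small intrinsic value of answering correctly, and $c$ the effort-cost
curvature. `evcontrol` implements this model together with a complete
synthetic experiment — a cued Stroop task crossing reward with efficacy —
and the analysis stack that turns behavior, single-trial EEG, and
pupillometry into hierarchical-regression estimates of the incentive
effects. Because every generator coefficient is recorded, the entire
pipeline is validated end-to-end by parameter recovery, with no external
data.

## Model choices in the EVC stage

The qualitative shape of the payoff and cost curves is fixed by the theory;
the functional forms here are deliberately minimal:

* **Performance function.** $P(u) = \mathrm{logit}^{-1}(\beta_0 + \beta_1 u
  - \gamma k)$ with $k = 0, 1, 2$ for congruent/neutral/incongruent
  targets. A logistic keeps $P$ in $(0,1)$, strictly increasing in control
  and decreasing in interference. Defaults: $\beta_0 = -1$, $\beta_1 = 4$,
  $\gamma = 1$.
* **Cost.** Quadratic, $c\,u^2$ with $c = 0.5$: the simplest strictly
  convex cost giving interior optima across the study's conditions.
* **Payoff mixture.** Efficacy weighs the performance-contingent reward
  path against a non-contingent path paid at rate $r_0$ (default 0.7,
  roughly the criterion success rate the simulated task produces, though it
  is a free parameter — the synthetic experiment replaces it with an
  empirically yoked rate). The intrinsic-accuracy term $v = 0.05$ keeps a
  small amount of control worthwhile even at $E = 0$, reproducing the
  observation that people do not disengage entirely when effort is
  inefficacious. Setting $v = 0$ recovers $u^\* = 0$ at zero efficacy
  exactly.
* **Grid.** 101 points on $[0,1]$, argmax ties broken toward smaller $u$
  (effort is costly, and the rule is deterministic). A 10,001-point
  brute-force oracle in the tests guards the discretization.

Under the defaults the optimal-control surface is nondecreasing in both
reward and efficacy, and the reward effect is larger at high efficacy —
the interaction signature the behavioral data show. These parameter values
are declared fixtures of the simulation, not estimates of any dataset.

## What the synthetic experiment emulates

`design_config()` reproduces the three study layouts: dichotomous
$0.10/$1.00 reward crossed with 0/100% efficacy in four (Study 1) or eight
(Study 2) blocks of 75 trials, and the parametric version (Study 3, 300
trials, rewards $0.10–$0.80 crossed with 25–100% efficacy). Congruency is
assigned in equal thirds within block; reward-by-efficacy cells are
balanced within block up to rounding.

**Yoking.** On trials whose outcome is not performance-determined
(probability $1 - E$), reward is drawn at the rolling mean of the last 10
performance-determined outcomes, with 0.5 as the cold-start before any
history exists (the design is silent on the cold start; 0.5 is the
unbiased default). History pools across blocks within subject. This
equates expected reward across efficacy levels; a 10,000-trial simulation
with trends disabled matches the two rates within 0.02.

**Behavior.** RT is built from a subject intercept, $-g\,u^\*$ speeding
(gain $g = 30$ ms per unit control), 30 ms slowing per congruency step, a
practice trend, per-subject incentive random slopes, and mean-centered
lognormal noise (right-skewed, SD ≈ 57 ms); responses beyond the 1000 ms
recording window (and a 0.2% lapse rate) are missing, and missing
responses are scored as errors. Accuracy is Bernoulli with log-odds linear
in $u^\*$, congruency, and trial. Because the $2 \times 2$ cell means are
exactly spanned by the effect-coded regressors, the planted fixed effects
of both behavioral models are known in closed form (condition-mean
contrasts), which is what makes exact coverage checks possible. For the
parametric design the recorded truth is the least-squares projection of
the cell means onto the linear coding — the estimand of the fitted model
under balance, though the generator is then not exactly linear in the
coded levels (a deliberate property of mapping $u^\*$ through the EVC
model).

**EEG.** The generator works in two layers. The *amplitude layer* draws
single-trial component amplitudes: P3b linear in reward and efficacy (no
interaction); CNV linear in reward, efficacy, *and* their interaction,
plus a leak term $\kappa\,\mathrm{P3b}$ (default 0.16) capturing the
overlap of a positive-going component with the following negative ramp,
plus a baseline leak; ERN/CRN driven by response accuracy and congruency;
FRN driven by reward receipt. The *waveform layer* renders these
amplitudes into 512 Hz, six-channel epochs (cue −200..1500 ms; stimulus,
response, feedback −200..800 ms) as fixed temporal templates times fixed
topographies, normalized so that the quantifier's windowed ROI mean equals
the planted amplitude exactly; baselines are planted as constant offsets;
AR(1) background noise and deterministic >±150 µV artifact injections are
optional. With noise disabled, quantification returns the amplitude layer
to machine precision — the property that licenses running large recovery
experiments on the amplitude layer directly while the waveform path is
validated at small scale.

**Pupil.** Each task event (fixation, cue, target, response, feedback)
contributes an Erlang-gamma impulse response $h(t) = t^{n} e^{-n t /
t_{\max}}$ with $n = 10.1$, $t_{\max} = 1.30$ s, rescaled to unit peak (the
unnormalized form has magnitude $t_{\max}^{n}$, numerically hostile at $n
\approx 10$; rescaling only changes the units of the coefficients). Cue
amplitudes are linear in the incentive coding with a *negative* efficacy
effect (defaults 1.0 low vs 0.7 high efficacy): certainty about control
mattering reduces, not increases, the cue-evoked dilation. Traces are
forward-convolved at 500 Hz with slow sinusoidal drift, white noise, and
blink gaps.

What the generator does **not** emulate: continuous raw EEG with ocular
artifacts (epochs are generated post-cleaning), realistic scalp physics,
luminance effects on the pupil, reinforcement learning of efficacy, or
sequential dependencies beyond the yoking history. Passing recovery tests
therefore demonstrates that the analysis stack is correct and calibrated
for data of this structure — not that it is robust to every pathology of
real recordings.

## Quantification and preprocessing choices

* Baseline interval is half-open $[-200, 0)$ ms; quantification windows
  are closed and sample-inclusive after rounding to the 512 Hz grid —
  deterministic sample selection shared between generator and quantifier.
* "Gradient" in the artifact rule means the absolute difference between
  successive samples; an epoch is rejected when any sample exceeds
  ±150 µV or any step exceeds 50 µV.
* The FRN is scored peak-to-peak at FCz: minimum in 250–350 ms, maximum in
  the 100 ms strictly *before* that minimum's latency; a flat epoch scores
  0 rather than erroring, keeping batch quantification total.
* ERN/CRN uses FCz with a response-locked $[-200, 0)$ baseline (the
  frontocentral site and baseline anchoring are conventions; the windows
  are fixed a priori).
* Pupil preprocessing: blink gaps padded by 200 ms on each side (onset
  −200 ms to offset +200 ms — the more conservative reading of the
  ambiguous convention; the pad is configurable) and linearly
  interpolated; decimation to 20 Hz by non-overlapping block means (an
  implicit anti-alias average); within-subject z-scoring of the whole
  series. Deconvolution regressors are rendered at 500 Hz and decimated by
  the *same* block means, so a noise-free forward simulation inverts to
  machine precision for any non-degenerate schedule; a rank-deficient
  design raises an error naming the collinear regressors.

## The hierarchical models

All models are two-level mixed-effects regressions fit with `lme4`
(Gaussian responses by maximum likelihood, accuracy by binomial-logit
Laplace approximation). Regressors follow the conventions of the analysis
they reproduce: ±0.5 effect coding for dichotomous reward/efficacy
(standardized levels for the parametric design), sliding-difference
congruency contrasts estimating (neutral − congruent) and (incongruent −
neutral), within-subject mean-centering of trial number and baselines, and
within-subject z-scoring of ERP amplitudes used as predictors. The CNV
model includes the same trial's P3b as a covariate (absorbing component
overlap) and its own baseline; the P3b model includes its baseline.

Random structures are declared per model (incentive slopes for RT,
intercepts elsewhere, independent by construction) and pruned
data-dependently: if the random-effects covariance is singular — smallest
singular value below $10^{-6}$ relative to the largest; for the diagonal
structure used here the variances are the singular values — the slope with
the smallest variance share is dropped and the model refit, down to an
intercept. The pruning path is recorded and deterministic. Fixed-effect
p-values use the large-sample normal approximation; at the ~20,000
observations of a study-scale run the difference from Satterthwaite-type
corrections is negligible.

**ERP slope comparison.** Whether the CNV predicts accurate RT more
strongly than the P3b is tested by a likelihood-ratio test between the
full model and one constraining the two slopes to equal magnitude with
opposite sign (the CNV is negative-going, so its behavioral slope is
sign-flipped before equating): the constrained model replaces the two
regressors with their difference, and the statistic is $\chi^2_1$. Both
models are fit by ML; nesting guarantees the constrained likelihood never
exceeds the full one.

**Coupling modes and exactness.** Cue-stage neural variability feeds into
RT in one of two modes. The default (`residual`) couples only the
incentive-orthogonal residual components of P3b and CNV, leaving the
behavioral models exactly specified (their planted coefficients are the
condition-mean contrasts); the ERP slopes in the ERP-to-behavior models
are then mildly attenuated estimands and are scored for sign only. The
`full` mode couples the within-subject z-scored amplitudes themselves,
making the ERP-to-behavior model exactly specified instead — this is the
mode the slope-comparison size/power experiments use. The pupil model in
recovery runs uses the coefficient layer (per-subject, per-condition cue
magnitudes with measurement noise) rather than re-deconvolving 44
continuous sessions; the trace-level forward-then-inverse path is
validated separately and exactly, so repeating it inside every replicate
would only add runtime. Pupil-coefficient models are fit on raw
coefficients with a subject random intercept (z-scored copies are emitted
for inspection); fitting on within-subject z-scores would divide each
subject by a noisy scale and break the correspondence between planted and
estimated values.

## Recovery experiments and their scale

`run_recovery()` repeats simulate-then-fit over seeded replicates (the
master seed spawns per-replicate streams through a fixed affine map, so
any replicate can be regenerated in isolation) and scores, per planted
coefficient: sign recovery, 95% CI coverage (for exactly specified
estimands), and rejection at $\alpha = 0.05$. The shipped validation runs
20 replicates at the Study-2 scale — 44 subjects by 600 trials — for the
default-effect and null configurations, and 20 + 20 replicates for the
size and power of the slope-comparison test; unit tests use miniature
studies (a few subjects, tens of trials). These sizes give binomial bands
tight enough to detect miscalibration while keeping a full validation run
in the tens of minutes on a single core.

## Known limitations

* The parametric (Study 3) design's behavioral truth is a projection, not
  an exact coefficient; coverage claims are made only for the dichotomous
  designs.
* Accuracy inherits a tiny bias from scoring missing responses as errors
  (rate 0.2%); it is far below the CI resolution of the shipped runs.
* Wald CIs with 21–44 clusters are mildly anticonservative; the coverage
  criterion (≥90% aggregate over replicates) accounts for this.
* The waveform layer's fixed templates make quantification exact by
  construction; it validates window/ROI bookkeeping, not robustness to
  latency jitter or topographic variability.
* ERN/FRN epochs carry no baseline covariates in the emitted amplitude
  table (their baselines are planted at zero); the outcome models
  therefore omit baseline regressors.
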