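---
title: "Do observers know their own visual sensitivity? A conjoint-measurement simulation and test battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Do observers know their own visual sensitivity? A conjoint-measurement simulation and test battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjointvision)
```

## The scientific question

Visual sensitivity falls off steeply with retinal eccentricity, and the
falloff depends on stimulus contrast. Models of efficient visual search
assume the visual system has access to this map of its own reliability —
that an observer planning where to look can compare, say, a low-contrast
target 2° from fixation against a high-contrast target 10° out and know
which one they would classify more reliably. `conjointvision` implements a
complete in-silico version of an experimental paradigm that tests this
assumption with the tools of conjoint measurement, replacing the human
subject with a configurable synthetic observer so that every analysis can
be validated against a known ground truth.

The paradigm has two phases:

1. **Calibration.** A top/bottom 2AFC discrimination is measured at every
   combination of 3 contrasts (LOW < MED < HIGH) and 18 eccentricities
   evenly spaced from 2° to 12.2° (spacing 0.6°), 5 blocks × 6 repetitions
   per cell: 3 × 540 = 1620 trials. This yields the observer's *true*
   sensitivity map.
2. **Decision.** The observer repeatedly chooses which of two
   eccentricity–contrast pairs they would rather attempt later for a $5
   reward per correct classification. 12 one-up one-down staircases (70
   trials each, 840 total) locate eccentricity–contrast pairs the observer
   *judges* equally discriminable; 90 equi-contrast and 90
   equi-eccentricity trials probe dominance. All 1020 trials are randomly
   interleaved.

Three properties of the choices are then tested. **Equivalence**: do
subjectively indifferent pairs have equal true probability correct?
**Transitivity**: are the subjective equivalences self-consistent around
the contrast cycle? **Dominance**: is nearer preferred at equal contrast,
and higher contrast at equal eccentricity? Finally, every suboptimal
choice is priced in forgone expected reward.

## The psychometric model

Probability correct as a function of eccentricity $e$ is modelled as a
decreasing Quick–Weibull function with 2AFC chance floor,

$$p(e) = 0.5 + 0.5 \cdot 2^{-(e/\tau)^\beta},$$

where $\tau$ (degrees) is the position parameter — the eccentricity of
75% correct — and $\beta$ governs steepness. Performance is perfect at
the fovea and decays to chance. The form has two convenient exact
properties used throughout:

* closed-form inverse, $e = \tau\,(-\log_2(2p-1))^{1/\beta}$;
* *log-linear equivalence transforms*: if two curves
  $(\tau_1,\beta_1)$, $(\tau_2,\beta_2)$ describe two contrasts, the
  eccentricity $e_2$ exactly as discriminable as $e_1$ satisfies
  $\log e_2 = a + b \log e_1$ with $b = \beta_1/\beta_2$ and
  $a = \log\tau_2 - b\log\tau_1$.

No lapse or guessing parameters are fitted: the analysis estimates
exactly two parameters per contrast, by maximum likelihood on the
Bernoulli trials (bounded quasi-Newton on log-parameters, five fixed
starts over $\tau \in [1,30]$, $\beta \in [0.5,10]$, objective tolerance
$10^{-8}$, ties broken toward smaller $\tau$). Degenerate data — all
correct, all incorrect, or perfectly separable — push a parameter to its
box bound and are flagged `converged = FALSE` with a warning rather than
silently returned.

## The synthetic observer

An `observer_model` couples a **true map** (one curve per contrast, used
for calibration responses) with a **subjective map** and a stochastic
choice rule (used for decisions). The true map must satisfy dominance on
the stimulus grid — probability correct strictly increasing in contrast
at fixed eccentricity, strictly decreasing in eccentricity — and this is
validated at construction; the subjective map is unconstrained, because
distorted beliefs are precisely what the battery is meant to detect.

Three choice rules are provided:

* `subjective_prob` — P(choose A) $=$ logit$^{-1}(\lambda(\hat p_A -
  \hat p_B))$ on the subjective probabilities, with inverse temperature
  $\lambda$ (`noise`; $\infty$ = deterministic, 0 = coin flip). This is
  the simplest monotone stochastic-choice model and produces staircase
  variability resembling empirical runs.
* `lexicographic` — a lexicographic semiorder: eccentricity decides
  whenever the eccentricity difference exceeds a threshold (default 2°);
  otherwise contrast decides. Generically intransitive.
* `transform` — the observer carries explicit per-mapping log-linear
  equivalence transforms. This family exists because no single subjective
  curve triple can violate transitivity: composing the three analytic
  transforms around the LOW→MED→HIGH→LOW cycle always yields slope
  $\frac{\beta_L}{\beta_M}\frac{\beta_M}{\beta_H}\frac{\beta_H}{\beta_L}=1$
  and intercept 0. Intransitivity therefore requires pairwise-specific
  mappings; the `corkscrew` preset gives each of the three transforms
  slope $2^{1/3}$ (composite slope 2), each anchored at the geometric
  middle of its staircase operating range so trajectories stay inside the
  stimulus range.

The default true map is $\tau = (5.0, 6.0, 7.2)$ at common $\beta = 2$.
These values were chosen on protocol-feasibility grounds: every fixed
target (the 0.6–0.9 probability points of each curve) *and* every
veridical match point of the 12 staircases must lie inside the
presentable range $[2, 12.2]$ with at least ~0.8° of margin, so that a
staircase can oscillate around its equilibrium without pinning against a
boundary. Sensitivity spans roughly 0.55–0.98 over the grid, comparable
to empirical retinal scaling curves for mid-contrast configural targets.
The default choice noise $\lambda = 20$ makes a one-step (0.6°)
eccentricity handicap near indifference shift choice odds to roughly
3:1 — enough stochasticity for staircases to mix, not so much that they
random-walk.

The nominal Weber contrasts attached to the LOW/MED/HIGH labels (0.11,
0.20, 0.36) are display metadata only; no computation uses them.

## Staircases and PSE estimation

Each staircase fixes one pair (eccentricity at the 0.6, 0.7, 0.8 or 0.9
probability point of the fitted *from*-contrast curve) and adapts the
variable pair's eccentricity: chosen ⇒ one step (0.6°, one grid spacing)
outward (harder), rejected ⇒ one step inward (easier), clipped to
$[2, 12.2]$. The one-up one-down rule converges on the 50% preference
point. The PSE estimator is the mean of the reversal eccentricities
after discarding the first two reversals (the approach phase); at least
four reversals are required. A tail-mean alternative (mean of the last
35 trial eccentricities) is available via `method = "tail"` for
sensitivity analysis, and the pipeline falls back to it (with a warning)
for staircases that pinned at a boundary and never reversed — a
situation a deterministic synthetic observer can produce but a noisy one
essentially cannot. The variable target starts at the fixed target's
eccentricity — a symmetric, unbiased start. A boundary clip never counts
as a reversal: direction is defined by the choice, not the realised move.

When fitted curves place a requested probability point outside the
presentable range, the design constructors raise an error by default;
the pipeline instead truncates to the range limit with a warning
(`boundary = "clip"`), as an experimenter constrained by the display
would.

## The test battery

**Equivalence.** For each of the 12 subjective-indifference pairs the
signed difference $\Delta p$ (true probability of the lower-contrast
member minus the higher-contrast member, from the fitted calibration
curves) is computed, with percentile bootstrap CIs at per-pair size
$.05/12$ (Bonferroni). A one-sample two-tailed t-test on the 12 signed
differences — treated as independent — tests for systematic over- or
underestimation of the contrast effect. Eccentricity errors (PSE minus
the truly equivalent eccentricity) and their median absolute value are
also reported.

**Transitivity.** Per mapping, $\log \mathrm{PSE}$ is regressed on
$\log$ fixed eccentricity by OLS over the four staircases (natural
logs); the three fitted transforms are composed around the cycle into a
composite intercept $a$ and slope deviation $b$ (composite slope − 1),
both exactly 0 under transitivity. 95% bootstrap CIs are
Bonferroni-corrected for the two statistics; the observer is flagged
intransitive if either interval excludes 0. The transforms are fitted
to the four PSE points, not to trial-level choices: the PSEs are the
quantities the log-linear relation connects.

**Dominance.** Errors are choices of the farther target at equal
contrast, or the lower contrast at equal eccentricity. Error rates get
95% equal-tailed intervals from a Beta(errors + 1, non-errors + 1)
posterior (uniform prior).

**Expected gain.** Each decision trial's loss is
$(\max(p_A,p_B)-p_{\text{chosen}})\times \$5$; the loss fraction
normalises by the ideal expected gain. It is zero exactly when every
choice is truly optimal (up to ties).

## Bootstrap design

Two resampling units feed the confidence intervals:

* *Calibration*: within every contrast × eccentricity cell the binomial
  count is redrawn (equivalent to resampling that cell's trials with
  replacement) and the curves are refitted from a warm start. Refitting
  can be disabled (`refit = FALSE`) to hold curves fixed.
* *Staircases*: a model-based "re-walk". The preference function
  P(choose variable | eccentricity) is fitted once per staircase by
  logistic regression; B fresh 70-trial walks are regenerated from it
  (same start, step and clipping) and the reversal-mean PSE re-estimated
  on each.

The re-walk deserves justification, because the more obvious
nonparametric scheme — resampling the observed reversal eccentricities
within a staircase — is badly anticonservative here: reversals within a
run are positively correlated through the walk's position, so their
within-run spread understates the across-run variability of the
reversal mean by roughly a factor of two, which in null simulations
inflated the intransitivity flag rate to ~35% at a nominal ~5%. The
re-walk reproduces the estimator's sampling distribution *including*
the serial dependence, and brings the null flag rate to the nominal
level (~5% over 100 simulated veridical observers). Percentile
intervals are used throughout; basic (reversed-percentile) intervals
were evaluated and rejected empirically — the re-walk bootstrap is
essentially unbiased about the point estimate, so reversing quantiles
only flips skew and worsened null calibration.

## What the simulator does and does not emulate

Emulated: the full trial economy (counts, interleaving, randomisation
within blocks), Bernoulli calibration responses from the true map,
staircase dynamics driven by any of the three choice rules, and the
reward structure. Not emulated: stimulus rendering, fixation control,
practice trials, learning or fatigue across the session, reaction
times, and any trial-to-trial dependence in the observer (responses are
conditionally independent given the maps). Passing tests therefore
validate the *analysis machinery* and the statistical calibration of the
battery under a plausible observer family — they do not certify the
battery's behaviour under, say, non-stationary human observers.

A note on scale: the headline numbers reported for human cohorts by
studies using this paradigm (median absolute eccentricity errors of
several degrees, composite statistics near $a \approx -0.6$,
$b \approx 1$, dominance error medians around 8–11%, reward losses of
10–18%) reflect particular human subjective distortions that are
unknown; the presets here reproduce the *qualitative* signatures
(same-signed equivalence failures, outward-spiralling intransitivity
with $a < 0, b > 0$, small dominance error rates) rather than those
quantities.

## Numerical choices and problem sizes

* Optimisation: L-BFGS-B on $(\log\tau, \log\beta)$, 5 fixed starts,
  objective tolerance $10^{-8}$; bootstrap refits warm-start from the
  point estimate with a single start.
* Degenerate inputs: all-correct/incorrect calibration ⇒ pinned
  parameters and `converged = FALSE`; single visited eccentricity or
  separable choices in a staircase ⇒ flat preference fit; fewer than 4
  reversals ⇒ error (module surface) or tail-mean fallback (pipeline).
* Ties in deterministic choice resolve to probability one half.
* Seeds: every stage consumes a stream derived from (master seed, stage
  label) via a 32-bit hash, so whole experiments are pure functions of
  their configuration.
* The shipped test-suite simulations use 100 observers for parameter
  recovery, 100 veridical seeds for null calibration and 50 corkscrew
  seeds for power (B = 1000), and the pipeline's fast mode (B = 500)
  for end-to-end runs; the full protocol default is B = 10000.

## Known limitations

* The re-walk bootstrap conditions on the fitted preference function;
  with very flat preference (noise near 0) the logistic slope is poorly
  determined and intervals become conservative.
* PSEs for mappings whose equilibrium sits within ~1 step of a range
  boundary are biased inward by clipping; the default observer family
  avoids this regime by construction, but user-supplied maps need not.
* The equivalence t-test treats the 12 pairs as independent although
  they share the fitted calibration curves; the bootstrap CIs do not
  make this assumption.
* Cohort medians are computed only over observers whose three fits all
  converged.
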