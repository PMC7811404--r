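---
title: "Models and methods behind pulsecue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pulsecue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsecue)
```

## The scientific setting

`pulsecue` analyzes how the amplitudes of visual-cortical responses to
discrete, pulsatile sensory cues are modulated while a subject accumulates
evidence toward a navigation decision. The experimental paradigm it targets
is the head-fixed virtual T-maze ("accumulating towers") task: as the
subject runs down a corridor, tower-shaped cues appear transiently along
the right and left walls, and at the end of the maze the subject turns to
the side that had more cues. Calcium imaging at 15 Hz provides per-neuron
fluorescence traces (dF/F); a minority of neurons respond to each cue with
a stereotyped impulse response whose *amplitude* varies from cue to cue.
The package provides the full analysis chain for these cue-locked cells -
deconvolution of per-cue amplitudes, statistical identification of cue
locking, a family of amplitude-modulation models, population decoding of
task variables, and behavioral metrics - together with a synthetic-data
generator that emulates the task and the neural forward model, so that
every stage can be validated by parameter recovery on data with known
ground truth.

## The synthetic task generator

One simulated trial consists of a 30 cm pre-cue corridor, a 200 cm cue
region (250 cm variant available), and a 100 cm delay, ending at the T-arm.
Per-trial cue counts are Poisson with mean 7.7 on the rewarded (majority)
wall and 2.3 on the other wall; positions are uniform over the cue region
conditional on consecutive same-side cues being at least 12 cm apart. The
constrained-uniform sample is drawn by the order-statistics gap
construction (sort n uniforms on an interval shortened by (n-1) times the
refractory gap, then add back multiples of the gap), which is exactly the
distribution that rejection sampling at fixed counts would produce, at
O(n) cost. Counts whose spacing cannot fit in the region at all (about
6e-4 probability per side) are redrawn, a truncation that changes the count
means by less than 0.01.

Counts are drawn *unconditionally*: in roughly 5% of trials the realized
minority count ties or exceeds the majority count. These trials are kept
(the rewarded side remains the configured majority side), which keeps the
empirical count means at their nominal values and simply caps the
achievable accuracy of any evidence-using agent - a property the real task
shares in spirit, since near-tied trials are at chance.

Running speed is a mean-reverting positive process (0.5 s relaxation time)
around a configurable mean with a configurable stationary SD; position
integrates speed at the 85 Hz display rate. The view angle is smoothed
noise during the corridor plus a ramp toward the chosen arm over the second
half of the delay; in theta-controlled sessions it is exactly zero until
midway through the delay. Only summary statistics of the kinematics (speed
scale, view-angle spread) matter downstream, so no attempt is made to model
real mouse gait or deceleration profiles.

A cue becomes visible when the subject approaches within 10 cm of its maze
position (so onset distances fall in an interval of width one display
frame below 10 cm) and disappears 200 ms later. Its visual angle is the
signed angle from the instantaneous heading to the cue center, located 4 cm
off-axis: at zero view angle, `atan2(4, 10)` = +21.8 degrees for right
cues, about +22 degrees, mirrored for left cues.

The behavioral agent is a lapse-mixed logistic reader of the per-third
evidence differences, `P(right) = lapse + (1 - 2 lapse) * plogis(sum(w_i
Delta_i) + bias)`, with a default decreasing weight profile (primacy).
Rewarded sides are sampled with an error-rate de-biasing rule: over a
40-trial window the per-side error rates (Laplace-smoothed) set the
sampling probability, so the side the agent neglects is offered more
often. Any rule with this sign property would do; the specific smoothing
is not critical.

What the generator does *not* emulate: reward consumption and licking,
inter-trial neural activity, slow non-stationarities (fatigue, adaptation
drift over the session), photon shot noise, or neuropil contamination.
Passing recovery tests on this generator therefore demonstrates
correctness of the estimators under the model's assumptions, not
robustness to every artifact of real imaging data.

## The neural forward model

Each cue-locked neuron responds to its preferred-side cues with a common
impulse response scaled by a per-cue amplitude:

dF/F(t) = sum_i A_i g(t - t_i - tau_lag - dtau_i) + noise,

where g is a two-sided Gaussian (rise SD sigma_rise before the peak, fall
SD sigma_fall after, continuous at zero) convolved with the calcium
indicator kernel h(t) = (1 - exp(-t/0.035)) exp(-t/0.300) / h0, normalized
so its peak is exactly 1 (the analytic argmax is tau_on *
log((tau_on+tau_off)/tau_on), about 79 ms for the GCaMP6f-like defaults).
The two-sided Gaussian carries the fixed prefactor `2 / (sqrt(pi) *
(sigma_rise + sigma_fall))`; since amplitudes multiply the kernel, any
fixed convention is self-consistent, and this one is used throughout
(generator and fitter alike).

Traces are rendered on an internal fine grid of 64 samples per imaging
frame (about 1 ms), box-averaged to the 15 Hz frame clock, with i.i.d.
Gaussian noise added per frame. Per-cue onset jitters are Gaussian with a
50 ms SD by default, matching the scale of timing variability the fitting
stage is designed to absorb. Amplitudes are Gamma with shape k (default 4)
and mean given by the neuron's modulation model; mean amplitudes are of
order 1, an arbitrary but convenient dF/F calibration. The default noise
SD is 20% of the cell's single-cue response peak.

Ground-truth modulation types mirror the four model families described
below. Null-type cells carry a saturating speed-tuning *spline* drawn in
the null model's own family (control values `1 + b * (-0.35, -0.15, 0,
0.15, 0.22)` at the speed quantiles, `b ~ U(0.7, 1.4)`): a merely linear
speed factor would sit in the intersection of the model classes, where the
adaptation and cue-count branches can represent the same truth with fewer
parameters and AICc parsimony would (correctly, but uninformatively)
reclassify such cells. SSA cells default to xi = 0.5, lambda = 0.8 s;
choice cells get opposing contra/ipsi gains and slopes with randomized
sign (so populations contain both positively and negatively
choice-modulated cells); count cells a linear dependence on the signed
preferred-side count difference.

Distractor cells - slow within-trial ramps or place-field-like bumps vs.
position, plus noise - are generated alongside cue-locked cells so the
cue-locking test has true negatives.

## Impulse-response fitting

`fit_impulse_model()` maximizes the Gaussian likelihood (equivalently,
minimizes squared residual) over the kernel parameters, non-negative
per-cue amplitudes, and L2-penalized per-cue jitters. The engine exploits
the session's structure: fitting frames are restricted to per-trial
windows (trial span plus a 2 s tail), and because inter-trial gaps exceed
the kernel support, the amplitude subproblem decomposes into small
per-trial non-negative least-squares problems (solved by Lawson-Hanson
NNLS). The schedule is:

1. *Kernel search* (up to 8 sweeps): per-trial NNLS for amplitudes
   alternating with bounded 1-D refinements of tau_lag (0-0.4 s),
   sigma_rise (0.02-0.35 s), sigma_fall (0.03-0.8 s).
2. *Jitter rounds* (3 by default): per-cue shift search on a 25 ms grid in
   [-150, +150] ms with parabolic refinement, amplitude held fixed (a
   profiled amplitude absorbs timing mismatch and measurably degrades
   recovery), penalized by `(sigma^2 / 0.05^2) * dtau^2` where sigma^2 is
   the larger of the current residual variance and a high-frequency noise
   estimate - so the 50 ms jitter prior stays active even on noiseless
   traces; then NNLS and kernel touch-ups. Iteration stops when the
   relative residual change falls below 1e-6 or the kernel stops moving.

The primary cue side is the one with the better single-side AICc under a
common quick protocol; the winner is then fitted in full. A secondary
(opposite-side) response is fitted on the primary residual with a reduced
refinement protocol and retained only if the two-side model's relative
AICc likelihood satisfies `exp((AICc_two - AICc_one)/2) <= 0.05`, i.e. the
richer model is at least 20 times more likely. (The literal inequality
direction from the source description, which would accept the richer model
whenever it is merely better, is available as `secondary_rule =
"literal"`.)

AICc is `2 npar + nF log(RSS/nF) + 2 npar (npar+1)/(nF - npar - 1)` with
npar = 3 kernel parameters + m amplitudes + m jitters (plus the secondary
terms when present). Whether jitters "count" is a convention; what matters
is that real and shuffled fits use the same count so the significance
score is unaffected.

**Cue-locking significance.** For each of (by default) 100 shuffles, cue
onset times are redrawn uniformly within each trial's cue-region traversal
interval (counts preserved per trial) and the model re-scored with the
kernel fixed at the fitted shape, amplitudes re-estimated by NNLS, and one
round of jitter updates - the same amplitude-and-jitter treatment the real
fit's final state received, so the comparison is not biased by differential
optimization effort. The significance is `z = (median(null AICc) -
AICc_fit) / quantile_sd(null AICc)`; larger z means stronger locking, and a
cell is called cue-locked when z exceeds 3 (strict inequality; ties break
conservatively). Kernel parameters are not re-optimized per shuffle:
the kernel's shape is timing-insensitive to first order, and re-fitting it
a hundred times per cell would multiply the cost by two orders of
magnitude for a negligible change in the null distribution.

**Known identifiability limit.** With 15 Hz sampling, cues as close as
0.2 s, a response kernel that outlives the inter-cue interval, and free
per-cue jitters, closely spaced cues can nearly trade amplitude for
timing. An oracle analysis (NNLS with the *true* kernel and *true*
jitters) puts the per-cell amplitude-recovery correlation at 0.84-0.96
(mean about 0.90) under the default noise level (20% of peak), and the
cold-start fitter typically reaches 0.75-0.91 per cell; pooled across a
heterogeneous population the correlation exceeds 0.9. Per-cue amplitudes
at this signal-to-noise should therefore be treated as noisy estimates
whose population-level statistics are reliable, not as exact per-event
measurements.

The residual-slope diagnostic averages per-trial residuals in 10 equal
position bins of the cue region and reports the linear trend across bins,
scaled so that +/-1 corresponds to a start-to-end residual change equal to
the cell's mean model-predicted signal - a cheap check for unmodeled slow
components. Cells enter analysis only if they show at least 0.1
fluorescence transients per trial, a transient being a contiguous epoch
above 3 noise SDs for at least 2 frames (the threshold definition is a
package convention; the inclusion rate is the standard one).

## Amplitude-modulation models

Per-cue amplitudes A_i are modeled as Gamma(shape k, mean mu_i) with
mu_i = rho(phi_i) x (speed term) x (model-specific term):

* **null**: rho(phi) x s_v(v), with s_v a natural cubic spline with control
  points at the 0/25/50/75/100% quantiles of the cue-onset speed
  distribution.
* **SSA** (stimulus-specific adaptation/facilitation): rho x (1 + phi_v *
  v_tilde) x h, with the recursion `h(mu_prev, dt) = 1 + (xi * mu_prev - 1)
  exp(-dt/lambda)`; xi < 1 is depression, xi > 1 facilitation, recovering
  toward 1 with timescale lambda. The printed convention is implemented
  literally: h takes the full previous mean and the session's first cue has
  mu = 1. A variant that tracks only a dimensionless adaptation state (so
  xi = 1 is exactly "no adaptation" for any base means) is available as
  `variant = "state"` in `ssa_mean_sequence()`.
* **choice**: rho x (1 + phi_C * v_tilde) x s_y^C(y), with one natural
  cubic spline per upcoming choice C (control points at 0, L/2, L of the
  cue region) and per-choice Gamma shapes k_C.
* **cue-counts**: rho x (1 + phi_v * v_tilde) x s_D(counts), where counts
  are the cumulative preferred-side, opposite-side, or signed difference
  counts (spline control points {0,3,8} or {-4,0,4}), the definition chosen
  per cell by AICc.

The angular receptive field rho is either a skew-Gaussian,
`exp(-(phi-phi0)^2 / (2 (sigma + zeta (phi-phi0))^2)) - exp(-1/zeta^2)`,
clipped to 0 where the width term crosses zero (the printed form is
undefined there), or a sigmoid `1 - rho0/2 + rho0 (1 +
exp(-(phi-phi0)/zeta))^(-nu)` with free real exponent nu (the sign
ambiguity in the printed exponent is absorbed by nu's sign). The form is
chosen per cell and branch by AICc. Speeds are standardized as `(v - Q50) /
(Q90 - Q10)`; only cues at speeds within 25% of the median speed enter the
fit (read as v in [0.75, 1.25] x median), and at least 30 amplitudes are
required.

The likelihood is the *exact* Gamma(shape k, scale mu/k) density; the
printed form of the negative log-likelihood omits k-dependent constants
that would bias the shape estimate, so the exact density is used. The
shape k is profiled out analytically (its stationarity condition `log k -
digamma(k) = c` is solved by the standard initial approximation plus
Newton steps), per choice for the choice branch. Zero amplitudes - exact
zeros produced by the NNLS non-negativity constraint - are replaced before
Gamma fitting by draws from the amplitude distribution obtained by fitting
the same cue timings to a simulated noise-only trace at the cell's
estimated noise SD, giving a noise-floor distribution whose scale is
proportional to sigma_F.

Each branch is optimized by 8 candidate starts (one heuristic, the rest
dispersed) ranked by objective value, with the best polished by bounded
quasi-Newton (`nlminb`, relative tolerance 1e-8); spline values are
parameterized on the log scale so means stay positive. The polish count is
exposed via `options(pulsecue.amp_polish = )`. This search found the
global optimum in every spot-check against wider polishing, at a quarter
of the cost.

**Selection and averaging.** The best model is the alternative branch with
the lowest AICc unless the null's relative likelihood against it,
`exp((AICc_best - AICc_null)/2)`, is at least 0.05 - ambiguity defaults to
the null (the boundary sits at an AICc gap of 5.99). The ensemble
predictor is the Akaike-weight average, `w_m` proportional to
`exp(-(AICc_m - min AICc)/2)`.

**Choice-modulation strength.** The profile `delta_A(y)` is the difference
between the ensemble's predicted amplitudes on preferred-choice
(cue-side) versus anti-preferred-choice trials, evaluated along the cue
region at the fixed visual angle of zero view angle (+/-22 degrees), the
median speed, and zero accumulated evidence, divided by the harmonic-mean
normalizer `<A> = (1/(2L) sum_C integral dy / max(A_C(y), sigma_F))^(-1)`
(the printed formula shows `<A>` as a trailing factor while defining it as
an inverse mean; "normalized to the average amplitude" implies division,
which also makes delta_A invariant to global amplitude rescaling). The
integral uses a 101-point trapezoid rule. For the SSA branch, whose mean
is defined by a recursion over cue history, ensemble predictions on
reference contexts use the recursion's stationary state at the session's
median inter-cue interval (capped when the facilitation fixed point would
diverge).

## Population decoding

The neural state for a cue presentation is the vector of amplitudes of
cells that are cue-locked, prefer the contralateral side, and have no
secondary responses. Decoders are fitted separately for cues in each third
of the cue region. Six task variables are decoded: view angle, speed,
running evidence (the tally including the current cue), upcoming choice,
previous choice, and previous reward. Binary variables use a linear
support-vector classifier and continuous ones linear epsilon-regression
(the performance metric, Pearson correlation between held-out predictions
and labels, requires continuous-capable decoding); regularization is fixed
at cost 1 and features are z-scored with training-fold statistics.
Cross-validation is 3-fold with folds assigned at the *trial* level so
cues from one trial never straddle the train/test split.

Significance uses 100 permutation pseudo-experiments in which whole trial
blocks of state rows are re-assigned against the fixed labels - preserving
inter-neuron correlations and within-trial structure while breaking the
state-behavior relationship - with the add-one convention `p = (1 + #{null
r >= r_obs}) / (n_null + 1)` so p is never zero. Benjamini-Hochberg
correction across a session's (variable, third) tests uses the standard
largest-rank step-up rule; the literal "first rank" reading of the source
description is available behind a flag and is never more permissive.

Uncorrelated task-variable modes are the orthonormal-column matrix Y
closest in Frobenius norm to the column-standardized variable matrix X,
obtained from the polar decomposition X = YH via the SVD (Y = UV'). X is
centered and column-normalized first so "uncorrelated" means zero Pearson
correlation rather than raw orthogonality. The session-level
meta-regression of decoding accuracy on area/layer indicators and
cue-locked cell count uses linear support-vector regression with
confidence intervals from bootstrapping sessions.

## Behavioral metrics

Psychometric curves are the fraction of rightward choices in 11
integer-centered evidence bins spanning the observed range symmetrically,
with Jeffreys binomial intervals, fitted by weighted Levenberg-Marquardt
least squares to `pR = p0 + B / (1 + exp(-(Delta - Delta0)/lambda))`
(multiple lambda starts; the direct residual formulation tolerates
step-like data where a model-matrix setup would reject a singular initial
Jacobian). For an equal-weight lapse-mixed logistic agent this family is
exact, with p0 = lapse, B = 1 - 2 lapse, Delta0 = 0, lambda = 1/w - the
identity used in recovery tests. The evidence-weight analysis is a
logistic regression of choice on the per-third evidence differences with
1000-bootstrap confidence intervals; on separation it falls back to a
lightly ridge-penalized fit (strength 1e-3) and flags it. Session
inclusion uses the maximum fraction correct over a 100-trial sliding
window, at least 0.65 (inclusive). Spread statistics follow the
quantile convention: SD = (Q84 - Q16)/2 (0.9945 x SD for Gaussian data),
SEM = that over sqrt(n), and binomial intervals are equal-tailed Jeffreys.

## Validation scale and reproducibility

The shipped test suite validates every stage by parameter recovery at
these problem sizes, chosen to give stable statistics at interactive
runtimes: generator statistics on 10,000 trials; impulse-fit recovery on a
40-trial session (about 200 preferred-side cues per cell) with 80
cue-locked cells plus 20 distractors and 24-shuffle significance;
model-selection confusion on a 60-trial session (about 300 cues) with 40
cells per modulation family at k = 4; decoding calibration on 150 null
populations and 20 planted-signal populations with 60-permutation nulls;
and behavioral recovery on 5,000-trial sessions with 300-1000 bootstrap
resamples. Every stochastic stage draws from an explicit integer seed
through a seed-scoped RNG helper, so all results - including the full
pipeline driver `run_pipeline()` - are bitwise reproducible from their
seeds.

## Known limitations

* Per-cue amplitude estimates approach an identifiability ceiling when
  same-side cues are closer than the kernel support (see above); population
  statistics are reliable, single events less so.
* The amplitude-model family is the printed four-branch family; no
  interaction models, hierarchical pooling across cells, or time-varying
  kernels.
* The synthetic kinematics and de-biasing rule are simple surrogates;
  only their summary statistics are meaningful.
* The decoder is linear by design; nonlinear decodabilty is out of scope.
* Spike inference is out of scope: the pipeline starts and ends with
  dF/F-scale quantities.
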