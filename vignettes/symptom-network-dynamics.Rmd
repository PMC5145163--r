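---
title: "Symptom-network dynamics: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom-network dynamics: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The dynamic model

`symptomnet` treats a disorder as a network of J binary symptoms. The state
of symptom i at time t is X_i(t) ∈ {0, 1}; the system-level readout is the
state sum D(t) = Σ_i X_i(t) ∈ [0, J]. Two functions define the dynamics.
The *total activation* of symptom i,

$$A_i^{(t)} = c \sum_j w_{ij} X_j^{(t-1)} + S_i^{(t)},$$

collects the weighted activity of its neighbours at the previous time point,
scaled by a global connectivity multiplier c > 0 and shifted by an external
stress input S. The *probability function*

$$P\bigl(X_i^{(t)} = 1\bigr) = \frac{1}{1 + e^{\,b_i - A_i^{(t)}}}$$

turns activation into a Bernoulli rate: the further activation exceeds the
per-symptom barrier b_i, the more likely the symptom switches on. All J
symptoms are resampled at every step (synchronous update), each an
independent Bernoulli draw given the previous state, so the process is a
Markov chain on the 2^J binary configurations.

Key assumptions worth keeping in mind: symptoms are binary (no graded
severity); the weight matrix is symmetric with a zero diagonal (no
autocatalytic self-loops); parameters are constant within a run; stress acts
additively and, in the standard protocol, identically on every symptom.

### Why synchronous updates

The model's activation indexes *all* neighbours at t−1, which is exactly a
synchronous scheme, and no sequential update order is implied anywhere in
its definition. We therefore resample all symptoms simultaneously by
default. An asynchronous mode (one uniformly chosen symptom per step,
`update = "asynchronous"`) is available as a robustness check: synchronous
logistic dynamics can in principle sustain artefactual period-2 behaviour
that single-site dynamics cannot, and comparing the two is the cheap way to
check none of the conclusions depend on the scheme.

### The barrier convention b = |τ|

The estimation stage returns thresholds τ_i on the conditional-logistic
scale, where negative values mean a preference for 'off'. The simulator's
default maps these to barriers as b_i = |τ_i| (`b_mode = "abs"`). This is
deliberate but worth flagging: under the conventional Ising reading one
would take b_i = −τ_i, and the two coincide exactly when every τ_i is
negative — the typical situation for disorder symptoms, and the regime the
synthetic generator produces. For data containing symptoms with *positive*
thresholds the conventions genuinely diverge (|τ| penalises activation of a
symptom that prefers 'on'), so the conventional mapping is provided as
`b_mode = "neg"`. Nothing downstream depends on the mode except through the
b vector.

### Numerical guards

The logistic is evaluated via `stats::plogis`, which is branch-stable: at
|b − A| of 10^4 it returns exactly 0 or 1 rather than overflowing, and never
NaN. Bernoulli draws are consumed in fixed node order 1..J each step from a
single seeded generator, so a (network, config, seed) triple reproduces a
trace bit for bit — the experiment commands rely on this to make output
files byte-identical across reruns.

## The stress protocol

The tipping-point experiment sweeps a scalar stress level along a triangular
ramp — by default from −15 up to 15 and back down in steps of 0.01, i.e. a
6000-step full cycle — while the state carries over continuously across
reversals; nothing is reset at a peak or trough, which is precisely what
lets a bistable system display hysteresis. When the requested number of
steps is not a multiple of the cycle length the final cycle is simply
truncated; a run of 10000 steps contains one full cycle plus a partial
second ascent. The ramp's endpoints are generous by design: ±15 saturates
every symptom regardless of coupling, guaranteeing both attractors are
visited on every cycle.

Because each stress level recurs many times, the response is summarised by
averaging D within stress bins, separately for ascending and descending
steps: per-bin mean = (sum of D over qualifying steps) / (number of
qualifying steps). Bins are half-open intervals of width 0.20 anchored at
the sweep minimum. A plausible alternative reading — overlapping ±0.20
windows centred on each stress value — was rejected because non-overlapping
bins conserve mass (bin counts sum exactly to the number of steps), which
in turn makes the hysteresis area a well-defined integral: the sum over
shared bins of |meanD_up − meanD_down| times the bin width. The area is
zero for a memoryless system and grows with the stress span over which the
two branches disagree.

The *forbidden zone* detector operationalises the unstable band of
intermediate severities: the widest contiguous run of D levels each
occupied for less than 0.5% of steps, lying strictly between two levels
that exceed that occupancy. The 0.5% dwell threshold is a judgement call —
small enough that a 10000-step run can still certify a level as "practically
unvisited" (≤ 50 visits), large enough to tolerate the handful of transit
points the system necessarily passes through while jumping. Interior-ness
is required so that the detector returns nothing for a unimodal occupancy
profile (e.g. the zero-coupling binomial case).

## Early warning signals

Critical slowing down is quantified as the lag-1 autocorrelation of D in a
sliding window: at each step, the Pearson correlation between the window's
series and its one-step-lagged copy. The window default is 100 steps — long
enough that the correlation estimate has usable precision (sampling s.d.
≈ 0.1 under independence), short enough to resolve the pre-tipping rise,
which develops over a few hundred steps at the default ramp speed. Windows
in which D has zero variance yield NA (undefined), never 0: a constant
plateau carries no information about recovery speed, and coding it as zero
would fabricate a signal. With `detrend = TRUE` each window is linearly
detrended first, as is common in the early-warnings literature; the default
is the raw-state autocorrelation.

Transitions are located as crossings of the midline D = J/2 that persist
for at least 10 steps, which suppresses single-step spikes while keeping
genuine switches; near a tipping point the state can still legitimately
re-cross several times in quick succession. The rising-indicator test then
compares the mean indicator in a 200-step window ending just before a
transition against a long (2000-step) baseline window further back. Two
practical details matter here. First, on a strongly coupled system the
depressed plateau is often *exactly* constant, so any fixed short baseline
window can be entirely undefined; the baseline is therefore averaged over
the defined values in a long window, and a transition is only evaluated
when both windows contain at least 20 defined values. Second, when another
transition falls inside a transition's comparison windows the comparison is
confounded; this errors by default, and `on_overlap = "skip"` drops just
the affected transitions, which is the right behaviour when scanning many
seeds automatically.

## Network estimation

Weights and thresholds are estimated from N × J binary data by nodewise
logistic regression: each symptom is regressed on all others with an L1
penalty, the penalty level is selected per node by the extended BIC,

$$\mathrm{EBIC}_\lambda = -2\ell_\lambda + k_\lambda \log N
  + 2\gamma k_\lambda \log(J-1),$$

with k the number of nonzero coefficients, and the two directed
coefficients for a pair are symmetrised into one undirected weight. The
node's intercept is its threshold τ_i. Defaults follow established practice
for binary network estimation: γ = 0.25, AND symmetrisation (edge kept only
when both directions are nonzero, weight their mean; OR available), a
100-point log-spaced penalty path from the data-derived λ_max down to
0.001 λ_max, intercepts never penalised, and EBIC ties broken toward the
larger λ (sparser model). The penalized path itself is computed by `glmnet`;
the path is requested through its path-generation controls rather than as a
precomputed λ vector because the solver only guarantees that the null model
heads an internally generated path — an externally supplied copy of the
same grid can return a spurious nonzero coefficient at λ_max, which
matters exactly in the no-signal case the EBIC is supposed to get right.

The estimator targets the conditional distributions of the Ising model

$$P(x) \propto \exp\Bigl(\sum_i \tau_i x_i + \sum_{i<j} w_{ij} x_i x_j\Bigr),$$

whose full conditionals are logistic with intercept τ_i and slopes w_ij —
so on data drawn exactly from this distribution the regression recovers the
generator's parameters up to sampling noise and the lasso's shrinkage. Note
the estimation target uses τ itself; the |τ| convention exists only inside
the simulator's probability function.

## Synthetic data: what it emulates and what it does not

The generator stands in for the kind of empirical input the estimation
stage expects: a moderately sparse 14-symptom network with positive
couplings and clearly negative thresholds, so individual symptoms prefer
'off' and a fully developed episode is rare without either strong coupling
or external stress. Defaults are J = 14, edge density 0.4, weights uniform
on [0.5, 1.5], thresholds uniform on [−4, −2.5]. The coupling and threshold
scales were chosen together so that the three canonical connectivity
settings produce the three qualitative regimes the model is about: at
c = 0.80 a monostable healthy state with brief spontaneous excursions and
recovery; at c = 1.10 an intermediate regime; at c = 2.00 genuine
bistability — a depressed attractor deep enough to produce hysteresis under
the stress ramp and a wide low-occupancy band of intermediate severities.
Weaker couplings (e.g. weights around 0.5 with thresholds around −2.5)
still order the regimes correctly but make the attractors too shallow for
path dependence: the up and down stress responses coincide. Since
hysteresis under strong connectivity is a central phenomenon of the model,
realistic defaults must support it.

Exact sampling enumerates all 2^J configurations (J ≤ 20) and draws i.i.d.
rows from the normalised distribution — there is no approximation anywhere,
which is what makes the estimator's recovery tests clean. A single-site
Gibbs sampler covers larger J, with the exact sampler as its oracle at
small J.

What the synthetic data deliberately does *not* emulate: respondent
heterogeneity (every row comes from the same network, whereas real
populations mix architectures), any family/twin correlation structure,
item-level measurement error, and missingness. Passing recovery tests on
this generator therefore demonstrates correctness of the estimation
machinery under its own assumptions — not robustness to the ways real
questionnaire data violate them.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic input at
the following scales, chosen as the smallest that make each check
statistically decisive: dynamics runs of 10000 steps (the standard
experiment length) on the J = 14 reference system, five seeds per
condition; exact-chain validation on J = 3 with a 200000-step run compared
at total-variation distance < 0.02; estimator recovery at J = 6, N = 5000
with three replicates, plus ten replicates of a J = 5, N = 2000
independence null; AR(1) calibration on 4000-point series at window 500.

## Known limitations

* Binary symptoms and a single global connectivity scalar are strong
  simplifications; graded severities and edge-specific scaling are out of
  scope.
* The hysteresis area is a summary of the *binned mean* response; it does
  not distinguish deterministic path dependence from slow stochastic
  switching, and at weak coupling its floor is set by sampling noise rather
  than by zero.
* The forbidden-zone detector reports occupancy, not stability: a band can
  be empty in a short run for reasons other than dynamical instability.
* Estimation quality degrades gracefully but noticeably for dense small
  graphs (neighbourhood regressions share predictors), where occasional
  small false-positive edges at moderate N are expected.
* The cusp-catastrophe likelihood formalism sometimes used to analyse such
  bistable systems is intentionally not implemented; discontinuity is
  quantified directly through the hysteresis and forbidden-zone statistics.
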