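# symptomnet

Major depression — and psychopathology more broadly — can be modelled not as
a latent disease entity but as a *network* of symptoms that switch each other
on and off: one bad night of sleep makes fatigue more likely, fatigue feeds
concentration problems, and in a tightly coupled network a small push can
cascade into a full, self-sustaining episode. `symptomnet` is an R toolkit
for studying that view quantitatively. It is aimed at researchers in
computational psychiatry and network psychometrics who want to simulate
symptom dynamics, probe vulnerability and tipping points, and estimate
symptom networks from binary questionnaire data.

## The model

Each of J symptoms is binary, X_i ∈ {0, 1}. At every time step the *total
activation* of symptom i is the weighted activity of its neighbours, scaled
by a global connectivity parameter c and shifted by external stress S:

    A_i(t) = c · Σ_j w_ij X_j(t−1) + S_i(t)

and the symptom switches on with the logistic *probability function*

    P(X_i(t) = 1) = 1 / (1 + exp(b_i − A_i(t)))

where b_i is a per-symptom barrier derived from the threshold τ_i estimated
from data (b_i = |τ_i| by default). All symptoms are resampled synchronously
each step. The scalar readout is the state sum D = Σ X — the number of
active symptoms, between 0 and J.

Around this core the package provides:

* **Vulnerability experiments** — connectivity c multiplies the whole weight
  matrix; weakly connected systems (c = 0.80) hover near D = 0 and recover
  spontaneously from excursions, strongly connected ones (c = 2.00) fall
  into and stay in a high-D "depressed" attractor.
* **Stress-ramp / hysteresis protocol** — a triangular stress sweep (−15 to
  15 in 0.01 steps) applied to all symptoms, with 0.20-wide binned averaging
  of D separately for ascending and descending stress, a hysteresis-area
  statistic, and a forbidden-zone detector for the unstable band of
  intermediate severities.
* **Early warning signals** — sliding-window lag-1 autocorrelation of D as a
  critical-slowing-down indicator, with transition detection and a
  rising-indicator test against a plateau baseline.
* **Ising network estimation** — nodewise L1-regularised logistic regression
  (via glmnet) with extended-BIC model selection (γ = 0.25) and AND/OR edge
  symmetrisation, recovering weights w_ij and thresholds τ_i from binary
  respondents × symptoms data.
* **Exact synthetic data** — random sparse networks and exact (2^J
  enumeration, J ≤ 20) or Gibbs samplers from the corresponding Ising
  distribution, so every analysis is testable end to end without any
  external data.

## Worked example

```r
library(symptomnet)

## a reproducible synthetic 14-symptom system
net <- random_network(generator_spec(seed = 101))
net
#> Symptom network: 14 nodes, 31 nonzero edges
#>   thresholds: -3.27 -3.62 -3.46 -3.99 -3.65 -3.84 -3.08 -3.69 ...

## vulnerability: the same network at weak, medium, strong connectivity
for (cc in c(0.80, 1.10, 2.00)) {
  tr <- simulate_network(net, sim_config(connectivity = cc,
                                         n_steps = 10000, seed = 1))
  cat(sprintf("c = %.2f  mean D = %5.2f  max D = %2d  time at D = 0: %4.1f%%\n",
              cc, mean(tr$D), max(tr$D), 100 * mean(tr$D == 0)))
}
#> c = 0.80  mean D =  0.56  max D =  5  time at D = 0: 57.2%
#> c = 1.10  mean D =  0.75  max D =  9  time at D = 0: 50.0%
#> c = 2.00  mean D = 13.07  max D = 14  time at D = 0:  0.1%
```

The weakly connected system stays essentially healthy (more than half its
time fully symptom-free); the strongly connected one ends up with nearly all
14 symptoms active — same symptoms, same thresholds, different wiring
strength.

```r
## stress ramp on the vulnerable system: hysteresis and the forbidden zone
sch   <- make_ramp_schedule(-15, 15, 0.01, n_steps = 10000)
tr    <- run_stress_experiment(net, sim_config(2.00, 10000, seed = 1), sch)
curve <- bin_hysteresis_curve(tr, bin_width = 0.20)
hysteresis_area(curve)
#> [1] 15.8
forbidden_zone(tr)
#> [1]  2 11
```

A hysteresis area of ~16 (in symptoms × stress units) means the stress level
at which the system tips into the depressed state is much higher than the
level to which stress must fall before it tips back — and severities between
2 and 11 active symptoms are essentially never observed: they are not stable
states.

```r
## critical slowing down before the tipping points
ew  <- sliding_autocorrelation(tr, window = 100)
res <- detect_rising_indicator(ew, find_transitions(tr), on_overlap = "skip")
res
#>      t type pre_mean baseline_mean rise rising
#> 1 4695 down     0.38         -0.05 0.43   TRUE
```

Ahead of the switch out of the depressed state the lag-1 autocorrelation of
D climbs from ≈ −0.05 (plateau baseline) to ≈ 0.38 — the early-warning
signature.

```r
## estimate the network back from exact Ising samples
dat <- sample_ising_exact(net, N = 5000, seed = 2)
est <- estimate_network(dat)
est
#> Symptom network: 14 nodes, 19 nonzero edges
#>   thresholds: -3.33 -3.23 -3.48 -3.95 -3.34 -3.75 -2.96 -3.51 ...
```

A command-line front end (`inst/scripts/symptomnet`) exposes the same
experiments as `simulate`, `stress`, `estimate` and `generate` subcommands
driven by a YAML config.

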