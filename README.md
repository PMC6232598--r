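# bibswarm

Bayesian and inverse Bayesian (BIB) inference for collective animal motion.

Classical Bayesian updating revises a belief over a *fixed* set of
hypotheses; when the environment drifts, the best fixed hypothesis can only
be an average. Inverse Bayesian updating closes the loop the other way: at
each step the likelihood row of the currently least probable hypothesis
`h_s = argmin P(h)` is replaced, with probability `1 − P(h_s)`, by the
empirical symbol frequency `f(d)` over the last `M` observations, so the
hypothesis set itself is rewritten by experience. The combination — Bayes
update, then probabilistic likelihood replacement — tracks nonstationary
sources that defeat a fixed hypothesis set, and when wired into an
agent-based swarm (velocity alignment within radius `R`, plus movement
toward positions whose discretized relative local density
`d = min(3, ⌊4 n_r / n_2r⌋)` matches the level `d_max` preferred by the
dominant hypothesis) it is a candidate mechanism for the perpetual
alternation of swarming and dispersing seen in animal groups.

The package is for researchers in collective behaviour and agent-based
modelling who want the inference engine, the tracking benchmark, the
trajectory-analysis pipeline (polarization order parameter
`ψ = ‖Σ V_k/‖V_k‖‖/N`, density-datum streams, forward-frequency benchmarks
`F(d)`), the swarm simulator, and seeded synthetic generators, as reusable,
tested parts.

## Worked example

Track a source whose `P(d0)` follows a sine curve (baseline 0.5, amplitude
0.4, period 1000) with a four-symbol alphabet, comparing the fixed
hypothesis set against the rewriting one:

```r
library(bibswarm)
env <- make_sin_env(n = 4, baseline = 0.5, amplitude = 0.4,
                    period = 1000, horizon = 5000)
run_tracking(env, M = 100, mode = "b",   seed = 1)
#> <tracking_result> mode=b, M=100, mean |truth - prediction| = 0.1654
run_tracking(env, M = 100, mode = "bib", seed = 1)
#> <tracking_result> mode=bib, M=100, mean |truth - prediction| = 0.1055
```

The Bayes-only agent can only hop between the rows of its initial
likelihood (prediction 0.7 or 0.1) with a lag set by accumulated evidence;
the BIB agent follows the drift with a lag of roughly `M/2`, cutting the
tracking error by about a third here. Sweeping the window length shows the
noise-versus-lag trade-off:

```r
m_sweep(env, c(40, 100, 2000), replicates = 5, seed = 42)
#>      M     error
#> 1   40 0.1304558
#> 2  100 0.1186663
#> 3 2000 0.2531912
```

Simulate a swarm and count polarization collapse/re-formation cycles:

```r
prm <- swarm_params(n_agents = 100, r = 30, R = 30, p = 0.7, steps = 5000)
run <- run_swarm(prm, mode = "bib", seed = 1)
phase_crossings(run$psi)$n_collapse   # dozens: perpetual phase turnover
```

The synthetic phase-alternating fixture plus the analysis pipeline close
the loop: predictions from the rewriting inference sit closer to the
forward-looking frequency `F(d)` than Bayes-only predictions on every
studied seed (see `vignettes/bib-inference.Rmd` for the model details and
for the limits of what the swarm model reproduces).

A thin command-line wrapper covers the same ground
(`inst/cli/bibswarm toy-track|analyze|simulate|gen-bag|gen-traj`, YAML
configs via `--config`).

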