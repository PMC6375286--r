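# stresstiming

Tools for quantifying *when* single bacterial cells switch on gene-expression
responses after a sudden stress, and for inferring from that timing how many
rate-limiting molecular steps lie between the stressor and the response.

When a stressor (an antibiotic, say) hits a growing microcolony, each cell
activates stress-response promoters at its own moment. Time-lapse microscopy
with fluorescent reporters yields, for every tracked cell lineage, a
*response time*: the time after stress addition at which reporter expression
first crosses a threshold. Two statistics of the response-time distribution —
the mean μ_t and standard deviation σ_t — carry mechanistic information.
If the response is triggered by completion of a chain of *n* memory-less
(exponential) molecular steps, completion times follow an Erlang
distribution and

    σ_t / μ_t  ≥  1 / √n,

so the *randomness parameter* R = (σ_t/μ_t)² bounds the number of
rate-limiting steps from below: n ≥ 1/R. Rounding 1/R up gives an estimate
of the effective number of rate-limiting steps; σ_t ≤ μ_t must always hold
(at least one step). Across promoters, the smallest observed σ_t/μ_t defines
a *precision limit*: a line through the origin below which no promoter's
timing variability falls.

The package implements the complete analysis chain:

* **Synthetic microcolonies** (`generate_dataset()`): exponentially growing,
  dividing cells; latent activation times drawn per founder from Erlang
  chains (single-channel, or serial/parallel dual-reporter architectures);
  traces rendered with maturation delay, autofluorescence, photobleaching,
  background and measurement noise.
* **Trace preprocessing** (`read_trace_table()`, `compute_expression()`,
  `normalize_traces()`, `growth_rate_series()`, `doubling_series()`):
  per-area expression after background/autofluorescence subtraction, growth
  rates and continuous doubling curves across divisions.
* **Response times** (`compute_response_times()`): colony-threshold measure
  (25% of the median full response among >3-fold responders) and per-cell
  half-maximum measure, with linear or frame-resolution crossings.
* **Lineage-aware statistics** (`subsample_trajectories()`,
  `timing_summary()`, `paired_correlation()`, `strict_order_test()`):
  single-trajectory subsampling to undo lineage pseudo-replication,
  bootstrap errors, subsample-averaged Pearson correlation, and a
  strict-temporal-order permutation test for dual reporters.
* **Statistical kinetics** (`randomness_and_steps()`, `fit_erlang()`,
  `ks_consistency()`, `precision_limit()`): step-count bounds, ML Erlang
  fits, simulated Kolmogorov–Smirnov consistency, precision-limit slope.
* **Pipeline** (`run_pipeline()`, `inst/scripts/stresstiming-cli.R`):
  seed-reproducible simulate → preprocess → respond → stats → kinetics runs
  from a flat YAML config.

## Worked example

Sample completion times of a 37-step chain with mean 1.87 h and recover its
kinetics:

```r
library(stresstiming)

x <- sample_erlang(chain_spec(n_steps = 37, mean_time = 1.87), 1e5, seed = 1)
round(c(mean = mean(x), sd = sd(x), cv = sd(x) / mean(x)), 3)
#>  mean    sd    cv
#> 1.870 0.307 0.164

fit_erlang(x)
#> erlang_fit: shape 37 (ML 37.19), scale 0.05054 h, mean 1.87 h, n = 100000

slope_in_minutes(sd(x) / mean(x))
#> [1] 10
```

The sample CV matches 1/√37 ≈ 0.164: a process this precise needs at least
37 rate-limiting steps, and its timing standard deviation grows by 10
minutes per hour of mean response time. A full in-silico experiment — 200
founder cells, an 8-step chain with mean 4 h, noiseless reporters — recovers
the chain length from the rendered movies:

```r
cfg <- sim_config(n_founders = 200, growth_rate_mean = 0.55,
                  division_size_ratio = 8, frame_interval = 0.25,
                  pre_stress_duration = 0.5, post_stress_duration = 11.5,
                  chain = chain_spec(8, 4),
                  reporters = list(yfp = reporter_spec(production_rate = 5000)),
                  seed = 88)
ds   <- generate_dataset(cfg)
expr <- compute_expression(ds$traces)
rts  <- compute_response_times(expr)
s    <- subsample_trajectories(expr, rts,
                               stats_config(n_subsamples = 100,
                                            n_bootstrap = 100, seed = 89))
ts   <- timing_summary(s, "yfp")
ts
#> timing_summary (yfp): mu_t = 4.201 +/- 0.100 h, sigma_t = 1.522 +/- 0.066 h
#>   200 founders, 100 subsamples, responder fraction 0.99
randomness_and_steps(ts$mu_t, ts$sigma_t)
#> kinetics_estimate: sigma_t/mu_t = 0.362, R = 0.131, n_min = 7.62 -> n = 8 step(s)
```

The measured mean exceeds the latent 4 h by the reporter's threshold-climb
lag (~0.2 h here); the step-count estimate returns the true n = 8.

A YAML-driven run of the same pipeline:

```sh
Rscript inst/scripts/stresstiming-cli.R run \
    --config inst/extdata/demo-config.yaml --out /tmp/demo --seed 1
```

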