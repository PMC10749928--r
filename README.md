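# bmtpp — burst- and memory-aware transformer for temporal point processes

`bmtpp` is an R package for analyzing and modeling *bursty* event
sequences: ordered timestamps whose inter-event times (IETs) are
heavy-tailed and serially correlated, as in neuronal spike trains,
earthquakes, and human activity logs.

It has three layers:

1. **Heterogeneity statistics.** Burstiness
   `B = (σ − ⟨τ⟩)/(σ + ⟨τ⟩)`, its finite-size-corrected form
   `B_n = (√(n+1)·r − √(n−1)) / ((√(n+1) − 2)·r + √(n−1))` with
   `r = σ/⟨τ⟩`, the lag-1 memory coefficient `M`, causal per-event prefix
   series of both, log-binned IET histograms, and ensemble summaries
   (`burstiness()`, `burstiness_corrected()`, `memory_coefficient()`,
   `prefix_bm_series()`, `dataset_summary()`).
2. **Generators.** Farlie–Gumbel–Morgenstern copula samplers that produce
   power-law or exponential IET sequences with a target memory
   coefficient (`generate_powerlaw_dataset()`,
   `generate_exponential_dataset()`), plus self-correcting and Hawkes
   process simulators (`simulate_self_correcting()`, `simulate_hawkes()`).
3. **Model.** A causal transformer temporal point process that embeds
   discretized `(B, M)` prefix tokens (Cantor-paired, dense-ranked to a
   `b²` vocabulary) together with sinusoidal encodings of the raw event
   times, refines hidden states with an LSTM, and trains four heads —
   next event time `t̂_{i+1} = W_t h(t_i)`, a softplus intensity
   `λ = β log(1 + exp(w_λᵀh/β − 1))`, a categorical head over the token
   vocabulary, and scalar `B̂, M̂` heads — under the objective
   `L = L_t + α₁L_λ + α₂L_{B,M} + α₃L_B + α₄L_M`
   (`train_bmt()`, `evaluate_bmt()`, `run_ablation_suite()`).
   Forward and backward passes are hand-written matrix algebra; gradients
   are finite-difference-verified in the test suite.

See `vignettes/bmtpp-methods.Rmd` for the modeling assumptions and
numerical choices.

## Worked example

```r
library(bmtpp)

# 60 power-law copula sequences: alpha ~ U[2.1, 2.9], M ~ U[-1/3, 1/3]
ds <- generate_powerlaw_dataset(60, seed = 7, n_range = c(50L, 150L))
dataset_summary(ds)$ensemble
#>      mean_iet         B           M
#> mean 3.193605 0.1981479 -0.05807542
#> sd   1.127437 0.2197636  0.13035071

seq <- ds[[1]]
head(prefix_bm_series(seq))
#>   event          B          M valid
#> 1     1         NA         NA FALSE
#> 2     2         NA         NA FALSE
#> 3     3         NA         NA FALSE
#> 4     4 -0.7804637 -1.0000000  TRUE
#> 5     5 -0.7002602 -0.9258459  TRUE
#> 6     6 -0.6909803 -0.9657532  TRUE
```

The ensemble rows are the mean and SD across sequences of each
per-sequence statistic: these power-law sequences are bursty on average
(mean corrected burstiness 0.20) with near-zero average memory, and the
prefix series shows the causal `(B_i, M_i)` values (first three events
masked) that the model tokenizes and embeds.

```r
cfg <- reduced_config("BMT")   # 2 layers, d = 32, b = 8 — desk profile
mdl <- train_bmt(ds, cfg, epochs = 20, lr = 1e-2, batch_size = 4, seed = 1)
evaluate_bmt(mdl, ds[mdl$split$test])
#> <bmt_eval> 12 sequences / 1126 events: RMSE 123.9, LL/event -2.047, CE/event 2.02
```

RMSE is the pooled root-mean-squared error of absolute next-event-time
predictions (in the sequences' time units), log-likelihood and token
cross-entropy are per event. `run_ablation_suite()` repeats this across
the six embedding/loss variants with shared splits and seeds and emits the
standard comparison table (with `N/A` cross-entropy for variants without
the joint token head).

## Command line

```sh
Rscript inst/cli/bmt.R generate --family powerlaw --n-sequences 100 --seed 1 --out data.jsonl
Rscript inst/cli/bmt.R metrics  --data data.jsonl --out summary.tsv
Rscript inst/cli/bmt.R train    --data data.jsonl --variant BMT --epochs 20 --lr 0.01 --out model.rds
Rscript inst/cli/bmt.R ablate   --data data.jsonl --seeds 1,2,3 --out report.tsv
```

Datasets are JSON Lines (one object per line with `timestamps`,
`observation_end`, optional `label`/`metadata`); `read_timestamp_lines()`
imports plain whitespace-delimited timestamp files.

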