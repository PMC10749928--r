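---
title: "Modeling bursty event sequences with bmtpp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bursty event sequences with bmtpp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmtpp)
```

## The problem

Event sequences — spike trains, earthquakes, message timestamps — are often
*bursty*: their inter-event times (IETs) follow heavy-tailed distributions
and are serially correlated, so clusters of rapid events alternate with long
silences. Two single-number summaries dominate the literature:

* **Burstiness** $B = (\sigma - \langle\tau\rangle)/(\sigma +
  \langle\tau\rangle)$, a monotone transform of the coefficient of variation
  $r = \sigma/\langle\tau\rangle$ of the IETs: $-1$ for a perfectly regular
  sequence, $0$ for a Poisson process, approaching $1$ for extreme bursts.
  For short sequences the empirical $r$ is biased, so the package follows
  the finite-size-corrected form
  $$B_n = \frac{\sqrt{n+1}\,r - \sqrt{n-1}}{(\sqrt{n+1}-2)\,r + \sqrt{n-1}},$$
  where $n$ is the number of events. Throughout, $\sigma$ is the
  *population* standard deviation (divisor $n$), the convention under which
  the correction was derived.
* **Memory coefficient** $M$: the lag-1 Pearson correlation between
  consecutive IETs. Positive $M$ means long gaps follow long gaps.

`bmtpp` provides these statistics, copula-based simulators that control
them, and a transformer-based temporal point process (TPP) that consumes
them: the model embeds discretized $(B, M)$ prefix statistics alongside
sinusoidal encodings of the event times, and its objective rewards
reproducing them.

## Synthetic generators

### FGM copula samplers

Consecutive IETs are coupled with a Farlie–Gumbel–Morgenstern copula:
given $\tau_i$, the conditional inverse CDF of $\tau_{i+1}$ is
$$\tau_{i+1} = F^{-1}\!\left[\text{survival form of } \frac{2c}{c + 1 -
\sqrt{(c+1)^2 - 4cu}}\right], \qquad u \sim U[0, 1),$$
which preserves the marginal while imposing a lag-1 correlation through
$c$. Two marginals are built in:

* **power law** $P(\tau) = (\alpha - 1)\tau^{-\alpha}$ on $\tau \ge 1$, with
  $c = \frac{(2\alpha-3)^2}{(\alpha-1)(\alpha-3)} M (1 - 2\tau_i^{1-\alpha})$;
* **exponential** with mean $\mu$, with $c = 4M(1 - 2e^{-\tau_i/\mu})$
  (for this marginal the FGM correlation parameter is exactly $4M$).

Numerical choices worth knowing:

* Near $c = 0$ the bracket suffers catastrophic cancellation; for
  $|c| < 10^{-12}$ the samplers switch to the analytic independence limit
  ($\tau = u^{-1/(\alpha-1)}$, resp. $\mu\ln(1/u)$).
* The FGM copula is a valid joint distribution only for $|c| \le 1$, but the
  formulas are implemented **literally, without clamping**: the standard
  generator recipes draw $M$ up to $\pm 1/3$ (and power-law exponents near
  3), which pushes $c$ far outside validity. The inverse remains
  well-defined and produces strictly positive gaps; the price is that the
  realized $M$ deviates from the target outside the valid regime. The
  package reproduces the recipes as stated rather than "fixing" them,
  because the downstream statistics are defined by that literal procedure.
* Ensemble recipes: power-law sequences draw $\alpha \sim U[2.1, 2.9]$,
  $M \sim U[-1/3, 1/3]$, $n \sim U\{50..500\}$, first gap $\sim U[1, 2]$;
  exponential sequences draw $\mu \sim U[1, 100]$, same $M$ and $n$, first
  gap $= \mu$. Time starts at 0 with no event at 0, so $t_1$ equals the
  first gap and the observation window ends at $t_n$ (the recipes specify
  no origin or trailing window; this is the package's convention).

### Point-process simulators

* **Self-correcting process**: $\lambda(t) = \exp(\zeta t - N(t)\eta)$,
  sampled by exact compensator inversion (closed form because $\lambda$ is
  exponential in $t$ between events), written in `log1p` form so the
  exponent never overflows. Long-run mean gap is $\eta/\zeta$. Defaults
  $\zeta = 1, \eta = 0.2$: any $\zeta = 5\eta$ gives mean gap $0.2$, and
  this $\eta$ additionally reproduces the mildly regular ensemble
  statistics ($B \approx -0.05$, $M \approx -0.08$) that the reference
  self-correcting dataset exhibits; stronger correction (e.g. $\eta = 1$)
  would give $B \approx -0.17$.
* **Hawkes process**: $\lambda(t) = \zeta + \eta\sum_{t_i<t} e^{-(t-t_i)}$
  via Ogata thinning, with a nonstationarity warning and a hard event cap
  for $\eta \ge 1$.

### What the generators do and do not emulate

The synthetic families reproduce heavy-tailed marginals, controlled lag-1
memory, and regular/clustered alternatives — the features the model's
embeddings target. They do **not** emulate marks/event types,
non-stationary daily rhythms, or multi-scale correlations beyond lag 1
found in real data; passing tests on these families therefore demonstrates
mechanism, not field performance.

## The model

Each event $i$ of a sequence is embedded as
$z_i = z_t(t_i) + z_e(B_i, M_i)$:

* $z_t$ is the sinusoidal encoding of the *raw timestamp* (not the rank),
  $\omega_k = 10000^{-2k/d}$. Low-frequency coordinates are nearly linear
  in $t$, which is what lets a linear head read absolute time back out.
* $B_i, M_i$ are the statistics of the prefix $t_1..t_i$ only (causality is
  exact), discretized into $b$ uniform bins each on $[-1, 1]$, fused by the
  Cantor pairing $d_{B,M} = \frac12(d_B + d_M)(d_B + d_M + 1) + d_M$, and
  mapped through a dense rank to indices $0..b^2-1$. The Cantor image of a
  $b \times b$ grid is sparse (max value $2b(2b+1)/2 + b$), so the dense
  rank keeps the embedding matrix at exactly $d \times b^2$; the first
  three events of every sequence are masked (their prefix statistics are
  noise) and map to a reserved padding column excluded from every loss.

The encoder is a standard causal transformer: per layer, multi-head
scaled-dot-product attention (per-head query/key width $d_K$, per-head
value width $d_V/m$, output projection $d_V \times d$), then a
position-wise feed-forward network, each wrapped in residual connections
with post-layer-normalization; a single unidirectional LSTM pass refines
the hidden representations afterwards. Residual/normalization placement and
the LSTM's depth (one layer, width $d$) are not pinned down by the
architecture's verbal description; the package adopts the standard
transformer encoder and the most parsimonious LSTM, and records both as
assumptions.

Four heads read the hidden state $h(t_i)$:

* next event time $\hat t_{i+1} = W_t h(t_i)$ (absolute time, taken
  literally);
* intensity $\lambda = \beta\log(1 + \exp(w_\lambda^\top h(t_i)/\beta - 1))$,
  **piecewise-constant on $[t_i, t_{i+1}]$** — the definition contains no
  elapsed-time term, so the non-event integral of the log-likelihood is the
  closed form $\sum_i \lambda_i \Delta t_i$ (the test suite checks it
  against adaptive quadrature). $\beta$ defaults to 1 (unreported
  upstream; exposed in the configuration). The intensity at an event uses
  the hidden state of the *preceding* event, preserving causality;
* a softmax over the $b^2$ token vocabulary predicting the next discretized
  $(B, M)$;
* scalar $\hat B, \hat M$ through linear maps squashed by $\tanh$ — the
  value heads' exact form is unspecified upstream; $\tanh$ is the simplest
  symmetric map onto $[-1, 1]$ with 0 at zero pre-activation.

The training objective is
$L = L_t + \alpha_1 L_\lambda + \alpha_2 L_{B,M} + \alpha_3 L_B +
\alpha_4 L_M$ with $L_\lambda = -LL$ and defaults $\alpha_1 = 10^3,
\alpha_2 = 4\cdot10^3, \alpha_3 = \alpha_4 = 10^4$. Six ablation variants
toggle the embedding and the loss terms (`?bmt_config`); the token
cross-entropy head exists whenever the joint embedding does, so the
embedding-only variant still reports (but does not train) it.

All forward/backward passes are hand-written matrix algebra; analytic
gradients of every term are verified against central finite differences to
$10^{-4}$ relative on small models in the test suite.

## Training choices

* ADAM $(0.9, 0.999)$, step learning-rate decay (factor 0.9; "every 15
  steps" is read as 15 epochs and is configurable), dropout 0.1 on sublayer
  outputs, mini-batches of sequences with gradients averaged per batch.
* Splits are 70/10/20 by sequence (none are specified upstream), seeded;
  early stopping on validation total loss with patience 10; the returned
  parameters are the best-validation ones.
* Per-sequence losses are sums over events (taken literally), so long or
  large-horizon sequences weigh more within a batch.
* RMSE is reported as the square root of the *mean* squared error pooled
  over all predicted events, so it is comparable across datasets;
  log-likelihood and token cross-entropy are reported per event. Reported
  per-event cross-entropy for a $b = 40$ vocabulary is bounded by
  $\ln 1600 \approx 7.38$ under a uniform predictor; published values above
  that bound must use some other normalization, which is one reason the
  package pins its own.
* Determinism: a single seed drives split, initialization, shuffling, and
  dropout; identical seeds reproduce identical runs.

## Desk-scale profiles

The full-scale configuration ($d = d_H = 128$, $d_K = d_V = 32$, 8 layers,
8 heads, $b = 40$) is faithful but not something a laptop reproduces in
minutes. `reduced_config()` (2 layers, 2 heads, $d = 32$, $b = 8$) is the
package's desk profile. The ablation harness at desk scale uses 200
power-law sequences of 50–150 events, batches of 4, and a learning rate of
$10^{-2}$ for at most 40 epochs: with the paper-scale $10^{-4}$ the
absolute-time head (whose weights must grow large to decode time from
low-frequency encodings) cannot move far enough in a desk-scale step
budget, so training stalls; smaller batches and the larger rate give ADAM
enough steps to converge while keeping the whole suite inside a test run.
The vocabulary of $8^2 = 64$ tokens keeps the cross-entropy head learnable
from a few thousand events. These choices are shared by all variants, so
ablation comparisons remain like-for-like.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
ds <- generate_powerlaw_dataset(60, seed = 7, n_range = c(50L, 150L))
dataset_summary(ds)$ensemble

cfg <- reduced_config("BMT")
mdl <- train_bmt(ds, cfg, epochs = 20, lr = 1e-2, batch_size = 4, seed = 1)
evaluate_bmt(mdl, ds[mdl$split$test])
```

## Known limitations

* Unmarked sequences only; no event types.
* The copula recipes are reproduced literally, including their
  outside-validity memory targets; realized ensemble statistics therefore
  disagree with some published summary numbers that are mutually
  inconsistent (a mean below its own stated minimum cannot be matched by
  any generator).
* Prefix statistics are recomputed per prefix from scratch ($O(n^2)$ per
  sequence) for exact equality with truncated-sequence computation;
  sequences beyond a few thousand events would want an incremental scheme.
* Desk-scale ablation results are qualitative (orderings, not absolute
  errors); full-scale numbers require the full configuration and a long
  training budget.
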