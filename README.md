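# ampbalance

Timescale-aligned amplitude balance analysis for multichannel time
series.

## What problem this solves

Multichannel recordings — the motivating case is BOLD fMRI network time
courses, but nothing here is imaging-specific — mix two kinds of
disagreement between channels: *timing* differences (leads, lags,
stretching, shrinking) and *amplitude* differences (one signal genuinely
stronger or weaker than another). Correlation-family measures are
sensitive to the first and blind to the second; naive amplitude measures
confound the two. `ampbalance` isolates amplitude disparity after
correcting timing, and then analyzes how that disparity evolves as a
small set of recurring states.

The package is aimed at researchers analyzing network time courses
(resting-state fMRI ICN time series and similar band-limited
multichannel data) who want amplitude-balance metrics, their time-resolved
dynamics, surrogate-based null tests, and test–retest statistics in one
coherent, fully seeded toolkit.

## The metric

For series $x, y$ the package computes window-constrained dynamic time
warping with the generalized pointwise cost
$\lambda_\gamma(a,b) = |a - b|^\gamma$ over the Sakoe–Chiba band
$|i - j| \le w$:

$$
C(i,j) = |x_i - y_j|^\gamma + \min\{C(i{-}1,j{-}1),\,C(i{-}1,j),\,C(i,j{-}1)\}
$$

The optimal anchored path $\varphi$ (length $L$) gives the distance
$D = \sum_\tau |x_{\varphi_x(\tau)} - y_{\varphi_y(\tau)}|^\gamma$ and the
normalized distance $D_n = D/L$ (nDTW) — the mean aligned cost, read as
timing-invariant amplitude disparity (low = convergence, high =
divergence). Dropping the summation gives a per-timepoint disparity
trace, resampled to the original signal length with monotone PCHIP
interpolation so its mean still reproduces $D_n$.

Downstream, the time-resolved traces over all channel pairs are
clustered (city-block k-means, elbow-selected k) into recurring
convergent / mixed / divergent states, and the resulting state sequences
are summarized as Markov chains: transition matrices, stationary
distribution, spectral gap, total-variation mixing time, entropy rate,
mean dwell time, occupancy, and a transition-perturbation analysis.
Supporting modules provide minimum-order Butterworth band-pass
preparation with a cutoff-derived warping-window rule, phase-randomization
surrogates (full-band and band-residual), test–retest reliability
statistics, and synthetic-data generators for every pipeline stage.

## Worked example

Two copies of the same band-limited waveform, one delayed by 3 samples
and amplified 1.6-fold — a timing difference stacked on a genuine
amplitude difference:

```r
library(ampbalance)

base <- gen_band_limited_noise(0.6, 300, fs = 0.5, seed = 7)
x <- base
y <- 1.6 * c(base[4:300], base[298:300])    # 3-sample lag + gain

w <- dtw_window_from_cutoff(0.01, tr = 2)   # 45 samples (N = 90, i.e. 180 s)
params <- dtw_params(gamma = 1.5, window = w)

dtw_align(scale(x)[, 1], scale(y)[, 1], params)
#> warp_alignment: L = 303 (N = 300, M = 300), D = 7.9808, Dn = 0.0263393,
#>                 gamma = 1.5, w = 45

mean(abs(scale(x) - scale(y))^1.5)          # no alignment, same cost
#> 1.4596
```

The unaligned mean cost (1.46) is dominated by the 3-sample lag; after
alignment the residual disparity ($D_n$ = 0.026) is some fifty times
smaller — that residual is what the z-scored gain difference leaves
behind, the quantity the metric is built to expose.

The time-resolved version keeps the same mean:

```r
disparity_trace(scale(x)[, 1], scale(y)[, 1], params)
#> disparity_trace: N = 300, Dn = 0.0263393, rel. consistency diff = 0.4214%
```

State dynamics on a 3-state transition matrix (convergent / mixed /
divergent ordering):

```r
P <- rbind(c(0.85, 0.15, 0.00),
           c(0.10, 0.85, 0.05),
           c(0.00, 0.15, 0.85))
chain_summary(P)
#> chain_summary: pi = [0.3333, 0.5000, 0.1667], gap = 0.1500,
#>                mixing time = 41, H = 0.6787 bits (42.8%)
```

Here the chain spends half its time in the mixed state, converges to its
stationary distribution at rate 0.15 (41 steps to reach total-variation
distance 1e-3 from the worst-case start), and sits well toward the
ordered end of the entropy scale (42.8% of the 3-state maximum of
log2(3) = 1.585 bits).

The full pipeline — preparation, pairwise nDTW, disparity tensor, state
clustering, chain summaries — runs from one seeded configuration:

```r
co <- gen_cohort(cohort_spec(seed = 1))     # synthetic two-group cohort
bundle <- run_pipeline(co$panel_group1, run_config(seed = 5))
bundle$model$k                              # elbow-selected state count
bundle$aggregate_summary                    # pooled chain analytics
```

See the methods vignette
(`vignettes/amplitude-balance-methods.Rmd`) for the models, parameter
semantics, and design rationale, including what the synthetic generators
do and do not emulate.

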