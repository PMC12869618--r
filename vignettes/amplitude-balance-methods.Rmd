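---
title: "Timescale-aligned amplitude balance: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timescale-aligned amplitude balance: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r setup}
library(ampbalance)
```

## The problem and the model

Brain networks (and many other multichannel systems) operate on different
intrinsic timescales. When two signals are misaligned in time, conventional
similarity measures confound two distinct phenomena: differences in *when*
things happen and differences in *how strongly* they happen. This package
quantifies the second after correcting for the first.

The core object is a window-constrained, gamma-parameterized dynamic time
warping (DTW) distance. For series $x$ (length $N$) and $y$ (length $M$),
the cumulative cost matrix is filled over the Sakoe–Chiba band
$|i - j| \le w$ with the three-predecessor recursion

$$
C(i,j) = |x_i - y_j|^\gamma +
  \min\{C(i-1,j-1),\; C(i-1,j),\; C(i,j-1)\},
$$

anchored at $C(0,0) = 0$ ($+\infty$ elsewhere on the boundary). The optimal
warping path $\varphi$ of length $L \ge \max(N, M)$ yields the distance
$D = \sum_{\tau=1}^{L} |x_{\varphi_x(\tau)} - y_{\varphi_y(\tau)}|^\gamma$
and the normalized distance $D_n = D / L$ — the mean aligned pointwise
cost. For $\gamma = 2$, $D$ is the energy and $D_n$ the power of the
aligned difference signal. Because the path has already absorbed timing
distortions (up to the window), $D_n$ reads as *timing-invariant amplitude
disparity*: low values mean the two signals maintain proportionate
amplitudes (convergence), high values mean imbalance (divergence).

### The gamma exponent

`gamma` tunes what counts as disparity: $\gamma < 1$ amplifies small
amplitude differences, $\gamma > 1$ emphasizes large ones, $\gamma = 1$ is
neutral. The package default is `gamma = 1.5`, which in test–retest
comparisons of this metric family trades a slight loss of small-disparity
sensitivity for noticeably better session-to-session reliability. All
functions accept any positive exponent.

### The window rule

The half-width $w$ bounds how far the alignment may reach
($|i - j| \le w$). Too small, and genuine lags are not corrected; too
large, and the path can "dodge" amplitude structure (the classic
singularity problem) while costs smear along the path. The package ties
$w$ to the spectral content of the prepared signal: the slowest component
passed by the band-pass filter has period $1/f_{3\mathrm{db}}$, and full
anti-correlation of that component corresponds to a half-period lag, so a
window covering such lags in both directions suffices. For a non-ideal
(Butterworth) filter the adopted rule is

$$
f_{3\mathrm{db}} = \frac{0.88}{(N_w/2 - 1)\,\mathrm{TR}}
\quad\Longrightarrow\quad
N_w = 2\left(\frac{0.88}{f_{3\mathrm{db}}\,\mathrm{TR}} + 1\right),
\qquad w = \mathrm{round}(N_w / 2),
$$

implemented in `dtw_window_from_cutoff()`. At the conventional BOLD low
cutoff (0.01 Hz) and TR = 2 s this gives $N_w = 90$ samples (180 s) and
$w = 45$ — at least as long as the 100 s (50-sample) bound an ideal filter
would demand (`window_rationale()` documents that arithmetic: 100 s
wavelength, 50 s half-wavelength shift for an anti-correlation of −1).
Both the rule and a literal integer window are accepted everywhere
(`dtw_params(window = "auto")` vs an explicit count), since either reading
of the published window heuristics may be wanted.

## Signal preparation

`design_bandpass()` finds the minimum-order Butterworth band-pass meeting
"no more than 3 dB ripple in the passband, at least 30 dB attenuation in
the stopband" via the analog-prototype order formula after bilinear
pre-warping. The natural frequencies are placed at the passband edges, so
the half-power points sit exactly there (10·log10(2) ≈ 3.0103 dB — tests
check against that exact constant, not a rounded 3). Stop edges default to
`f_lo / 2` and `min(f_hi + 0.05, 0.98 * Nyquist)` and are recorded in the
spec so a design is reproducible from its serialized form. The installed
`signal` package's own band-pass order selector mis-handles this case
(it returns a band-*stop* design), which is why the order computation is
done in-package while coefficients and filtering still come from
`signal::butter()` / `signal::filtfilt()`. Filtering is forward–backward
(zero phase; the magnitude response is squared), per subject and channel;
`zscore_panel()` then standardizes each channel. Edge transients are not
trimmed at this stage — trimming happens once, before state clustering.

## Time-resolved disparity

Dropping the summation from $D_n$ gives the per-step trace
$D_{tr}(\tau) = |x_{\varphi_x(\tau)} - y_{\varphi_y(\tau)}|^\gamma$, whose
mean over the path *is* $D_n$ exactly (`raw_trace()`; tested to machine
precision). Because $L$ varies between pairs, the trace is resampled to
the original length $N$ with the monotone piecewise cubic Hermite
interpolant (PCHIP, `signal::pchip`): shape-preserving, no overshoot below
the local data range (so the resampled trace stays nonnegative), and
continuous first derivatives. The abscissa is the path index $1..L$,
queried at $N$ uniform points — the path index is the only time scale the
trace is defined on; an alternative mapping through the mean reference
time $\tfrac12(\varphi_x + \varphi_y)$ was evaluated and performs worse
(it distorts the mean, which is the quantity the resampling must
preserve).

Resampling perturbs the mean slightly. On i.i.d. standard-Gaussian pairs
at the package defaults (N = 150, gamma = 1.5, w = 45 from the cutoff
rule) the median percentage difference between the trace mean and $D_n$
is about 1.2% — `scripts/acceptance.R` recomputes this value from scratch
on 10,000 pairs. The discrepancy shrinks with longer series and smaller
gamma (i.i.d. pairs are the worst case: heavy warping, long paths); the
grid below reproduces the dependence:

```{r sensitivity-grid}
grid_cell <- function(N, gamma, w, n_pairs = 500, seed = 1) {
  pairs <- gen_gaussian_pairs(n_pairs, N, seed)
  stats::median(vapply(pairs, function(p) {
    al <- dtw_align(p$x, p$y, dtw_params(gamma, w))
    100 * resample_trace(raw_trace(al), N)$rel_diff
  }, numeric(1)))
}
# e.g. grid_cell(150, 1.5, 45); grid_cell(1200, 1.5, 123); grid_cell(150, 0.5, 45)
```

For band-limited signals of the kind the pipeline actually consumes the
relative difference is far smaller, since the optimal paths stay close to
the diagonal.

## Surrogate null models

`phase_randomize()` draws one uniform phase sequence per subject and adds
it to *all* channels' spectra identically (DC and Nyquist untouched,
conjugate symmetry enforced). A common phase rotation leaves every
amplitude spectrum and every cross-spectrum — hence the full linear
correlation structure — unchanged to machine precision, destroying only
phase-dependent (non-stationary) structure. Phases are drawn independently
per subject; nothing in the procedure requires sharing them across
subjects. `band_residual_surrogate()` implements the four-step scheme that
confines randomization to the residual high band: randomize the wide-band
panel (Z), re-filter with the narrow-band design (Y), subtract (X = Z − Y,
avoiding an explicit high-pass whose edge response would ring at the band
boundary), and add X back to the original narrow-band data. The
0.01–0.15 Hz content of each surrogate equals the original narrow-band
panel by construction, up to the filter's transition-band tolerance
(around 10% RMS for content hugging the band edge, where attenuation is
only 3 dB). `surrogate_null_test()` compares observed pair statistics to
their surrogate distributions (rank-sum when several observations per
pair exist, the empirical rank p-value for a single observation) with
Benjamini–Hochberg correction across pairs.

## Test–retest statistics

Two sessions of a pair-metric matrix are summarized by the paired
within-subject statistic $|t|_{within} = |\bar d| / (s_d / \sqrt n)$ and a
non-parametric between-subject analogue
$|t|_{between} = \mathrm{median}(d) / (\mathrm{IQR}(d) / \sqrt n)$ on
session 1 (with $d_i = |s_{1,i} - \bar s_1|$), combined as
$trt = 1 - |t|_{within} / |t|_{between}$; values near 1 indicate high
reliability. The printed formulas are ambiguous about $\sqrt n$ vs $n$ in
the denominators; the $\sqrt n$ reading follows the named t-test
convention and is the default, with `sqrt_n = FALSE` available for the
literal reading (the ratio $trt$ is unaffected when both statistics use
the same convention). Degenerate cases are explicit: identical sessions
give $|t|_{within} = 0$ (perfect consistency, the 0/0 convention); zero
spread with nonzero mean gives an `Inf` sentinel with a warning, as does
zero IQR in the between-subject statistic.

One property worth a caution: both statistics are scale-free, and the
paired $|t|$ of pure mean-zero session noise is pivotal — its distribution
does not depend on the noise amplitude. $trt$ therefore does *not* respond
to the sheer size of unstructured session noise; it responds to
*systematic* session effects relative to residual noise. The test suite
asserts that well-posed version (trt degrades monotonically as a constant
session offset grows), not the ill-posed "less noise ⇒ higher trt".

## Recurring states and their dynamics

`disparity_tensor()` stacks the time-resolved traces over all channel
pairs and subjects; `trim_edges()` removes 5 timepoints at each end
(DTW anchors both endpoints, biasing the trace there). `fit_states()`
concatenates all subjects' timepoints (rows) over pair features (columns)
and runs k-means under the city-block distance for k = 1..10, 20 random
initializations each, with the per-feature *median* centroid update — the
L1-optimal centroid, consistent with the assignment metric (a mean-update
variant is behind a flag, since some toolboxes pair city-block assignment
with mean updates). The Lloyd loop stops on a stable assignment or a
non-improving objective; with median updates the assignment can oscillate
between tied label sets, so the objective criterion is load-bearing, and
it is suspended on iterations where an emptied cluster was re-seeded.

`select_k_elbow()` freezes a quantitative reading of "first significant
inflection of the WSS derivative": with $d_2(k)$ the discrete second
difference of the WSS curve and $d_1(k+1)$ the following slope, the score
$d_2(k)/|d_1(k+1)|$ is largest exactly where a steep descent meets a flat
tail, and the first maximum is selected. A literal argmax of $d_2$ alone
fails on curves whose first drop dwarfs everything (it would always return
k = 2); the ratio form reproduces the intended elbow on planted-elbow
curves and is unit-tested. Curves without positive curvature return a
`no_elbow` flag.

`orient_states()` produces display centroids (−(centroid − global
median)) so positive means convergence, ranks states by mean display
value into convergent / mixed / divergent roles (ties broken by state
index), and never touches the raw centroids. `state_pair_map()` keeps the
top `ceil(f · n_pairs)` pairs of the dominant sign (or half-fractions of
both signs for the mixed state), thresholding within each state's own
centroid.

Transition structure is estimated per subject by counting consecutive
label moves and row-normalizing (`transition_matrix()`); subjects with a
never-left state are flagged non-ergodic and excluded from chain
summaries (dwell time and occupancy remain defined). The aggregate matrix
pools counts before normalizing (count-weighted; a mean-of-probabilities
variant is behind a flag). Chain analytics follow the standard
definitions: stationary distribution via the left unit eigenvector
(cross-checked against power iteration in tests), spectral gap
$1 - |\lambda_2|$ with $\lambda_2$ taken by modulus (complex pairs occur
for k ≥ 3), total-variation mixing time with tolerance $10^{-3}$ from the
simplex vertex farthest from $\pi$ (the vertex of the least probable
state, since $TV(e_k, \pi) = 1 - \pi_k$), and entropy rate
$-\sum_i \pi_i \sum_j P_{ij} \log_2 P_{ij}$ reported in bits and as a
percentage of $\log_2 k$. Ergodicity is decided by matrix primitivity
(some boolean power of the adjacency pattern strictly positive, checked
to the Wielandt bound), which covers irreducibility and aperiodicity at
once. `perturb_transitions()` increments one cell at a time by a
magnitude drawn log-uniformly from $[10^{-3}, 10^{-1}]$, renormalizes the
row, and records percentage changes of the gap and entropy rate; one
magnitude per sample is shared across cells so cells stay comparable, and
structurally absent transitions can be masked out.

## What the synthetic data emulate — and what they do not

`gen_modulated_pair()`, `gen_band_limited_noise()` and
`gen_gaussian_pairs()` reproduce the sensitivity-analysis designs:
amplitude- and phase-modulated sinusoid pairs (slow sinusoidal modulators
with seeded phases; modulator shape is a package choice since only the
axes of the design are fixed), band-limited unit-variance noise for the
bandwidth sweep, and the i.i.d. Gaussian ensemble for the consistency
validation.

`gen_cohort()` plants a hidden 3-state chain (convergent / mixed /
divergent) in a two-group cohort. The emission design went through
explicit failure analysis, and the final form encodes two hard-won
constraints:

* **Paths must stay anchored.** If channels are independent signals, DTW
  paths wander across the full window and the path-index resampling
  misplaces the trace in time by many samples, erasing state boundaries.
  Every channel therefore shares one slow band-limited base signal per
  subject (bandwidth 0.25 of Nyquist), each channel receiving its own
  smooth bounded warp (≤ 2 samples — the timing confound the metric must
  resolve), which keeps every pair's optimal path near the diagonal.
* **Emission must survive z-scoring monotonically.** Multiplicative
  per-state gains do not: z-scoring rescales each channel by its whole-run
  SD, and the middle gain always lands nearest that normalizer, making
  the planted contrast non-monotone. The disparity is therefore additive:
  each channel adds an independent fast component (bandwidth 0.9 of
  Nyquist) scaled by the current state's level (defaults 0, 0.9, 2.2).

The planted chain (self-retentions 0.98 / 0.97 / 0.96, transitions routed
through the mixed state, no direct convergent–divergent moves) has dwell
times of ~25–50 samples, deliberately long relative to the few-sample
boundary resolution of the windowed time-resolved trace; the divergent
state's self-retention is boosted by 0.02 in group 2 (the
divergence-prevalence shift). Default sizes (8 subjects per group, 16
channels, 500 timepoints, TR 2 s) keep a full pipeline run in the
low minutes on one core.

What passing recovery tests do **not** show about real data: the
generator has no hemodynamic forward model, no physiological noise, no
spatial structure, and its states are exact Markov with sharp switches.
Real disparity dynamics are slower-mixing, noisier, and supported on far
more channel pairs (which helps clustering). Two quantitative limits of
the per-timepoint hard clustering are visible even on this favorable
synthetic ground and are measured by the acceptance suite: label accuracy
plateaus around 0.87–0.93 across realizations (boundary-zone timepoints
are intrinsically ambiguous at the trace's temporal resolution), and the
isolated label flips (~2% of interior timepoints) each create two
spurious state transitions, biasing off-diagonal transition-probability
estimates by more than their binomial sampling error at these run
lengths. Quantities that average over time (roles, occupancy, dwell-time
contrasts, the selected k) are robust to both effects; individual
transition probabilities inherit a method-level bias that end-to-end
recovery assertions must take into account.

## Numerical choices and degenerate inputs

* DTW ties (in filling and backtracking) prefer the diagonal predecessor,
  then the vertical, then the horizontal — paths are deterministic.
* The cost matrix is stored full-size with band-restricted computation:
  O(N·w) time, O(N·M) memory (≤ ~12 MB at the longest series considered),
  keeping indexing simple and exactness trivially auditable.
* Infeasible windows (|N − M| > w), non-finite inputs, zero-variance
  channels, too-short series for a filter, and non-ergodic chains all
  raise errors naming the offending object rather than propagating NaNs.
* `0 log 0 := 0` in the entropy rate; eigenvector components are clipped
  of negative rounding dust before renormalizing π.
* All stochastic stages take explicit integer seeds; `run_config()`
  refuses a missing seed, and `run_pipeline()` stamps outputs with a
  config hash so byte-identical reruns are checkable.

## Problem sizes used by the shipped checks

The packaged tests run the DTW oracle on 500 random small instances, the
Gaussian-pair consistency at 2,000 pairs (the acceptance script uses the
full 10,000), chain closed forms over parameter grids plus 1,000 random
ergodic matrices, and one full cohort recovery at the default study
conditions above. These sizes were chosen so the whole suite completes in
a few minutes on a single core while every assertion retains its
statistical force.
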