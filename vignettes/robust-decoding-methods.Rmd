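---
title: "Robust BMI decoding with multiplicative RNNs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust BMI decoding with multiplicative RNNs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(robustbmi)
```

## The problem

Intracortical brain–machine interfaces decode intended cursor kinematics
from multiunit spike counts recorded on chronically implanted electrode
arrays. The mapping from observed counts to intended movement — the
*recording condition* — is not stationary: electrode micromotion, unit
loss and gain, impedance changes and physiological state shift it within
and across days. A decoder fit from a short block of recent calibration
data works only while the condition it saw persists; when the condition
changes, performance can collapse without warning.

`robustbmi` implements a decoding strategy built for this regime: a
**multiplicative recurrent neural network (MRNN)** decoder trained on a
large multi-day corpus with **spike-count data augmentation**, so the
decoder has seen many recording conditions — natural and synthetic — by
the time it is used. A **feedback-intention-trained Kalman filter
(FIT-KF)** provides the standard baseline, and a synthetic multi-day
corpus generator plus a closed-loop task simulator make the whole
pipeline runnable and testable without animal data.

## The MRNN decoder

The network state is an activation vector $x \in \mathbb{R}^N$ with rates
$r = \tanh x$. Unlike a standard RNN, the input — the vector
$u(t) \in \mathbb{Z}_{\ge 0}^{E}$ of binned spike counts — does not enter
as an additive bias; it re-parameterizes the recurrent weight matrix
itself through a factorization

$$ J^{u} r \;=\; J^{xf}\,\big[(J^{fu} u) \odot (J^{fx} r)\big], $$

with $J^{xf}\!: N\times F$, $J^{fu}\!: F\times E$, $J^{fx}\!: F\times N$,
so the full $N \times N \times |u|$ tensor is never materialized and $F$
controls the complexity of the input–state interaction ($F = N$ by
default). One reading of this multiplicative interaction is that the
current spike counts *select a decoder*: the effective recurrent matrix,
and hence the computation applied to the neural history, adapts bin by
bin to the input statistics.

The continuous-time dynamics are discretized with a first-order Euler
step at the bin width $\Delta t$, with leak $\alpha = \Delta t / \tau$:

$$ x \leftarrow (1-\alpha)\,x + \alpha\,\big(J^{u} r + b^x\big), \qquad
   z = W_o\, r + b^z , $$

where $\tau$ (default 100 ms, up to ~150 ms is physiologically sensible)
sets the network's intrinsic time scale and smooths the outputs. The
equation body in the source description is a figure placeholder; the
leaky-integration form above is the standard rate-network convention
consistent with "$\tau$ sets the time scale" and $\Delta t \ll \tau$.

Two networks with $M = 2$ outputs are trained independently — one reads
out normalized 2-D velocity, the other normalized position — and share
one kinematic normalization (per-dimension maximum-absolute scaling over
the training corpus, so targets lie in $[-1, 1]$ where the $\tanh$-rate
readout is comfortable; the scales double as the conversion gains
$\gamma_v, \gamma_p$ back to workspace units).

### Initialization, and a degeneracy worth knowing about

Factor matrices are initialized i.i.d. Gaussian with variances
$g_{xf}/F$, $g_{fu}/E$, $g_{fx}/N$ (all $g = 1$); $W_o$ and $b^z$ start
at zero. A subtlety of the multiplicative architecture: if $b^x$ is
*also* exactly zero, then $x = 0$ is a fixed point of the dynamics for
every input (the input only acts through $\mathrm{diag}(J^{fu}u)$
multiplying $r = \tanh 0 = 0$), and one can show every parameter gradient
except $b^z$'s vanishes identically there — the textbook initialization
is an exact saddle and training never starts. `hf_train()` therefore
draws $b^x \sim \mathcal{N}(0, 0.1^2)$ by default (`b_x_sd`), which
breaks the degeneracy while leaving the zero-readout property of a fresh
network intact; `init_mrnn()` keeps $b^x = 0$ unless asked.

## Training

**Sequences.** Five consecutive reaching trials are concatenated into one
training sequence; the first two trials only seed the hidden state
(which starts at zero), the last three carry squared error. The window
slides with stride 1, so a day of $n$ trials yields $n-4$ sequences and
every trial except a day's first two contributes to learning.
Variable-length sequences are zero-padded into one batch with an explicit
learn mask.

**Multi-day minibatches.** Every minibatch draws sequences from *every*
training day (about `minibatch_fraction` = 1/5 of all sequences in
total), so each optimization step sees the input distributions of all
recording conditions in the corpus.

**Augmentation.** Before each step the minibatch's counts are re-perturbed:
for electrode $c$ of a sequence with true total $n$ spikes, the target
total is $\hat n = \mathrm{round}(\eta^j \eta_c n)$ with
$\eta^j \sim \mathcal{N}(1, \sigma_\text{trial}^2)$ shared across the
sequence (global rate modulation, e.g. arousal) and
$\eta_c \sim \mathcal{N}(1, \sigma_\text{electrode}^2)$ per electrode
(per-channel gain/baseline change). Defaults
$\sigma_\text{trial} = 0.045$, $\sigma_\text{electrode} = 0.3$. If
$\hat n \notin [0, 2n]$ the pair is resampled — the symmetric bound that
keeps the mean perturbed total approximately $n$ ($\hat n$ is rounded to
the nearest integer before the bound check; spikes are integers).
Surplus spikes land in uniformly random bins (increments allowed),
deficits remove uniformly chosen existing spike events; $n = 0$
electrodes are untouched. The perturbation is drawn anew on every
optimizer iteration and never applied at decode time.

**Hessian-free optimization.** The gradient comes from full
backpropagation through time on the minibatch; the search direction
solves the damped Gauss–Newton system
$(G + \lambda I)\,\delta = -\nabla L$ by conjugate gradient (at most
`max_cg_iters`, default 50, from a zero start, no preconditioner), where
$G v$ is computed matrix-free by a forward directional pass followed by a
backward pass. $\lambda$ starts at 0.1 and adapts by the
Levenberg–Marquardt reduction ratio (×1.5 when the quadratic model
over-promises, ÷1.5 when it is trustworthy); steps that do not reduce the
minibatch loss are rejected. As a classic Hessian-free economy, curvature
products may use a random subset of the minibatch
(`curvature_fraction`, default 0.5) while the gradient always uses all of
it. Snapshots are taken every `snapshot_interval` steps (default 10, with
200 total steps) and scored on held-out sequences (the last 10% of each
day, unperturbed); the best snapshot is returned, so the result is never
worse on held-out data than the initial parameters. Warm-starting from an
existing decoder's weights (`init_params`) supports the iterative
retrain-with-new-data workflow and is also how the package trains large
multi-day decoders economically: a short run on a couple of days followed
by short warm-started runs on the growing day range.

## The FIT-KF baseline

A Kalman filter on the state $z = [p_x, p_y, v_x, v_y, 1]$ (cm, cm/s,
constant bias), $z(t+\Delta t) = A z(t) + w$, $y(t) = C z(t) + q$ with
$w \sim \mathcal{N}(0, W)$, $q \sim \mathcal{N}(0, Q)$, fit by maximum
likelihood (least squares) on reach data with two FIT ingredients:

* **Intention rotation.** Training velocities are re-aimed from the
  cursor straight at the target with magnitude preserved, and zeroed
  inside the target acceptance window — the user is assumed always to
  intend motion toward the target.
* **Position feedback.** At decode time the cursor position is known to
  the user via vision, so the filter pins the position (and bias) state
  to the drawn cursor with exactly zero covariance each step and
  subtracts the position-explained activity from the observation before
  the velocity update.

Position rows of $A$ are fixed to kinematic integration
($p \leftarrow p + v\,\Delta t$); position columns of the velocity rows
are zero; $Q$ is symmetrized with a $10^{-6}$ diagonal load so it stays
invertible when electrodes outnumber bins in small fits. The canonical
bin width for this decoder family is 25 ms; the implementation fits at
the corpus's own bin width (20 ms for the default generator) rather than
resampling, which keeps the two decoders' comparisons on an identical
timebase.

## The synthetic corpus generator

No public dataset accompanies this problem, so the generator *is* the
study system, and its defaults define the desk-scale study conditions:

* **Task geometry.** Radial-8 center-out-and-back reaching: 8 peripheral
  targets at 8 cm, outward reaches of 700 ms and inward of 600 ms
  (matching the windows of the behavioral-similarity metric), each
  followed by a stationary target hold. Within every cycle of 8 outward
  reaches the target order is freshly permuted, and hold durations are
  drawn uniformly from 400–800 ms. Both randomizations matter: with a
  perfectly rhythmic corpus (fixed holds, cycled targets) the recurrent
  decoder learns to *anticipate* upcoming movement from elapsed time —
  e.g. inward velocity after exactly 500 ms at a peripheral target —
  which poisons closed-loop holds. Endpoints get 0.3 cm Gaussian scatter,
  so behavior is statistically stable but not identical across days
  (across-day behavioral similarity stays above 0.9, while neural
  conditions drift).
* **Tuning.** Rectified-linear cosine tuning per electrode:
  $\lambda_e = \max\{0,\; g_\text{day} g_e\,[b_e + o_e + d_e\,(v \cdot
  R(\theta)\,\text{pd}_e) + a_e\,(p \cdot \text{pd}_e)]\}$ in Hz, counts
  Poisson($\lambda\,\Delta t$). Defaults: baselines 15–35 Hz, depths
  0.2–0.9 Hz/(cm/s), position gains 0–0.4 Hz/cm, uniform preferred
  directions. The rectified-linear (not exponential) rate keeps mean
  rates interpretable and the regression-recovery property testable.
* **Drift.** Per-day random walks on per-electrode gains (sd 0.15/day)
  and baselines (2 Hz/day), a common preferred-direction rotation
  (0.1 rad/day), a log-normal global day gain (sd 0.05), electrode
  dropout (probability 0.05/electrode/day, gain set to 0), and with
  probability 0.2 a day instead revisits a perturbed copy of a uniformly
  chosen past condition, so chronologically distant days can be the most
  similar — the structure that makes "stale" corpora exploitable. A
  synthetic "day" under these magnitudes stands in for a multi-week
  epoch of a real chronic recording; drift magnitudes are free parameters
  of the emulation, not calibrated to any primate dataset.

What the generator does **not** emulate: spike waveforms and sorting,
cross-electrode correlation beyond shared tuning, learning or adaptation
by the user, non-Poisson count dispersion, and within-day drift. Passing
tests on this generator shows the pipeline's machinery and relative
decoder behavior under controlled nonstationarity; it does not certify
absolute performance on real arrays.

## Closed-loop simulation

The drawn cursor follows the blending law

$$ d \leftarrow \beta\,\big(d + \gamma_v\, v^\text{norm}\,\Delta t\big)
   + (1-\beta)\,\gamma_p\, p^\text{norm}, \qquad \beta = 0.99, $$

clamped to the 40 × 30 cm workspace — velocity-dominated with a slight
position contribution that offsets accumulated drift (the equation
bodies for the drawn position are elided figure placeholders in the
source description; this convex form is the reading consistent with
"β sets the amount of position versus velocity decoding"). Offline
accuracy comparisons always use $\beta = 1$, since the Kalman baseline
decodes velocity only. The FIT-KF moves the cursor by integrating its
decoded velocity, feeding the drawn position back as its known-position
input.

The **feedback user model** closes the loop without an animal: the user
watches the cursor with a reaction delay (5 bins = 100 ms), and issues
*corrective submovements* — each aimed from the visible cursor at the
target, following a minimum-jerk speed profile whose duration scales
with remaining distance (700 ms per 8 cm, clamped to 250–900 ms),
re-planned when the previous submovement ends without acquisition; the
intended velocity is zero inside the target window, and Gaussian
intention noise (2 cm/s) is added throughout. Intermittent corrective
control is the standard picture of primate cursor correction, and it
keeps the intended kinematics statistically close to the reaches the
tuning model was fitted around. Counts are emitted from the intended
velocity and the current cursor position through the day's tuning and
condition, exactly as in the generator.

Task rules mirror the behavioral protocols: 4 × 4 cm acceptance window,
500 ms hold, 5 s timeout (2 s under hand control), alternating
center/peripheral targets (radial-8) or non-overlapping random targets
in a 20 × 20 cm region; a block stops early and is marked *failed* —
scored 0 targets/min — when the success rate falls below 50% after at
least 10 trials. Metrics: targets per minute (peripheral successes over
block time), time to target (excluding the hold), dial-in time (first to
final window entry), normalized time to target (successes following
successes, per cm of inter-target distance), and offline decode
r² (squared Pearson correlation per dimension, averaged).

## Analyses

* **Electrode importance.** Per electrode, the mutual information (bits)
  between the reach-direction label and the binned count category,
  categories $\{0,1,2,3,4,5{+}\}$ (5 spikes in a 20 ms bin is already a
  250 Hz instantaneous rate). All bins of a trial are pooled under the
  trial's direction with the empirical direction priors; log base 2 is a
  convention only — the ranking is base-invariant. Ties break by
  ascending electrode index. Dropping simulates sudden loss: the top-k
  rows are zeroed, with no retraining.
* **Subspace similarity.** Per day, electrode-by-time activity is
  centered by *across-day* electrode means and eigendecomposed; the top
  K = 10 eigenvectors define the day's neural subspace, and day pairs are
  compared by the minimum principal angle (arccos of the largest singular
  value of $V_i^\top V_j$, clipped into $[0,1]$).
* **Behavioral similarity.** Trial-averaged velocity traces per target
  (700 ms after radial-target onset outward, 600 ms inward), concatenated
  over the 8 targets (10,400 ms per dimension), Pearson-correlated across
  days per dimension, and averaged over x and y.

## Desk-scale problem sizes

The package's own experiments (test suite and worked examples) run at a
deliberate desk scale chosen once: corpora of 10 days × 100 trials/day ×
32 electrodes at 20 ms bins, networks with $N = F = 30$, $\tau$ = 150 ms
for closed-loop decoders, and shortened Hessian-free schedules built on
warm-start chains (a fresh 20-step run on the two oldest days, then
10-step warm-started runs as the day range grows to 5 and 9 days; at most
12 CG iterations; curvature on half the minibatch). The full-scale
defaults (200 steps, 50 CG iterations, minibatch 1/5) remain
`hf_config()`'s defaults. Directional robustness experiments repeat over
5 seeds, evaluate each closed-loop condition over two interleaved blocks
(averaging targets/min, as in an AB AB block-set design), and compare
decoders within seed.

## Known limitations

* Closed-loop absolute performance of the MRNN at this desk scale is
  below the Kalman baseline's under unperturbed conditions; 32 modestly
  tuned electrodes carry much less per-bin information than the 96–192
  of a real array, and the recurrent decoder is the more data-hungry of
  the two. The robustness comparisons are therefore made *within*
  decoder (retained fraction of own performance) or as completion/failure
  contrasts, not as absolute rate comparisons.
* The Gauss–Newton curvature subset and the shortened schedules trade
  optimization quality for runtime; with the full-scale defaults the
  same code paths run unchanged.
* The corpus container is hierarchical JSON — human-readable and exact
  for integer counts, but not the right choice for hour-scale raw
  recordings.
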