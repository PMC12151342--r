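---
title: "Methods: virtual thermal-plaid experiments and sensorimotor encoding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual thermal-plaid experiments and sensorimotor encoding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Larval zebrafish thermoregulate by swimming in discrete bouts through
temperature gradients. When the fish controls its own stimulus — every swim
moves it through the thermal landscape — sensory input and motor output are
coupled (closed loop). When the same temperature sequence is played back to
another fish regardless of where it swims, that coupling is broken (open
loop, "yoked replay"). Comparing the two conditions isolates the
contribution of sensorimotor feedback to stimulus processing.

`thermoplaid` implements the full analysis chain for this paradigm on
simulated data: a bout-based virtual fish in a doubly periodic ("plaid")
laser-power landscape, yoked replay pairing, swim-bout detection from
tail-angle traces, a small convolutional network encoder of swim-initiation
probability, receptive-field extraction by differentiating the trained
network, conversion of receptive fields into bout-frequency modulation, a
linear decoding comparison on simulated mixed-selectivity neuron activity,
and fish-level bootstrap statistics.

## The virtual experiment

### Thermal landscape

Laser power at position $(x, y)$ (mm, from the arena's top-left corner) is

$$P(x,y) = A\left(\tfrac{1}{2}\sin\tfrac{2\pi x}{p} +
\tfrac{1}{2}\sin\tfrac{2\pi y}{p}\right) + P_0,$$

with amplitude $A = 750$ mW, offset $P_0 = 1250$ mW and axis period
$p = 15$ mm, so power spans 500–2000 mW. Along either axis the field repeats
every 15 mm; along the (1,1) diagonal — the direction in which the warmest
and coolest points alternate — the repeat distance is
$p\sqrt{2} \approx 21$ mm. Both readouts are exposed
(`plaid_repeat_distance()`); an autocorrelation-based numerical counterpart
(`plaid_diagonal_repeat_empirical()`) recovers the diagonal value from the
field itself.

Power maps to temperature through an affine calibration anchored at
500 mW → 25 °C and 2000 mW → 28 °C, the simplest map consistent with the
temperature range delivered at the sample. Temperature is treated as
instantaneous in laser power; a configurable first-order thermal lag
(`thermal_lag_s`, default off) is available for sensitivity analyses.

### Generative swim policy

Time is discretized into 40 ms bins (25 Hz). In every bin the probability of
initiating a bout is

$$\Pr(\text{bout start}) = \operatorname{logistic}\!\Big(\beta_0 +
\sum_{j=1}^{25} k^T_j\,(T_{t-j} - T_\mathrm{ref}) +
\sum_{j=1}^{25} k^B_j\,E_{t-j}\Big),$$

where $T$ is the binned temperature (°C), $E$ marks bins in which a previous
bout ended, and the kernels span a one-second history (lag 1 = 40 ms ago).
Defaults: $\beta_0 = \operatorname{logit}(0.04)$ (a 1 bout/s homogeneous
rate when both kernels are zero), $T_\mathrm{ref} = 26.5$ °C. The default
temperature kernel is biphasic — recent warmth (~80 ms) promotes swimming,
warmth around 550 ms ago suppresses it — making the virtual fish sensitive
to heating transients. The default bout-history kernel imposes a strong
refractory period decaying over ~250 ms plus a mild rebound near 500 ms,
which shapes interbout intervals into the realistic 0.5–1.8 s range.

The hazard is evaluated in *every* bin, including during an ongoing bout; a
trigger mid-bout truncates the current bout and starts a new one (a "double
bout"). This choice keeps the zero-kernel case an exact homogeneous
Bernoulli process — the calibration anchor for rate checks — at the cost of
a ~10% rate of chained bouts that a threshold detector necessarily merges.

Bout kinematics are sampled per bout: duration uniform on 100–200 ms,
displacement lognormal with median 2 mm (sdlog 0.35), and turn angle a
mixture of straight swims (70%, SD 5°) and turns (30%, |mean| 30°, SD 10°).
These distributions are consistent with the ranges reported for freely
swimming larvae; the exact forms are not printed anywhere, so the simplest
standard families were chosen once. During a bout the fish turns at onset
and translates evenly across frames; headings reflect off the 50 mm-radius
arena wall. Between bouts the fish is stationary. A synthetic 250 Hz
tail-angle trace (22 Hz sinusoidal beating at 0.5 rad during bouts, 0.01 rad
Gaussian jitter elsewhere) makes the bout detector runnable end to end.

Replay experiments receive the paired closed-loop fish's frame-level
temperature trace verbatim (`make_replay_pair()`); the replay fish moves
under the same policy, but its temperature is independent of its own
position. All randomness derives from a single integer seed per fish;
outputs are bitwise reproducible.

### What the generator emulates — and what it does not

It reproduces: discrete bout kinematics at 250 Hz, position-coupled
temperature in closed loop, exact yoked pairing, history-dependent swim
initiation with known ground-truth kernels, and mixed-selectivity neuron
activity (below). It deliberately omits: thigmotaxis and any wall-seeking
behavior (the analysis excludes the edge region anyway), habituation and
baseline phases, tracking noise on centroid and heading, tail-shape
idiosyncrasies, and — importantly — any *adaptive change of the policy
between conditions*. Both fish of a pair share one policy, so passing tests
demonstrate that the pipeline recovers what the generator put in; they do
not demonstrate that real fish change their receptive fields under
feedback, which is exactly the scientific question the pipeline exists to
ask of real data.

## Bout detection

Swim vigor is the population SD of the cumulative tail-bend angle over a
trailing 10-frame window (the first nine frames use the partial window); a
bout opens when vigor crosses 0.1 rad/frame upward and closes when it falls
below, half-open in frames. No pre-smoothing is applied to the tail angle.
A bout still open at the trace end closes at the final frame.
Displacement is the distance between 5-frame mean positions before start
and after end; turn angle is the difference of 5-frame mean-vector headings
mapped to [0°, 180°]. Bouts whose flanking windows leave the trace keep
their timing but carry `NA` kinematics. Analyses exclude bouts starting
within 4 mm of the wall (`edge_filter()`).

With the default tail-trace parameters, detection recovers >95% of
separable synthetic bouts with starts within ±2 frames (the trailing window
delays the crossing by about two frames) and produces no detections on
jitter-only traces at noise SD up to 0.02 rad.

## The swim-probability encoder

One sample per 40 ms bin: a 25-bin temperature history and a 25-bin
bout-end history (both strictly causal — the current bin never predicts
itself), labeled by whether a bout starts in the bin. The main text of the
source literature describes a one-second history while its methods mention
ten seconds; one second (25 bins) is used here because the 25 s⁻¹ factor in
the bout-frequency transform and the 25-point multiple-comparison
correction both presuppose 25 bins. The window length is a configuration
knob (`history_s`).

The network: one *linear* convolutional layer of 20 units spanning the full
history of both channels (a learned temporal basis), two dense layers of 64
units with Swish activation, dropout 0.5 after every layer (training only),
and a linear output approximating the log-odds of a bout. Training
minimizes binary cross-entropy with Adam and L2 weight decay $10^{-5}$.
Temperature inputs are standardized internally; the stored scale restores
receptive-field units. No class reweighting is applied. The train/test
split holds out a random contiguous 20% block within each experiment,
limiting leakage through autocorrelation. Per-fit seeds control
initialization, dropout, batching and the split location.

Defaults follow the 256-sample minibatch at step $10^{-3}$; the test suite
fits with minibatches of 1024 at step $2\times10^{-3}$ (linear lr–batch
scaling), which converges in fewer wall-clock seconds to the same held-out
performance. Training runs in single precision with a counter-based
generator for dropout masks seeded per batch from R's RNG, so fits remain
exactly reproducible under `set.seed()`. We found that training far beyond
~40 epochs at the data scales used in the test suite slowly *degrades*
receptive-field recovery: the network starts absorbing in-sample spurious
correlations that the tiny weight decay does not suppress. The epoch count
is therefore a genuine tuning parameter, and the suite documents the values
it uses rather than hiding them.

The circular-permutation control rotates labels relative to both input
channels by a fixed 1/3 of each experiment, destroying input–output
coupling while preserving autocorrelation and the label marginal. Encoders
trained on permuted data score at chance (held-out ROC-AUC within
[0.45, 0.55]) and provide the noise floor for receptive fields.

## Receptive fields and their behavioral effect

The receptive field is the gradient of the network's output log-odds with
respect to each input bin, averaged over a random subset of data points
(default 10,000; dropout off). For weakly correlated stimuli this is the
spike-triggered-average analogue, but it remains unbiased under the strong
autocorrelation of self-generated temperature sequences. Temperature
coefficients are reported per °C (positive = warmer past raises swim
probability); bout coefficients per bout-end event. Backpropagated
gradients agree with central finite differences to better than $10^{-4}$
relative error.

The behavioral effect of a temperature receptive field $\vec{k}$ on a
stimulus history $\vec{s}(t)$ (deviation from the trace mean) is

$$\Delta lp(t) = \vec{k}^{\,T}\vec{s}(t), \qquad
\Delta p(t) = \operatorname{logistic}\!\big(\Delta lp(t) + \bar{lp}\big) - \bar{p},
\qquad \Delta bf(t) = \Delta p(t)\cdot 25\,\mathrm{s}^{-1},$$

with $\bar{p}$ the mean bout probability per bin on the training split and
$\bar{lp} = \operatorname{logit}(\bar{p})$. The printed form of the
probability transform in the source literature is typographically garbled;
the reading above is the only one under which zero log-odds modulation maps
to zero probability modulation and the modulation floors at $-\bar{p}$, as
"modulation around the mean" requires. Centering the stimulus makes
$\Delta lp$ average to zero exactly, so $\Delta p$ describes modulation
around the mean rate. Summaries across experiments pool $\Delta bf$ into a
histogram and compare per-experiment SDs of paired receptive fields with a
Wilcoxon signed-rank test; per-lag differences across fit replicates use
rank-sum tests with Bonferroni correction over the 25 lags.

## Mixed-selectivity neurons and condition decoding

Synthetic neuron models stand in for fitted encoding models of real
thermosensorimotor neurons, which are not available. Each neuron's 5 Hz
drive is $w_s\,\dot{T} + w_m\,b + w_c\,\dot{T}\,b$ ($\dot{T}$ the
temperature derivative in °C/s, $b$ the bout raster), optionally rectified
at zero, convolved with an exponential calcium kernel ($\tau$ uniform on
1.5–2.5 s) plus Gaussian noise (SD 0.1). The default population mixes
sensory-only, motor-only, additive and coincidence types (20/20/20/40%);
the "mixed-selectivity" subset ($w_c \neq 0$ or rectified) is the
coincidence-detector population whose response requires temperature change
*and* movement to co-occur — the hallmark the decoding analysis exploits.

Decoding: activity of the mixed subset is pooled across all experiments,
reduced to 10 principal components, and a ridge-penalized logistic
regression classifies each 5 Hz bin as closed-loop or replay. Splits are by
*experiment* (two thirds train, stratified by condition), never by time
bin; the ridge penalty is chosen by 5-fold inner cross-validation whose
folds are also cut by experiment; 100 random splits give the AUC
distribution. Raw-input benchmarks use the four channels (temperature, bout
starts, displacement, turn) over trailing windows: a 0 s window has 5
parameters, a 10 s window 201. Bin-level classification is the primary
readout (it is what the parameter counts imply); experiment-level AUCs from
mean scores are reported alongside.

Under these study conditions the coincidence-neuron decoder is strong (the
bout-locked temperature step is a high-signal event at the default noise),
while *no* linear function of the lagged inputs can represent the
$\dot{T}\times b$ product; the only linearly available signal is a small
feedback-induced bout-rate difference. The neuron decoder therefore beats
the instantaneous input decoder in essentially every split, and — unlike in
real data, where the neural code is far noisier — the 10 s input decoder
does not close the gap. The suite asserts both directions and reports the
second honestly; this is a property of the synthetic benchmark worth
knowing before transferring conclusions to real recordings.

## Fish-level statistics

Behavioral samples are clustered: bouts within a fish are far more similar
than bouts across fish. The package's KS test therefore computes the
observed statistic on pooled values but builds its null by resampling
*whole fish* with replacement from the combined pool, with the original
number of fish per side. The p-value is the fraction of null statistics at
least as large as the observed one, floored at $1/n_\mathrm{boot}$ and never
reported as zero. A flag (`resample_within`) additionally resamples values
within each drawn fish for sensitivity checks. Type-I error at
$\alpha = 0.05$ is calibrated to [0.03, 0.07] by Monte-Carlo in the test
suite. Binned densities carry fish-level bootstrap standard errors per bin.
`ranksum()`/`signed_rank()` wrap the standard two-sided nonparametric tests,
reporting the normal z-approximation and the smaller-rank-sum convention
(fully one-sided paired differences give statistic 0).

## Numerical choices and problem sizes

- Simulation, training, gradient extraction and bootstraps are bitwise
  reproducible under a fixed seed; dropout masks use a counter-based
  generator seeded from R's RNG per batch.
- Training is single precision (ample for SGD); forward passes and
  gradients for receptive fields run in double precision.
- Degenerate inputs are rejected loudly: single-class labels, zero-length
  bout lists, calibration with equal anchors, permutation shifts of zero,
  windows longer than the experiment.
- The test suite runs at scales chosen for a single-CPU workstation: 20
  closed-loop experiments of 10 minutes (≈300k samples) with 10 encoder
  fits of 40 epochs each for kernel recovery and 10 more for the
  permutation control; 20 yoked pairs of 3
  minutes for the bout-ΔT comparison; 10 pairs with 150 neurons and 100
  splits for decoding; 500 replicate KS calibrations at 26 + 26 fish ×
  200 values with 199 bootstrap variates. Larger runs only sharpen the
  same comparisons.

## Known limitations

- The generator's fish do not adapt their policy to the feedback
  condition, so condition differences arise only through the stimulus
  statistics, not through changed sensorimotor gains.
- Because the circular shift of the permutation control is fixed (one third
  of each experiment), every control fit shares a single permuted dataset;
  resampling across fits measures only fit-to-fit variance and its
  confidence bands are anticonservative for "coefficient equals zero". The
  null fields come out flat to about 1% of the trained fields' amplitude,
  but a few lags' fit-resampled bands resolve that residual in-sample
  offset and exclude zero. A calibrated null band would need to vary the
  shift (or the dataset) across fits.
- Simulated replay temperature is piecewise constant, so per-fish *median*
  bout-wise temperature changes in replay are exactly zero on both sides of
  the bout/rest comparison; per-fish *means* instead resolve a small, real
  alignment of bouts with stimulus transients that a temperature-responsive
  policy produces even in open loop.
- The vigor threshold detector merges bouts separated by less than the
  10-frame window and splits very long bouts at mid-bout vigor dips;
  kinematic distributions are conditioned on separable bouts.
- Receptive-field estimates at individual lags are noisy when the stimulus
  is near-constant within the history window (temperature changes only at
  bouts); recovery is assessed by correlation with the generative kernel,
  not lag-wise equality.
- The linear calibration and instantaneous thermal coupling idealize the
  physical laser-to-temperature chain.
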