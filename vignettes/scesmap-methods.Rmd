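---
title: "Methods: evoked-potential detection and mapping in scES EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked-potential detection and mapping in scES EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scesmap)
```

## The problem

Epidural spinal cord stimulation (scES) mapping experiments deliver trains of
stimulation pulses while surface EMG is recorded from up to 14 leg muscles.
During an intensity ramp the voltage steps up a ladder (typically 0.1 or
0.5 V increments up to 10 V, at 2 Hz, with at least five pulses per level —
an *event*); the analyst's question is, per muscle, the lowest voltage whose
event evokes reliable short-latency muscle responses: the recruitment
threshold `V_s0`. Manual inspection of hundreds of such records is slow and
error-prone; `scesmap` automates it as a five-stage pipeline:

1. **Epoching** — cut each channel at the pulse onsets and stack the
   inter-pulse stretches as rows of a matrix, the 2-D "image" of the record.
2. **Denoising** — smooth that image with a generalized Gaussian Markov
   random field (GGMRF) estimator.
3. **Detection** — decide per segment whether an evoked potential is
   present, using a CUSUM of Gaussian log-likelihood ratios against a
   baseline noise model (the AGLR detector), with a Teager–Kaiser energy
   (TKEO) comparator as an alternative.
4. **Feature extraction** — peak-to-peak amplitude, min–max interval,
   onset latency, integrated EMG, binary activation.
5. **Visualization** — muscles × stimulation-parameter colormaps with the
   pre-threshold region masked.

## Epoching

Segments are half-open `[onset, next onset)` in 0-based sample indices. The
matrix is made rectangular by truncating every row to the *minimum*
inter-onset gap, which preserves the early-response region where detection
happens; the final pulse keeps its row only when a full minimum gap of
samples remains after it. Stimulation artifacts at segment start are
retained — the detector's model window sees them identically in baseline
and test segments, so they cancel in the comparison.

## GGMRF denoising

Each pixel `s` of the image is replaced by the minimizer of

```
|x - d_s|^q  +  sigma^q * lambda^p * sum_r b * |x - d_r|^p
```

where `d_s` is the observed pixel, `d_r` the current estimates of its
8-neighborhood, `q = 2` (Gaussian data prior), `p = 1.01` (edge-preserving),
`sigma = 1`, `lambda = 5`, `b = sqrt(2)`. Because neighbours in the row
direction are the *same post-stimulus latency in adjacent segments*, the
prior pools evidence across consecutive pulses: responses that repeat from
pulse to pulse survive, uncorrelated noise is suppressed, and — unlike a
band-pass filter — the response's shape and latency are essentially
unmoved (the package asserts an argmax shift of at most one sample on clean
templates).

Numerical choices, since only the argmin is specified by the model:

* **Optimizer**: iterated conditional modes — raster-order coordinate
  descent with a golden-section line search per pixel over
  `[min, max]` of the observed value and current neighbours (the objective
  is strictly convex there for `q = 2`, `p > 1`). Each sweep monotonically
  decreases the global MAP objective; this is asserted by a property test.
* **Boundary**: out-of-grid neighbours are clamped to the nearest edge
  pixel. The clamped-edge multigraph is symmetric, so the sweeps still
  descend one well-defined global objective.
* **Stopping**: when no pixel moves more than `tol = 0.01` µV in a sweep,
  or after `max_iters = 20` sweeps. A non-finite `tol` is the identity
  (zero sweeps).
* The neighbourhood radius is exposed (`radius = 1` is the 8-neighbourhood)
  because the appropriate size is application-dependent.

## AGLR detection

Activation is assumed to change the *variance* of the segment's amplitude
distribution, not its mean. Each segment's model window is fit with a
Gaussian by maximum likelihood (divide-by-N deviation, floored at
`sigma_floor = 1e-6` µV to guard degenerate windows); the first event of the
ramp — the lowest voltage, which does not usually trigger activation — is
pooled into the baseline model `N(mu, sigma_0^2)`, and `mu` is reused as the
common mean everywhere. The per-sample log-likelihood ratio

```
s_k = ln(sigma_0 / sigma_i) + (y_k - mu)^2 (1/sigma_0^2 - 1/sigma_i^2) / 2
```

summed over the window gives the closed-form per-segment CUSUM statistic

```
S_i = n ln(sigma_0 / sigma_i) + ((n - 1)/2) (sigma_i^2/sigma_0^2 - 1)
```

implemented exactly as printed, including the `n` vs `n - 1` coefficient
asymmetry (`symmetric = TRUE` switches the second coefficient to `n/2`, the
exact identity when `sigma_i` is the MLE about `mu`). Note `S_i` is a
divergence: a segment *quieter* than baseline also scores positive.

The dynamic threshold is `h = max(S_baseline) + sd(S_baseline)` (sample
standard deviation; the denominator convention is not specified upstream).
A segment is active when `S_i > h` strictly; an event is active when at
least 50% of its pulses are; `V_s0` is the earliest active event's voltage.

For recorded ramps the model window is the **first one eighth** of each
segment, confining the statistic to the interval where primary responses
occur and excluding secondary (late) responses. On the simulated benchmark
(below) the whole segment is modelled: its contiguous 40 ms segments contain
only the primary response, so the guard serves no purpose there.

**Onset latency** re-uses the same statistics: the segment is linearly
interpolated to 10 kHz, `s_k` is computed against the baseline model, and
the onset is the start of the first 2 ms window whose running mean exceeds
`mean + 3 sd` of `s_k` under the baseline, both in closed form
(`E[s_k] = ln r + (1 - r^2)/2`, `sd[s_k] = |1/sigma_0^2 - 1/sigma_i^2|
sigma_0^2 / sqrt(2)` with `r = sigma_0/sigma_i`). The window-start
attribution compensates the rise time of the response; on clean templates
the estimate lands within 1 ms of the true insertion point.

**TKEO comparator**: `Psi(x_k) = x_k^2 - x_(k-1) x_(k+1)`; the per-segment
maximum of `Psi` is thresholded by the same dynamic-threshold rule. It runs
on the raw matrix by default (whether the upstream comparison smoothed its
TKEO input is unstated; raw is the conventional usage).

## The synthetic world

`simulate_benchmark_signal()` reproduces the published stress test: 50
segments, the first 20 silent; one evoked-potential template per active
segment, the n-th scaled by `0.01 n`; stationary white Gaussian noise at a
requested SNR; the first 10 segments are the detection baseline. Two
choices deserve justification:

* **Template**: the activation shape is never specified upstream, so the
  default is one sinusoid cycle under a Hann window, 30 ms — a biphasic
  waveform with exactly zero endpoints and zero net area, normalized to
  unit peak. It is configurable.
* **Geometry**: the impulse train has *unit spacing on the template's time
  scale* (`delta(t - n)`), i.e. segments are contiguous and the template
  spans most of each segment. The default is 80-sample (40 ms) segments
  with a 5 ms latency margin. This matters: with sparse 500 ms segments
  (the real 2 Hz protocol) the un-smoothed AGLR is nearly as accurate as
  the smoothed detector at −10 dB, which contradicts the published
  comparison; with the contiguous geometry the package reproduces the
  reported ordering (smoothed ≈ 80% at low SNR, comparators below 50%).
* **SNR convention**: signal power is the mean square over the active
  (post-silent) region only, so silent segments do not dilute the
  difficulty implied by a given SNR; noise is stationary over the whole
  record. Whether the upstream convention included the silent region is
  unstated; the active-region convention keeps the mapping from SNR to
  difficulty independent of the silent-segment count.

`simulate_mapping_session()` emulates a full intensity ramp: each muscle
has a true threshold on the ladder; every pulse at or above it carries the
template scaled linearly with the suprathreshold voltage (`amp_gain = 50`
µV/V, i.e. 25 µV at threshold on a 0.5 V ladder — a realistic recruitment
scale against the 2 µV default background noise), at a 10 ms latency.
What the generator does *not* emulate: motor-unit physiology, M-wave/
H-reflex structure, stimulation artifacts, electrode lift, non-stationary
noise, or secondary (late) responses. A green test therefore establishes
correctness of the pipeline's statistics on its stated noise model, not
robustness to every artifact of recorded EMG.

## Evaluation

Segment-level scoring against ground truth: sensitivity, specificity,
accuracy and Dice similarity as percentages; ratios with zero denominators
are flagged undefined, never silently 100. Five-number summaries use
linear-interpolation quartiles (`quantile` type 7); the upstream convention
is unstated. `snr_sweep()` runs seeded replicates of the benchmark per SNR
and detector; per-replicate seeds are drawn once from the master seed.

## Known limitations

* **Five-value baselines are noisy.** With the protocol minimum of five
  pulses per event, `h = max + sd` of five draws has a heavy per-segment
  false-alarm rate (~15% in our Monte-Carlo); roughly one session in six
  shows a spurious sub-threshold event, so `V_s0` errs low — never high —
  on noisy sessions. This mirrors the wide specificity spread reported for
  the method on recorded data. Pooling more baseline events (when the
  experiment provides them) tightens `h`.
* **Edge calibration under heavy smoothing.** ICM smoothing leaves the
  image's edge rows — which include the first-event baseline — with ~2×
  the residual noise of interior rows on microvolt-scale sessions, which
  biases the baseline model and can collapse `V_s0` to the first
  post-baseline event. On such data run the detector on the raw matrix
  (the default in the package's session-scale tests), or enlarge the
  baseline. The benchmark path (10-row baseline spanning the edge
  gradient, amplitudes of order 0.1) is unaffected.
* The CUSUM statistic responds to variance changes in either direction;
  a segment quieter than baseline can cross `h` for long windows.
* Detection assumes one primary response per pulse (voltage ramps at 2 Hz);
  frequency ramps are visualized via integrated EMG without detection.
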