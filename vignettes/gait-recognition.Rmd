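---
title: "Methods: IMU gait recognition and assistance planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IMU gait recognition and assistance planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitrec)
```

# The problem

A soft hip-assist exoskeleton pulls the thigh forward with a belt during
the swing phase of each leg. For that to help rather than hinder, the
controller must (a) recognize the wearer's motion state — assistance is
applied during level walking and removed in the other nine states
(standing, stairs up/down, slopes up/down, turning left/right, steering
left/right) for safety — and (b) anchor the force profile to the gait
events of the coming swing: start at toe off (TO), peak at maximum hip
flexion (HMax), end at heel strike (HS). Both recognitions must run online
from body-worn inertial sensors alone: five IMUs (waist, both thighs, both
feet) each providing 3-axis angular velocity (rad/s) and 3-axis
acceleration (m/s²), 30 channels sampled at 200 Hz. Magnetometers are
deliberately unused (environmental sensitivity).

Because the legs alternate, a full cycle contains six events in a fixed
cyclic order — L-HS, R-TO, R-HMax, R-HS, L-TO, L-HMax — and the interval
between consecutive events defines the *gait phase*, labeled by its
starting event. Six phases per cycle is exactly the granularity the
planner needs: each leg's swing is delimited by its own TO and HS with its
HMax in between.

# The recognition models

## Event detection rules

Three signal rules segment the cycle without any learning:

- **HS** — falling zero crossing of the foot sagittal angular velocity
  (the ankle passes through maximum dorsiflexion as the heel lands). The
  event sample is the first sample at or past zero (`x[k] > 0 ≥ x[k+1]`
  reports `k+1`, 0-based); values within `tol = 1e-9` of zero count as
  zero so that an exact crossing is not pushed one sample late by
  floating-point residue.
- **TO** — sharp negative trough of the same channel (maximum
  plantar-flexion rate at push-off), found by a peak rule: local minima
  with prominence at least `min_prominence` (default 3× a
  median-absolute-deviation noise estimate of the channel), retained
  deepest-first under a refractory window.
- **HMax** — falling zero crossing of the thigh sagittal angular velocity:
  the hip angle's derivative vanishes at its maximum, so the
  angular-velocity crossing marks the angle peak without needing optical
  motion capture.

All detectors take a `min_separation` refractory window; the pipeline uses
a quarter of the nominal cycle period, a standard debounce for signals
with one event of each kind per cycle. Per-side detections are merged by
`build_timeline()`, which keeps the *maximum-cardinality* subsequence
consistent with the cyclic order (computed exactly by dynamic programming
over the six-phase successor chain; dropped events are reported).
`validate_event_order()` checks an existing timeline with a forgiving
walk: an event matching the expected successor, or skipping ahead of it by
at most half a cycle, is accepted (forward skips read as missed
detections); cyclic regressions and non-increasing indices are
violations. This makes a single out-of-place event cost a single
violation instead of cascading through the rest of the bout.

## Motion-state recognition: binary-tree RBF-SVM

The state classifier operates on the instantaneous standardized 30-channel
vector (per-channel z-scoring with mean and *population* standard
deviation fitted on training data only; test data reuses the training
statistics, so no leakage). Ten classes are handled by a balanced binary
tree: each internal node is a soft-margin binary SVM with an RBF kernel
separating the left half of its class list from the right half, in the
fixed order (SD, LW, US, DS, USL, DSL, TL, TR, LS, RS) — nine binary
models, tree depth four. The published description of the tree's exact
topology is not fully specified, so the balanced split over the canonical
state order is this package's deterministic choice, configurable through
the order given to `build_tree()`.

Hyperparameters follow the full-scale recognizer: penalty `C = 2` and
`gamma = "scale"`, resolved as `1 / (30 · var(all training feature
values))` — approximately `1/30` after standardization. The quadratic
program is solved by the SMO implementation in `e1071` (libsvm); the
package stores the support vectors, dual coefficients `λᵢyᵢ ∈ [−C, C]`
and bias, and evaluates its own kernel-expansion decision function
`f(x) = Σ λᵢ yᵢ K(xᵢ, x) + b`, which the test suite checks against a
hand-looped oracle to 1e-8. Prediction descends the tree by decision
sign; a value of exactly zero deterministically takes the first branch.

## Gait-phase recognition: LSTM

The phase classifier consumes length-5 sliding windows (25 ms of context)
of the standardized channels; each window's target is the label of its
*last* sample, so prediction at time *t* uses only samples *t−4 … t*
(causal, suitable for online use). The recurrent cell is the standard
LSTM on the concatenation `[h_{t−1}, x_t]`:

$$f_t = \sigma(W_f [h_{t-1}, x_t] + b_f),\quad
  i_t = \sigma(W_i [h_{t-1}, x_t] + b_i),\quad
  o_t = \sigma(W_o [h_{t-1}, x_t] + b_o)$$
$$C_t = f_t \circ C_{t-1} + i_t \circ \tanh(W_c [h_{t-1}, x_t] + b_c),
  \qquad h_t = o_t \circ \tanh(C_t)$$

The final hidden state passes through a fully connected layer with a
rectifier and a 6-way softmax. Full-scale defaults: 128 LSTM units, 32 FC
units, 200 epochs, batch 64. The loss (categorical cross-entropy), the
optimizer (Adam, learning rate 1e-3), the initialization (Glorot uniform,
seeded) and the FC nonlinearity are unspecified in the source description
and are this package's choices, fixed at conventional values. The entire
network — forward pass, backpropagation through time, Adam — is
implemented in base R; gradients are verified against central finite
differences in the test suite, and the cell against an elementwise
evaluation of the gate equations to 1e-10.

## Assistance planning

The swing-phase force imitates the rectus femoris profile:

$$F(t) = A\,\sin\!\left(\frac{\pi t}{T_a} + \alpha\right)
           \sin\!\left(\frac{\pi t}{T_a}\right) + f,
  \qquad t \in [0, T_a],$$

zero outside the window and clamped below at zero inside it. The printed
source form of this equation is typographically ambiguous; the
product-of-sinusoids reading is implemented as the default because it
vanishes at the window start and gives the phase shift α direct control of
the peak location, and a single-sinusoid form
`A·sin(πt/Ta + α) + f` is available via `form = "simple"`. Parameters:
`A` force magnitude (N; default 40 in examples, a hardware choice),
`Ta` swing period (s) = the TO→HS interval, `α` phase shift (rad),
`f` offset (N; default 2, keeping the belt taut). The peak of the product
form sits at `t* = Ta(π − α)/(2π)`, so α solving for a requested peak is
closed-form; the acceptance checks confirm the peak on a 1e-4-resolution
grid to within 1e-3·Ta. With α solved per swing, the clamp can zero a
short initial stretch of the window when `A` is large and `f` small; this
is the price of exact peak placement and is documented rather than hidden.

Online timing uses constant-cadence prediction: the next TO/HMax/HS are
the previous cycle's event times plus the previous period
(exact under constant cadence; under cadence jitter the error is bounded
by the per-cycle period change, which the test suite verifies). Assistance
is gated by motion state at swing granularity: a swing whose majority
predicted state is LW gets the (A, f) profile, any other state a zero-force
profile.

## Evaluation conventions

Confusion matrices put predictions on rows and true classes on columns and
are column-normalized (each supported column sums to 1), matching the
convention in which per-class recognition rates are read down the
diagonal. Accuracy is trace/total; F1 is macro-averaged (classes with no
support on either axis are excluded and flagged); MCC uses the multiclass
covariance form, with 0 returned when a marginal is degenerate. Splits are
always subject-wise — whole subjects on one side, deterministically by id
order (matching the 20/5 and 22/3 hold-out protocols) — and cross-
validation is subject-grouped five-fold, because per-sample splits of
highly autocorrelated 200 Hz data would leak.

# The synthetic-data generator

No public recording of the original 25-subject dataset exists, so the
package ships a generator whose defaults *are* the study conditions:
200 Hz, 1.0 s nominal cycle, gyro noise σ = 0.05 rad/s, accelerometer
noise σ = 0.10 m/s², own-leg event fractions HS = 0.00, TO = 0.60,
HMax = 0.85, legs offset by half a cycle (standard level-gait
phenomenology; the source states only the event ordering). Per-subject
variation is a ±10 % multiplicative jitter on cycle period and channel
gains. One top-level seed drives everything through a stated counter
scheme (`stream seed = (seed·7919 + subject·131 + state index) mod
2³¹−1`), so any subset regenerates identically.

The waveforms are built to satisfy the detector-facing contract exactly:
the foot sagittal gyro has its falling zero crossing at each HS truth
index and a sharp Gaussian trough (width ≈ 2.4 samples, realistic for the
push-off spike) at each TO truth index, with a square-root-shaped positive
swing lobe so the signal enters and leaves zero steeply — under noise the
crossing stays localized to within a couple of samples. The thigh gyro is
a sinusoid crossing zero (falling) at each HMax index. The remaining
channels carry cycle-locked sinusoids with spread phases. Motion states
modulate this baseline by per-channel gains and offsets (standing zeroes
the oscillation; stairs shift waist vertical acceleration; slopes shift
waist fore-aft acceleration; turning/steering bias waist yaw and pitch
rates), with every pair of states separated by more than three noise
standard deviations in at least one channel, so the ten classes are
learnable by construction.

What the generator does *not* emulate: soft-tissue artifacts, drift,
sensor misalignment, double support asymmetries, within-bout cadence
drift, or biomechanically derived joint-angle trajectories. Consequently
the synthetic benchmarks demonstrate that the pipeline's machinery is
correct and that its models can recover structure they were designed for;
they do not certify accuracy on human data. A further consequence: the
synthetic signal is nearly instantaneously decodable, so lengthening the
phase-classifier window from 1 to 5 samples improves accuracy only
marginally here, while on real data temporal context matters more.

Ground-truth events that fall on the very first sample of a bout have no
preceding sample and are undetectable by the crossing rule, so recovery
rates are computed over interior events (index ≥ 3).

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own benchmark sizes: event recovery on 50 cycles at noise
0.05 rad/s; the ten-state SVM on 5 synthetic subjects × 3 cycles per
state with a 4/1 subject split, training on every 4th sample (200 Hz
samples are highly redundant) with a 4000-sample per-node cap, evenly
thinned; the six-phase LSTM with 32 hidden units for 30 epochs on
5 subjects × 10 level-walking cycles (4/1 split). Full-scale settings
(128 units, 200 epochs) remain available through the configuration.

Numerical conventions worth knowing: 0-based sample indices everywhere;
z-scoring uses the population standard deviation; constant channels are
flagged and standardized with a unit divisor; softmax subtracts the row
maximum; prediction ties break toward the lowest class index; the SVM
solver runs at libsvm's default termination tolerance 1e-3 (configurable);
and all randomness flows from explicit integer seeds, restored after use
so library calls never disturb the caller's RNG state.

# Known limitations

- The synthetic benchmark is a stand-in: published full-scale accuracies
  were measured on 25 human subjects and are not reproducible from this
  package's data.
- The binary-tree topology over the ten states is a documented default,
  not a reconstruction of the original (underspecified) tree.
- `plan_assistance()` anchors profiles at detected events of completed
  swings and `predict_assist_times()` predicts the next swing from the
  previous cycle; closing the loop on streaming data (detect → predict →
  actuate sample-by-sample) is left to the controller integrating this
  package.
- The LSTM trains on a single CPU in base R; at full scale (128 units,
  200 epochs, millions of windows) a GPU framework would be the practical
  choice — the implementation here is exact but sized for desk-scale data.
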