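---
title: "Decoding 3D reach kinematics from cortical field potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding 3D reach kinematics from cortical field potentials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

During a reach, electrocorticographic (ECoG) field potentials over
sensorimotor cortex carry a graded, time-resolved representation of the
arm's kinematics: movement speed modulates band-limited spectral power
(desynchronization of the mu and beta rhythms, synchronization of the
gamma bands) and the slow time-domain potential, and the direction of
movement is carried by the spatial pattern of these modulations across
electrodes. `reachdecode` implements a complete offline analysis of this
encoding for a 3D center-out reaching task: feature extraction from
multichannel voltages, a hierarchical decoder for speed and velocity,
surrogate-based significance testing, cross-condition (cross-arm)
decoder transfer, and forward-model interpretation of the decoder
weights.

Because raw intracranial recordings of this kind are not publicly
distributable, the package is built around a first-class synthetic-data
generator with a *known* forward model. Every downstream stage is tested
against the generator's ground truth; the package is equally usable on
real recordings supplied as delimited-text tables (voltages, kinematics,
and a trial-event table).

# The task model and the synthetic generator

One session consists of `n_trials` center-out reaches to the 8 corners of
a cube with 0.5 m edges, balanced across corners. Each trial has a 1 s
center hold (Hold-A, the spectral baseline), a 2 s planning delay, a
reach, and a 0.5 s exterior hold (Hold-B). Reaches follow a minimum-jerk
(quintic) profile, whose bell-shaped speed peaks at `1.875 * D / T` for a
reach of length `D` in time `T`. Hand position is sampled at 120 Hz;
slow positional jitter (Gaussian noise low-passed at 2 Hz, SD 2 mm by
default) emulates tremor and motion-capture noise, and is deliberately
gentle enough that its differentiated speed stays below the 10%-of-peak
movement threshold while still exercising it. Stored velocity is the
central difference of (jittered) position, so differentiating position
recovers the stored velocity exactly.

The voltage model writes each channel as a sum over the seven canonical
bands (theta 4-8, mu 8-12, beta-1 12-24, beta-2 24-34, gamma-1 34-55,
gamma-2 65-95, gamma-3 130-175 Hz) of a band-limited Gaussian carrier
whose instantaneous amplitude follows the kinematics log-linearly:

    amplitude_cb(t) = baseline_cb * exp(w_s * speed(t - lag) + w_v . v(t - lag))

plus a slow DC-coupled component proportional to lagged speed and
velocity (the local motor potential correlate), pink `1/f` background
noise, and optional mains interference at 60 Hz. Encoding lags live on
the analysis lag grid (50 ms steps in [-1000, 500] ms; negative lags mean
cortex leads the limb). The default ("strong") encoding uses speed
weights of -0.5 on mu/beta-1, +0.9 and +0.7 on gamma-2/3, velocity
tuning of strength 0.6 along one random preferred direction per channel
in the gamma bands (-0.3 in beta-1), slow-potential couplings of
magnitude 10 uV/(m/s) with channel-varying sign, and short neural-leading
lags (-200..0 ms). Those numbers were chosen once so that desk-scale
decoding lands in the regime the method is meant for (held-out speed
correlations above 0.7, velocity correlations in the 0.5-0.95 range) and
are not tuned per run. Carriers are amplitude-modulated narrowband
Gaussian noise rather than sinusoids so that autoregressive spectral
estimation sees realistic spectra; a consequence worth knowing is that a
band of width `B` carries only about `B * T_win` power degrees of freedom
per analysis window, which caps single-feature correlations with speed at
about 0.7 even at infinite SNR.

What the generator does *not* emulate: epileptiform activity, electrode
drift or impedance changes, movement artifacts, cross-channel correlated
noise, or any nonstationarity across the session. Passing tests on
synthetic data therefore demonstrates correctness of the pipeline and
realistic behavior of its statistics, not clinical-grade performance on
patient recordings.

# Signal conditioning

Channels excluded by visual inspection are dropped (an index list in the
configuration; there is no automatic artifact detector). Remaining
channels are re-referenced to the common average of their reference
group (one group per electrode array or amplifier bank), band-pass
filtered 0.1-260 Hz, and notch filtered at every mains harmonic below
260 Hz. No filter family is canonical for this step; the package uses
zero-phase (forward-backward) Butterworth filters -- a 2nd-order
high-pass at 0.1 Hz cascaded with a 4th-order low-pass at 260 Hz, and
2nd-order band-stop notches of 2 Hz width. The high-pass is kept at low
order because sub-hertz Butterworth corners make higher-order
transfer-function filters numerically fragile at 1200 Hz. Sample
indexing is 0-based and half-open throughout the trial segmentation.

# Feature extraction

Spectral power is estimated with the maximum-entropy (Burg) method,
order 75, in 300 ms windows stepped by 50 ms, evaluated in 2 Hz bins
centered 3-253 Hz. The Burg recursion and the analytic evaluation of the
AR power spectral density at the bin centers are implemented in C++ for
throughput (a desk-scale session needs roughly 2 x 10^5 window fits);
the recursion is verified against `stats::ar.burg` to machine precision
in the tests.

Normalization is the two-stage z-score: log power per bin is z-scored
against the pooled baseline windows (window centers within [Hold-A onset
+ 200 ms, Hold-A end] of any trial), bins are averaged within each
canonical band, and the band series is z-scored against the same
baseline a second time. The second pass is what makes a 2-bin band (mu)
and a 23-bin band (gamma-3) enter the decoder with identical baseline
variance. Baseline statistics are pooled across all trials of a session:
per-trial baselines (the natural alternative; the choice is genuinely
open) would make the z-scores noisier at no benefit for a stationary
baseline, and pooling is what gives the decoder one consistent feature
scale per session.

The local motor potential (LMP) is the second-order Savitzky-Golay fit
evaluated at the center of each 300 ms window (the canonical SG output;
closed-form projection weights, exact on quadratics), z-scored against
the same baseline windows. Window bookkeeping is identical across the
spectral and LMP paths, and the kinematic stream is averaged onto the
same frame grid with trapezoidal weights so that the frame value of a
linear signal equals its value at the window center exactly.

# Kinematics, onset, and labels

Velocity is the central difference of position; speed its norm. Movement
onset is the first frame whose speed exceeds 10% of the trial-specific
maximum (for a minimum-jerk profile this crossing sits at ~0.086 of the
movement duration), with a manual per-trial override hook for visually
corrected onsets. Movement/rest training labels use the same
trial-specific 10% threshold; whether the threshold should instead use
the session maximum is ambiguous, and the trial-specific reading keeps
onset detection and labeling consistent with each other.

# The hierarchical decoder

Decoding frames run from 2 s before each trial's detected movement onset
to the trial end. The design matrix holds every channel x feature
(7 bands + LMP) at every lag in [-1000, 500] ms (31 lags, 50 ms steps):
column (c, f, l) at frame t is feature (c, f) at window t + l. Frames
lacking full lag coverage at the session edges are dropped, not
zero-padded.

The decoder has three parts:

* **Movement/rest classifier** -- elastic-net logistic regression
  (`glmnet`) on one column per channel x feature, taken at the lag with
  maximum absolute correlation with speed (ties break toward the
  smallest, then the negative, lag). The mixing parameter (0.1, 0.5,
  0.9) and the penalty path (30 values) are searched by sevenfold
  cross-validation with folds over whole trials; classification error is
  the criterion. The 0.5 probability cut switches states.
* **Two multivariate PLS regressions** -- one trained on movement
  frames, one on rest frames, each mapping the full lagged design to
  (speed, Vx, Vy, Vz) through a shared latent space (SIMPLS). The
  component count (up to 10) minimizes sevenfold cross-validated mean
  squared error summed over the four outputs; the model then refits on
  the whole training set. A single four-output model (rather than four
  univariate ones) matches the shared-latent-structure reading of the
  method.
* **Renormalization** -- per frame, the active model's raw velocity is
  scaled to unit norm and multiplied by the predicted speed, enforcing
  `|v| = speed` exactly; negative predicted speed clamps to zero with
  zero velocity (speed is nonnegative by definition; the degenerate
  zero-vector keeps its zero).

Predicted velocities integrate (cumulative sum x 50 ms) into
trajectories; a trial scores a "target hit" when the predicted endpoint
displacement falls in the same spatial octant as the actual displacement
(the 3D reading of "same quadrant"; chance for 8 balanced targets is
12.5%).

# Evaluation and surrogate statistics

Evaluation resamples 7/8 of the trials (whole trials, never frames) for
training, 100 times at full scale and 20 times at the desk scale used by
the tests; metrics are Pearson correlations between predicted and actual
speed/velocity over concatenated test frames plus the targets-hit
percentage.

Two null constructions bracket chance performance:

* **Temporal surrogate** -- training-trial order is permuted and each
  trial's kinematic frames are circularly shifted (wrapping start to
  end), preserving each trial's value multiset and autocorrelation while
  destroying the neural-kinematic alignment; a surrogate decoder is
  trained on these kinematics and tested on the original test set.
* **Weight-shuffle surrogate** -- the (channel, feature) assignment of
  trained PLS weight blocks is permuted (lag structure intact) 100 times
  at full scale, 25 at desk scale.

For both surrogate types the actual classifier gating and the actual
predicted speed still drive state switching and velocity modulation
(only the PLS regression weights are surrogate), so surrogate speed
correlations stay positive while surrogate velocity correlations center
on zero -- differences from the actual model then isolate the PLS
model's directional information rather than the movement/rest
classification.

Actual and surrogate accuracy distributions are compared with a
two-sided rank-sum test (normal approximation with tie and continuity
correction; exhaustive enumeration when both groups have at most 10
samples). The Bonferroni family is enumerated from the analysis plan --
5 parameters x 2 hands x 2 prediction conditions x 2 surrogates at the
group level, 5 between-hand, 10 true-vs-cross, and 160 per-patient
comparisons -- giving m = 215 and a corrected critical p of 0.00023 for
the full plan.

Cross-condition transfer applies a trained decoder unchanged (all lags
maintained) to the other session's held-out trials; it requires
identical channel sets and performs no channel matching.

# Activation patterns and movement-related statistics

Decoder weights are not encoding strengths; the forward-model activation
pattern `A = Sigma_X W Sigma_S^-1` is. `Sigma_X` is estimated from the
training features without materializing the p x p covariance
(`cov(X) M = Xc'(Xc M)/(n-1)`), and `Sigma_S` (the covariance of the
model outputs; the scalar score variance for the classifier) is
pseudo-inverted with a relative conditioning threshold of 1e-10 when
degenerate. The top 25% of |A| defines the summarized set: channel and
feature-type shares (each summing to 1 over the set, then min-max
rescaled per training repeat before averaging across repeats -- the
rescale-then-average order is a documented choice, with the raw shares
also returned), and the peak lag per selected channel x feature pair.
Cross-arm similarity is the Pearson correlation of |A| vectors.
Channel summaries project onto user-supplied 2-D electrode coordinates
as normalized Gaussian-kernel superpositions (a convex combination, so
the map never exceeds the input range); anatomical localization is out
of scope.

Movement-related activity is tested per electrode x feature x window x
hand with one-sample t tests of the onset-aligned z-scores against 0,
and between hands with two-sample t tests; all p-values are corrected
jointly with the Benjamini-Yekutieli step-up, chosen over
Benjamini-Hochberg precisely because overlapping windows make the tests
strongly dependent. Percent-active time courses per band are compared
across hands by lagged correlation (+-500 ms).

# Numerical and reproducibility choices

* Degenerate spectra (constant windows) floor at machine epsilon rather
  than erroring inside the hot loop; degenerate baselines are an error.
* Zero-variance features are excluded from lag selection with a warning
  and assigned lag 0.
* Correlations against zero-variance predictions are recorded as 0 and
  flagged rather than propagating NaN.
* All randomness (trial order, carriers and noise, splits, shuffles,
  surrogate shifts) flows from explicit integer seeds; identical
  configuration and seed reproduce results bit-identically. The run
  manifest records the configuration hash, seed, package version, and
  stage timings.
* Problem sizes: the package's study condition ("desk" preset) is 16
  channels, 160 trials, 20 train/test resamples, and 25 weight shuffles
  per resample; the acceptance script and the end-to-end tests use this
  size, while unit tests use 4-8 channels and 8-32 trials. The "full"
  preset (100 resamples, 100 shuffles) matches a complete analysis and
  is the default only for real studies.

# Known limitations

* The generator's noise is channel-independent; common-mode artifacts
  that common-average referencing is designed to remove are only
  represented by the shared mains sinusoid.
* PLS latent-dimension search is capped at 10 components; heavily
  overdetermined encodings might prefer more.
* The EDF container is not read or written; voltages and kinematics
  interchange as delimited text (and in-memory objects), which is
  lossless but larger on disk.
* Onset detection assumes one movement per trial; multi-peaked reaches
  need the manual override.
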