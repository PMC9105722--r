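---
title: "Estimating ground reaction forces from plantar pressure: models, statistics, and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ground reaction forces from plantar pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Force plates measure the ground reaction force (GRF) a runner's foot
experiences, but only in the laboratory.  Pressure-measuring insoles are
wearable, yet they record normal pressure under the foot, not the force
vector.  `grfpress` implements a complete pipeline for learning the mapping
from a 99-sensor insole, summarized into five anatomical regions, to the
time-continuous vertical and anterior--posterior (A/P) GRFs during treadmill
running across speeds and slopes — together with the statistical machinery
needed to say *where* in the stance phase a model's predictions differ
systematically from the measured forces.

Two estimator families are provided behind a common interface:

* `grf_lm()` — least-squares linear models of the form
  `GRF(q) = sum_i coef_i * PR_i(q)` where `PR_1..PR_5` are the
  mass-normalized region pressures at stance node `q`.  Coefficients can be
  solved once for all conditions (`scope = "pooled"`) or independently per
  speed/slope condition (`scope = "per_condition"`), which lets condition
  information enter without being a regressor.
* `grf_rnn()` — a bidirectional LSTM sequence-regression network
  (BiLSTM(400) → 30% dropout → BiLSTM(200) → 20% dropout → FC(300) →
  FC(150) → FC(2), hyperbolic-tangent activations, per-node outputs) that
  maps the 8 input channels (five region pressures, body mass, treadmill
  speed, slope) to both GRF components at every stance node.  A 6-channel
  variant omits speed and slope to test whether pressure alone suffices.

Everything downstream — leave-one-subject-out (LOSO) validation,
subject-specific fine-tuning, RMSE/correlation summaries, range-normalized
time-continuous percent error, and 1D statistical parametric mapping (SPM)
with random-field-theory thresholds — operates on `step_dataset` objects:
stance phases time-normalized to 101 nodes (0–100% of stance).

## Units and conventions

* Forces are modelled in body weights (BW = mass × 9.80665 m/s²); raw trial
  storage stays in newtons.
* Region pressures are divided by body mass before modelling.
* A/P force is positive during propulsion, negative during braking.
* Sample intervals are 1-based and half-open, `[on, off)`, throughout the R
  API; this is the R idiom and is documented wherever intervals are
  serialized.
* Slopes are in degrees; negative is downhill.

## The synthetic testbed

Real synchronized insole + force-plate recordings are large and proprietary
per instrument.  The simulator (`simulate_cohort()`, `simulate_steps()`)
generates the full measurement process with known ground truth so that every
pipeline stage is testable end to end.

**Waveform family.**  Each stance is a sum of raised-cosine lobes: an early
*impact* lobe (rearfoot strikers only), a whole-stance *active* lobe whose
peak grows from 2.0 to 2.8 BW between 2.6 and 3.8 m/s, a *braking* lobe
(first half of stance) and a *propulsion* lobe (second half) of ±0.25–0.45 BW
whose balance shifts with slope (uphill → more propulsion), plus two
auxiliary lobes described below.  Raised cosines were chosen for smoothness,
compact support and closed-form integrals; the amplitude ranges are
physiologically plausible defaults, not fitted values, and are frozen as the
package's study conditions.

**Planted mapping.**  The five region curves are nonnegative fixed linear
combinations of the lobes, constructed so that a *fixed, known* coefficient
pair — `planted_coefficients()` — reproduces both GRFs exactly:
`vert = A' PR / mass`, `ap = B' PR / mass`.  Two of the lobes (a
medial/lateral forefoot asymmetry and a heel/midfoot/toe load shift) lie in
the null space of both `A` and `B`: they perturb the pressure field without
changing the forces.  This matters because with only four lobes the five
region curves would span a rank-4 space and the planted coefficients would
not be identifiable; the null-space lobes give the regression design full
rank within every condition — including uphill conditions where forefoot
striking removes the impact lobe — so exact recovery is a meaningful test.

**Saturating mode.**  With `mapping_mode = "saturating"` each
mass-normalized region curve is compressed through `S * tanh(p / S)` with
fixed per-region scales before being observed.  The compression strength is
set so that the best pooled linear fit leaves a residual RMSE above 0.02 BW
on both components — a guaranteed margin for the nonlinear estimator to
exploit, mirroring the qualitative advantage a recurrent network has over a
per-curve scaling model.

**Trial assembly.**  `assemble_trial()` renders the GRFs at 2400 Hz in the
treadmill (belt-aligned) frame and the 99 sensor pressures at 100 Hz,
prepends a quiet-stance phase and three 2.5 BW half-sine synchronization
jumps (0.10 s landing impacts, the sharp transients real jump landings
produce, separated by ~1 s of near-zero load, loading the heel and toe
bands), delays the pressure stream by a configurable integer lag, and adds
Gaussian noise (clipped at zero for pressure).  Defaults: 2 N per force channel and 0.5 kPa per sensor, both
realistic for laboratory-grade instruments.  The ledger records the true
lag, the stance intervals both as continuous times and as 20 N-threshold
crossings of the low-passed noise-free vertical force (the convention the
detector uses), and noise-free per-step curves.

**Idiosyncratic subjects.**  A per-subject gain multiplies the *forces* but
not the pressures, emulating a runner whose pressure-to-force relationship
deviates from the cohort — the scenario in which subject-specific
fine-tuning should pay off.

**What the simulator does not emulate.**  Sensor-to-skin coupling drift,
spatially correlated sensor noise, foot-strike variability within a trial,
belt-speed fluctuations, curved/overground running and surface compliance.
Passing tests on synthetic cohorts therefore demonstrate the correctness of
the algorithms and the sensitivity of the statistics, not field accuracy on
any particular instrument.

## Preprocessing

`extract_steps()` composes the chain; each stage is exported:

1. `rotate_grf_to_gravity()` — planar rotation by the slope angle so the
   vertical component is parallel to gravity (a pure belt-normal force F on
   a 6° slope becomes (F·cos 6°, F·sin 6°)).
2. `lowpass_filter()` — zero-phase low-pass with the squared magnitude of a
   third-order 50 Hz Butterworth, i.e. the effective response of a
   forward–backward pass.  It is applied in the frequency domain with
   odd-reflection padding: `|H(f)|² = 1/(1+(f/50)^6)` exactly.  A
   time-domain bilinear-design filtfilt reaches the same passband but warps
   the response near Nyquist fractions (at 2400 Hz a 100 Hz sine is
   attenuated by 1/66.7 instead of the analytic 1/65) and, in the `signal`
   implementation, has unpadded edge transients; the frequency-domain form
   has unit DC gain, zero phase and no start-up artifacts by construction.
   Only the force channels are filtered; pressure curves are left as
   recorded.
3. `synchronize_streams()` — the vertical force is band-limited and
   decimated to the pressure rate and cross-correlated with the raw total
   pressure over the jump window (with near-white sensor noise the plain
   cross-correlation is the maximum-likelihood lag estimator; pre-smoothing
   the pressure would only correlate the noise).  The integer lag comes
   from a parabolic refinement of the correlation peak, which is far more
   stable than the raw argmax when two adjacent lags are nearly tied.  A
   correlation floor (default 0.6) turns ambiguous alignments into errors
   rather than silent misalignment.
4. `detect_steps()` — stance intervals are supra-threshold runs of the
   filtered vertical force (20 N, the common force-plate convention), with
   sub-threshold dips shorter than 50 ms bridged, candidates shorter than
   100 ms discarded, candidates whose peak stays below 100 N rejected as
   noise excursions, and everything before the steady-state analysis start
   excluded.  With a smooth force onset the threshold crossing has a finite
   slope (a few N per sample), so boundary precision necessarily degrades
   with force-plate noise; at the defaults boundaries match the ledger to
   ±1 sample.
5. `sum_regions()` / `time_normalize()` — five-band region sums (22/20/20/
   20/17 sensors; the anatomical layout of commercial insoles is not
   public, so the map is schematic and configurable) and linear
   interpolation onto 101 nodes.  Linear rather than spline interpolation
   avoids overshoot on ~28-frame pressure stances.  Pressure frames are
   interpolated on their true time stamps, which removes most of the
   half-frame phase misalignment between the 100 Hz and 2400 Hz streams.

Steps whose pressure window falls outside the recording after lag correction
are dropped and counted (`attr(, "dropped")`).

## The recurrent network

No deep-learning runtime is assumed: the BiLSTM forward pass,
backpropagation through time and the Adam optimizer are implemented natively
(RcppArmadillo), with the sequence laid out so that input projections, the
fully connected stack and all weight-gradient accumulations are single
matrix products.  The kernels are templated on precision — single precision
for training throughput, double precision backing the finite-difference
gradient checks in the test suite.  All randomness (weight initialization,
epoch shuffling, dropout masks, validation split) is drawn from R's RNG
under caller-supplied seeds, so runs are exactly reproducible at a fixed
thread count.

Training minimizes the mean squared error over both components and all 101
nodes.  Inputs are Z-scored per channel with statistics computed from the
training split only (`compute_norm_stats()`); applying training statistics
to a held-out subject deliberately leaves it off-centre — the no-leakage
property the LOSO harness asserts.  Dropout is active only during training.

Defaults (`rnn_options()`): Adam at 1e-3, batch 64, up to 30 epochs, early
stopping on a held-out 10% of the training *steps* with patience 5 (with
five training subjects a whole-subject validation split would cost 20% of
the cohort, so the split is at step level), fine-tuning at 0.1× the base
rate for up to 20 epochs.  The desk-scale experiments in the tests and the
acceptance script use 2e-3 and at most 15 epochs — on the easy synthetic
mapping the higher rate converges in a fraction of the epochs the full-size
problem would need — and a longer fine-tuning schedule (150 epochs at
0.25×), because ~10% of one subject's steps yields only a handful of
minibatches per epoch and the shorter default schedule leaves the
personalized model visibly undertrained.

The full-size architecture (400/200 BiLSTM, 300/150 FC) is available via
`rnn_spec(reduced = FALSE)`; the reduced desk spec (32/16, 48/24) is the
default for CPU-bound work and is what the test suite trains.

## Evaluation stack

* `rmse()` / `pearson_r()` — per-step summaries over the 101 nodes; both
  feet are evaluated together.  Cohort aggregation averages per-step values
  within each test subject first, then across subjects (mean ± SD), so each
  subject carries equal weight regardless of step count.
* `percent_error_curve()` — at each node, `100·|pred − true| / range(true)`
  with the range taken per step; steps with zero range are excluded rather
  than producing infinities.  The range normalization makes the curve
  invariant under a common affine rescaling of prediction and truth.
* `paired_t_field()` — node-wise paired t statistic with `J − 1` degrees of
  freedom; mean-centred differences are returned for smoothness estimation.
* `estimate_fwhm()` — the standard random-field gradient estimator:
  residual curves are normalized to unit sum of squares per node and
  `FWHM = sqrt(4·log 2 / mean squared gradient)`, clamped to [1, 101].
* `rft_threshold()` — the critical value solves
  `P(T > u) + resels · rho1(u) = alpha/2` per tail, with
  `resels = (n_nodes − 1)/FWHM` and the 1D Euler-characteristic density for
  t fields `rho1(u) = sqrt(4·log 2)/(2π) · (1 + u²/df)^(−(df−1)/2)`;
  bisection to 1e-6.  Because only the expected-EC correction is added, the
  threshold is always at least the pointwise two-tailed t quantile and
  decreases as the field gets smoother.
* `spm_paired_test()` — composes the above; significant clusters are
  maximal runs with `|t|` above the threshold (set-level inference only; no
  cluster-extent p-values).  A zero-variance difference field — e.g. perfect
  predictions — is reported as "no significant clusters" with a warning
  instead of an error.  The two-tailed test allots α/2 per tail.
* `subject_level_spm()` — samples a fixed number of steps (default 18)
  without replacement under a stated seed so subject-level tests have
  comparable power to the cohort-level test paired over 18 subjects.

The RFT machinery is validated internally against two independent
references: a sign-flip permutation oracle for the max-|t| distribution
(the thresholds agree within a few percent at J = 18, FWHM = 10) and a
500-replicate null simulation whose family-wise false-positive rate must
fall in [0.03, 0.08] at α = 0.05.  The smoothness estimator recovers known
Gaussian kernel FWHMs of 5–20 nodes within 15% at J = 50.  These are checks
of calibration on stationary smooth Gaussian fields; real gait residuals are
nonstationary along stance, for which RFT thresholds are known to be
slightly conservative.

## Validation harness

`run_loso()` trains the chosen estimator once per fold on the training
subjects only — including normalization statistics and per-fold network
seeds derived from `(seed, fold)` — and fills a prediction array aligned
with the input dataset.  `cohort_report()` adds per-condition SPM comparing
subject-mean predicted against subject-mean measured curves (paired over
subjects), mean percent-error curves and early/late stance-window error
summaries.  `subject_report()` ranks subjects by their mean percent error
(over all nodes and conditions) and tags the lowest/median/highest-error
exemplars per component.  `finetune_experiment()` trains a generic model
without the target subject, continues training on a condition-stratified
10% sample of the target's steps, and evaluates generic and personalized
models on the identical held-out remainder — reporting RMSE, mean percent
error and the number of significant SPM nodes summed over conditions.

## Problem sizes

The test suite and `scripts/acceptance.R` run everything on analytic step
cohorts of 6 subjects × 11 conditions × 2 feet × 10 steps (1320 steps;
LOSO therefore trains ~1100-step folds) with the reduced network — sizes
chosen so a complete LOSO comparison trains in a few minutes on one core
while leaving the qualitative structure (condition coverage, subject
heterogeneity, foot strike mixture) intact.  Raw-trial pipelines (rendering
at 2400 Hz/100 Hz) are exercised on 1–2 subject cohorts.  The simulator
defaults (`sim_config()`) describe the full protocol: 18 subjects, 11
conditions, 30 steps per trial and foot.

## Known limitations

* The raw-pipeline linear fit is an errors-in-variables regression: sensor
  noise on 28-frame pressure stances attenuates and mixes coefficients even
  though predictions remain accurate; coefficient-recovery claims therefore
  hold for the analytic (noise-free) construction.
* Stance-boundary localization is threshold-based; its precision is limited
  by the force slope at the 20 N crossing and degrades with force-plate
  noise beyond ~1% of peak force.
* The medial/lateral GRF is not modelled (emitted as low-amplitude noise by
  the simulator, never predicted).
* Network training is CPU-oriented; no GPU path, no hyperparameter search.
* SPM here covers paired t tests on 1D fields only.
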