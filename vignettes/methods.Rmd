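---
title: "Classifying Go/NoGo conditions from EEG time-frequency features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Go/NoGo conditions from EEG time-frequency features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In a Go/NoGo task, frequent "Go" stimuli demand a button press and rare
"NoGo" stimuli demand withholding it. The two conditions engage partly
distinct neural processes -- response selection versus inhibition -- that
express themselves as event-related spectral perturbations (ERSPs): transient
increases (event-related synchronization) and decreases (desynchronization)
of band-limited EEG power, localized in time, frequency and cortical source.

`ersplearn` implements an end-to-end pipeline that learns, from multi-subject
EEG, which source x band x time-window power changes discriminate the two
conditions:

1. group independent component analysis (ICA) over all subjects' trials,
2. single equivalent-dipole fits of each component's scalp map, with a
   residual-variance screen for plausibly dipolar, brain-borne components,
3. ERSP estimation of the component activations and reduction to a band x
   time feature vector per subject and condition,
4. a penalized single-hidden-layer network classifier of the condition,
   with the component subset, hidden-unit count M and weight-decay penalty
   lambda chosen by nested fivefold cross-validation, and
5. interpretation of the trained network through bootstrap-validated
   hidden-unit "signatures" that map each discriminating feature back to a
   region, band, epoch and direction.

Because comparable human data are not publicly distributable, the package
carries a first-class synthetic-data module: dipolar sources with planted,
ground-truth spectral effects, so every stage can be validated against a
known truth.

# The generative model of the simulator

**Head and sensors.** Three concentric spherical shells (brain / skull /
scalp at 80 / 85 / 92 mm, skull conductivity 1/80 of brain) with the exact
series solution of the dipole potential; electrodes are a Fibonacci lattice
cap on the scalp sphere. The spherical model replaces a boundary-element
model deliberately: it is closed-form, fast, and identical between the
simulator and the dipole fitter, which enables exact recovery tests.

**Sources.** Each source emits a 1/f background (random-phase spectrum with
amplitude f^(-gamma/2), support 1-45 Hz) plus ongoing band-limited
oscillations in the five canonical bands (theta 4-8, lower alpha 9-10,
upper alpha 11-12, lower beta 13-20, upper beta 21-30 Hz). Oscillation
supports sit inside their nominal bands (e.g. theta at 5.5-6.0 Hz) so the
0.5-s analysis window's spectral mainlobe (half-width about 4 Hz) has
decayed below about half a dB at any non-adjacent band's rows; the two
alpha bands are only 1 Hz apart and cannot be insulated at this resolution.
The oscillation-to-background amplitude ratio defaults to 2, which leaves
enough oscillatory floor for planted power *decreases* to be measurable
(an attenuation can only be seen against existing band power). Per-trial
lognormal amplitude gains (sd 0.4 log-units) emulate trial-to-trial
variability and give the source marginals the heavy tails that make ICA
identifiable. Source orientations are fixed anatomical properties, drawn
once from a constant seed, not per-cohort randomness.

**Effects.** A planted effect multiplies one band's oscillation envelope by
a raised cosine over its window: gain 10^(mag/20) for an increase,
attenuation for a decrease. Epoch labels map to early = 0-0.25 s,
mid = 0.25-0.55 s, late = 0.55-0.8 s, with effect centers well inside each
epoch. Nothing in the published design quantifies these labels; the mapping
is this package's choice and is used identically by the simulator and the
signature summary.

**Reaction times.** Go RTs are truncated normal on [0.15, 1] s (mean 0.38,
sd 0.05); the study reports no RT statistics, so these are plausible-value
defaults.

**Study-scale versus desk-scale.** `default_scenario()` reproduces the full
emulated design (57 subjects, 64 channels, 160/40 trials at 512 Hz, six
sources at the catalogued equivalent-dipole coordinates, one effect per
non-empty cell of the region x band x epoch truth table).
`scaled_scenario()` is the desk-scale version every heavy test uses:
12 subjects, 24 channels, 40/10 trials simulated directly at 128 Hz, five
sources, and ten effects in four well-separated regions. The occipital
source is omitted there because it lies < 7 mm from the superior-parietal
source -- closer than any ICA can resolve at this scale. Effect magnitudes
(6.5 dB, seed regions at 0.8x) were calibrated once, by simulation, so that
pooled CV accuracy sits near 0.9-1 and the planted effects are recoverable
by the bootstrap screen; they were frozen before the acceptance suite was
written and are conditions of the study, not tuning knobs.

# Preprocessing

Zero-phase windowed-sinc FIR filters (Hamming window, transition width 25%
of the cutoff) implement the 1-50 Hz band-pass; integer-ratio resampling
decimates after an anti-alias filter, non-integer ratios use windowed-sinc
interpolation. Trials are flagged when peak-to-peak amplitude exceeds a
threshold on any channel or when the log high-frequency (> 20 Hz) power is
a robust (median/MAD) outlier across trials; the log scale matters because
trial power is roughly lognormal, and robust centering keeps contaminated
trials from masking themselves. Bad channels are interpolated with
spherical splines (order 4); the average reference is applied last. The
pipeline order is fixed: filter, downsample, epoch, reject, interpolate,
re-reference.

# Group ICA and dipole screening

Per subject, retained trials are mean-centered per channel, concatenated
across conditions, and scaled to equal total variance; subjects are then
concatenated. Extended infomax (natural-gradient block updates with
kurtosis-sign switching, after PCA whitening) estimates the unmixing; the
weight estimation subsamples columns (seeded) for speed, and components are
scaled to unit activation variance and ordered by map norm. A held-out
subject is projected through the saved weights using its own variance as
the scale, so no cohort statistic crosses a fold boundary.

Each component map gets a single equivalent dipole by grid-seeded
Nelder-Mead over location with a linear least-squares moment at each
candidate; residual variance (rv) is the unexplained map energy. Components
are kept iff rv <= 0.15 and the dipole lies in the plausible-source region
(radius <= 78 mm, outside an 8 mm central sphere) -- a geometric stand-in
for a gray-matter test, since no anatomy exists here. Across folds,
components are matched by nearest dipole location within 5 mm.

# ERSP and features

The ERSP uses a short-time Fourier transform: 0.5-s Hann windows every
0.05 s, zero-padded x2 to a 1 Hz grid, frequencies 1-30 Hz, frames -0.75 to
1.75 s. Power is converted to dB per trial (10 log10), trial-averaged, and
baseline-corrected by the mean over the -0.75..0 s frames. The "0.05-s
segments" of the original description is read as the hop, not the window: a
0.05-s window cannot give 1 Hz resolution.

Features average the ERSP over the five bands and eight 0.1-s bins covering
0-0.8 s, ordered (component, band, bin) with bin fastest, giving
p = 40 x (number of components) -- 240 for the six-component study-scale
catalog. A per-subject window shift, slope x (subject RT - cohort RT) from
an OLS regression of theta peak latency on mean Go RT (training subjects
only), is rounded to the frame grid, clamped, and applied identically to
both conditions. Finally each (subject, component) block is centered and
variance-scaled across all its entries (both conditions jointly -- the
variance-pooling question is not settled by the source description; joint
blocks make the two conditions directly comparable). Held-out subjects are
self-normalizing by construction.

# The classifier

Hidden units z_m = logistic(alpha_m0 + sum_j alpha_jm x_j) feed a single
logistic output f_NoGo = logistic(beta_0 + sum_m beta_m z_m), f_Go = 1 -
f_NoGo. The two-class single-output form is chosen deliberately: it gives
exactly M(p+2)+1 weights, matching the stated parameter count (a softmax
pair would add M+1). The loss is cross-entropy plus lambda (sum alpha_jm^2 +
sum beta_m^2); biases are excluded from the penalty, reading the penalty
formula literally, with `penalize_bias = TRUE` available because the
reference implementation of weight decay penalizes biases too (both
behaviors are tested). Training is BFGS with analytic gradients
(finite-difference-checked to 1e-6 relative) from uniform [-0.5, 0.5]
initial weights; restarts keep the best training loss; probabilities are
clamped at 1e-12 inside the loss.

# Nested cross-validation and the subset search

The sample unit is the subject x condition pair, exactly as in the emulated
design, so one subject's two conditions may straddle folds. Folds are
random, roughly equal, stratified by condition. Inside each fold the entire
stream -- group matrix, ICA, dipole fits, screening, projection, ERSP, RT
regression, scaling, subset search, training -- sees only training samples;
a manifest records every stage's sample list and `audit_manifest()` verifies
the held-out samples appear nowhere.

The component-subset search is greedy forward selection in batches with
backward elimination, seeded by the two a-priori components (nearest kept
dipoles to the thalamic and pre-SMA coordinates). With only a few dozen
samples the inner-CV misclassification rate is too quantized and too noisy
to drive a greedy search directly, so moves are accepted by paired
statistics computed on the same samples and folds: an addition must either
improve the error with a McNemar-style z of at least `select_z` (default
3.2, calibrated against the best-of-many-candidates selection null) or,
when the error is not significantly worse, improve the per-sample held-out
log-probability with z of at least `select_ce_z` (default 2.8); removals are
kept whenever they do not significantly worsen either, which breaks ties
toward smaller subsets. The selection model is a small network with a heavy
penalty (`M_select = 2`, `lambda_select = 1`) so the held-out probabilities
are smooth, and each candidate score averages `select_repeats` inner-CV
partitions. A known limitation follows from the statistics, not the code:
when planted components are strongly redundant (every component carrying
the same contrast), the last additions are genuinely indistinguishable from
selection noise and the search may stop one component short; the end-to-end
recovery results below reflect that.

The (M, lambda) grid is tuned by the median pooled CV error over restart
seeds, ties broken by the restart-robustness proportion (fraction of
restarts with error above 0.09) and then by smaller M. Pooled held-out
predictions at the winner give the confusion matrix, precision/recall/f,
binomial SE, and the trapezoid AUC of the pooled f_NoGo scores (pooled
rather than per-fold ROC, for determinism).

# Signatures

A subject qualifies for the "canonical" input when both of its conditions
are correctly predicted with winning/losing probability ratio >= 3; the
canonical X* per condition averages the qualifying subjects. Each hidden
unit m is attributed to the condition that moves its activation away from
its resting response to the neutral input x = 0 (features are per-subject
z-scores, so 0 is the subject average); "solely due to" one condition is
operationalized as >= 90% of the |beta_m|-weighted movement, otherwise
"mixed", in which case the unit is read on both canonicals. The profile
s_jm = alpha_jm X*_j is bootstrap-tested by resampling qualifying subjects
(B = 50000 by default; the model is not refit inside replicates -- the
resampled object is the signature, and refitting 50,000 networks would be
both infeasible and a different inference). Feature j is significant when
the percentile interval at the Bonferroni single-test level 0.05/(2p)
excludes zero. Significant local |s| peaks within each band segment map to
(region from the dipole catalog, condition from the unit attribution, band,
epoch from the bin, direction from the sign of the canonical band x time
panel value). A peak is only reported if its canonical panel magnitude is
at least 1.5 dB: with a dozen qualifying subjects, percentile intervals at
such extreme levels are anti-conservative, and requiring a visible panel
deviation suppresses exactly those artifacts (a peak invisible on the
time-frequency panel would not be reported by a human reader either).

Bootstrap resampling is over subjects, not trials: the signature is a
subject-mean object, so the subject is the exchangeable unit.

# Problem sizes and numerical choices

Heavy computations run at fixed, documented sizes: end-to-end recovery uses
the 12-subject scaled scenario over 20 seeds with B = 2000 bootstrap
replicates (B = 5000 in the analysis scripts); the familywise-error
simulation uses 200 replicates of 40 null features over 40 subjects at
B = 5000; ICA weight estimation subsamples to 16000 columns with a 100-pass
cap inside the CV (512 passes and a 1e-7 weight-change tolerance are the
defaults elsewhere); dipole fits use a 30-term series (truncation below
1e-3 in amplitude for sources up to 72 mm) with three grid-seeded
Nelder-Mead starts. Degenerate inputs are guarded explicitly: zero-variance
subject blocks pass through with unit scale, zero-variance feature blocks
warn and use unit scale, all-trials-rejected and no-qualifying-subject
conditions raise named errors, and optimizer divergence in the dipole fit
returns rv = 1 with the component marked outside the brain.

# What passing tests do and do not show

The simulator emulates the statistical structure the analysis assumes:
dipolar sources, 1/f background, band-limited oscillations with smooth
condition-dependent envelopes, between-subject amplitude and RT variation,
white sensor noise. It does not emulate real artifacts (blinks, muscle,
line noise), non-dipolar or moving sources, correlated sensor noise,
inter-subject anatomical variability, or any latency-RT coupling. Passing
the recovery tests therefore shows the pipeline is correct and
leakage-free under its own assumptions -- not that those assumptions hold
for any particular recording.
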