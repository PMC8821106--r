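---
title: "Measuring gait stability on rolling-hills terrain with slopegait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gait stability on rolling-hills terrain with slopegait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Everyday walking surfaces are rarely flat. Mild, continuously varying
slopes (sidewalk grades are legally capped near 3 degrees) force the
postural control system to adjust foot placement, timing and trunk posture
step by step. A standard laboratory model of such terrain is a treadmill
platform whose sagittal pitch follows a sum of slow sinusoids — a
"rolling hills" profile oscillating within ±3 degrees — while the walker's
full-body kinematics are captured optically at 100 Hz.

`slopegait` implements the complete measurement chain for this paradigm:

1. **terrain** — generation of the rolling-hills pitch signal and
   classification of steps into uphill / downhill / excluded classes;
2. **gait_synth** — a kinematic treadmill-walker simulator with exact
   per-step ground truth, so every downstream stage is testable without
   motion-capture data;
3. **signals** — zero-lag Butterworth filtering and numerical
   differentiation;
4. **events** — velocity-based heel-strike / toe-off detection from marker
   kinematics;
5. **gaitparams** — spatiotemporal measures, the mediolateral margin of
   stability, trunk posture and trunk-acceleration variability;
6. **stats** — two-way repeated-measures ANOVA with sphericity
   diagnostics, Greenhouse–Geisser correction, partial eta squared, and
   Bonferroni post-hoc tests;
7. **cli_io** — tab-delimited trial files, YAML configuration and the
   end-to-end study pipeline `run_pipeline()`.

# The terrain model

The platform pitch is

$$\theta(t) = s \sum_{i=1}^{4} a_i \sin(2\pi f_i t + \phi_i),$$

with default frequencies $f_i$ = 0.16, 0.21, 0.24 and 0.49 Hz. Only the
frequencies are protocol constants; component amplitudes and phases are
free, so the defaults use equal amplitudes and zero phases (a
deterministic signal), with `phase_seed` providing reproducible random
phases when a different realization is wanted. The scale $s$ is chosen
*after* summation so that the realized extreme over the generated horizon
equals `peak_deg` (3 degrees) exactly — the protocol states the ±3 degree
range of the terrain, not per-component amplitudes, so the normalization
is part of the generator's contract and is tested to 1e-9.

Terrain is a function of time, not of belt distance, because the platform
oscillation is a time signal in the source protocol; the walker experiences
it after completing a configurable flat lead-in (40 m by default),
measured by integrating the belt-speed channel.

**Step classification.** A step is *uphill* when the mean platform pitch
over its interval lies in the closed band [1, 3] degrees and *downhill*
in [−3, −1]; "between … and …" is read inclusively and documented here so
the band-edge tests are exact. Any step whose open interval contains a
strict local extremum of the pitch signal (a hill crest or trough) is
excluded regardless of its mean — an extremum falling exactly on a step
boundary does not exclude, since a boundary heel strike coincides with the
turning point rather than spanning it. Steps with |mean pitch| < 1 degree
inside the hills section belong to no analysis class; the *level* class is
drawn only from the middle 20 m of the 40 m flat lead-in ([10, 30) m of
belt travel, half-open).

# The synthetic walker

The simulator is kinematic: trajectories are prescribed, not produced by a
dynamic model. That is sufficient because the pipeline measures kinematics
only. In a treadmill frame, the stance heel translates backward at belt
speed $v = L/T$ (step length over step time) from a fixed landing position
$L/2$; the swing heel advances along a half-cosine profile with a
half-sine vertical clearance arc and lands $L$ ahead of the other heel.
Toe markers ride a rigid foot 0.15 m anterior to the heels. The CoM
channel oscillates mediolaterally at stride frequency (amplitude 2 cm,
well inside the heels, so the walker is constructed stable) and
vertically at step frequency; the pelvis sways anteroposteriorly by a few
millimetres. C7 sits one trunk length above the PSIS midpoint, displaced
anteriorly by $\tan(\text{lean}) \times \ell_{trunk}$ plus a step-frequency
oscillation that drives trunk-acceleration RMS.

Default parameters are typical level-walking values for healthy young
adults with normal arm swing — step length 61.6 cm, step time 0.51 s,
step width 19.8 cm, double support 30.1 % of stride, trunk lean
7.49 degrees — used as realistic centres for simulation, not as
reproduction targets. Arm-swing conditions act through documented effect
knobs: holding the arms scales step length by 0.92 (slowing derived speed)
and adds 1 degree of forward lean; active swing scales step length *and*
step time by 1.08 (leaving speed about unchanged) and straightens the
trunk by 2 degrees; trunk oscillation scales 0.8× / 1.3× so
anteroposterior acceleration RMS orders held < normal < active. These
scalings are synthetic: the protocol prescribes the arm instructions, not
their quantitative effect sizes. Any override must preserve the step-length
ordering held < normal < active.

Measurement imperfections are additive i.i.d. Gaussian marker noise
(default SD 3 mm, a typical optical capture noise floor, applied to the
seven physical markers but not to the model-derived CoM channel) and
Gaussian per-step timing jitter with SD 3 % of the step time. Identical
seeds give bit-identical trials.

What the generator does *not* emulate: impact transients, soft-tissue
artifact, marker dropout, foot rotation during push-off, arm kinematics
(arm condition acts only through its parameter effects), self-paced
belt-speed control (the belt channel is generated directly), and any
platform roll/sway/heave. Passing tests therefore certify the analysis
chain on clean, well-posed kinematics; they do not certify robustness to
every artifact of real capture sessions.

# Filtering and differentiation

All marker and CoM channels are low-pass filtered before measurement with
a zero-lag Butterworth filter: a 2nd-order design applied forward and
backward, giving a net 4th-order, zero-phase response — "4th order,
zero-lag" is read as *net* order, the dominant biomechanics convention.
No cutoff correction is applied for the double pass, so the gain at the
nominal 10 Hz cutoff is 0.5 (the squared single-pass −3 dB point); the
gain-at-cutoff test asserts exactly that. Edge transients are controlled
by odd (point-symmetric) reflection padding of at least three filter
lengths, which preserves DC levels and linear trends at the boundaries.
Platform pitch and belt speed are not filtered; they are not optical
signals. Derivatives use central differences (exact for quadratics), with
one-sided differences at the endpoints, and are always taken after
filtering.

# Event detection

Heel strikes and toe-offs are found from the anteroposterior heel and toe
coordinates expressed relative to the pelvis (PSIS midpoint — a sacrum
marker is not in the marker set): heel strike at the
positive-to-negative zero crossing of the relative heel velocity (the
maximum of relative position), toe-off at the opposite crossing of the
relative toe velocity. A position-extremum variant is available behind
`method = "position"` for robustness comparisons.

Two numerical details matter at 100 Hz:

* **Corner refinement.** Around an event the relative coordinate has a
  corner — stance translates at belt speed while the adjacent swing end or
  start is nearly flat — and both a filtered-peak search and a plain
  window arg-extremum settle on the flat side of the corner, one to two
  samples off and, worse, systematically *inflating* double support under
  noise (strikes early, toe-offs late). Candidates are therefore refined
  on the unfiltered relative signal and then snapped at most one sample
  toward the steep side when the neighbouring sample lies within half a
  stance-sample-drop of the extremum; this recovers nearest-sample
  localization on corners and is bounded by one sample on smooth signals.
* **Refractory suppression.** Candidates closer than 0.25 × the median
  inter-event interval are merged, keeping the larger-excursion one.

Force-plate verification is not available for synthetic data; it is
replaced by `check_event_integrity()` (ordering, alternation,
interleaving, toe-off placement) plus ground-truth comparison against the
generator. A residual bias of the event definition itself is worth
knowing: because events are extrema of a *relative* coordinate, any pelvis
velocity at contact shifts the extremum by pelvis velocity divided by the
heel's local deceleration; with the default 5 mm pelvis sway this is well
under one sample, but on real data with vigorous pelvis motion the
velocity-based definition inherits this bias.

# Step measures and the margin of stability

One step spans from a heel strike of one foot to the next heel strike of
the other; the step table holds one row per heel strike after the first.

* **Step length** is the hypotenuse of the anteroposterior and vertical
  heel separations at the leading heel strike (mediolateral separation is
  excluded by definition); **step width** is the absolute mediolateral
  heel separation (the measure is conventionally named but nowhere
  formally defined; lab-frame ML is used since platform roll is zero).
  Both are *read* at the midpoint of the initial double-support phase:
  with both feet planted the separation is constant over that phase and
  equals its contact-instant value, while the filtered trajectories are
  locally linear there instead of cornered, removing a ~1 % read-out
  bias.
* **Step time** is the interval between consecutive heel strikes.
  **Double-support percentage** sums the two double-support phases of the
  stride starting at the step's leading heel strike and divides by the
  stride time. Against continuous-time ground truth, per-step DST carries
  an irreducible quantization floor of about one sample per stride
  (~1 pp at 100 Hz) when event instants fall between samples.
* **Speed** is the mean of the belt-speed channel over the step.
* **Margin of stability.** The trial-level inverted pendulum has length
  $l$ = the mean 3D distance from the leading lateral heel marker to the
  CoM over all heel strikes (one pendulum per trial, not per step), and
  eigenfrequency $\omega_0 = \sqrt{g/l}$, $g$ = 9.81 m/s². The
  extrapolated centre of mass is $xCoM = CoM_p + CoM_v/\omega_0$
  (mediolateral components only, velocity from filtered central
  differences), and the mediolateral margin of stability at the leading
  heel strike is the signed distance from the xCoM to the lateral heel
  marker, mirrored between sides so that positive always means the xCoM
  lies medial to the lateral boundary of support.
* **Trunk measures.** Trunk angle is the inclination of the
  PSIS-midpoint→C7 line from global vertical in the sagittal plane
  (positive = forward lean), averaged per step. Trunk acceleration RMS
  (per axis) uses the twice-differentiated filtered C7 marker — the trunk
  point is configurable to the C7–PSIS midpoint — computed per step and
  averaged within a slope class (the per-step-then-average choice is
  documented and switchable in spirit; a per-section RMS differs only
  through step-length weighting).
* **Variability.** Coefficients of variation are
  $100 \times \mathrm{SD}/|\bar{x}|$ with the $n-1$ SD. Summaries per
  (trial × slope class) require at least 3 contributing steps
  (configurable floor).

All internal computation is in metres and seconds; reported units are cm,
%, and degrees.

# Repeated-measures statistics

Each outcome variable is analysed with a two-way within-subjects ANOVA
(arm condition × slope class, one cell mean per subject), decomposed into
subject, main-effect, interaction and effect×subject error strata;
$F = MS_{effect}/MS_{effect\times subject}$ and partial
$\eta^2 = SS_{effect}/(SS_{effect}+SS_{error})$. Normality can be screened
with `shapiro_wilk()`. For within factors with three or more levels,
Mauchly's W is computed from the covariance of orthonormal contrast
scores and the Greenhouse–Geisser $\epsilon$ rescales both degrees of
freedom; the corrected p is reported whenever Mauchly's p < 0.05.
Two-level factors cannot violate sphericity ($\epsilon \equiv 1$), which
is why slope effects always carry F(1, n−1)-type degrees of freedom while
three-level arm effects carry F(2, 2(n−1)). Post-hoc comparisons are
paired t-tests on subject-level means collapsed over the other factor,
Bonferroni-corrected by the number of comparisons *within the family*
(3 for the arm factor; per-variable ANOVAs define separate families), with
a simple-effects mode (`by_level = TRUE`) for within-slope contrasts.
Designs must be complete and balanced; nothing is imputed.

The implementation is validated three ways: an explicit-summation oracle
for every sum of squares (to 1e-9 relative on random 15-subject
fixtures), agreement with `aov()` error strata and `stats::mauchly.test`,
and a seeded null simulation in which the arm main effect rejects at
5 % ± 1.5 % over 1000 replicates.

# The study pipeline

`run_pipeline()` simulates `n_subjects` synthetic participants, each
walking one trial per arm condition over a 40 m flat lead-in followed by
rolling-hills terrain, then runs the full chain and the ANOVAs for both
contrasts (uphill vs level, downhill vs level). Between-subject parameter
variation is drawn from configurable SDs (step time 0.03 s, step length
5 cm, step width 2 cm, double-support fraction 0.02, trunk lean 1.5°) so
that subject strata carry realistic variance. The default hills section
lasts 150 s, long enough that every (subject × arm) trial yields at
least 3 steps in each slope class; the packaged tests run a 3-subject,
60 s-hills configuration, which already exercises every stage. Runs are
deterministic given the seed, to the byte, and per-trial generator seeds
derive from the run seed.

```{r, eval = FALSE}
library(slopegait)
cfg <- default_config()
cfg$study$n_subjects <- 15
res <- run_pipeline(cfg, seed = 1, out_dir = "study_out")
subset(res$anova, variable == "mos" & contrast == "uphill_vs_level")
```

# Numerical choices and degenerate inputs

* Sample indices are 1-based throughout the R interface, with half-open
  step intervals [start, end); file outputs carry times in seconds, so
  the on-disk contract is index-convention-free.
* Plateau extrema report their first sample; constant or monotone series
  have no extrema.
* A terrain configuration that sums to an identically zero signal, an
  empty frequency list, non-positive durations, cutoffs at or above
  Nyquist, fewer than two heel strikes per side, constant samples handed
  to the normality test, incomplete ANOVA designs, and rank-deficient
  contrast covariances are all hard, named errors rather than silent
  results.
* Zero-variance ANOVA outcomes are flagged `degenerate` with `NA`
  statistics instead of dividing by zero.
* Trial files round-trip doubles exactly (17 significant digits); gaps up
  to 0.1 s are linearly interpolated with a warning, longer gaps are
  errors, and millimetre-scaled files are rejected with conversion advice.

# Known limitations

The simulator's clean kinematics make the recovery tests sharp but
idealized; real marker sets bring artifacts the generator deliberately
omits (see above). The margin of stability uses the lateral heel marker
as the base-of-support boundary, the literal reading of its defining
equation; a full lateral-boundary estimate (e.g. fifth metatarsal) would
shift absolute values. Human cohort means are not reproducible from
synthetic walkers — the package's claims are about the measurement chain,
which is why acceptance focuses on terrain structure, classifier
correctness, parameter recovery, the analytic margin-of-stability chain,
statistical calibration and event-detection exactness.
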