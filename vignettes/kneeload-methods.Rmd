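---
title: "Knee contact forces by static optimization and their test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knee contact forces by static optimization and their test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeload)
```

## The problem

Musculoskeletal models estimate the muscle and joint contact forces that
cannot be measured directly in vivo. For the knee, the quantities of
clinical interest are the medial and lateral tibiofemoral compartment
contact forces (TFJ), their total and the medial share, the
patellofemoral contact force (PFJ), and the summed quadriceps and
hamstrings forces. Before such estimates can support clinical decisions,
their test-retest reliability must be known: how much of a change between
two visits is real, and how much is measurement noise, marker
re-application error, and day-to-day variation?

`kneeload` implements both halves of that question as one tested
pipeline:

1. a lower-limb rigid-body model solved by per-frame static optimization,
   turning marker trajectories and ground reaction data into knee force
   waveforms; and
2. the reliability analysis applied to its peak outputs — intraclass
   correlation coefficients (ICC), the standard error of measurement
   (SEM), and the minimal detectable change (MDC).

Because raw laboratory data cannot be redistributed, the package ships a
synthetic motion-capture study generator that emulates the standard
design (9 subjects x 2 sessions x 3 trials x {level gait, stair ascent})
with a controllable variance structure, so every stage is exercised
end to end.

## The mechanical model

The limb is five rigid segments: foot, shank, thigh, pelvis and patella.
Segment poses are estimated per frame from skin-marker clusters by
orthogonal Procrustes (least-squares rigid fit); the pelvis provides the
hip centre, and knee/ankle centres derive from epicondyle and malleolus
markers through the cluster templates. The patella has zero degrees of
freedom: its pose is a deterministic, configurable function of thigh pose
and knee flexion angle (default: rotation by 0.7 x flexion about the
femoral mediolateral axis at a 4.5 cm radius — a documented stand-in for
cadaver-derived patellar tracking, not a measurement).

For each frame the package assembles a linear equilibrium system over the
unknowns

* muscle forces `F_i` (nonnegative, bounded by `F_max = PCSA x sigma_max`,
  default `sigma_max` 31.39 N/cm^2),
* the patellar tendon force `F_pt`,
* ligament forces `L_j` (tension-only, bounded), and
* joint reaction vectors: ankle, medial and lateral tibiofemoral contact,
  hip, and patellofemoral (free 3-vectors).

The 22 equations are Newton–Euler force and moment balance of foot, shank
and thigh (moments about each segment's proximal joint centre, with the
ground wrench on the foot and full inertial terms
`m c x (a - g) + I alpha + omega x I omega`), force balance of the
massless patella, and one coupling row tying the patellar tendon to the
rho-weighted sum of the quadriceps forces (rho is a monotone lookup in
knee flexion). Reactions carry `+I` on the segment distal to a joint and
`-I` on the proximal one; contact levers are taken from the knee centre
in the shank rows and from the hip centre in the thigh rows.

The system is indeterminate (more unknowns than equations), and the
muscle/ligament distribution is resolved by minimizing the sum of cubed
stresses

$$J = \sum_i \left(\frac{F_i}{F_{max,i}}\right)^3 +
      \sum_j \left(\frac{L_j}{L_{max,j}}\right)^3$$

subject to equilibrium and bounds. Reactions do not enter the cost.

### Numerical solution

Two structural facts shape the solver:

* The costless, unbounded reaction columns are eliminated analytically
  before optimization: a QR factorization of the reaction block yields
  the left null space, and the bounded problem is solved against the
  projected constraints only. Reactions are then recovered minimum-norm
  via an SVD pseudo-inverse. The pseudo-inverse matters: the transfer of
  mediolateral shear between the two tibiofemoral contact points lies in
  the null space of the equations (it is statically indeterminate), and
  the minimum-norm resolution is the physically conservative choice.
* With a reduced muscle set, optimal solutions routinely pin antagonists
  at exactly zero force. A primal-dual interior-point method (perturbed
  KKT system with slack duals for both bounds, fraction-to-boundary
  steps, diagonal elimination to a small Schur solve per iteration)
  handles such boundary optima reliably; a pure primal barrier does not.

Convergence requires primal feasibility to `1e-8 (1 + max|b|)` and a
matching complementarity gap. A frame that cannot be solved is flagged,
not fatal; a trial is unusable when more than 20% (configurable) of its
frames fail, mirroring how trials without a satisfactory solution are
excluded from reliability analysis in practice. On synthetic studies
realized equilibrium residuals of converged frames are below `1e-7` in
max norm.

## Signal processing

* Zero-phase (forward-backward) low-pass Butterworth filtering; the
  requested order is the effective order (an order/2 design applied
  twice). Marker channels default to 6 Hz, kinetic channels to 15 Hz.
  Zero-phase filtering is chosen because stance timing must not shift;
  endpoints are handled by odd reflection padding of several cutoff
  periods, with the filter state referenced to the endpoint level so
  constants pass through exactly.
* Stance is the longest contiguous run of vertical force above a 20 N
  threshold (configurable; the threshold is a convention, not a
  measured value).
* Stance-phase signals are cubic-spline resampled to 100 points spanning
  0–100% inclusive; the spline interpolates the original samples, so
  resampling is idempotent on 100-point inputs.
* Stair trials place the instrumented step (a rigid box) on the force
  plate. Treating the box as quasi-static, the foot-step wrench is
  recovered by force/moment balance: foot force = plate force minus
  supported box weight, and the foot centre of pressure is placed on the
  top surface so the net moment about the box centre of mass vanishes,
  with any residual axial couple returned as a vertical free moment.

## Outcome variables and peaks

Medial, lateral and patellofemoral forces are magnitudes of the
corresponding reaction vectors normalized by body weight. Total TFJ is
defined as `|medial| + |lateral|` so that the two compartment shares sum
to exactly 100% pointwise; shares are flagged undefined where total TFJ
falls below 0.05 BW (0/0 protection). Quadriceps force is the sum of the
three vasti; hamstrings the sum of biceps femoris long head,
semitendinosus and semimembranosus. Peaks are maxima over the 100-point
grid, reporting the earliest grid point on ties. The peak medial share is
the peak of the share waveform (pointwise-peak reading); computing the
share at the TFJ peak instead is a one-line change on the returned
waveforms, and the pointwise reading is the package default.

## Reliability statistics

For a subjects-by-sessions matrix of peak values (subject-session means
over usable trials), the package computes:

* ICC as the two-way random, absolute-agreement, single-measures
  coefficient ICC(2,1) from the ANOVA mean squares, with the consistency
  form ICC(3,1) selectable. ICC(2,1) is the default reading of an
  unspecified SPSS two-way model.
* `SEM = SD_T1 sqrt(1 - ICC)`, with `SD_T1` the between-subject SD of
  the session-1 subject means (the reading consistent with the published
  worked examples).
* `MDC = SEM x 1.96 x sqrt(2)`.
* MDC% with the mean of the two session means as default denominator
  (this convention reproduces the published percentages; a T1-only
  denominator is available).

Waveform-level agreement uses Pearson correlation and pointwise RMS over
the 100-point grid: all unordered trial pairs within session 1, session
means between sessions, and group mean curves with pointwise normal
confidence bands.

Rounding to printed table precision (2 decimals for xBW, 1 for % and
degrees) is half-up and applied only at report time; all internal values
keep full precision. Published reliability tables for this study design
are bundled (`published_reliability()`); not every printed SEM/MDC cell
is reproducible from its own row's printed SD and ICC (the source tables
were computed from unrounded inputs), and
`consistent_published_cells()` marks exactly which cells round-trip.
Worked-example checks assert only those.

## The synthetic study generator

The generator emulates the study conditions rather than any individual's
data:

* Cohort: heights uniform on 152–185 cm, mass via body-mass index 19–31,
  matching a healthy older-adult cohort; subject-mean peak knee flexion
  varies between subjects (gait 17 ± 5 degrees, stair 60 ± 6).
* Kinematics are prescribed joint-angle curves on a planar-dominant
  chain (small out-of-plane components), built from the planted foot
  upward; gait knee flexion peaks near 24% of stance. Marker positions
  come from exactly rigid per-segment templates (18 markers), after
  which isotropic Gaussian noise (SD 1 mm) and systematic per-session
  marker offsets (SD 3 mm, emulating re-application error) are applied.
* Ground reactions: a two-peak vertical curve for gait normalized to
  unit mean over stance (impulse = body weight x stance time to within
  ~2% after discretization), a single early-peak curve for stair ascent
  normalized to a 1.05 BW peak (stair stance overlaps double support, so
  its impulse is deliberately below BW x time); heel-to-toe CoP
  progression for gait, forefoot CoP for stair; a small lateral shear
  and a ground free moment chosen so the net axial moment about the
  ankle is near zero (the deep rotators that absorb axial torque in a
  full muscle set are not modelled).
* Stance duration defaults to 1.0 s at 200 Hz with 0.15 s unloaded
  lead-in/out.
* For direct reliability-statistic testing, `generate_peak_dataset()`
  bypasses the solver: values are grand mean + subject effect +
  subject-session shift + trial noise with specified SDs, so the true
  ICC is known in closed form.

What the generator does *not* emulate: soft-tissue artifact, marker
occlusion/gaps, EMG, force-plate noise spectra, inter-trial kinematic
correlation beyond the session level, or any subject's real waveforms.
Passing tests therefore demonstrate internal consistency, numerical
correctness and estimator behaviour under a known truth — not validity
against in vivo measurements.

## The default geometry file

The bundled musculoskeletal geometry (`default_geometry_path()`) is a
reduced, file-configurable set: 18 straight-line muscle elements, the
patellar tendon, four knee ligaments (ACL/PCL/MCL/LCL) and three contact
points, with de-Leva-style segment inertia ratios. All attachment
coordinates, PCSAs and ligament bounds are synthetic placeholders — the
cadaver datasets used by full-scale models are not redistributable — and
were calibrated so that the reduced set positively spans the
three-dimensional moment demands of the synthetic tasks (including under
3 mm session marker offsets): a model whose muscles cannot produce a
demanded axial or frontal moment has no feasible solution at all. That
calibration is why the set includes dedicated rotational actuators
(tensor fasciae latae, tibialis posterior, peroneus tertius) beyond the
textbook flexor/extensor groups, and why some attachment sites are
shifted from anatomical landmarks. Muscle paths are straight lines with
optional fixed via points (frictionless), with no wrapping surfaces and
no force–length–velocity properties; strength scales with
`(mass/70)^(2/3)`. A richer file with the same schema (any element
count) drops in unchanged.

## Sizes, determinism and limitations

The full synthetic study (9 x 2 x 3 x 2 = 108 trials, ~200 stance frames
each) runs in about 2–3 minutes on one CPU and is byte-reproducible for
a fixed design seed; unit suites use single trials or small designs. A
handful of trials per study (typically 0–7 of 108, varying with seed) are
excluded because session offsets push some frames outside the reduced
muscle set's feasible cone — the same failure mode, at a similar rate, as
optimization failures in laboratory practice.

Known limitations: no pelvis/trunk equilibrium; massless quasi-static
patella; two-point knee contact with minimum-norm shear resolution; no
EMG constraints; the ICC at small n (9 subjects) is a noisy estimator,
and the package reports its Monte-Carlo spread rather than pretending
point recovery.

## A worked example

```{r example, eval = FALSE}
library(kneeload)

geom <- load_geometry()
design <- study_design(seed = 1)        # 9 x 2 x 3 x {gait, stair}
report <- run_study(design, geom, study_config())
print(report)

# reliability table for gait at printed precision
format_reliability_table(report$tables$gait)

# one trial end to end
prof <- subject_profile(mass = 72, height = 175)
trial <- generate_trial(prof, "gait", seed = 42)
res <- solve_study_trial(trial, geom, study_config())
res$peaks
```
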