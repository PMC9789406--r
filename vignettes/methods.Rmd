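---
title: "Quantifying the swim-to-walk transition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the swim-to-walk transition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polygait)
```

## The scientific problem

Elongate amphibious fishes such as *Polypterus senegalus* switch from
pectoral-fin-powered swimming to an axial-and-fin walking gait as water
becomes shallow. The interesting question is whether that switch is a
discrete change of motor program or the visible consequence of a continuous
change in muscle drive interacting with changing physical constraints
(buoyancy giving way to friction). Answering it requires a consistent
quantitative pipeline: body midlines and landmarks from high-speed video,
trial-level kinematic variables, EMG burst metrics normalized so they can be
compared across individuals, and circular statistics for the timing of
events within stroke cycles.

`polygait` implements that pipeline end to end, together with a synthetic
trial generator that carries complete ground truth. Because raw video and
EMG from such experiments are rarely deposited, every estimator in the
package is validated against the generator: each analysis stage can be run
on data whose true parameters are known exactly.

## The synthetic trial model

### Body

The body midline is constructed from its tangent angle,

$$\psi(s, t) = -\frac{2\pi}{\lambda}\,A(s)\,\cos\!\big(2\pi(f t - s/\lambda)\big),$$

with positions obtained by integrating $(\cos\psi, \sin\psi)$ along the arc
coordinate $s \in [0, 1]$ and adding a steady forward translation. To first
order in $A$ this realizes the traveling wave
$y(s,t) = A(s)\sin(2\pi(ft - s/\lambda))$, while guaranteeing three
properties a coordinate-based construction does not have: the body's arc
length is exactly one body length (BL) in every frame, points equally
spaced in $s$ are simultaneously material points and arc-length-uniform
samples, and bending shortens the nose–tail chord the way a real bent fish
does. The last property is essential: the curvature coefficient is defined
from that chord, and a parameterization with fixed horizontal extent would
hold it at zero regardless of bending. A consequence of the tangent-angle
form is that the realized lateral amplitude at a site differs from the
nominal envelope $A(s)$ by a term of order $A'(s)\lambda/2\pi$ (a standing-
wave correction); the generator therefore records the *realized* per-site
amplitude, swing distance, and maximum-amplitude timing, computed from the
noiseless continuous model, as the ground truth that estimators are held
to.

Defaults are chosen to be realistic for a ~10 cm fish at moderate speed:
body length 95 mm, wave frequency 2 cycles s⁻¹, wavelength 1 BL, amplitude
envelope growing from 0.015 BL at the nose to 0.06 BL at the tail, forward
speed 1 BL s⁻¹, 500 frames s⁻¹, 4 s trials (≈ 8 tailbeat cycles,
comfortably above the five-cycle inclusion rule).

### Pectoral fins and nose elevation

The right fin angle (interior angle nose–skull–fin-tip) oscillates
sinusoidally about 90 deg with half-range 30 deg (RoM 60 deg) at
1.2 cycles s⁻¹. The left fin is a time-warped sinusoid whose maxima are
placed *exactly* at the jittered left-adduction times: per cycle, a phase
offset is drawn from a von Mises distribution around the nominal offset
(0 deg in-phase, 180 deg out-of-phase, or a mixture for the mixed
condition) and the warp interpolates phase linearly between those anchors.
An earlier design that interpolated the phase offset itself produced
realized phases that were averages of adjacent draws — serially correlated
and no longer von Mises — which the distributional screening below rightly
rejected; anchoring the extrema removes the artifact. Nose elevation is a
raised cosine peaking at a configurable phase of the fin cycle with height
0.08 BL, in the range reported for shallow-water locomotion in this genus.

### EMG

Each electrode carries baseline Gaussian noise plus bursts of
amplitude-modulated Gaussian noise under a raised-cosine envelope. Axial
bursts occupy a fixed fraction (duty 0.35) of each tailbeat cycle, onset
phases advance by 30 deg per electrode from anterior to posterior, and
right-side channels are shifted by half a cycle, producing the
anterior-to-posterior, side-alternating activation wave. The raised-cosine
envelope makes the top-5% normalization analytically approximable and is a
reasonable smooth model of burst recruitment.

### The depth sweep

Water depth (in body depths, BD) maps to generator parameters through
configuration, not hard-coded science: the amplitude envelope scales up as
depth falls below 1 BD (more body bending once buoyant support is lost),
the left–right fin phase offset switches from 0 to 180 deg below a
threshold depth (default 0.8 BD), and anterior burst gain rises smoothly
and strictly as depth decreases while posterior gain stays fixed. The
mapping is recorded in the output so every trial's conditions are
auditable. These mappings are a stand-in: the source experiments report
trends, not per-depth envelope shapes, so the sweep emulates the structure
of the findings (fin-phase switch; anterior muscle effort rising with
constant duty factor) rather than their numerical values.

## Estimators and numerical choices

**Midlines.** Masks are skeletonized by Zhang–Suen thinning (no installed
imaging package provides 2-D thinning); spurs shorter than 5% of the
skeleton are pruned, more than two surviving endpoints is an error, and the
path is traced between endpoints by breadth-first search, which is robust
to the double-linked corners thinning can leave. Paths are resampled to 100
points equally spaced in arc length with endpoints preserved. Midline
containers enforce equal spacing to 1% — for clean resampled paths;
digitization noise legitimately violates it, so the generator disables
validation when noise is added.

**Travel frame.** The travel axis is the principal direction of the nose
path over the trial, oriented by net displacement; lateral displacement
(left positive) is the perpendicular coordinate in BL.

**Smoothing and extrema.** All peak-based estimators operate on zero-phase
Butterworth low-passed signals (default cutoffs: 6 Hz for body signals,
4 Hz for fin angles at 500 fps — well above the 1–2 Hz signals, well below
the digitization-noise band). `signal::filtfilt` applies no end padding and
produces large transients on trending signals (the x-coordinate is a ramp),
so every call is wrapped in odd-reflection padding, which is exact for
linear trends. Extremum *values and times* are refined by a local quadratic
fit over ±12.5% of a cycle: unlike a pointwise max over noisy samples,
the fit has no selection bias (a pointwise max inflates fin RoM by ~10% at
0.01 BL landmark noise; the fit recovers it within ~1%). Candidate extrema
come from sign changes of the smoothed derivative, with alternation
enforced and low-prominence wiggles (< 10% of signal range) pruned.

**Kinematic variables.** Speed is net nose displacement over duration (not
path length) in BL s⁻¹. The curvature coefficient is
$1 - \min_t d(t)/\mathrm{BL}$ over a cycle, where $d$ is the nose–tail
chord; 0 is a straight fish, 1 nose-touching-tail, and a chord exceeding
BL by more than 2% is treated as a calibration error. Swing distance sums
the planar path of a site between successive lateral extrema. Wave and fin
frequencies are means of reciprocal periods (not reciprocals of mean
periods). Nose elevation is referenced to the trial minimum (the substrate
is not separately recorded), with per-cycle maxima expressed as phases of
the corresponding fin cycle.

**Stroke phases.** Cycles are anchored at both named events: adduction
start (fin) or swing-right start (tail) at 0 deg and the opposite event at
180 deg, with each half-cycle mapped linearly. A single whole-cycle linear
map cannot honor both anchors when half-cycles are asymmetric. Bursts are
attributed to the cycle containing their onset; offsets may wrap past
360 deg and are flagged rather than discarded.

**EMG conditioning and metrics.** A zero-phase 60 Hz notch precedes a
zero-phase 40–4000 Hz band-pass (4th-order Butterworth), cutoffs clipped
below Nyquist with a warning. Burst detection thresholds a 10 ms
moving-average rectified envelope at median + 3·MAD, backtracks each
crossing to median + 1·MAD (the slow rise of a smooth envelope otherwise
delays onsets), merges gaps < 25 ms and drops bursts < 20 ms; manually
scored annotations override detection, mirroring the original workflow, and
the synthetic study uses the generator's annotations by default (the
analogue of manual scoring). Note the physics of detection latency: burst
amplitude adds to baseline noise in quadrature, so at burst-to-baseline
amplitude ratio 5 a raised-cosine burst is detectable only ~15–25 ms after
its nominal onset; sharp-onset bursts are recovered within 10 ms. RIA is
the rectified within-burst sample sum as a percentage of the theoretical
maximum (mean of the top 5% of pooled rectified amplitudes for that
electrode and fish — pooled across the fish's trials, configurable — times
the burst's sample count, so the time base cancels exactly and RIA is
invariant to channel gain). Duty factor is burst duration as a percentage
of cycle duration; values over 100% are allowed and flagged.

## Circular statistics

Degrees are the user-facing unit; radians are internal. The decision
procedure applied to every phase sample follows the sequence: a
Hermans–Rasson omnibus test (pairwise angular-difference statistic with the
2.895 coefficient; Monte-Carlo p-value, default 9999 draws, seeded,
with the +1 correction); if non-uniform, a von Mises goodness-of-fit check
(Watson U² against the ML fit, parametric-bootstrap p — the procedure is
not named in the source literature, so any calibrated GOF with the same
behavior on clear cases is acceptable and the implementation is swappable);
if the fit holds, Rayleigh's test with the standard second-order p
approximation. Non-uniform samples that fail Rayleigh (or the GOF) are
labelled multimodal and no mean or angular variance is reported for them;
unimodal samples get the circular mean and angular variance $1-\bar R$.
For ultra-concentrated samples the von Mises CDF switches to its
wrapped-normal limit (a 4096-point density grid cannot resolve
$\kappa > 200$), and an essentially point-mass sample (fitted
$\kappa > 10^6$) is accepted as the $\kappa\to\infty$ limit of the family.
Within-trial screening for purely in-sync/out-of-sync behavior runs the
same procedure with the omnibus step skipped.

Group comparisons use the Watson–Williams F with the $1 + 3/(8\kappa)$
correction (a warning flags doubtful concentration), and angular dispersion
(absolute circular distance to the own-group mean) is compared by
Kruskal–Wallis with pairwise Wilcoxon follow-ups. Bonferroni correction
takes an explicit family size so comparisons can be counted per variable.

One property of this procedure matters for interpreting study output: the
GOF step rejects true von Mises samples at its nominal rate (~5% per
sample), so across many depth-by-site cells an occasional spurious
"multimodal" label is expected even when every cell is truly unimodal. The
study-level check of the fin-phase switch therefore asserts the *switch*
(all unimodal cells above the threshold near 0 deg, all below near
180 deg, with at least one unimodal cell on each side), not that every
cell is unimodal.

## Study sizes and what passing shows

The bundled synthetic study uses 5 depths × 4 trials × 4 s — about 16
fin-phase samples per depth and ~28 bursts per electrode per depth — sizes
at which every stage's behavior is already unambiguous while the full
pipeline, including Monte-Carlo classification at 1999 draws, runs in well
under a minute. Calibration checks in the test suite use 1000–4000
replicates.

The generator emulates the statistical structure of depth-graded locomotor
trials: traveling-wave kinematics with depth-dependent amplitude, a
discrete fin-coordination switch with von Mises phase jitter, and an
anterior-to-posterior, side-alternating burst wave with depth-dependent
anterior gain. It does not emulate 3-D camera calibration error, tracking
dropouts, electrode cross-talk, within-trial speed variation, or
fish-specific idiosyncrasies. Passing tests therefore demonstrate that the
estimators and the statistical decision procedure are correct and
calibrated on data of known structure — not that any biological conclusion
about real fish is reproduced numerically.

## Known limitations

- Frames are processed independently in mask-based midline extraction; no
  temporal smoothness is enforced between frames.
- The fin angle is computed in the top-view x–y projection by default.
- Mixed-effects modelling of the linear variables (speed × depth × site
  with fish as a random effect and per-depth variance weights) is out of
  scope by design: the pipeline exports tidy per-trial tables ready for
  `nlme`/`lme4`, and does not re-implement those fits.
- Burst detection latency on smooth envelopes is bounded below by the
  signal-to-noise physics described above; studies needing precise onsets
  at low SNR should supply manual annotations, as the original workflow
  did.
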