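---
title: "Methods: high-content phenotyping of thermal escape responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-content phenotyping of thermal escape responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormescape)
```

# Overview

`wormescape` reimplements, as a tested pipeline, the analysis chain used to
phenotype *Caenorhabditis elegans* escape responses to targeted infrared
laser pulses: bright-field image stacks of a single crawling worm are
segmented, skeletonized, decomposed into eigenworm posture modes, converted
into translational and phase velocity, and discretized into a four-state
ethogram (forward, reverse, pause, omega turn); stimulus-aligned population
summaries (state fractions, mean phase velocity with SEM, escape distance)
quantify the response. A companion module converts dual-excitation BCECF
ratiometric fluorescence stacks into temperature-change maps of the laser
pulse itself.

The original study's raw recordings are not deposited, so the package ships
a synthetic locomotion generator with exact ground truth. Every stage is
validated against that truth; the cohort-level analyses in `analysis/`
operate on synthetic cohorts whose study design (20 Hz imaging, ~1 mm
worms, 100 ms pulses, escape motif, 15 s interstimulus trains) mirrors the
assays the pipeline was built for.

# The synthetic worm

The body is a traveling sinusoidal bend expressed in the tangent angle
along an arc-length-parameterized midline of length $L \approx 1$ mm:

$$\psi(s, t) = \psi_0(t) + A\,\sin\!\big(2\pi s/\lambda - 2\pi\varphi(t)\big)
  + \Theta(t)\,(s/L - \tfrac12),$$

with wavelength $\lambda = 0.9L$, bend amplitude $A \approx 0.55$ rad, and
undulation phase $\varphi$ advancing at $f$ cycles/s (0.4–0.7 in the
cohorts). The first two posture modes of this model form a quadrature pair,
which is exactly the assumption the eigenworm phase analysis rests on.
Omega turns are rendered by the $\Theta$ term as a smoothly ramped
constant-curvature coil (default total bend 5.8 rad, which collapses the
head–tail distance to ~9% of its crawling value without self-intersection;
10 rad produces a self-occluding loop with an interior hole). Turn duration
and curvature are free parameters of the generator — they are documented
defaults, not calibrated values.

Two generator choices matter for interpretation:

* **Transition ramps.** The true phase velocity decelerates into and out of
  every state transition at a capped rate (default 1.6 cycles/s²) instead
  of switching instantaneously. The spike filter (below) defines changes
  above its thresholds as physiologically impossible, so a realistic
  generator must keep genuine behavior inside that envelope; instantaneous
  transitions would be excised as artifacts, and real worms do decelerate
  over a few hundred milliseconds.
* **Background and noise.** Frames composite a dark worm (intensity 0.35)
  over a light field (0.75) carrying a static broadband plane-wave texture
  (sd 0.04, wavelengths 0.05–0.4 mm) fixed in world coordinates, plus
  additive Gaussian noise of sd 0.008 (2% of the worm–field contrast). The
  texture translates rigidly and subpixel-exactly with the stage, which is
  what makes registration testable; a real agar background also contains
  nonrigid features (condensation, lawn edges) that this model omits.

What passing tests on this material does and does not show: the pipeline's
*operations* (thresholding, midline finding, mode projection, phase
differentiation, flagging rules, registration arithmetic) are verified
against exact ground truth and independent oracles; claims about real
recordings (segmentation under uneven illumination, deep-coil posture
solving, dirt on the plate) are outside what the synthetic material can
establish.

# Segmentation

A panel of histogram threshold methods (Otsu, triangle, mean, isodata) is
polled per frame and the candidate whose largest connected component is
closest in area to the expected worm area wins; the expected area starts
from a length x width prior and becomes the running median of accepted
areas after an initialization window (25 frames). The polled mask seeds a
front propagation whose local speed is $1/(1 + ((I-\mu)/\sigma)^2)$ with
$\mu, \sigma$ the seed-interior intensity statistics; arrival times are
shortest paths on the 8-connected pixel lattice and pixels arriving within
a fixed budget (20 cost units; growth capped at 12 px from the seed) form
the refined mask. Interior holes are then filled unless they match a
looped-worm centre: area within 2–40% of the body and solidity above 0.7.

Degenerate inputs fail loudly rather than silently: constant frames, and
frames whose intensity range is below 0.08 (no object dark enough to be a
worm), return a `failed` flag.

# Skeletons and posture modes

The midline is found from the mask outline: the boundary is traced and
circularly smoothed, tips are boundary-curvature extrema constrained to be
at least 30% of the perimeter apart (ties broken by maximal separation),
the two sides are arc-length matched and averaged, and the result is
extended along its end tangents to the mask edge (boundary smoothing pulls
tips inward by 1–2 px) and resampled to N = 49 points. N is a convention,
not a measured constant. Looped masks (preserved hole) and degenerate
shapes raise a `complex` flag instead of emitting a skeleton; complex
frames are also flagged by skeleton-length outliers (beyond ±25% of the
running median).

Tangent-angle profiles (M = 48 samples) with the per-frame mean angle
removed are decomposed by SVD into an eigenworm basis; four modes suffice
for crawling postures, with the first two a quadrature pair. Because a
principal-component basis has arbitrary sign, mode 2 is calibrated so that
forward crawling winds the phase positively. By default the package uses a
deterministic reference basis built from a bundled synthetic ensemble
(three bend amplitudes plus shallow turns, fixed seed), so phase signs are
reproducible across recordings; an external basis can be loaded from CSV.

Complex frames are repaired through posture space: each mode trajectory is
fitted with a GCV-chosen smoothing spline over the good frames and
evaluated everywhere, which both bridges complex runs and lightly smooths
minor errors. Runs longer than 2 s, or touching the recording boundary,
are marked missing rather than fabricated, and reconstructed skeletons
carry a `reconstructed` flag: mode interpolation recovers undulatory
posture well, but a deep omega coil's true shape is not guaranteed by
interpolation alone, which is why turn detection does not rely on
reconstructed skeletons (see the flagging precedence below).

Head–tail orientation exploits the stimulus targets, which are known to be
at the head: at each stimulus frame the nearer endpoint becomes the head,
and the orientation propagates outward by minimizing frame-to-frame head
displacement. Anchors equidistant to both endpoints, and propagation jumps
above half a body length, produce annotation requests instead of silent
choices. Dorsoventral flips are assumed absent within a recording.

# Kinematics

Centroid tracks are smoothed per axis by a penalized spline with GCV
smoothing and Tukey-bisquare robustness iterations; speed is the magnitude
of the derivative, and its sign comes from the angle $\theta$ between the
movement vector and the centroid-to-head orientation (positive for
$\theta < \pi/2$). Zero-length movement carries the previous sign to avoid
chatter at near-zero speed.

Phase is $\varphi = \operatorname{atan2}(-a_2, a_1)/2\pi$ cycles — the
full-quadrant form of the printed two-quadrant arctangent, required for a
continuous phase — unwrapped over time; phase velocity $\omega$ is its
central-difference derivative (one-sided at the ends). Two cleaning rules
remove frames where near-zero $a_1, a_2$ let noise dominate:

1. frames adjacent to a change in $\omega$ above 0.18 cycles/s per frame
   (the printed threshold; a cycles/s² reading is available via
   `units = "per_second"`), and
2. frames within half the peak width of peaks in $|d\omega/dt|$ exceeding
   mean + 3 sd. The statistics default to the current recording (a
   population file can be supplied); because a 3-sd threshold computed on
   a nearly noiseless recording scales to zero and would flag ordinary
   fluctuations, peaks must also reach a physical floor — half the jump
   threshold expressed as a rate (1.8 cycles/s² at 20 Hz, configurable).

Removing more than half the frames marks the recording low-quality.

# Ethogram

Per-frame flags follow the printed thresholds with the precedence
turn > pause > forward/reverse: a frame is a turn when the head–tail
distance drops below half its average (posture evidence dominates during
coils, where $\omega$ is unreliable; preserved loop holes also count as
turn evidence); otherwise missing where $\omega$ was removed; otherwise a
pause when $|\omega| < 0.02$ cycles/s; otherwise forward or reverse by
sign. The average head–tail distance is the per-recording median over
non-turn-candidate frames, which is robust to the turns themselves.

The minimum bout duration is 0.25 s in seconds (5 frames at 20 Hz, 4 at
15 Hz). Sub-minimum segments are absorbed iteratively, shortest first:
reassigned to the surrounding state when both neighbors agree, merged into
the longer neighbor otherwise (ties into the preceding segment), and a
short segment at the recording boundary merges into its only neighbor.
The procedure is deterministic, idempotent, and never invents a state
label.

Population summaries resample each animal's state (nearest frame), phase
velocity (linear interpolation) and escape distance onto a common grid
with the stimulus at t = 0; state fractions are computed over non-missing
animals with n reported per time point, and SEM is sd/sqrt(n). Frames lost
to spike removal are excluded from the denominators. The same machinery
splits cohorts by modal pre-stimulus state or by the state at a single
time point (the short/long reversal classification at +2 s in
double-stimulus designs).

# Stage registration and targeting

Frame-to-frame stage motion is estimated by masked normalized
cross-correlation: frames are zero-padded, correlated in the Fourier
domain with per-offset mean and variance normalization (which removes the
aperture bias of plain correlation), and the peak is refined to 1/100 px
by evaluating the constituent correlation surfaces on a local fine grid
with matrix discrete Fourier transforms. When no mask is supplied a Hann
taper is used as the correlation weight — harmless under the per-offset
normalization and it suppresses a residual shift-proportional ripple.
During tracking, registration is restricted to a 15% border annulus minus
the dilated worm mask. Textureless regions return (0, 0) with a
low-confidence flag.

Per-frame displacements average the lag-1 estimate with lag-2 and lag-3
estimates scaled to per-frame increments, which suppresses accumulated
noise; the cumulative sum is converted to mm through the affine
pixel-to-mm calibration and anchored at the reported start position.
Calibrations (stage and galvanometer) are least-squares affine fits
requiring three non-collinear points.

The laser target is the skeleton point at arc length `fraction/2` from the
head — the midpoint of the anterior fifth for the default fraction 0.2 —
and the predicted targeting error is worm speed times one frame interval,
reflecting the one-frame lag between measurement and firing.

# Thermometry

The temperature-insensitive 440 nm channel is acquired only at the start
and end of a session and interpolated linearly per pixel; the 490/440
ratio is computed per frame (after an optional dark-offset subtraction,
default 0). The ratio–temperature slope is fitted by ordinary least
squares against known set points (23–26 °C) before and after stimulation
and the two slopes are averaged; a residual above 5% of the dynamic range
warns of nonlinearity. Pulse windows (default −0.25 to 3 s around each
onset, pulses every 6 s) are aligned on a common relative-time grid and
averaged pixel-wise; the ratio change relative to the mean of 3
pre-stimulus frames, divided by the averaged slope, gives ΔT for the full
field at every time point. The peak series is the mean over a 60 px
(37.4 µm) circular ROI centred on the beam; the centre is estimated as the
intensity-weighted centroid of the above-median part of the blurred
time-maximum map (robust when the beam is much wider than the field), with
a manual override available.

The synthetic sessions encode a spatial Gaussian (σ 85 µm, matching a
~200 µm FWHM beam) decaying exponentially (τ 2.5 s); with 6 s spacing each
pulse rides on ~9% of the previous tail, which the pre-stimulus baseline
subtraction removes, exactly as in the real procedure. Recovery oracles
use the generator's stored true ΔT field, itself closed form, and the
analytic disk average of a Gaussian
$A\,(2\sigma^2/R^2)(1 - e^{-R^2/2\sigma^2})$ checks the ROI arithmetic.

# Problem sizes and numerical choices

The shipped analyses and tests use: cohorts of 20 recordings of 2,400
frames at 20 Hz for ethogram recovery; 1,000-frame, 96 x 96 px worm-free
stacks at 2% noise for trajectory integration (drift 0.08 mm/s, a
realistic tracking-stage speed); a 12 s, 128 x 128 px rendered recording
for the end-to-end image pipeline; and 25-pulse, 101 x 101 px dual-channel
sessions per amplitude for thermometry. These sizes were chosen as the
smallest that exercise every rule with stable statistics. Ties in tip
finding break toward maximal separation; ties in bout merging toward the
preceding segment; zero-movement heading carries the previous sign; all
thresholds default to the printed analysis constants
(`pipeline_config()`).

# Known limitations

* Deep-coil skeletons are interpolated through posture space, not solved
  per frame; turn detection therefore leans on mask evidence during
  self-occlusion.
* The segmentation panel assumes a single worm and roughly uniform
  illumination; no illumination correction beyond the histogram methods is
  attempted.
* The behavioral-flag human-verification step of the original workflow is
  out of automated scope; the per-segment audit tables (`segments.csv`,
  `segment_quality.csv`) are the review surface.
* Synthetic data cannot certify performance on real recordings; it
  certifies the rules, the arithmetic, and their composition.
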