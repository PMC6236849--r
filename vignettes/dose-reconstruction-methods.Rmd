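---
title: "Methods: 4D-CBCT treatment-dose reconstruction in txdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4D-CBCT treatment-dose reconstruction in txdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(txdose)
```

# The problem

During a radiotherapy course the patient's anatomy on each treatment day
differs from the planning CT: setup is imperfect, breathing amplitude
varies, tumors shrink, organs deform. The dose actually delivered therefore
differs from the planned dose. Daily cone-beam CT (CBCT) — acquired anyway
for patient alignment — carries enough anatomical information to
reconstruct the delivered dose, provided three technical problems are
solved: the CBCT's Hounsfield numbers are not dosimetrically trustworthy,
its field of view (FOV) is smaller than the planning CT's, and for thoracic
targets the anatomy moves with breathing. `txdose` implements the standard
clinical answer: deformably register the planning CT to the daily (CB)CT,
synthesize a *pseudo-CT* (plan-CT numbers on the day geometry), compute
dose there, and warp/accumulate the dose back onto the planning CT for
comparison with the plan. For 4D (phase-sorted) imaging this is done per
respiratory phase after pairing each CBCT phase with the CT phase of
closest diaphragm position.

# Coordinate and field conventions

All geometry is world-space millimetres on axis-aligned grids; the origin
is the center of voxel `(0,0,0)` (0-based indices). Oblique direction
matrices are not supported — a deliberate limitation; both the phantom and
the public lung-landmark data are axis-aligned.

Displacement fields use the *pull* convention: a field on grid A maps a
point `x` in A to `x + d(x)` in B, and warping an image living on B onto A
samples it at `x + d(x)`. Every `vector_field` carries explicit `domain`
and `codomain` labels. The registration's *forward* field lives on the
(fixed) planning CT and points into the CBCT; pulling the CBCT-frame dose
onto the CT uses it directly, while the pseudo-CT needs the *backward*
field on the CBCT grid, obtained by numerical inversion.

Landmark files are whitespace-separated voxel-index triples, one per line,
paired across two files. The reader assumes 1-based indices (the convention
of the public lung 4D-CT benchmark); a 0-based override is provided because
the convention is not stated uniformly across datasets.

# The synthetic phantom

The phantom is the package's ground truth and defines the test conditions.
The reference anatomy (end of inhale) is an analytic HU function: an
elliptic soft-tissue body cylinder (40 HU), two lungs (-750 HU) with
elliptic cross-section, a flat base at the diaphragm plane and a domed
apex, a spinal-cord cylinder (100 HU), a spherical tumor (60 HU, default
radius 10 mm) and six vessel-like spheroids (0 HU, radius 4 mm) inside the
right lung that serve as landmarks. Tissue boundaries are blended over
3 mm so that images have usable gradients and warp consistently under
trilinear interpolation.

Breathing is one-dimensional superior–inferior motion with the cosine
phase law `s(p) = (1 - cos(2*pi*p/10))/2`, `p = 0..9`; phase 0 (end of
inhale) is the reference and `s = 1` at end of exhale. The displacement
magnitude field rises linearly from 0 at the lung apex to the diaphragm
amplitude `A_d` (default 10 mm) at the diaphragm, stays full over an 8 mm
sub-diaphragmatic plateau, and decays to zero over 18 mm in the abdomen so
the field vanishes before the image boundary — without this the ground
truth could not be represented (or inverted) on the grid. The tumor
excursion `A_t` (default 8 mm) is imposed exactly by a constant-displacement
capsule around the tumor path, blended smoothly into the diaphragm field,
so the tumor translates rigidly by `A_t * s(p)`.

The phase-to-reference pull field is written down analytically in Eulerian
form; phase images are evaluated directly as `reference(y + v_p(y))`, so
they contain *no resampling error*. The opposite-direction field is the
exact inverse of the analytic 1-D motion law, solved per point by scalar
fixed-point iteration to 1e-10 mm — it is exact inversion of a known
function, not registration. Warping any phase by its ground-truth field
reproduces the reference to ~1.5 HU mean absolute error (pure
interpolation error), which validates the field convention end to end.

CBCT degradation applies, in order: a rigid setup shift of the image
content, a global intensity scale/offset (default 0.95 / -10 HU), additive
Gaussian noise (default 20 HU), and cylindrical FOV truncation to air.
All randomness is seeded. What the phantom deliberately does *not*
emulate: CBCT scatter/cupping artifacts, breathing hysteresis or irregular
traces, texture inside organs. Passing tests on the phantom therefore shows
that the algorithms are correctly implemented and mutually consistent under
realistic geometry, contrast, noise and truncation — not that the
registration would reach the same accuracy on clinical images.

# Registration

Stage 1 is exhaustive integer-voxel block matching (default 20 mm blocks,
7.5 mm search radius) at the coarsest pyramid level, maximising the Pearson
correlation per block; ties break toward the smaller displacement and
low-confidence blocks (correlation <= 0.2 or near-flat intensity) stay
put. The sparse block displacements are interpolated to a dense initial
field and smoothed.

Stage 2 is a demons-style iteration driven by *locally normalised*
intensities: both images are transformed to `(I - local mean)/max(local
sd, floor)` over a 3^3-voxel window, which makes the update equivalent to
ascending the local correlation coefficient and robust to the CBCT's
global intensity distortion. The update force is the classic normalised
gradient force with symmetric (fixed + warped-moving) gradients, capped at
the level's voxel spacing per iteration; each update is smoothed with a
fluid Gaussian (4 mm) and the accumulated field with a diffusion Gaussian
(2 mm). Three pyramid levels by default; levels whose grid would drop
below 16 voxels per axis are skipped (they carry no usable structure and
destabilise the solution). Convergence is declared when the mean update
falls below 0.02 mm; mean-update growth over three consecutive iterations
(by more than 5 %, to ignore plateau jitter) flags divergence and stops
the level. The window radius, sigmas, step and tolerances are engineering
choices exposed in `registration_params()`; the defaults were fixed on the
phantom benchmarks (translation recovery, landmark TRE) and the 3^3
normalisation window in particular matters because the phantom's vessels
are only 4 mm.

FOV handling follows the clinical recipe: the CT is masked to the CBCT
FOV before registration (`crop_to_fov()`, with a crop record), and the
resulting field is expanded back to the full CT geometry by embedding it
(zero outside the FOV) and smoothing with a zero-padded Gaussian
(`expand_dvf()`, default sigma 5 mm) so the displacement decays smoothly
to zero outside the FOV instead of jumping.

Field inversion solves `b(x) = -f(x + b(x))` by under-relaxed fixed-point
sweeps `b <- b - 0.5 * (f(x + b) + b)`. The plain sweep (`relax = 1`) is
only contractive where the forward field's Jacobian is below one; on the
phantom the abdominal decay region reaches a slope of 1.25, where the
plain iteration 2-cycles, while the relaxed sweep converges wherever the
map remains invertible. After the mean composition residual passes the
tolerance (0.1 mm), sweeps continue while the *maximum* residual still
improves, because voxels near the steepest field gradients converge an
order of magnitude more slowly than the mean. Failure to converge sets a
flag rather than erroring, so a QA step can react.

# Phase matching

The diaphragm position of a phase image is the mean superior–inferior
coordinate of the most inferior lung voxel per axial column, over the
central 50 % (per-axis interquartile range) of lung columns — columns of
outside-body air are rejected by requiring non-lung tissue below the lung
voxel. On CBCT, where no contour exists before registration, the lung is
thresholded at -400 HU inside the FOV; the pairing depends only on the
lung boundary geometry, so it is invariant to the CBCT's intensity
scaling. A column-mean was chosen over the dome apex because it is less
sensitive to single-voxel noise; the apex alternative would change the
value by a constant offset that cancels in the pairing. Each CBCT phase is
paired to the CT phase minimising the absolute diaphragm difference;
many-to-one pairings are allowed and ties go to the smaller CT index.

# Pseudo-CT and dose

Intensity overrides (e.g. dental fill) are applied to the plan CT first,
in list order. Inside the FOV the pseudo-CT at day voxel `x` is the
trilinear sample of the overridden plan CT at `x + b(x)`; outside, the
matching-phase plan CT is resampled with the recorded couch shift — the
assumption (shared with the clinical implementation) being that anatomy
the CBCT cannot see did not deform.

The dose engine is explicitly a stand-in for a treatment planning system,
not a clinical calculation: per beam, voxels inside the divergent
rectangular aperture receive `weight * exp(-mu * radiological path) *
(SAD/d)^2`, with the radiological path ray-marched through relative
density `max((HU+1000)/1000, 0)` at voxel-spacing steps and `mu` defaulting
to 0.005 /mm (megavoltage water-like). It reproduces an exponential depth
dose in water to R² > 0.999 and responds to density changes, which is what
the warping/accumulation chain needs; it has no scatter, build-up or
penumbra model. Dose warping is direct trilinear pull-sampling with 0 Gy
outside — no mass/energy-transfer correction, a documented limitation
shared with interpolation-based clinical dose warping. 4-D accumulation
uses uniform 1/10 phase weights (phase-sorted acquisition spends equal
time per bin); weights must sum to one. Course accumulation warps each
daily dose through the replan chain (nearest replan CT first, then
stepwise to the pretreatment CT) and sums; `run_course()` normalises doses
so the per-fraction plan GTV D99 equals the prescription (default 12 Gy),
placing reports on a clinical scale.

# QA metrics

TRE is `|p_moving - (p_fixed + d(p_fixed))|` per landmark pair, pooled
per-landmark across cases (the benchmark reporting convention), with
per-case summaries alongside. DICE is `2|A∩B|/(|A|+|B|)`; the mean surface
distance is the symmetric average of directed nearest-surface-voxel
distances. Volume-change and centre-of-mass flags use *strict* inequalities
at 10 % and 3 mm. `D_q` is defined at voxel resolution: ROI doses sorted
descending, the cumulative volume-fraction curve interpolated linearly at
`q`/100 — this matches a brute-force full-sort oracle exactly and
guarantees `D99 <= D95 <= D90`. Percent-of-plan values are ratios of like
metrics times 100.

# Workflow model

Each fraction advances through four statuses in strict order — CBCT ready,
pseudo-CT ready, Tx-dose ready, cumulative dose ready — plus a terminal
FAILED state used by the orchestrator when a stage errors (remaining
fractions still run). The schedule is an XML document of our own schema
(patient, plan chain, per-fraction date/couch/status) that round-trips
losslessly and validates status strings on read. Database polling and
email notification of a clinical deployment are replaced by filesystem
artifacts and log events, which keeps the state machine testable.

# Problem sizes and numerical choices

The phantom defaults to 64³ voxels at 2.5 mm — large enough that the
10 mm breathing motion spans four voxels and registration benchmarks are
meaningful, small enough that a full commissioning run (nine deformable
registrations) completes in minutes on one CPU. Unit tests use 32³/5 mm
and 48³/3 mm versions of the same anatomy; the end-to-end course tests run
at 32³ with two reconstructed phases (the reference and end-of-exhale) and
reduced iteration counts, which exercises every pipeline stage without
changing any algorithm. Trilinear interpolation is exact on its own grid
and never overshoots; out-of-bounds policy is caller-supplied fill for
images, zero for vector fields, 0 Gy for dose, and plan-CT patching for
the pseudo-CT. Gaussian filters are separable FIR kernels truncated at
3 sigma (zero-padded where decay to zero is the point, renormalised where
boundary attenuation would bias image smoothing).

# Known limitations

Axis-aligned geometry only; no DICOM readers (MetaImage/NIfTI instead);
the dose engine is non-clinical; dose warping has no energy-transfer
correction; registration accuracy figures from the phantom do not transfer
to clinical image quality; ROI-constrained registration refinement is a
hook, not implemented; sub-diaphragm motion in featureless soft tissue is
unobservable for any intensity-driven registration — on the phantom this
is visible as HU error concentrated at high-contrast boundaries.
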