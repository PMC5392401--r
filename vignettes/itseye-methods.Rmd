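---
title: "Simulating intraocular telescopic systems in a schematic eye: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating intraocular telescopic systems in a schematic eye: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itseye)
```

## The problem

Patients with central retinal damage (most commonly age-related macular
degeneration) lose the high-acuity fovea and benefit from magnifying the
retinal image and, when the fovea itself is damaged, relocating it to a
healthy parafoveal region. A miniaturized Galilean telescope implanted in
the eye — an intraocular telescopic system (ITS) — does both: the
high-power positive/negative lens pair magnifies the image, and
deliberately decentring the anterior lens deviates it sideways by a prism
effect. This package simulates two such implants inside an aphakic
schematic eye and quantifies how optical quality (RMS wavefront error),
visual quality (the visual Strehl ratio, VSOTF) and image position change
as the anterior lens is decentred from 0 to 1 mm.

## The host eye

The host is an anatomically based schematic eye with a two-surface
aspheric cornea (radii 7.77 / 6.40 mm, conic constants −0.18 / −0.60,
thickness 0.50 mm, stroma index 1.376), a 3 mm pupil at 3.16 mm behind
the posterior cornea, and an axial length of 23.95 mm. The crystalline
lens is removed (the implants replace it) and its space is filled with
aqueous of index 1.336, so the only media are cornea and aqueous. The
original model's nasal pupil decentration and 5° visual-axis tilt are
dropped: the host here is rotationally symmetric, which makes a purely
*y*-axis lens decentration fully representative. The retina is a curved
image surface of radius −12.0 mm (concave toward the cornea); the source
model does not print an image-surface curvature, so this widely used
anatomical value is adopted and a `flat_retina` switch is provided for
debugging. All constants live in `eye_constants()` and can be overridden
per run through `simulation_config(eye_overrides = ...)`. The retina is
held fixed at the cited axial length; no best-focus refocusing of the
image surface is applied, and this assumption is echoed into the sweep
metadata.

Simulations use green light (587.6 nm) with fixed indices; chromatic
dispersion is out of scope. Two object vergences are studied: infinity
("far") and a 0.41 m reading distance ("near").

## Telescope designs

Each lens is specified by its total power and its anterior surface
power; the posterior surface power follows from the thick-lens
effective-power formula

$$D = P_a + P_p - \frac{t}{n} P_a P_p$$

with thickness $t$ = 1 mm and index $n$ = 1.55, and surface powers
convert to radii via $P = (n' - n)/R$ in the aqueous. The through-pupil
telescope (ITS 1, +53 D / −64 D) straddles the pupil: positive lens
1.66 mm behind the cornea, negative lens 2.6 mm behind the pupil, lens
separation 3.1 mm (far) and 3.65 mm (near). The behind-pupil telescope
(ITS 2, +66 D / −66 D) sits wholly in the posterior chamber with
separations 1.5 / 1.95 mm.

Two genuinely open layout choices were resolved as follows:

* **"Distance between lenses"** is read as the facing-vertex gap. For
  ITS 1 the two printed routes to the negative lens then agree exactly
  (1.66 + 1.0 + 3.1 = 2.16 + 2.6 mm behind the posterior cornea), which
  is strong evidence for this reading.
* **ITS 2's axial position behind the pupil** is not printed. The
  default stop-to-lens offset is 0.8 mm because at that placement the
  focus search over the lens separation returns 1.50 mm at infinity and
  1.96 mm at 0.41 m — the printed design separations — by the same
  self-consistency logic. The offset remains a parameter
  (`build_its2(placement_offset = ...)`) and is recorded in all outputs.
* **Which lens translates between far and near** is likewise not stated;
  the anterior lens is held fixed and the posterior lens moves toward
  the retina, and `focus_separation()` implements the same convention.

`focus_separation()` minimizes the retinal RMS spot radius over the
facing-vertex separation within [0.5, 6] mm (golden-section search,
1e-3 mm tolerance); it reproduces the design separations of ITS 1 to
better than 0.02 mm.

## Exact ray tracing

Surfaces are even aspheres, sag
$z(r) = cr^2 / (1 + \sqrt{1 - (1+k)c^2r^2}) + a_2 r^2 + a_4 r^4$.
Intersections use the closed-form conic root (taken nearest the vertex
tangent plane, numerically stabilized) polished by Newton iteration on
the full sag to a residual below 1e-10 mm; normals come from the sag
gradient; refraction is the vector Snell law. Rays beyond a surface's
semi-diameter, with no real intersection, or in total internal
reflection are marked dead.

Lens decentration is implemented with coordinate-break surface pairs
that shift the local frame along +y before the lens and restore it
after, exactly as sequential design software does; with zero shift they
are exact no-ops (asserted to 1e-14 in the tests). Decentration is
applied to the anterior (positive) lens only, along +y, which by the
rotational symmetry of the host loses no generality.

The 3 mm aperture stop defines the pupil. Rays are aimed iteratively so
that each crosses the stop on a uniform square grid inscribed in the
stop disc (aiming residual < 1e-6 mm, shared-Jacobian Newton updates).
The default pupil sampling is a 64 × 64 grid (≈ 3 200 rays); halving or
doubling it moves the reported RMS by well under 1%, and the heavier
optimization merit uses 32 × 32.

The wavefront OPD of each ray is referenced to the chief ray on a
reference sphere centred at the chief ray's retinal intersection and
passing through the exit-pupil centre (the exit pupil located by a
paraxial image of the stop through the trailing surfaces). This is the
standard exit-pupil convention of sequential tracers. Reported RMS
removes piston **and tilt**: tilt encodes the image displacement that
the study reports separately as retinal image decentration, and keeping
it would double-count that displacement in the decentred systems'
RMS. A `rms_remove = "piston"` flag restores piston-only removal for
sensitivity analysis; for centred systems the two conventions coincide.

Image decentration is measured as the lateral displacement of the
retinal spot **centroid** from the centred system's axial image point
(the chief-ray displacement is reported alongside), and converted to a
visual-field eccentricity by finding — in the centred twin of the
system — the object-space field angle whose chief ray lands at that
retinal height (bisection to 0.001°). The centred-system mapping is the
right one for "how far from the fovea did the image land".

## Zernike analysis

Wavefront maps are decomposed on the orthonormal OSA/ANSI Zernike basis
up to radial order 6 by least squares; with unit-RMS normalization each
coefficient is its mode's RMS contribution in waves, so Parseval's
relation ties the coefficient power to the direct map RMS (verified to
2% on traced maps, to 1e-9 on injected ones). Fits require at least
three valid samples per coefficient and reject rank-deficient designs.

## From wavefront to visual quality

The metric chain follows the standard Fourier-optics route: uniform
amplitude pupil function $P(\rho) = A\,e^{2\pi i W}$ on the 3 mm disc
(no Stiles–Crawford apodization), PSF as the squared modulus of its FFT
(zero-padded ×4; doubling the padding moves VSOTF by < 1e-3), OTF as
the FFT of the PSF normalized to 1 at dc, with frequency axes in
cycles/degree (per-sample pitch $\Delta p/\lambda$ cycles/radian; the
sampled band comfortably contains the 89.1 cyc/deg incoherent cutoff of
a 3 mm pupil at 587.6 nm, which pins the axis calibration). The visual
Strehl ratio is

$$\mathrm{VSOTF} = \frac{\iint \mathrm{CSF_N}\,\mathrm{Re}\,\mathrm{OTF}\;df_x\,df_y}
                        {\iint \mathrm{CSF_N}\,\mathrm{OTF_{DL}}\;df_x\,df_y},$$

using the real part of the OTF (the established visual-Strehl
convention; a modulus-based variant sits behind a flag).

**The neural CSF is the one genuinely unrecoverable ingredient.** The
study it reconstructs cites but does not print its CSF$_N$. The default
here is a radially symmetric stretched exponential,
$\mathrm{CSF_N}(f) = a\,e^{-(f/f_c)^q}$ with $a = 500$, $f_c = 10.3$
cyc/deg, $q = 1$, the shape of neural (post-optical) contrast
sensitivity measured with interference fringes, which declines roughly
exponentially with a characteristic frequency near 10 cyc/deg. An
earlier draft used the Mannos–Sakrison band-pass formula and was
replaced: that function fits the *overall* CSF (optics included), which
is the wrong object for a post-optical neural weight. Because
normalization cancels in the ratio, a diffraction-limited system scores
VSOTF = 1 under *any* parameter choice — the suite asserts this for
three very different parameter sets.

Consequences of the unrecoverable CSF are confined deliberately:
absolute VSOTF values are treated as soft regression quantities, while
RMS, image displacement and all geometric results are CSF-independent.
Where our wavefronts can be compared directly with the published ones
they agree to a few percent or better (e.g. the optimized, 0.2 mm
decentred near configuration gives RMS 0.03167 waves against a
published 0.03162), yet the published VSOTF at such cells is far lower
than Eq-above can produce from the same wavefront under any radially
symmetric neural CSF: the real-part OTF deficit at those aberration
levels is simply too small below ~40 cyc/deg. The published
VSOTF-versus-RMS mapping therefore contains conventions of the original
custom MATLAB chain that cannot be recovered, and VSOTF-shape
assertions (notably the optimized-system "plateau" between 0.4 and
0.8 mm decentration) reproduce for the behind-pupil telescope but not
for the through-pupil one in this reconstruction.

## Asphericity optimization

The "optimized" condition minimizes RMS wavefront error over the conic
constant and the $r^2$, $r^4$ even-asphere coefficients of the anterior
surface of the positive lens, from the spherical start (0, 0, 0), on
the centred system, per vergence — decentration is applied afterwards
and never re-optimized. The optimizer is a bounded derivative-free
Nelder–Mead simplex (two chained runs, parameter scaling ~(0.5, 3e-4,
1e-4), bounds |k| ≤ 50, |a2| ≤ 0.05 mm⁻¹, |a4| ≤ 0.01 mm⁻³); candidates
with undefined sag inside the aperture are rejected as infinite merit.
The three-parameter merit landscape is benign (defocus via $a_2$,
fourth-order correction via $k$ and $a_4$), so simplex refinement
reaches residuals near 1e-6 waves; the original study used a damped
least-squares optimizer, but only the achieved RMS matters for the
reproduced quantities, not the algorithm or the parameter values.

## Synthetic fixtures and oracles

Every stage is validated without the study's systems: a single
refracting sphere with closed-form focal distance ($n'R/(n'-1)$);
injected Zernike wavefronts that exercise the fit and the Fourier chain
with exactly known content; seeded random Galilean telescopes
(positive power 40–80 D, negative −80 to −40 D, separation 1–4 mm)
whose paraxial image distance is predicted by an independent 2 × 2
ray-transfer-matrix oracle — the exact tracer agrees with it to < 0.1%
at small aperture across 50 seeds; and the paraxial prism term
($n'u' = nu - (y - \delta)P$) predicting the image displacement of
decentred elements. All generators are pure functions of their seed.

## Problem sizes and numerical choices

Default study sizes: 64 × 64 pupil sampling for reported metrics,
32 × 32 for optimization merits, ×4 FFT padding, Zernike order 6. The
full 48-cell factorial sweep (2 telescopes × optimized/nonoptimized ×
far/near × 6 decentrations) runs in about a minute on one core; the
test suite uses 24–32-point sampling where structure rather than
precision is being asserted. Ray aiming tolerance 1e-6 mm, intersection
residual 1e-10 mm, focus search tolerance 1e-3 mm, field-angle
bisection 1e-3°. Degenerate inputs (flat surfaces, matched media,
zero-power surfaces, afocal outputs, vignetted rays) all have explicit
paths and tests.

## What the synthetic generator does not emulate

The fixtures emulate centred and decentred sequential optics with
analytically known truth; they do not emulate scattering, diffraction
at lens edges, polarization, chromatic dispersion, gradient-index
media, pupil apodization, or retinal sampling beyond the neural CSF
weight. Passing tests therefore demonstrate the fidelity of the
geometry, wavefront bookkeeping and Fourier metric chain — not clinical
performance of the implants; the known limitations above (CSF
unrecoverability, behind-pupil placement inference, fixed retina)
bound what the reproduced tables can claim about the original study.
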