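---
title: "Localized sub-particle reconstruction of flexible helical filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized sub-particle reconstruction of flexible helical filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(helixpsa)
```

## The problem

Some helical protein polymers — the meprin α filament is the motivating
case — are intrinsically flexible: they bend, over- and under-twist, and
expand or contract continuously along their axis, and neighbouring turns
make no stabilising contacts. Conventional helical single-particle analysis
aligns long boxed segments of such filaments against one average, and the
continuous heterogeneity caps the attainable resolution: the alignment that
is right for the middle of a segment is wrong at its ends, so the consensus
map is sharp only near the box centre and blurs outward, stalling at
nanometre-scale resolution no matter how many segments are averaged.

The remedy implemented here is pseudo single-particle analysis by localized
reconstruction. A low-resolution *consensus* of ~2-turn segments is first
obtained by projection matching without any imposed helical symmetry (C1).
Sub-region *vectors* are then assigned from the consensus box centre to each
dimer-pair region of the lattice; soft masks around each region (with a
buffer between them, so no particle is counted twice) define what to keep;
the CTF-modulated projection of everything *else* is subtracted from each
segment image; and a small re-centred *sub-particle* is extracted at each
vector. Each region of a flexible filament is locally rigid, so these
sub-particles behave as conformationally homogeneous single particles: a
local refinement around their inherited pose priors recovers the resolution
the raw images support.

## What the package provides

* `synthetic data` — `helical_lattice()`, `asym_unit_model()`,
  `flex_params()`, `lattice_poses()`, `render_volume()`,
  `simulate_micrograph()`, `simulate_dataset()`: ground-truthed filament
  micrographs with continuous flexibility, CTF and noise.
* `image core` — `density_map()`, `image2d()`, `ctf_evaluate()`,
  `project()`, `reconstruct()`, `fsc()`, `resolution_at()`, `sharpen()`,
  MRC 2014 and STAR readers/writers.
* `segment pipeline` — `trace_filaments()`, `extract_segments()`,
  `align_segments()`, `iterate_consensus()`.
* `sub-particles` — `define_vectors()`, `make_region_masks()`,
  `subtract_signal()`, `extract_subparticles()`, `subregion_reference()`.
* `local refinement` — `split_half_sets()`, `local_refine()`,
  `gold_standard_resolution()`.
* `structural metrics` — `helix_geometry()`, `helix_groove()`,
  `groove_and_spacing()`, `buried_interface_area()`,
  `sequence_average_mass()`, `mutations_per_domain()`.
* `run_pseudo_spa()` runs the whole pipeline on a simulated dataset.

## Conventions

Euler angles are intrinsic ZYZ `(rot, tilt, psi)` in degrees: the reference
volume is rotated by `R = Rz(psi) Ry(tilt) Rz(rot)` — a point at `p` in the
reference appears at `R p` — then projected along +z, and the image content
is translated by `(shift_x, shift_y)` Å. A worked example: `pose(90, 0, 0)`
maps the reference +x axis to +y; `pose(0, 90, 0)` maps +z to +x (the
filament axis into the image plane); their composition `pose(90, 90, 0)`
does both in that order. The same convention is written to STAR files, so
metadata remains interpretable by the dominant single-particle tools. The
CTF uses underfocus-positive defocus with
`CTF = -(sqrt(1 - A^2) sin chi + A cos chi)`; at zero frequency this equals
`-A`, and point scatterers are dark at low frequency, matching experimental
contrast.

Projection is central-slice extraction from a 2x zero-padded Fourier volume
with trilinear interpolation and sinc^2 gridding correction; reconstruction
inserts CTF-weighted slices into the same oversampled grid and applies the
Wiener division `sum(CTF_i F_i) / (sum(CTF_i^2) + w)` with
`w = 0.1 mean(sum CTF^2)` by default, which also compensates the slice
sampling density. FSC thresholds default to 0.143 for half-map comparisons
and 0.5 for map-vs-model, both exposed as arguments.

## The demonstration filament

The published envelope of the meprin α filament constrains the lattice,
but its helical symmetry parameters are not reported, so
the demonstration lattice is *inferred*: radius 92.5 Å, twist −49°
(left-handed, ~7.3 dimers per turn), rise 15 Å (pitch 110 Å). These values
reproduce the printed envelope — outer diameter ≈ 22 nm, lumen ≈ 15 nm,
groove ≈ 7 nm, repeating-site spacing ≈ 8 nm, and 6–8 dimer-pair regions in
a 20 nm box — but they are a calibrated stand-in, not a measurement. The
asymmetric unit is one C2 dimer built from 24 narrow (σ = 3.8 Å) Gaussian
sub-blobs grouped into three domain clusters per monomer (an inward
protease-like lobe on the lumen side and two outer adhesion-like lobes),
C2-symmetric about the radial axis. The narrow widths matter: a Gaussian of
σ = 8 Å has Fourier amplitude `exp(-2 pi^2 sigma^2 k^2) ≈ 3e-9` at the 4 Å
pixel Nyquist frequency, i.e. no usable signal where resolutions are
compared; σ = 3.8 Å leaves genuine signal out to Nyquist, as an atomic
structure would have.

## The flexibility model

`flex_params()` has four knobs: a circular-arc backbone of curvature
`bend_rate` (degrees per 100 Å), smooth per-unit twist and rise deviations
(`twist_jitter_sd` in degrees, `rise_jitter_sd` in Å), and the correlation
length of those deviations (`corr_length`, units; Gaussian-kernel smoothed
noise). Smoothness is essential to the physics being emulated: deviations
that are independent from unit to unit distort every dimer pair internally,
and then *no* locally rigid region exists for localized refinement to
exploit. With a 20-unit correlation length the lattice is locally
near-ideal while the accumulated phase drifts by many degrees across a
segment box — precisely the regime in which a segment consensus is
bottlenecked by alignment error but two-dimer sub-particles are not.

The defaults (bend 4°/100 Å, twist sd 2°, rise sd 1 Å, correlation 20
units) together with the simulation defaults (4 Å pixels, SNR 2 in the
filament footprint, per-micrograph defocus drawn from 8000–16000 Å, 4
micrographs × 4 filaments × 80 units ≈ 230 segments of 64 px) are the
package's frozen study conditions: they were calibrated once so that the
synthetic data exhibit the documented phenomenon — a consensus stalled at
~16 Å while localized refinement reaches ~10 Å at the same 4 Å pixel size —
and are not tuned per run. Defocus varies because a single defocus leaves
unfillable CTF-zero gaps in Fourier space; the upper bound keeps the CTF
oscillation resolvable in the 32 px sub-particle box.

## Pipeline choices

* **Bootstrap.** The consensus starts from a 15 Å low-passed rendering of
  the true lattice — the stand-in for an experimental tomography average.
  Starting from a featureless cylinder was tested and converges to a
  self-consistent wrong structure under C1 hard-assignment matching; the
  classification and symmetry machinery that rescues featureless starts in
  production packages is deliberately out of scope here.
* **Priors.** Tilt is searched within ±15° of 90° (filaments lie in the
  ice plane) and psi within ±15° of the trace tangent; rot is searched over
  the full circle. Ties take the lowest grid index, deterministically.
* **Coarse-to-fine.** The coarse grid (10°) runs on 2x Fourier-binned
  data, halving stages polish to 0.5°, and the final stage runs at full
  sampling. `method = "exhaustive"` provides the brute-force reference the
  tests compare against.
* **Score filter.** Segments below the 10th percentile of normalized
  cross-correlation are dropped — a stand-in for the 2D/3D classification
  cleanup that is out of scope.
* **Masks.** Region masks are soft spheres (radius 60 Å, 20 Å cosine edge
  falling to exactly zero at the radius, buffer 20 Å). Spherical rather
  than shape-adaptive masks are a reproducible simplification; the buffer
  equals the soft edge, the smallest value that guarantees no voxel feeds
  two regions.
* **Sub-particles.** 32 px boxes; the pose prior keeps the parent angles
  with the region's lattice rotation offset folded into `rot`, so all 6–8
  regions refine against one re-centred two-dimer reference. Localization
  precision is inherited from the consensus pose (nanometre scale); no
  independent translational pre-search is done before local refinement.
* **Local refinement.** A uniform grid within ±8° and ±5 Å of the prior
  (coarse 4°, fine 0.5°), run twice: between passes the reference is
  rebuilt from the refined poses and filtered at its measured half-map
  resolution, because a single pass against the resolution-limited
  consensus reference cannot reach the poses the data support, and an
  unfiltered rebuild would be aligned against its own noise. The second
  pass polishes only (no coarse stage). Sub-particles below the 10th score
  percentile are excluded from the final half-maps, mirroring the segment
  cleanup. A uniform window is used instead of a Gaussian prior — simpler
  and directly testable.
* **Half sets** are split by filament, never by sub-particle, so the
  half-maps share no parent signal.
* **Resolution reporting.** The consensus FSC uses a soft cylindrical
  solvent mask spanning the full box axis: the method's premise is that
  flexibility damage grows away from the box centre along the filament, so
  a centre-only mask would hide exactly that, while the empty box corners
  outside the cylinder would only add noise-noise decorrelation.

## A worked run

```{r}
flex_run <- run_pseudo_spa(flex = flex_params(seed = 1),
                           cfg = simulation_config(seed = 11), seed = 5)
flex_run$consensus$resolution   # ~16.3 A : the flexibility bottleneck
flex_run$localized$resolution   # ~10.3 A : recovered by localized refinement
flex_run$resolution_ratio       # ~1.58  : frequency gain

rigid_run <- run_pseudo_spa(flex = NULL,
                            cfg = simulation_config(snr = Inf, seed = 11),
                            seed = 5)
abs(1 / rigid_run$consensus$resolution -
    1 / rigid_run$localized$resolution) * 128  # 0 Fourier shells
```

The rigid control is run noise-free, and there the two reconstructions
agree exactly (both saturate at Nyquist): the localized procedure invents
nothing when there is no flexibility to defeat. The control must be
noise-free to be a clean null: at finite SNR the localized branch keeps a
genuine averaging advantage even on rigid filaments, because the 6–8
symmetry-equivalent dimer-pair regions of every segment are pooled onto a
single reference — lattice averaging that the C1 consensus deliberately
forgoes. That advantage is a real property of localized reconstruction
(production-scale analyses benefit from the same pooling), not an
artifact, and it is visible here as roughly one Fourier shell on noisy
rigid data.

## What the synthetic data do and do not show

The generator emulates the statistical structure the method assumes:
repeating dimer lattices, smooth continuous flexibility, CTF modulation
with defocus spread, and white Gaussian noise calibrated to a footprint
SNR. It does not emulate ice-gradient or structured noise, beam-induced
motion, radiation damage, detector physics, picking errors from crowded
fields, or per-particle optical aberrations. Passing tests therefore show
that the pipeline's operators are correct and that the localized strategy
defeats continuous flexibility of the modelled kind; they do not certify
performance on any particular experimental dataset.

Two numerical ceilings are worth knowing. First, reconstructions of
box-filling helical segments carry a forward-model mismatch: the images see
the infinite filament while the reference box truncates it, so even exact
ground-truth poses reconstruct to ~0.89 correlation against the rendered
truth at half-Nyquist; correlation targets near 0.98 are attainable only
for compact particles, as the round-trip tests show. Second, half-map FSC
under-reports blur that is common to both half-sets; with noise present the
attenuated signal sinks below the noise floor and the FSC crossing becomes
an informative resolution estimate, which is why the headline experiment
is run at finite SNR.

## Structural metrics

`helix_geometry()` thresholds the map (mean + 2 sd of positive voxels by
default), fits the axis direction by PCA refined with slab centroids, fits
the axis *position* by a Kasa circle fit in the perpendicular plane (the
centroid of a partial-turn helix lies off-axis; a circle fit does not), and
reads the outer and lumen diameters from the radial occupancy profile at a
1% annulus-occupancy cut. `helix_groove()` measures the turn envelope on
the unwrapped helical phase at a display-level contour (the mean positive
density): the groove is a surface feature and its width is what one sees at
a rendering contour. `buried_interface_area()` is Shrake–Rupley SASA
(probe 1.4 Å, 960 golden-spiral points per atom, Bondi-style radii) under
the halved-buried-area convention interface servers report;
`sequence_average_mass()` uses average residue masses plus one water;
`mutations_per_domain()` buckets residue numbers into user-supplied domain
ranges, since the domain boundaries are published only schematically.

## Known limitations

Maximum-likelihood (expectation-weighted) alignment, 2D/3D classification,
helical symmetry imposition and search, per-particle CTF refinement,
Ewald-sphere correction, shape-adaptive masks and non-uniform filtering are
all out of scope; correlation-based hard assignment with the priors above
is the whole of the alignment model. The desk-scale defaults (64 px
segments at 4 Å per pixel) put Nyquist at 8 Å: resolution statements are
demonstrations of the method's mechanism, about an order of magnitude from
the experimental regime (400 px boxes, sub-angstrom pixels, hundreds of
thousands of particles), which is configuration, not code.
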