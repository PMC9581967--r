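# helixpsa

Pseudo single-particle analysis of intrinsically flexible helical protein
filaments, in R.

## The problem and who this is for

Helical polymers such as the giant meprin α protease filament — a
left-handed spring of C2 homodimers, roughly 22 nm wide with a 15 nm hollow
core and a 7 nm open groove between turns — bend, twist and breathe
continuously. Conventional helical cryo-EM processing aligns long boxed
segments against one consensus average, and that continuous flexibility
caps the consensus at nanometre resolution: a pose that fits the middle of
a segment is wrong at its ends. This package implements, as tested and
reusable components, the *localized reconstruction* strategy that defeats
this: build a low-resolution C1 consensus of ~2-turn segments, assign
vectors from the box centre to each dimer-pair region, subtract the
CTF-modulated projection of everything outside a region from each segment
image, extract a small re-centred sub-particle per region, and refine the
sub-particles as independent single particles around their inherited pose
priors. Each region is locally rigid, so the local refinement recovers the
resolution the images actually support.

It is aimed at methods developers and students of cryo-EM image processing
who want an inspectable, fully synthetic, ground-truthed implementation of
this pipeline — every stage from micrograph simulation to gold-standard
FSC is a plain R function with tests — rather than a production replacement
for RELION or cryoSPARC.

## The model in brief

A filament is a helical lattice `(rise Δz, twist Δφ < 0, radius r)` of C2
dimers. Flexibility is a circular-arc backbone plus smooth (20-unit
correlation length) per-unit deviations of twist and rise, so the lattice
is locally near-ideal while the accumulated phase drifts across a segment
box. Images follow the standard weak-phase model: projections along the
beam, multiplied in Fourier space by
`CTF(k) = -(sqrt(1-A²) sin χ + A cos χ) e^(-Bk²/4)` with underfocus-positive
`χ(k) = πλΔf k² - (π/2) Cs λ³ k⁴`, plus white Gaussian noise calibrated to
a footprint SNR. Poses are intrinsic ZYZ Euler triples
`R = Rz(ψ) Ry(θ) Rz(φ)` with Å shifts; reconstruction is Wiener-weighted
central-slice insertion `Σ CTFᵢFᵢ / (Σ CTFᵢ² + w)`; resolutions are FSC at
the 0.143 gold-standard threshold between half-maps split by filament.

## A worked example

```r
library(helixpsa)

# the full pipeline on a simulated flexible filament dataset (~5 min)
flex_run <- run_pseudo_spa(flex = flex_params(seed = 1),
                           cfg = simulation_config(seed = 11), seed = 5)
flex_run$consensus$resolution
#> [1] 16.26
flex_run$localized$resolution
#> [1] 10.31
flex_run$resolution_ratio
#> [1] 1.576
```

The consensus of ~230 overlapping 64-px segments stalls at ~16 Å — the
flexibility bottleneck — while the localized sub-particle reconstruction of
the same data reaches ~10 Å, a 1.58× frequency gain. On the noise-free
rigid control (`flex = NULL, snr = Inf`) the two reconstructions agree
exactly: the procedure invents nothing when there is no flexibility to
defeat (the vignette explains why the clean null requires the noise-free
control).

The structural metrics reproduce the filament's envelope from the
demonstration model:

```r
m <- render_reference(demo_lattice(), demo_asym_unit(), 96, 4)
helix_geometry(m)$outer_diameter   # 224  (~22 nm diameter)
helix_geometry(m)$lumen_diameter   # 144  (~15 nm hollow core)
helix_groove(m, demo_lattice())$groove  # 70.8  (~7 nm groove)
length(define_vectors(demo_lattice(), box_a = 200))  # 6 dimer-pair regions
```

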