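---
title: "Predicting the elastic properties of a 3D-braided meniscus implant"
author: "braidfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the elastic properties of a 3D-braided meniscus implant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braidfe)
```

`braidfe` predicts the linear-elastic constants of a braided Kevlar/PCU
meniscus implant at three scales: the matrix-impregnated fiber bundle
(micromechanics), periodic unit cells of the braid (finite-element
homogenization), and the full implant under compressive service loads. This
vignette is the package's account of the underlying models, the choices that
were genuinely open, and what the results do and do not show.

## Constituents and units

The matrix is polycarbonate urethane (PCU), isotropic with E = 0.057 GPa and
v = 0.43; the reinforcement is Kevlar, transversely isotropic with axial
modulus 128.7 GPa, transverse modulus 12.87 GPa, axial Poisson ratio 0.3 and
all shear moduli 12.87 GPa. Internally everything is N/mm/MPa; GPa is
accepted only at the configuration boundary (`read_config()`), matching how
such constants are tabulated. Note that a transverse shear modulus equal to
the transverse modulus implies, through the in-plane isotropy identity
G23 = E22/(2 + 2 v23), a transverse Poisson ratio of −0.5; the constants are
used exactly as given, and every `trans_iso_material` enforces the identity.

## The bridging model for fiber bundles

A yarn infiltrated by matrix is treated as a homogeneous transversely
isotropic solid. The bridging matrix [A] maps the volume-average fiber
stress to the volume-average matrix stress. Its diagonal entries are
closed-form: `a11 = Em/E11f` axially, `a22 = β + (1−β) Em/E22f`
transversely, `a66 = α + (1−α) Gm/G12f` in axial shear, with bridging
parameters α, β conventionally in 0.3–0.6.

Two extraction conventions exist once [A] is in hand. The full matrix
product `S = (Vf·Sf + Vm·Sm·A)(Vf·I + Vm·A)⁻¹` — exposed as
`bridging_compliance()` — includes an axial–transverse coupling entry a12
chosen to keep the product nearly symmetric; it yields a noticeably stiffer
transverse modulus (0.58 GPa for the default bundle). The per-constant
engineering form, `X = (Vf + Vm·a)/(Vf·Sf_x + Vm·a·Sm_x)`, is what published
bundle tables for this class of composite correspond to (0.479 GPa here),
and it makes the axial modulus reduce exactly to the rule of mixtures.
`bundle_constants()` therefore uses the per-constant form; the full product
remains available for sensitivity analysis. The bundle's transverse Poisson
ratio is set from the isotropy identity so returned bundles are exactly
transversely isotropic.

**Calibration.** The bundle's fiber volume fraction is not part of the
constituent table; Vf = 0.70 is back-solved from the published bundle axial
modulus through the rule of mixtures ((90.1 − 0.057)/(128.7 − 0.057) ≈ 0.70)
and α = β = 0.30 back-solved from the transverse and shear moduli — the
lower end of the conventional range. `backsolve_params()` automates exactly
this inversion. These are documented defaults, not values claimed from any
measurement, and all three are exposed in the configuration.

Computed vLT is 0.339 (≈ Vf·v12f + Vm·vm); reference tables for this bundle
disagree with each other on vLT (0.37 vs 0.31), so the package reports the
computed value and treats neither as ground truth.

## Embedded-fiber finite elements

The kernel is the standard trilinear 8-node hexahedron: shape functions
Ni = (1+ξξi)(1+ηηi)(1+ζζi)/8, strain–displacement matrix B in Voigt order
(x, y, z, yz, zx, xy) with engineering shears, isotropic elastic matrix with
prefactor E(1−v)/((1+v)(1−2v)), and full 2×2×2 Gauss quadrature — exact for
affine elements, no reduced integration or hourglass control (the package
targets well-shaped mapped meshes; v = 0.5 is rejected as incompressible).

Fibers are polylines with a cross-section area and an axial modulus only —
bending, torsion and interface slip are out of scope. A fiber inherits its
displacement from the host element's shape functions, so meshes never need
to conform to the lattice. Fiber axial strain is the projected host strain
εₚ = [l², m², n², mn, nl, lm]·ε, and the segment stiffness
∫ B′ᵀ Ef B′ A h dx′ (2-point Gauss along the segment) is superposed on the
host element.

Numerical choices: endpoint natural coordinates come from Newton inversion
of the trilinear map (tolerance 1e−12, at most 50 iterations, centroid
start). Paths crossing element faces are split by bisection on host
membership (50 iterations on the path parameter), which conserves total
embedded length exactly by construction; segments shorter than 1e−6 mm are
dropped. Membership uses a strict natural-coordinate tolerance of 1e−8
first, then a loose fallback of 0.25 that absorbs the chordal sag of
coarsely faceted curved meshes — on such meshes a point of the smooth
parametric surface can lie a fraction of a millimetre outside every flat
element facet, and the fallback snaps it to the nearest host.

An important bookkeeping consequence: embedded bars *add* stiffness without
displacing matrix volume, the usual embedded-rebar convention. Mixture-bound
checks therefore cap moduli at `Vf·(fiber constant) + (matrix constant)`,
with the full matrix volume retained.

## Periodic homogenization

Unit cells are solved under six unit macroscopic strains with periodic
boundary conditions imposed by master–slave elimination: every node on a
periodic max-face is tied to its min-face image with displacement difference
ε̄·Δx, one master corner is pinned, and the reduced system is SPD and solved
by sparse Cholesky with deterministic ordering — constraints are satisfied
exactly and there is no penalty parameter to tune. Column j of the effective
stiffness is the volume-averaged stress (matrix Gauss average plus the axial
fiber overlay) under unit strain j. The raw C must be symmetric to 1e−6
relative before symmetrization, must be positive definite, and each run
records the per-case Hill check (macro energy vs volume-averaged micro
energy); the test suite verifies the strain-average theorem to 1e−10.

**Micro cell.** The "hexagonal" unidirectional cell is a rectangular
1 × 1 × √3 mm cell with one full and four quarter fibers in hexagonal
packing, realized as embedded axial bars whose summed area is exactly
Vf times the cross-section. For a homogeneous host with periodic axial
bars the affine field is the exact solution, so the axial modulus is
mesh-independent: EL = Em + Vf·E11f = 90.15 GPa, within 0.05 % of the
bridging value and within ~1 % of the reference finite-element bundle
value. Because bars carry no transverse stiffness, the cell's transverse
and shear columns stay matrix-like (0.07 and 0.02 GPa) — markedly below the
bridging transverse modulus. This is the known limitation of bar-based
micro cells; it propagates consistently through both meso pipelines, which
is what makes their cross-check meaningful.

**Meso cells.** The braid spacing (2 mm bundles, 2 mm gaps, 11/5 mm layer
pitch) gives a 4 × 4 × 2.2 mm cell holding one longitudinal and one
transverse bundle in two 1 mm sublayers plus a 0.2 mm matrix cap; the
interior cell adds a 1 × 1 mm vertical interlock column at the cell corner,
and the bottom cell is the exact z-mirror of the top (their homogenized
constants agree to 1e−6, a reflection-invariance check of the solver). The
published RVC tables cannot be reproduced bit-for-bit — the meso geometry is
under-determined in the source — so the package treats two properties as the
meaningful surface: (i) the fiber-embedded and multi-scale pipelines agree
within 5 % on all seven constants for the same cell, and (ii) the interior
cell's vertical modulus (5.8 GPa here) far exceeds the top/bottom cells'
(0.16 GPa), reproducing the qualitative signature of the vertical interlock.

**Multi-scale chain.** `multiscale_chain()` homogenizes the micro cell,
converts it to a transversely isotropic bundle material
(`as_bundle_material()`, with v23 set from the isotropy identity), assigns
it to the oriented bundle regions of each meso cell (Bond-rotated 6×6
stiffness), and homogenizes those — mirroring the micro → meso → macro
workflow of multi-scale composite analysis.

## The parametric implant geometry

The crescent outline is the region between an outer half-ellipse (16 × 26 mm
half-axes) and a concave inner half-ellipse (13 × 3 mm), chosen so that the
bounding box is exactly 32 × 26 × 11 mm, the two tip ends remain blunt
(3 mm) so the mapped mesh has no collapsed elements, and the radial width at
the apex (23 mm) accommodates the six level-1 transverse arcs at their 2 mm
width and ~2 mm spacing. The wedge thickness tapers linearly from 3 mm at
the inner edge to 11 mm at the outer edge, and fiber layers sit at fixed
fractions of the *local* thickness — transverse arcs stay flat while
longitudinal fibers follow the taper, as a molded layered truss would.

Defaults reproduce the design counts exactly: levels 1/2/3 carry 6/4/2
transverse arcs (target lengths 45/40/35 mm, trimmed symmetrically about the
apex) and 13/12/8 longitudinal fibers (lengths 26/18/12 mm — shortened by
8 mm then 6 mm), stacked bottom-to-top as levels 1,1,2,2,3. Longitudinal
fibers fan across the 180° span (15° apart at level 1), launched outward
from each level's inner station band; upper levels occupy the outer, taller
part of the wedge. Interlock U-loops (two vertical legs one gap apart,
joined at the lower layer) bind adjacent layers at every bundle crossing of
the upper layer's lattice. The braiding yarn cross-section is not specified
anywhere in the source; 0.5 mm² (half the bundle width at half height) was
chosen once as a plausible yarn and documented here. All dimensions scale
together (`scale_design()`), and counts are invariant under scaling.

## Macro comparison and its headline number

The macro model embeds the full lattice (bar area = geometric section × Vf,
bar modulus = fiber axial modulus) in the meshed wedge, fixes the base, and
applies each total load as a uniform vertical pressure (load over projected
top area) with consistent nodal forces; the stiffness is factorized once per
model. "Resistance to deformation" is the inverse of the maximum downward
displacement of the loaded surface at equal load, and the improvement is
(u_matrix/u_reinforced − 1)·100 — in a linear model this ratio is
load-independent, which the tests verify to 1e−6.

At the default 1 mm mesh the package obtains an improvement of ~133 %,
substantially above the ~60 % figure reported for comparable braided
implants. Two honest caveats accompany that number.

First, it is not mesh-converged. The pure-matrix displacement is stable
under refinement (0.124 → 0.136 mm at 400 N from 4 mm to 1 mm meshes), but
the reinforced displacement keeps softening, so the improvement falls
monotonically with refinement: roughly 642 / 379 / 228 / 227 / 184 / 133 %
at 4 / 3 / 2 / 1.5 / 1.25 / 1 mm. This is the known behaviour of embedded
near-rigid reinforcement lines in a very soft matrix (stiffness ratio
~2000): a bar constrains its entire host element, so coarse meshes
over-stiffen, and convergence toward the line-inclusion limit is slow. The
continuum-limit value lies below 133 % and plausibly nearer the published
figure, but verifying that would need meshes far beyond a desktop R run;
the package reports values at stated resolutions instead of extrapolating.

Second, the driver is a geometric choice the source leaves open. Isolating
fiber families shows the horizontal lattice alone contributes ~33 % (at a
2 mm mesh) while the interlock loops dominate: loops at every bundle
crossing, with successive layer pairs sharing plan stations, stack into
nearly continuous through-thickness Kevlar columns precisely where the
wedge is tallest and deflects most. Neither the interlock density nor the
yarn cross-section is specified anywhere in the source; both were fixed
once, a priori, and are exposed (`interlock_area`, the design fields) for
sensitivity studies rather than calibrated to match the published ratio.
Note also that reading the published figure as a deformation *reduction*,
(1 − u_r/u_m)·100, the 2 mm-mesh simulation gives ~70 %. The acceptance
suite keeps the stricter published-ratio check at a documented 2 mm
scaled-down mesh, and its failure under these conditions is recorded rather
than hidden.

## Problem sizes and determinism

Default meshes are deliberately modest: the micro cell is 2 × 2 × 3
elements (its axial answer is mesh-exact, see above), meso cells ~380
elements, and the macro wedge ~12 000 elements at the default 1 mm
resolution (a full comparison runs in minutes on one CPU); the test suite's
macro runs use 2–5 mm resolutions to stay fast, and the pure-matrix
solution changes by ~6 % between 4 mm and 2 mm meshes. Everything is
deterministic — direct sparse factorization, no iterative solvers, no
randomness — so identical configurations produce byte-identical outputs.

## What passing tests do and do not show

The synthetic geometry generator emulates the *designed* lattice: exact
fiber counts, nominal dimensions, idealized elliptical arcs and straight
fans. It does not emulate manufacturing variability (yarn waviness, resin
pockets, debonding), contact with the femoral condyle and tibial plateau,
friction, large deformation or viscoelasticity of PCU — all outside the
linear-elastic scope. Agreement between the two homogenization pipelines
shows internal consistency of the embedded-fiber discretization and the
multi-scale material assignment, not agreement with experiment; the
bar-based micro cell in particular understates bundle transverse stiffness
by construction. Where the implementation's results depend on geometry the
source leaves open (meso RVC tables, the macro improvement), the package
reports computed values and documents the dependence instead of fitting it.
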