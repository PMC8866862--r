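---
title: "Biomechanics of mandibular fracture fixation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomechanics of mandibular fracture fixation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

After open reduction of a simple mandibular fracture, the fixation hardware
must keep the interfragmentary tissue in a mechanical regime that allows bone
healing (local strains below roughly 15%) without itself yielding under
post-operative mastication loads. Titanium (Ti-6Al-4V) miniplates are the
clinical standard; biodegradable magnesium (WE43) and polylactide (PLA)
devices are candidate replacements with much lower elastic moduli. `mandifix`
builds an in silico test bench for this comparison: a parametric synthetic
mandible, four fracture scenarios (symphysis, body, angle, condylar neck),
miniplate/screw fixation in two plate thicknesses (1.0 and 1.5 mm), an
orthotropic linear-elastic finite-element solver, and the post-processing
statistics used to judge both implant safety (peak von Mises stress against
yield) and the healing environment (dominant principal strains in the
fracture gap).

# The synthetic mandible

No patient geometry ships with the package; the generator
(`mandible_params()`, `build_mandible()`) produces a desk-scale stand-in: a
rounded-rectangular cross-section (width 5 mm, height 6 mm, cortical shell
1.25 mm) swept along a horseshoe axis — an anterior arc of radius 9 mm over
150 degrees, a quarter-circle bend of radius 5 mm into each vertical ramus
(6.5 mm), then condylar neck (5 mm) and a flared condylar head (2 mm,
widening 1.35x). The condylar axis is set back 2 mm posteriorly, reflecting
that the condyle sits at the posterior ramus border while the
coronoid/temporalis side is anterior; this setback controls the muscles'
moment arms about the locked condyles. A homogeneous teeth block (2 mm high,
core width) is fused to the crest along the central 55% of the arc. Six
cortical label bands (symphysis, body, angle, ramus, condyle, coronoid
process) are assigned by axis arc length; the core is trabecular.

Dimensions are roughly 0.4x of a nominal adult mandible. This is a
deliberate choice: the package's study design calls for repeated re-solves
(24 fixation scenarios plus a refinement study down to 0.5 mm edges), and
the desk scale keeps every mesh in the 10^4-10^5-element range. Because the
model is linearly elastic, geometric similitude makes this exact rather
than approximate for fields: scaling geometry by k and forces by k^2 leaves
stress and strain unchanged. The loading module therefore multiplies the
muscle forces by `(arch_radius / 22.5 mm)^2` (0.16 by default). What the
desk scale does *not* preserve is the patient-specific shape — lever-arm
ratios, section moduli and hence absolute field magnitudes differ from any
real mandible, which is why the package's claims are orderings and patterns,
not absolute strains. The share of muscle force transmitted to the bite
point is correspondingly smaller here than the ~60% of a real mandible (the
stubby condylar clamp reacts most of the muscle moment), and healing-region
strains sit below clinical reports; comparisons across materials,
thicknesses and sites are unaffected, as all scenarios share the load path.

## Meshing

The solid is meshed by a mapped structured lattice in sweep coordinates
(axis arc length `s`, lateral offset `u`, vertical/anterior offset `v`).
Grid planes are snapped to the cortical interfaces, the segment boundaries
and the tooth-row limits, so region volume fractions are exact and stable
under refinement; each hexahedral cell is split into six tetrahedra around
its main diagonal (a translation-invariant pattern, hence a conforming
mesh), and midside nodes are inserted at physical edge midpoints to form
straight-edged quadratic tetrahedra (TET10). Straight edges make the
element Jacobian constant, so positivity is checked exactly. Vertex
positions are exactly mirror-symmetric about the mid-sagittal plane; the
quadratic nodes on curved segments deviate by O(h^2 x curvature) — about
0.15 mm at the default 1 mm edge — because the cell-diagonal pattern is not
mirror-invariant.

# Materials

The material table (12 cards) lives in
`inst/extdata/materials_table1.csv`: six orthotropic cortical regions,
isotropic trabecular bone (E = 300 MPa), teeth (17600 MPa), granulation
tissue for the fracture gap (E = 3 MPa, nu = 0.4) and the devices
(Ti-6Al-4V 110 GPa, sigma_y 880 MPa; WE43 44.2 GPa, 162 MPa; PLA 3.5 GPa,
70 MPa). For the orthotropic cards the compliance is built from the
engineering constants with the minor Poisson ratios derived by symmetry
(nu_ji = nu_ij E_j / E_i) and checked for positive definiteness on load.
Where an isotropic card prints a shear modulus (teeth, granulation, the
devices) the printed value is used even when it differs slightly from
E/(2(1+nu)); where none is printed (trabecular bone) the isotropic relation
supplies it. These cards are only ever used in an unrotated frame, so the
tiny cubic anisotropy implied by a printed G is inert.

Cortical orthotropy is expressed in a local frame with direction 1
longitudinal (the sweep-axis tangent), 2 tangential and 3 transverse;
per-element stiffness is rotated to global axes by full fourth-order tensor
rotation (energy-invariant by construction, verified against a Bond-matrix
oracle in the tests). Voigt order is 11, 22, 33, 12, 13, 23 with
engineering shear strains throughout.

# Fracture and fixation

A fracture is a 1.2-mm slab (configurable within 1.0-2.0 mm) across the
full section, relabeled as granulation tissue. The bone is *not*
topologically split: load crosses the gap through the soft tissue and the
device, and strains are evaluated inside the slab (the healing region).

Plates are lattice solids with cylindrical holes, built in plate-local
coordinates and wrapped onto the lateral bone surface through the same
sweep map as the bone, so they follow the curvature exactly. Device
dimensions are 2.0-miniplate-system proportions scaled with the geometry:
hole pitch 3.0 mm (2.5 mm for the condylar center-space plates), width
2.2 mm, screw diameter 1.0 mm, monocortical screws engaging 2.5 mm beyond
the surface. Scenario layouts follow surgical practice: two parallel 4-hole
plates at symphysis and body, one 6-hole plate riding the superior
(oblique-ridge) border across the angle, and a 2-hole plus 4-hole pair with
center space on the condylar neck. The fracture plane is snapped to the
nearest lattice column so the realized granulation slab is the same number
of cell layers at every site (gap strains scale inversely with the realized
slab thickness, so this keeps sites comparable); at the symphysis the
midline tie-break makes the cut paramedian. The two
thickness variants share the plate midsurface position so their screw axes
coincide and thickness is the only difference between them.

Devices are joined by linear multipoint tie constraints (no relative
motion), eliminated exactly through a sparse reduction matrix rather than
penalties — no stiffness parameter to tune, and rigid-body motion transmits
force-free. Screw nodes inside the bone are constrained volumetrically to
their host element's quadratic interpolation (the screw is embedded; the
bone is not carved out, a rebar-style simplification that slightly stiffens
the screw bed); screw surface nodes at plate level are projected onto the
nearest plate hole face.

# Loading and boundary conditions

Right unilateral clenching: seven muscle pairs (superficial/deep masseter,
anterior/medial/posterior temporalis, medial and inferior lateral
pterygoid) act on 2.5-mm-radius attachment patches (1.5 mm for the lateral
pterygoid on the short neck). Each patch resultant is maximum force x 0.2
(post-operative reduction) x side-specific activation x direction cosines
(X cosine sign flips between sides) x the similitude factor. Uniform
tractions are converted to consistent nodal loads; on straight quadratic
triangles these put zero on corners and a third of each face's share on
midside nodes, conserving the resultant exactly. Both condyles are fixed in
all three translations over their end patches (solid elements carry no
rotational DOFs, so this also suppresses condylar rotations) and the right
first-molar-second-premolar occlusal band is restrained vertically; its
vertical reaction is reported as the bite force.

# Solver

Element stiffness uses a 4-point Gauss rule — exact for the degree-2
integrand of straight TET10 elements, and verified in the tests against an
independent 11-point (Keast, degree 4) quadrature implemented in plain R.
After tie elimination and Dirichlet removal the system is solved by
supernodal sparse Cholesky, with a relative-residual guard at 1e-9.
The finest convergence-study mesh (0.5 mm, ~360k DOFs) would need a
multi-GB factor, so when a coarser companion level is available the solver
switches to a two-grid preconditioned conjugate gradient method: the
preconditioner combines a damped Jacobi sweep with a coarse correction
through the factorized next-coarser mesh, prolongated by quadratic shape
functions in sweep-parameter space. It converges to a relative residual of
1e-10 in a few dozen iterations and keeps memory near 1.5 GB. Strains and
stresses are recovered at the four integration points per element.

# Post-processing

Within the healing region, both principal extremes of the strain tensor
are computed per integration point and the dominant one (largest
magnitude, sign kept; ties go to tension) is retained, in percent. Points
are split by its sign into tensile and compressive subsets and summarized
by box statistics (min, Q1, median, Q3, max; unweighted over points by
default, volume-weighted behind a flag), plus the fraction of points below
the 15% interfragmentary-strain criterion. Device safety uses von Mises
stress at the device integration points with a singularity guard: the top
0.1% of values (ceil(0.001 N)) are excluded — tie constraints create
artificial stress concentrations — and the peak is the mean of the ten
next-highest values, reported also as a fraction of the device material's
yield strength.

# Study orchestration and verification

`run_study()` iterates the 4 x 3 x 2 scenario matrix, reusing the meshed,
tied and loaded model across the three materials of each site/thickness
pair; failures are collected per scenario without aborting the matrix.
`run_healthy()` solves the intact mandible for the bite-force readout.
`run_convergence()` re-solves the intact model at a ladder of edge lengths
(default 2.0, 1.0, 0.5 mm) with simplified isotropic properties (cortical
15000 MPa, trabecular 300 MPa, nu = 0.3) under a fixed masseter patch load
(Fx = 0, Fy = -50 N, Fz = 50 N applied verbatim, since only relative errors
matter), and reports region-average von Mises stress and principal strains
against the finest level; the 1.0-mm working mesh agrees with the 0.5-mm
reference to within a few percent, which is why 1.0 mm is the default
resolution. The choice of problem sizes — coarse 2-mm meshes in the unit
tests, the default 1-mm mesh for the scenario matrix — keeps the full suite
in the tens of minutes on a single core.

Verification is layered: exact identities (patch test reproducing linear
fields to 1e-10, zero force under rigid translation through ties, reaction
equilibrium at 1e-6 N, strain energy = 1/2 f'u), classical benchmarks
(slender cantilever within 2% of Euler-Bernoulli theory), independent
oracles (11-point quadrature, Bond matrices, brute-force order statistics),
and the qualitative reproduction of the study's headline patterns: no
device yields at post-operative load; PLA fixation strains the healing
region more than WE43, which is at or above titanium; posterior fracture
sites (angle, condylar neck) heal under higher strains than anterior ones;
and a 0.5-mm plate thickness increase matters less than the material
choice.

# What passing tests do and do not show

The generator emulates the study *conditions* — anatomy-like topology,
regional orthotropy, muscle-driven statics, gap-filled fractures — not a
patient. Passing the pattern tests supports the comparative conclusions
(material orderings, site orderings, the smallness of the thickness
effect) on this geometry; it does not validate absolute strain or stress
magnitudes against any real mandible, nor clinical strain bands. Known
limitations, mirrored from the modeling choices: linear elasticity only (no
PLA viscoelasticity or creep, no degradation over time), tie constraints
admit no screw-bone micromotion, screws are smooth cylinders embedded
without carved holes, teeth form one homogeneous block, and the condylar
restraint is a bonded patch rather than a joint contact.
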