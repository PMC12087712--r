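---
title: "Methods: decoupled CT-to-FE modelling of plated femur fractures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoupled CT-to-FE modelling of plated femur fractures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(osteofe)
```

## Scope and model

`osteofe` builds subject-specific finite-element models of locking-plate
osteosynthesis from CT-like attenuation volumes. The pipeline is: generate or
read a Hounsfield-unit (HU) voxel volume; reduce it to a voxel material
database; mesh the implant assembly; map HU to Young's modulus either
node-wise or volume-averaged; solve the linear-static elasticity problem; and
evaluate the three mechanical demands of fracture fixation — interfragmentary
motion (IFM), peak plate von Mises stress, and strain-threshold bone volume
(EqSV) — across staged callus healing.

The mechanical model is deliberately the simplest one that supports the
scientific question: small-strain isotropic linear elasticity, constant-strain
tetrahedra, tied (shared-node) interfaces everywhere, a single material law
for cortical and trabecular bone, and a constant Poisson ratio of 0.3 for
every region. Frictional screw contact, screw threads, orthotropy, plasticity
and mechano-regulated healing are outside scope; with tied interfaces the
strain field immediately at the screw-bone interface is known to be
approximate, which is why EqSV should be read as a comparative, not absolute,
measure.

## The material database and the two mapping routes

`build_material_database()` stores the scan-space bounds (voxel-extent
convention: each axis spans `origin − spacing/2` to
`origin + spacing·(dims−1) + spacing/2`), the voxel pitch, and the full HU
set. Storage is a one-line JSON header plus a little-endian int16 block, so
integer round-trips are bit-exact and testable.

**Node-wise mapping** (`assign_nodewise()`): each bone node takes the HU of
the voxel whose centre is nearest by Euclidean distance; the law turns it
into a nodal modulus; each element averages its four nodal moduli with equal
weights. Ties at exact half-spacing go to the lowest linear voxel index — an
arbitrary but documented and deterministic rule. Nodes outside the database
bounds clamp to the nearest in-bounds voxel, so a surface node displaced by
geometry manipulation can never abort a run.

**Volume-averaged mapping** (`assign_volume_averaged()`): each element
receives the law applied to the volume-averaged attenuation over its extent,
optionally quantized to the midpoints of 8 equal-width modulus bins. The
volume average uses a fixed equal-volume sub-sampling rule: the element is
red-refined three times in barycentric coordinates, giving 512 equal-volume
sub-tetrahedra whose centroids act as equal-weight quadrature points. We
initially used 64 points (two refinement levels) but measured its error on
worst-case i.i.d. random voxel fields at up to 4.7 % of the attenuation span
for voxel-scale elements; 512 points stays below 1 %, which is the bound the
package's oracle tests assert. On smooth clinical-like fields the error is
far smaller and 64 points would suffice; the default favours the provable
bound.

The binned variant quantizes the modulus, not the attenuation; the
quantization error is bounded by half the bin width per element, which is the
mechanism by which piecewise assignment creates artificial stiffness jumps
(and, at cortical boundaries, stress risers) in the conventional route.

## Material laws

The subject-specific chain is `ρ_ash = −0.009 + 0.0007·HU` (g/cm³),
`ρ_app = ρ_ash / 0.6`, `E = 6950·ρ_app^1.49` (MPa). The commercial default
used for comparison is the affine pair `ρ = 1.31e−10 + 1.067e−12·HU`,
`E = −331 + 4.56e12·ρ` (MPa); only the composition of the two affine maps is
observable, so the density constants are kept exactly as printed and no unit
interpretation is attempted. Both laws clamp at a floor of `E = 0.01 MPa`:
air and marrow voxels otherwise yield non-positive moduli, and a small
positive floor keeps the global stiffness matrix positive definite without
measurably stiffening the structure. Both laws are monotone non-decreasing
in HU by construction, and the suite property-tests this on 10^4 random
pairs.

## The phantom femur

No clinical scans are distributed, so `generate_phantom_femur()` emulates a
long-bone CT as the package's study condition. Defaults, chosen once to be
representative of a (desk-scale) adult distal femur and then left alone:
bone length 180 mm (a full femur is ≈450 mm; the distal half suffices for a
distal-fracture construct), diaphysis outer/inner radius 12/7 mm, distal
metaphyseal flare to 20 mm radius over 45 mm, cortical attenuation
1500 ± 50 HU (i.i.d.), trabecular 300 ± 80 HU with a 4 mm-correlation smooth
field (coarse-lattice Gaussian noise, trilinearly interpolated), medullary
canal −50 ± 25 HU, soft-tissue envelope 40 ± 15 HU of 6 mm thickness, air
background −1000 HU, isotropic 1 mm spacing (exposed as a free parameter),
and optional calibration rods at nominal 0/75/150 mg/cm³ (generated for
realism, not used for recalibration — the laws take HU directly).

Two features exist specifically because the mapping is node-wise. First, the
soft-tissue envelope: a real limb scan never shows air at the periosteal
surface, and surface nodes must sample tissue-like attenuation, not
−1000 HU. Second, the trabecular-filled proximal metaphysis (20 mm): the
medullary canal of a real femur is closed at both ends, and the loaded
proximal face must not terminate in floor-modulus marrow.

What the phantom does **not** emulate: anatomic curvature and anteversion,
cortical thinning laws, beam hardening, metal artefacts, partial-volume
blur, and the anatomically offset mechanical axis. Consequently the absolute
deflections and load shares of the phantom differ from any cadaver-derived
number (the symmetric phantom splits condylar load 50/50 where an anatomic
femur carries ≈54–57 % medially); passing tests demonstrate correctness of
the algorithms and recovery of the qualitative trends, not clinical
magnitudes.

## Meshing and geometry manipulation

Assemblies are meshed on a structured cubic lattice; each retained cell is
split into six positively oriented tetrahedra (Kuhn split), which is
conformal across cells because every shared face carries the same diagonal.
Region membership (bone, plate, screw, pad) is decided at the cell centroid;
screws displace bone material where they cross it (zero-interference screw
holes), unfilled plate holes are left void, and all coincident parts share
lattice nodes — realizing the tied-interface contract without constraint
equations. Periosteal nodes that protrude beyond the analytic bone surface
are snapped radially onto it (with per-node damping if a snap would invert
an element), so the mesh conforms to the geometry the way a surface-fitted
CAD mesh would. Undistorted Kuhn tetrahedra have a 45° worst dihedral angle;
snapped surface cells can be squashed to a few degrees, which is harmless
for a direct sparse solver but is the price of conformity.

The fracture is applied *after* meshing and mapping are decoupled:
`apply_fracture_gap()` re-tags bone elements whose centroid lies in a 4 mm
slab as callus and records the healing-stage modulus (C1/C2/C3 =
1/10/100 MPa). Tags are stage-independent; stages differ only in the callus
modulus, so a sweep re-solves the same mesh three times.

The default 7-hole plate (112 × 14 × 4 mm, 2 mm standoff, holes at
z = 12…88 mm with the hole nearest the fracture left empty) is parametric
plumbing, not a reconstruction of any commercial implant; every dimension is
a config value. Plate and screws are 316L-type steel at 193 GPa; the
condyles rest on two flexible pads (25 MPa) with fixed bases, and the
proximal face is restrained to the frontal plane and loaded axially with
2.38 × 70 kg × 9.81 m/s² ≈ 1634.5 N, the peak-gait load (the package
computes the value rather than hard-coding a rounded Newton figure).

## Solver and verification

The sparse symmetric stiffness matrix is assembled vectorized over elements
(the 144 entries of each 12×12 block as element-length vectors) and solved
by CHOLMOD Cholesky factorization after eliminating prescribed dofs;
non-homogeneous Dirichlet values are moved to the right-hand side. There is
no iterative fallback: determinism matters more here than scalability, and
an indefinite system is reported as a configuration error. Reactions are
recovered as `K u − f` at constrained dofs, so global equilibrium closes to
the factorization tolerance (≈10⁻⁹ relative on the verification problems,
asserted at 10⁻⁶).

Verification is classical: the patch test (irregular interior nodes, linear
boundary displacement → uniform strain to 10⁻¹⁰ relative); a single
tetrahedron against a dense 12×12 oracle assembled independently from
finite-difference shape gradients; and a slender cantilever
(100 × 10 × 10 mm, tip-loaded) against the Euler–Bernoulli closed form.
Constant-strain tetrahedra are bending-stiff, so the beam check depends on
refinement: a convergence run gave tip-deflection ratios of 0.79/0.86/0.94/
0.96 at 4/5/8/10 lattice divisions through the depth; the package's
verification mesh uses 12 divisions (h = 10/12 mm, ≈10⁵ elements), where
the ratio is 0.971 — inside the 5 % band with the shear contribution
(≈0.8 %) still unmodelled by the Euler–Bernoulli reference.

## Metrics

* **IFM** (`compute_ifm()`): periosteal nodes adjacent to each gap face are
  candidate markers; the near-cortex pair maximizes the plate-side
  coordinate, the far-cortex pair minimizes it, and the distal partner of
  each proximal marker is the candidate closest in the gap plane. IFM is
  point-pair based (surface averaging would be the alternative; point pairs
  are exactly testable against rigid-body kinematics). Axial IFM is the relative displacement component
  along the gap normal, shear the in-plane magnitude at the far pair.
* **Peak plate stress** (`peak_plate_stress()`): volume-weighted mean von
  Mises over plate elements whose centroids lie within a 3 mm-diameter
  sphere, maximized over seed elements. The averaged peak provably never
  exceeds the raw element maximum.
* **EqSV** (`compute_eqsv()`): element principal strains (closed-form
  symmetric eigenvalues; element-constant because the tetrahedra are
  constant-strain) thresholded at +0.5 % tension / −0.7 % compression,
  volumes summed over bone within 5 mm of any screw axis by default (the
  radius is a config value; "around the screws" has no canonical
  definition), with a whole-bone variant.

## Study protocols

`run_healing_sweep()` solves the plated, fractured assembly once per stage
and tabulates the three metrics. On the default phantom the far-cortical
axial IFM decreases strictly (1.54 → 0.89 → 0.17 mm at the default mesh),
peak plate stress decreases (465 → 270 → 57 MPa), and EqSV volumes do not
grow — the qualitative healing trends the method exists to recover.

`compare_mapping_methods()` is the mapping-verification protocol on the
intact bone: one solve with the node-wise field, one with the (8-binned)
volume-averaged field, reporting load-direction deflection of the loaded
face, volume-fraction histograms of element modulus on shared edges, and
3 mm-averaged sectional peak von Mises at 20/50/80 % of bone length. The
node-wise histogram converges toward the volume-averaged reference under
mesh refinement (L1 distance 0.73 at h = 3 mm vs 0.39 at h = 2 mm on the
default phantom); under axial load on the straight phantom the two
deflections differ by well under 1 %, against ≈20 % for an anatomically
loaded femur — bending, which the symmetric phantom deliberately lacks,
is what amplifies the mapping difference.

## Problem sizes and numerical choices

The package's default study sizes, chosen as its own verification scale:
phantom volume ≈ 7 × 10⁵ voxels at 1 mm; assembly mesh h = 2 mm
(≈ 8.7 × 10⁴ elements), mapping comparison at h = 3 and 2 mm, cantilever at
h = 10/12 mm (≈ 10⁵ elements). A full healing sweep plus verification runs
in a few minutes on one CPU; halving h roughly octuples assembly cost and
is a config-level change.

Other numerical decisions: nearest-voxel ties to the lowest linear index;
bin edges half-open with the upper extreme folded into the last bin;
out-of-range histogram moduli are an error, never silently dropped;
fracture-slab membership by element centroid; lattice cell size rounds the
requested edge length to divide the domain exactly; derived RNG seeds stay
below 2³¹. Degenerate inputs (empty regions, slabs missing the bone,
under-constrained systems, truncated containers) raise immediate, specific
errors.

## Known limitations

Tied screw-bone contact overestimates interface tension; constant-strain
tetrahedra need fine meshes in bending; the lattice mesher only represents
geometry to voxel-like fidelity away from the snapped periosteal surface;
the phantom is axisymmetric and straight, so shear IFM arises only from the
plate's asymmetry rather than anatomic torsion; and absolute magnitudes are
phantom-specific. None of these affect the package's purpose: a fully
testable, manipulable, subject-specific mapping workflow whose every
numerical claim is backed by an oracle in the test suite.
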