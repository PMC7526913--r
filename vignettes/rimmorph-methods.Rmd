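---
title: "Models and methods behind rimmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rimmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rimmorph` packages a complete 3D cellular-morphometry workflow for
membrane-labeled *C. elegans* embryos: a refractive-index (RI) matching
assay, a watershed-based 3D segmentation pipeline, per-cell shape
descriptors, a cortical-tension shape simulation, and a synthetic-data
generator that stands in for real microscope stacks. This vignette
explains each model, the tunable parameters and their defaults, the
numerical choices, and what the synthetic tests do and do not establish
about real data.

## The synthetic embryo generator

The generator emulates a membrane-channel (PH-domain marker) z-stack of
an early embryo.

**Geometry.** The embryo is an ellipsoid with semi-axes 25 × 15 × 15 µm
(the typical ~50 × 30 × 30 µm egg), discretized at a voxel pitch of
0.16 × 0.16 × 0.5 µm by default (the acquisition geometry of the imaging
setup the package targets). Its interior is partitioned into `n_cells`
regions by a nearest-seed (Voronoi) rule; seeds are placed by
deterministic best-candidate sampling, which keeps regions convex-ish and
comparable in size, like blastomeres at the 24–32-cell stage. Cells
flagged *round* — stand-ins for mitotic or germline-precursor (P4-like)
cells — are re-carved as the largest ball around their seed that fits in
their region, the shed shell being reabsorbed by adjacent cells so the
partition of the interior is preserved.

**Signal.** Membrane voxels (any voxel within `membrane_thickness_vox` of
a label change) get 2000 counts, cytoplasm 400, exterior 0. These are
EMCCD-like 16-bit-scale counts; the choice matters because the watershed
tolerance of the published pipeline (22 gray levels) is calibrated
against such data — on an 8-bit-like scale the same tolerance would be
restrictive rather than permissive and the pipeline's failure modes
invert.

**Optical degradation** (`optics_params()`). Slice `z` (depth `z·Δz` µm,
slice 1 nearest the coverslip) is blurred laterally with
σ(z) = σ₀ + r·z, scaled by exp(−λ·z), multiplied by a *speckle* field
`1 + s·z·F` (F a unit-variance Gaussian random field with 1.5 µm
correlation length), offset by a camera background (100 counts), and
finished with Poisson shot noise and Gaussian read noise (sd 30). The
speckle term deserves explanation: aberration does not dim a deep slice
uniformly — interference between misaligned wavefronts produces smooth,
patchy gain variations. White camera noise cannot reproduce the
over-segmentation seen in degraded real stacks, because the pipeline's
own Gaussian blur averages it away; a correlated field at the micrometre
scale survives the blur and seeds spurious catchment basins in deep
cells, which is exactly the failure mode observed in mismatched-medium
imaging. Two presets define the study conditions:

| preset | λ (1/µm) | blur growth r | speckle s (1/µm) | emulates |
|---|---|---|---|---|
| `matched` | 0.01 | 0.01 | 0.004 | RI-matched medium (~30% iodixanol) |
| `mismatched` | 0.03 | 0.025 | 0.012 | plain aqueous buffer |

These values were fixed once, calibrated only to reproduce the
*direction* of the depth effects (deep signal loss, more frequent deep
segmentation errors in the mismatched condition); no quantitative
attenuation measurement exists to anchor them.

**What is not emulated:** intracellular organelle texture, nuclei and
chromatin, the eggshell and perivitelline space, cell divisions during
acquisition, and any physically correct point-spread function.
Consequently, passing tests demonstrate that the algorithms behave
correctly under controlled degradation of known ground truth — not that
the pipeline's absolute accuracy on real embryos equals the synthetic
panel's.

## The DIC contrast model and RI matching

DIC converts optical path-length gradients into contrast, so a specimen
in an RI-matched medium nearly vanishes. The model is

`contrast(c) = 1 + k · |RI_sample − (RI₀ + m·c)| + ε,  ε ~ N(0, σ²)`

with RI₀ = 1.334 (egg-salt buffer), slope m = 0.0015 per % iodixanol (so
30% gives 1.379, the measured RI of the matched medium), specimen RI
1.379, gain k = 20 (giving contrast ≈ 1.9 in plain buffer, a typical
value for an embryo under DIC) and replicate noise σ = 0.05.
`find_matching_concentration()` is a per-concentration argmin of mean
contrast with an explicit smallest-concentration tie rule.
`welch_t_test()` and `holm_sidak()` implement the statistics used for the
"matched vs. others" comparisons; the Holm–Šídák step-down is applied to
pairwise Welch tests against the matched group rather than to ANOVA
post-hoc contrasts — with the synthetic model both give the same calls,
and only the pairwise comparisons are ever reported.

## The segmentation pipeline

`run_pipeline()` composes three stages with the published parameter set.

**Attenuation correction** (opening radius 3 px, reference = midplane,
i.e. slice `floor(n_z/2) + 1`). Per slice, a grayscale opening with a
3-px disc suppresses the thin bright membranes, leaving a
cytoplasm/background level; its mean over *specimen foreground* (opened
values above a global Otsu cut) estimates the slice's signal level.
A log-linear decay is fitted to these levels (weighted by foreground
size) and each slice is multiplied by `b̂(ref)/b̂(z)`. Two design points:
restricting to foreground prevents the varying embryo cross-section from
biasing the estimate, and fitting (rather than per-slice ratios) keeps
the gain profile smooth in z — raw ratios imprint estimator noise onto
the stack as axial gradients that split cells. For a stack whose slices
decay exactly exponentially the fit is exact.

**3D Gaussian blur** with σ = (2, 2, 0.6) voxels, separable, sampled
kernels truncated at 4σ, reflective boundaries.

**Tolerance watershed** ("border" image type: the bright-membrane
intensity image itself is flooded, no gradient). Extended minima with
dynamic h = 22 are computed by morphological reconstruction by erosion of
`image + h` over `image`; each minima component seeds a basin; flooding
follows a fully deterministic rule — the unlabeled frontier voxel with
the smallest (intensity, linear index) is assigned the label of its
smallest-(intensity, index) labeled neighbor — so identical inputs give
identical label grids, and a naive linear-scan implementation of the same
rule serves as the test oracle. Every voxel receives a label; the basin
with the largest grid-border contact is classified as exterior.
Segmentation quality is α = 100·n_true/n_detected, uncapped, so
over-segmentation gives α < 100% and merging α > 100%.

On the synthetic panel (ten 24-cell embryos, 0.4 × 0.4 × 0.8 µm voxels)
the pipeline detects 24 ± 2 cells under `matched` optics (mean α ≈ 96%)
and over-segments under `mismatched` optics (mean α ≈ 83%). The
attenuation-correction ablation uses a harsher stress condition
(λ = 0.13/µm) in which deep membranes fall below the watershed tolerance
without correction; correction reduces the count error from ~10 cells to
≤ 2.

## Morphometry

Volume is voxel count × voxel volume. Surface area comes from a
triangulated iso-surface: the cell mask is padded by one empty voxel
(border-touching cells still close), smoothed with a Gaussian, and meshed
at level 0.5 by marching tetrahedra on the Kuhn subdivision of each grid
cube — a translation-consistent tetrahedralization, so the mesh is
watertight with consistently outward-oriented faces, and the
divergence-theorem volume is exact for the mesh. Smoothing removes the
staircase bias of binary masks (which would inflate a sphere's area by
~25–30% and break the ψ ≤ 1 invariant); its width adapts to the region,
σ = min(1, r_eq/12) voxels per axis, because a fixed σ erodes small
regions (curvature shrinkage ∝ σ²/r). With this rule a digital ball of
radius 20 voxels measures within 0.5% of the continuum area and
sphericity stays ≤ ~1.04 at every size; values slightly above 1 are
discretization artifacts and the package asserts ψ ≤ 1.05 in its own
tests. Sphericity is ψ = 36π V²/S³ with V from voxel counting. The
ellipsoid fit takes the voxel-position covariance and scales eigenvalues
as a_i = √(5 λ_i), exact for homogeneous solid ellipsoids; both
descriptors are reported because shape tables in the field variously use
the area-based and the fit-based quantity. Meshes export as binary
little-endian STL in micrometres.

## The cortical-tension simulation

A 2D cross-section of a 13-cell embryo is modeled as polygons sharing
vertices. Every polygon edge is a contractile element: outer (surface)
elements carry the cortical tension of their cell's type, inner
(interface) elements a cell–cell tension. The energy is

`E = Σ_e γ(e)·ℓ(e) + Σ_c K_A (A_c − A₀_c)²`

The area term is not part of the published description, which specifies
only tensions and viscosity, but pure line tension would collapse the
cells; K_A = 10 (with cell areas ~0.4 in scene units) keeps relaxed areas
within 2% of target, a soft-incompressibility stand-in for cytoplasmic
volume conservation. Viscosity is absorbed into the drag μ of the
overdamped dynamics `x ← x − (dt/μ)·∂E/∂x`, since only steady states are
compared. The scene builder clips a Voronoi diagram of 13 hand-placed
sites to an ellipse (semi-axes 1.6 × 1.0), snaps shared vertices
(tolerance 0.03, which also removes sliver edges), types the posterior
triplet E.p/P4/D with P4 at the posterior pole touching both, and
subdivides every boundary into ≥ 3 elements. Elements stretched beyond
twice the initial mean are re-split mid-run.

**Numerics.** Fixed-step explicit Euler excites a slowly growing
oscillation of stiff local modes on this scene at any practical dt, so
the integrator backtracks: any step that would raise the energy is
halved until it does not (energy is then nonincreasing by construction),
and the step relaxes back toward the nominal dt = 0.005 afterwards. A
step collapse of more than eight orders of magnitude raises an error
advising a smaller dt. Convergence is declared when the nominal-step
displacement falls below `tol`.

**Readout.** Interface curvature is a least-squares circle fit to the
shared vertex chain, signed positive when the arc bows into the
neighbor (the focal cell bulging). At equilibrium an interface obeys the
Young–Laplace balance ΔP = γ_in·κ with ΔP = 2K_A(A₀ − A) differences;
the doublet test verifies this within 5%. The bulge flag of
`tension_sweep()` fires when both P4 interfaces have dimensionless
curvature κ·L > 0.15 (arc sagitta ≈ 7.5% of the chord) with P4 convex —
"started to curve" is qualitative in the source experiments, so the
threshold is an explicit, reported parameter rather than a hidden one.
With the default scene, tensions 0.1 everywhere and the P4 sweep
{0.1, 0.15, 0.2}, the onset ratio is 1.5: at equal tension κ·L stays
below 0.08 with inconsistent signs, at 1.5× both interfaces exceed the
threshold decisively (κ·L ≈ 0.6).

## Reproducibility and problem sizes

Every stochastic stage takes an explicit integer seed
(`withr::with_seed`, so the global RNG state is untouched), and
`run_workflow()` expands one global seed into per-stage seeds and writes
a manifest with parameters and file hashes. The test suite runs full
embryos at 0.4 × 0.4 × 0.8 µm voxels (~430k-voxel stacks) and panels of
ten embryos — sizes chosen so the whole suite, including the brute-force
oracles, completes in minutes while each stack still spans ~30 µm of
depth and 24 cells.

## Known limitations

* The attenuation-correction internals of the original Fiji plugin are
  not published; the foreground-restricted fitted-gain model here matches
  its stated purpose and the reproducible examples, not necessarily its
  code path.
* The aberration model is first-order (separable blur, exponential decay,
  multiplicative speckle); it reproduces directions and rough magnitudes
  of depth effects, not the physics of a mismatched point-spread
  function.
* Sphericity from meshed digital masks carries a few-percent size- and
  orientation-dependent bias; comparisons should stay within one voxel
  geometry, as the package's own tests do.
* The 2D tension model has no rheology beyond drag, no rest lengths, no
  T1 rearrangements; it predicts steady-state interface curvature, not
  dynamics or internalization itself.
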