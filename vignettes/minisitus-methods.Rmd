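---
title: "Multi-resolution map fitting with minisitus: models, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution map fitting with minisitus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minisitus)
```

# The problem

Hybrid structural modelling places atomic models into lower-resolution
density maps from cryo-electron microscopy, tomography or small-angle X-ray
scattering. Three structure types interconvert throughout: atomic models
(PDB), volumetric maps on a cubic lattice, and coarse bead or feature-point
models. minisitus implements the data model, the conversion conventions, a
cross-correlation docking engine, and the surrounding volume algebra as a
tested R library with a command-line front end.

# The map model and formats

A `volume_map` is a scalar field on a cubic lattice: voxel spacing `width`
(Å), the physical coordinate `origin` of voxel `(0,0,0)`, and counts
`(NX, NY, NZ)`. Data are ordered with x fastest and z slowest, matching the
ASCII Situs map format (a 7-number header followed by the densities). The
binary MRC/CCP4 family is supported as a deliberately narrow modern subset:
mode 2 (float32) only, axis order 1,2,3 only, orthogonal cells only, cubic
spacing enforced to 0.1%, byte order auto-detected from header plausibility
(dimensions in 1..100000, known mode code). Historical dialect variations
beyond this subset are rejected loudly rather than guessed at; the origin is
taken from the ORIGIN record when nonzero and otherwise from the start
indices times the voxel width. This strictness trades breadth for the
guarantee that anything read is interpreted unambiguously.

# Resolution conventions

"Resolution" differs across communities, and the package derives all
conversions from first principles at run time rather than storing constants:

* crystallographic `r_c = 1/R_c`, the inverse of the Fourier cutoff radius;
* Rayleigh point resolution `r_p`: first zero of the Airy pattern
  `[J1(2*pi*r*R_c)/(2*pi*r*R_c)]^2`, located by root-finding on `besselJ`;
* the Gaussian kernel `exp(-3 r^2 / (2 sigma^2))` with `r_s = 2*sigma`
  (the "2-sigma" convention used for `pdb2vol`-style resolution lowering);
* the EMAN kernel `exp(-pi^2 r^2 / r_e^2)`.

Gaussians are tied to the diffraction-limited case by matching each kernel's
FWHM to the FWHM of the central Airy disk. Running
`resolution_factor_table()` reproduces the conversion constants printed in
the field's literature (0.610, 0.514, 1.471, 0.756, 1.886, 1.282, 0.969) to
their three printed decimals. One caveat is inherent: chained constants in
print are quotients of already-rounded three-decimal numbers (for example
0.756/0.610 = 1.239), whereas the unrounded first-principles chain gives
1.2411 for the same ratio. The tests therefore compare computed factors at
the printed three-decimal precision with a +-0.002 band, which absorbs
exactly this rounding provenance and nothing more.

# Rasterization (pdb2vol) and its inverses

`pdb2vol` lowers resolution in two stages: trilinear projection of atom
weights onto the lattice (conserving total weight exactly), then FFT
convolution with a kernel sampled on the lattice. The Gaussian kernel is
truncated at `3*sigma`, where its amplitude is `exp(-13.5) ~ 1.4e-6`; maps
are padded by the truncation radius so convolution never clips, with the
origin shifted accordingly. Because convolution is linear, multi-fragment
densities are rasterized once from the summed lattice. `vol2pdb` inverts the
representation (not the blur): positive voxels become pseudo-atoms with the
density in the occupancy field, which `pdb2vol(weighting = "occupancy")`
round-trips.

`pdb2sax` projects a structure onto a hexagonal close-packed lattice with
center spacing twice the bead radius. Two conventions are not printed
anywhere authoritative and are therefore explicit, documented choices here:
a lattice site is kept when at least one atom lies within one bead radius of
it, and the lattice phase is anchored so a site coincides with the atom
centroid (both configurable). Bead counts consequently carry a small
phase sensitivity, at the level of a few beads out of hundreds on
protein-sized models.

# Scoring

The cross-correlation used throughout is the cosine form
`CC = sum(a*b) / (||a|| ||b||)` *without* mean subtraction: calculated
densities are positive mass distributions, so `CC` is in `[0,1]` for
nonnegative maps, and for a fixed probe the cosine and Pearson scores rank
translations identically. Under partial overlap the probe norm is taken over
its own support (constant across translations) and the target norm over the
full volume.

The 6-neighbor Laplacian emphasizes contours. Plain bulk correlation is
discriminative only while interior density variation survives the blur —
roughly, at resolutions finer than 10 Å relative to protein-sized features.
Beyond that the overlap integral rewards placing probe mass on whatever
density is nearby, and its maximum drifts toward regions where neighboring
subunits' tails add up; we observed exactly this inward drift on a simulated
15 Å hexamer ring. Contour scoring restores the pose signal and is the
prescribed mode in the ~10–30 Å range; with Laplacian filtering the same
fixture's top pose lands within half a voxel of the planted
protomer. Edge masking zeroes the Laplacian on the map boundary and within
one voxel of zero-density regions, suppressing the singular shells that
thresholding or segmentation would otherwise inject into the score.

# Exhaustive search (colores analog)

`colores_search` samples orientations on a z-y-z Euler grid with uniform
`phi`, `psi` and equal-area `theta` (`cos theta` uniform) — approximately
homogeneous on SO(3) without a published angle generator to follow — with
polar duplicates removed. Each orientation is rasterized on a fixed-size
cube about the probe centroid so the padded target FFT is computed once;
translations are scanned by the Fourier correlation theorem with zero
padding (linear, not circular, correlation), and per-orientation best
translations are merged, ranked, and pruned by a minimal centroid-distance
rule (default twice the voxel width) standing in for the original's
undocumented peak clustering. Translational resolution is one voxel;
orientation resolution is the angular step.

# Multi-fragment refinement (collage analog)

`collage_refine` maximizes the joint CC of all fragments at once over the
`6K` pose parameters, using a derivative-free Powell direction-set method
built from golden-section line searches; moves are accepted only when they
improve the score, so the trace is monotone by construction. The text
sources describe the optimizer variously as conjugate-gradient and Powell;
with no analytic gradient defined for the trilinear-plus-convolution
pipeline, the derivative-free direction-set form is implemented.
Convergence stops when a full pass gains less than `1e-6` CC.

Rotation increments are parametrized as rotation vectors (axis times angle,
in degrees) composed onto the current orientation about the fragment
centroid. An earlier Euler-increment form stalled with residual rotations of
several degrees: near the identity, z-y-z increments are gimbal-degenerate
(φ and ψ both rotate about z), so coordinate line searches cannot produce
x-axis corrections at first order. The rotation-vector form keeps all three
rotational degrees of freedom independent and the same fixture then refines
to fractions of a degree.

Normalizing by the joint calculated norm penalizes steric clashes: two
overlapping fragments inflate `||rho_calc||` without gaining target overlap,
so clashing configurations score strictly lower than separated ones — the
tests assert this on a two-fragment fixture.

# Symmetry

`pdbsymm` generates C, D and helical symmetry mates about an axis that
defaults to z through the target map center. The symmetry-constrained loop
alternates mate generation with a *single* refinement pass and keeps only
the refined master, so the final complex is exactly symmetric by
construction; convergence is declared when the master moves less than
0.05 Å and 0.1° between loops. The D-group two-fold axis phase is not
pinned by any printed convention and defaults to 0° (along x), configurable.

# Feature points and cloud matching (matchpt analog)

`vq` computes codebook vectors by best-of-restarts weighted k-means with
k-means++ seeding under a fixed seed. The historical quantizer is a
neural-gas-type update; distortion minimization is the contract either way,
and the tests assert the fixed-point property rather than a particular
update rule. Point variability across restarts — used in practice to select
the level of detail — is computed by optimally assigning each run's codebook
to the best run's (Jonker–Volgenant assignment) and averaging matched
distances; this is a documented stand-in for an aggregation whose exact
original form is not restated in the available sources. The level-of-detail
rule divides the structure volume by `r_s^3` and brackets the point count at
30–50% of that bound.

`matchpt` docks a small cloud (N points) into a larger one (M): seed
correspondences come from probe point triples matched to target triples
with compatible edge lengths (tolerance 1.5 times the target's mean
nearest-neighbor spacing by default), each seed is fit by SVD superposition
with a reflection guard, extended greedily by nearest unused target point
(exhaustively once two or fewer points remain), re-fit and ranked by RMSD.
For instances up to `M = 7` an exact search over all injections is available
and is the oracle the heuristic is validated against.

# Synthetic fixtures

All tests run on generated data. `make_monomer` builds an anisotropic
pseudo-atomic blob (axis scales 1 : 0.62 : 0.40, principal moments pairwise
distinct by at least 10% so no orientation is accidentally symmetric), and
`make_assembly_map` plants it in a C-symmetric ring and simulates the map
with Gaussian rasterization. The default hexamer emulates a RecA-like ring
at its true physical scale — monomer radius of gyration 16 Å, ring radius
33 Å, 15 Å resolution, 3 Å voxels — because shrinking the molecule while
keeping the blur fixed would silently degrade the *relative* resolution and
with it the pose signal (an earlier desk-scaled fixture produced a filled
disk whose best bulk-CC pose sat at the ring center). What passing these
tests shows is recovery of planted truths on noise-free simulated data;
experimental maps add noise, missing density, scale errors and magnification
anisotropy that these fixtures deliberately do not model.

Problem sizes used by the test-suite and the acceptance script — a ~60-voxel
target map, 744 orientations at the 30° step, six fragments of 180
pseudo-atoms, 100 random instances for the matching and correlation oracles
— were chosen so each end-to-end check represents the method faithfully at
desk scale.

# Numerical choices and limitations

* FFT sizes are padded to products of 2, 3 and 5; linear correlation is
  enforced by padding with the probe extent.
* Lattice mismatch in volume algebra is a strict error; `resample_to`
  provides deliberate trilinear registration instead of silent coercion.
* Projections multiply the along-axis sum by the voxel width (a Riemann
  line integral); the projection/difference commutation identity is
  invariant to this choice.
* `segment_connected` uses 6-connectivity, matching the Laplacian stencil.
* The MRC subset does not write or read symmetry records, axis
  permutations, or non-float modes; SPIDER and X-PLOR formats are out of
  scope, as are Fourier-space filters, flexible (non-rigid) refinement and
  FSC resolution estimation of experimental maps.
* PDB occupancy carries bead radii and encoded densities at two decimals —
  the column format's own precision limit.
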