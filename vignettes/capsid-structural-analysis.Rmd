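---
title: "Structural analysis of prolate phage heads with capsidgeom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural analysis of prolate phage heads with capsidgeom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidgeom)
```

## The system and the analyses

Tailed bacteriophages of the phi29 type package their genome into a prolate
icosahedral head: two T = 3 Caspar–Klug end caps joined by an equatorial
band of hexamers (elongation number Q = 5), with one five-fold vertex
replaced by a dodecameric portal, the connector.  The 12-fold connector
sitting in a 5-fold vertex creates a symmetry mismatch that shapes several
bespoke analyses: which rotational placements of the connector are sterically
permitted, whether the head and tail keep a fixed relative orientation, and
how far the connector moves within the capsid between maturation states.
capsidgeom implements these analyses, together with the supporting
infrastructure they need (structure and map IO, superposition, density
correlation, interface geometry), as ordinary R functions over plain
containers.

## The prolate lattice model

`build_lattice()` places capsomer centres on a spherocylinder: hemispherical
end caps of radius `width/2` with the five-fold axis on z, joined by a
cylinder carrying `Q - T` inserted rings of five hexamers.  Cap positions
come from the regular icosahedron — vertices carry pentamers; for T = 3 the
face centres carry hexamers.  Ring azimuths alternate by 36 degrees down the
stack, which makes consecutive rings antiprismatic and the whole site set
D5-symmetric before the connector is assigned.

Adjacency is **combinatorial**, not distance-thresholded.  On a prolate
surface the centre-to-centre spacings vary enough (e.g. an equatorial
in-ring spacing of `2 R sin 36°` versus a cap spacing near `0.65 R`) that no
single cutoff reproduces the Caspar–Klug contact graph; instead the ring
construction records exactly which sites touch: apexes contact their
surrounding ring; rings flanking an apex are in-ring adjacent; consecutive
rings pair antiprismatically (two nearest by azimuth); and for T = 3 each
ring also contacts the same-azimuth site two rings away, the band geometry
of a triangular lattice wrapped on a cylinder.  The resulting graph has
pentamer degree 5, hexamer degree 6 and Euler characteristic
V − E + F = 2 for every supported (T, Q) — properties the test suite checks
directly.

```{r lattice}
lat <- build_lattice(lattice_spec(3, 5, width = 400, connector_vertex = TRUE))
table(lat$type)
nrow(enumerate_fiber_sites(lat))
```

Head fibers are enumerated as the quasi-three-fold junctions where one
pentamer meets two mutually adjacent hexamers; junctions of three hexamers
and junctions at the connector vertex carry none, which yields the
characteristic 55 fiber positions of the phi29 head (5 per pentamer with
one vertex portalized).  Stoichiometry follows: 6 subunits per hexamer plus
5 per pentamer gives 235 major capsid proteins; 3 per fiber gives 165; the
portal is a dodecamer.

Geometric free choices, fixed once: the cylinder length is
`0.3 × (width/2) × (Q − T)` — close to the ideal band-row spacing of half a
capsomer diameter and, for T = 3, Q = 5 at width 400 Å, giving the observed
length-to-width ratio of 1.3 (520 Å by 400 Å).  The connector replaces the
bottom (z-minimum) apex.  Hexamer ring classes are labelled H1...H6 in
decreasing z, which reproduces the conventional labelling with H3/H4
equatorial and H6 adjacent to the connector.  The overall length check is
treated as loose (5%) because the experimental "~520 Å" does not state
whether surface ridges are included.

## Symmetry, orientations and the mismatch statistic

All angles are degrees; orientations are (alt, az, phi) triples under an
**intrinsic ZYZ** convention, `R = Rz(az) Ry(alt) Rz(phi)`.  The convention
was chosen so that az is the rotation about the symmetry (z) axis, i.e. the
angle degenerate under cyclic symmetry; it is isolated in
`euler_to_matrix()`/`matrix_to_euler()` so no other code depends on it.  At
gimbal lock (alt of 0 or 180) phi absorbs the in-plane angle and az is
reported as 0; orientation pairs are screened on alt/phi **before** azimuth
statistics are taken, so gimbal-degenerate particles never contribute.

For a particle whose tail has Cn symmetry, `min_azimuth_diff()` takes the
minimum wrapped azimuth difference over the n symmetry-equivalent tail
orientations; its value lies in [0, 180/n].  Pairs whose alt or phi differ
by more than 5 degrees (the screening threshold used for such data) are
discarded first.  `mismatch_summary()` bins the minimal differences
(1-degree bins) and reports a concentration statistic: the fraction of
particles within ±2 bin widths of the histogram mode.  The fixed/non-fixed
call uses a threshold of 0.5.  This operationalizes a judgement that is
usually made from plots: a connector locked to the capsid concentrates all
mass near one value (concentration near 1), a freely rotating one gives a
flat histogram (concentration near the bin fraction, about 0.25 for n = 12).
Both regimes sit far from 0.5, so the classification is insensitive to the
exact threshold.

## The rotational clash scan

`rotational_scan()` rotates a mobile assembly about a symmetry axis in
1-degree steps (configurable) and scores each placement with the
MolProbity-style clashscore, 1000 × (bad overlaps) / (atoms of the mobile
model).  A bad overlap is a heavy-atom pair interpenetrating by at least
0.4 Å given per-element van der Waals radii (C 1.70, N 1.55, O 1.52,
S 1.80, P 1.80 Å); the boundary counts as bad, hydrogens are ignored.  The
mobile-only denominator reflects that the scan scores placements of the
mobile body; a union denominator is available
(`denominator = "union"`) since either normalization is defensible.  Pair
counting uses a cell-list spatial hash whose result is defined (and tested)
pair-exhaustively.  Alongside the clashscore the scan tracks the minimum
distance between two named-atom selections — in the connector-in-capsid
instance, the 12 Tyr122 CA atoms of the connector against the 5 Trp156 CA
atoms of the capsid wall.  `allowed_windows()` extracts the maximal
contiguous clash-free intervals, merging wrap-around runs; the width of a
window is (number of free grid angles) × step.

## Superposition and displacement

`kabsch()` is a standard SVD least-squares superposition with the
determinant correction that excludes reflections.  `rmsd_ranges()` pairs
atoms strictly by (chain, residue number, insertion code, atom name) —
sequence- or structure-based equivalencing is deliberately out of scope —
and errors on any gap rather than pairing silently.  Three fitting modes
cover the comparisons that arise in practice: fit on the measured ranges,
fit on all shared atoms, or no fit at all for pre-aligned frames.
`cog_displacement()` measures positional change of a subassembly in a
common frame: the frame models (the capsids) are superposed on their shared
CA set, the transform is applied to the second state, and the displacement
of the unweighted centroid ("gravity centre"; no mass weighting, as none is
implied by the measurements it supports) of the selection is reported.
Measuring the connector's axial shift this way separates genuine relative
motion from accompanying capsid expansion.

## Density operations

Models are rasterized as sums of spherical Gaussians (sigma = 1 voxel by
default, amplitude proportional to atomic number, support truncated at
5 sigma) — a smooth stand-in for scattering-factor profiles that is fully
adequate for the correlation-based uses below.  `fsc()` computes per-shell
normalized Fourier correlation (shell width one Fourier voxel) and reports
resolution at the first downward crossing of the 0.143 gold-standard
threshold by linear interpolation.  `map_model_cc()` correlates a grid with
a model rasterized on the same grid over all Fourier components to Nyquist;
by Parseval this equals the Pearson correlation of mean-removed real-space
values, which is how it is computed.

`calibrate_pixel()` estimates a map's true Å/pixel: the grid's voxel size
is relabelled with a sweep of trial values (the origin is held fixed in
voxel units and rescales proportionally), the map–model CC is recomputed at
each trial value against a fixed reference model, and a quadratic fit to
the five points bracketing the CC maximum gives the calibrated pixel at its
vertex.  A maximum on the sweep boundary is flagged and warned about, never
extrapolated.  The full reciprocal-space rigid-body search that experimental
pipelines interpose at each pixel value is out of scope; the reference pose
is taken as known, which holds for the synthetic fixtures and for
pre-docked reference models.

`local_symmetry_average()` averages a map over n rotations inside a
spherical mask (trilinear interpolation, outside values 0) — the operation
used to pull weak scaffolding features out of noise under a local five-fold.
It is idempotent only to interpolation tolerance (about 1% RMS on the test
grids).

## Interface geometry

`radial_profile()` slices an assembly into 5 Å slabs along a symmetry axis
and reports vdW surface-to-surface diameters: outer = 2 × max(radial
distance + vdW radius), inner channel = 2 × max(0, min(radial distance −
vdW radius)).  The surface-to-surface convention is stated because
published "outer diameter" figures rarely say which convention they use;
empty slabs are reported missing, not zero.  `salt_bridges()` pairs basic
side-chain nitrogens (Lys NZ; Arg NE/NH1/NH2; His behind a flag) with
acidic side-chain oxygens (Asp OD1/OD2, Glu OE1/OE2) within 4 Å, one entry
per residue pair.  `buried_area()` is Shrake–Rupley SASA with a
deterministic golden-spiral point set (960 points per atom by default),
reported per side — (SASA(a) + SASA(b) − SASA(a∪b)) / 2 — to match the
scale on which single-interface contact areas are usually quoted; a `total`
flag reports both sides.  With 960 fixed sample points the measure is
deterministic but rotationally exact only to sampling resolution (about 2%
on the two-sphere closed form and under rigid moves); raising `n_points`
tightens this at linear cost.

## The synthetic generators and what they do (not) show

Each generator is bit-reproducible given (seed, parameters): it derives its
own RNG stream from the user seed and a per-generator key (stream seed =
seed × 48271 + hash(key) mod 2³¹−1), so extending one generator never
perturbs another, and the caller's RNG state is restored afterwards.  Every
generator returns machine-readable truth with its data.

* `make_ring_in_wall()` emulates the connector-in-vertex geometry: a C12
  ring with radial spokes inside a C5 wall of alternating radial and
  tangential blocks.  The interface sits at radius 400 Å so that one scan
  degree subtends more than a vdW contact and window edges stay sharp at
  1-degree steps.  The exact clash-free windows are computed by interval
  arithmetic over all atom pairs and sized to the requested width; with a
  12-fold mobile and 5-fold wall they repeat every 360/lcm(12,5) = 6
  degrees.
* `make_two_state()` plants an axial shift (default 13 Å) and, optionally,
  a per-subunit hinge about a tangential axis through each subunit's
  centroid — a level motion that changes conformation while leaving the
  centre of gravity fixed, so displacement and conformational change can be
  validated independently.  A random rigid nuisance transform is applied
  jointly to the second state and its frame, forcing the analysis to earn
  the common frame by superposition.
* `make_orientation_set()` draws head orientations quasi-uniformly (alt
  restricted to [10, 170] degrees, clear of the gimbal poles) and couples
  tail azimuths as fixed, free, or oscillating (wrapped normal, half-width
  = 2 sigma, so about 95% of offsets lie within the stated half-width);
  planted outliers deviate in alt by 10 degrees, beyond the 5-degree
  screen.
* `make_funnel()` builds a two-layer tube of pseudo-atom rings with a
  flaring mouth (stem outer/inner diameters 55/32 Å, 180 Å long, mouth
  144 Å — the lower-collar geometry) and plants a radial narrow-end
  expansion (+8 Å, i.e. +16 Å in diameter) and a stem contraction
  (1.4 Å).
* `make_noisy_map()` rasterizes a model at a true pixel size (default
  1.30 Å), mislabels the header (default 1.32 Å) and adds Gaussian noise at
  half the signal RMS — the calibration problem with known answer.

These fixtures are deliberately idealized: pseudo-atoms are carbons, rings
are exactly symmetric, noise is white and Gaussian, and planted motions are
exactly rigid.  Passing the recovery tests therefore demonstrates that the
*algorithms* are correct and their tolerances honest (shift to ±0.01 Å,
pixel to ±0.005 Å, windows to ± one scan step, diameters to ±0.5 Å); it
does not demonstrate robustness to conformational flexibility, non-white
noise, map anisotropy, or model error in real reconstructions.

## Numerical choices and degenerate inputs

* Boundary-inclusive clash counting, with a 1e-9 Å tolerance so an overlap
  exactly at the threshold counts on either side of float rounding; the
  spatial-hash candidate cutoff carries a 1e-6 Å margin for the same
  reason.
* `kabsch()` refuses fewer than 3 pairs and collinear inputs; proper
  rotations are enforced by the determinant correction.
* Maps must have isotropic voxels within 0.1% and orthogonal cells; axis
  order is normalized to x-fastest on read.  MRC mode 2 (float32) is
  written, so round trips are exact only once values are float32.
* FSC shells start at one Fourier voxel (DC excluded); same-origin maps
  give first-shell correlation 1 exactly.
* Window extraction merges wrap-around runs only for full-circle scans.
* `capsomer_counts()` validates T against h² + hk + k²; the geometric
  builder supports T ∈ {1, 3} (any Q ≥ T) and refuses others explicitly.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated desk-
scale inputs: lattices up to Q = 9 (62 sites), point sets of tens to a few
hundred atoms, 32³–56³ voxel grids, orientation sets of 1000 particles, and
360-step rotational scans over a few hundred atoms — sizes chosen so the
whole suite completes in about a minute and a half on one CPU while still
exercising every code path at the tolerances stated above.

## Known limitations

Skew prolate classes (elongation not along a five-fold) and T numbers other
than 1 and 3 are not constructed geometrically; no sequence or structural
alignment (numbering-identity pairing only); no CTF, no reconstruction, no
anisotropic magnification model; SASA uses a spherical probe without
reentrant surface decomposition; the clashscore denominator question
(mobile vs union) is resolved by a documented default rather than by
evidence, as published figures do not state it.
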