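---
title: "Quantifying 3D foam structure, mechanics and rearrangements with foamvox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D foam structure, mechanics and rearrangements with foamvox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foamvox)
```

# The measurement problem

Liquid foams imaged by fast X-ray tomography arrive as time series of 3D
grayscale volumes: bright liquid films and Plateau borders surrounding dark
gas bubbles. Physical questions — how wet is the foam, how large and how
polydisperse are the bubbles, how is elastic stress stored and released, how
does the foam flow and rearrange — all reduce to image quantification:
turning each tomogram into per-bubble tables, and consecutive tomograms into
displacement fields and topological-event lists.

`foamvox` implements this chain in R. Everything operates on plain 3D arrays
with `dim = c(nz, ny, nx)`, axis order (z, y, x), and **zero-based** voxel
coordinates in all reported tables. Phase maps code liquid as 1; label maps
code liquid as 0 and bubbles as integers ≥ 1. Gas regions are treated as
26-connected and the liquid phase as 6-connected throughout. The
performance-critical 3D primitives (connected labeling, Euclidean distance
transform, grayscale reconstruction, marker watershed, local thickness,
surface meshing) are small C++ routines under `src/`, the same tier at which
R image-analysis packages implement their kernels; no installed R package
provides them in 3D.

# From grayscale volume to bubbles

The processing chain is `remove_background()` → `segment_phase()` →
`remove_speckles()` → `segment_bubbles()` → `remove_edge_bubbles()`.

**Background removal** subtracts a Gaussian low-pass estimate of the image
(standard deviation `scale`, which should exceed the bubble diameter) and
restores the global mean, flattening slow illumination drifts without
touching the gas/liquid contrast. A spatially constant volume is returned
unchanged.

**Phase segmentation** thresholds the histogram, by default with Otsu's
method computed over the voxels inside the validity mask only. The half-open
convention is fixed and tested: intensity ≥ threshold is the high class, and
`liquid = "high"` by default (aqueous foams image bright in absorption
contrast). Because the measured liquid fraction depends on this choice, the
threshold actually used is attached to the output as an attribute and
recorded in batch manifests.

**Speckle removal** flips connected components of either phase smaller than
a size threshold (liquid specks first, then gas specks), with the package's
connectivity convention per phase. The operation is idempotent on its own
output, which the tests check.

**Bubble segmentation** is a marker-controlled watershed of the negated
Euclidean distance transform of the gas phase. Markers are the h-maxima of
the distance map, computed by grayscale reconstruction; the default depth
`h = 2` voxels suppresses the shallow distance maxima that cause
over-segmentation in wet foams while preserving genuine bubbles with radii
of a few voxels or more. Flooding is deterministic: highest distance first,
FIFO among equal priorities, markers seeded in ascending voxel order, so
ties resolve to the lowest label and re-running the pipeline is
bit-reproducible. Every gas voxel is assigned to exactly one label — the
tests assert that label volumes sum to the gas voxel count exactly — and
regions smaller than `min_volume` are merged into their largest
face-adjacent neighbor. Bubbles clipped by the field of view (or by a
cylindrical sample mask) are removed by `remove_edge_bubbles()` before any
per-bubble measurement that assumes a closed interface.

# Structural parameters

The liquid fraction is the number of liquid voxels over the number of valid
voxels, globally or on a Cartesian grid of sub-volumes; grid cells with no
valid voxel report `NA` rather than 0, and partial cells at the far edges
are kept but flagged. `region_properties()` returns one row per bubble:
centroid, volume `V` (the exact voxel count), equivalent radius
$R_V = (3V/4\pi)^{1/3}$, the shape tensor and its strain (below).

Radius statistics follow the Sauter convention: with $\langle\cdot\rangle$
the number average over bubbles,

$$\langle R \rangle = \langle R_V \rangle,\qquad
R_{32} = \frac{\langle R_V^3 \rangle}{\langle R_V^2 \rangle},\qquad
p_{32} = \frac{R_{32}}{\langle R \rangle} - 1 .$$

$R_{32} \ge \langle R \rangle$ by the power-mean inequality, with equality
exactly for a monodisperse foam, so $p_{32}$ is a non-negative
dimensionless polydispersity that vanishes iff all bubbles have the same
size. This form of $p_{32}$ is a deliberate, prominently recorded choice —
it satisfies the monodisperse anchor and is trivially swappable should a
different normalization be preferred.

Local thickness uses the maximal-inscribed-sphere definition: the value at
a voxel is the diameter of the largest sphere fully inside the phase that
contains the voxel. It is computed from the distance transform by sphere
painting from non-dominated centers, with the sphere surface placed half a
voxel inside the nearest background voxel center; the implementation is
validated against an exhaustive per-voxel sphere-fitting oracle on small
volumes. It is intended for volumes up to roughly $128^3$ voxels.

# Contacts and films

Two bubbles are in contact when their regions, grown by `dilation` voxels
into the liquid (default 1), meet. The criterion is a configuration item,
not a claim about any particular physical film thickness: with the default
it detects films up to about two voxels thick. `get_contacts()` returns the
three artifacts downstream stages need: a topology table (coordination
number Z and neighbor labels per bubble), a contact-pair table, and a 3D
image of labeled film regions. Each film is then fitted by an ellipsoid via
its second-moment tensor: the normal is the eigenvector of the smallest
eigenvalue (sign convention: positive z-component), and the in-plane
semi-axes use the uniform-disc calibration $a = 2\sqrt{\lambda_1}$,
$b = 2\sqrt{\lambda_2}$ (a uniform disc of radius r has in-plane second
moments $r^2/4$), giving the planar-film area $A = \pi a b$. Contacts with
fewer than three non-collinear voxels are flagged degenerate rather than
fitted.

# Strain and stress

Per-bubble elastic strain is estimated from two anisotropy proxies. The
*shape tensor* is the second moment of a bubble's voxel coordinates about
the centroid, $S = \langle (r-\bar r)(r-\bar r)^{\mathsf T} \rangle$; for a
uniform ellipsoid its eigenvalues are $(a^2, b^2, c^2)/5$. The *texture
tensor* is the average outer product $M = \langle l\,l^{\mathsf T}\rangle$
of the link vectors from the bubble center to its neighbors' centers. Both
carry squared-length units, so the associated strains are logarithmic
(Hencky) deviations from the isotropic state built from the geometric mean
of the eigenvalues, with the factor ½ that converts squared lengths to
length-based strain:

$$U = \tfrac12\left(\ln \Lambda - \overline{\ln \Lambda}\right)
\quad\text{in the eigenbasis,}$$

which makes $U$ symmetric and traceless by construction (asserted to
$10^{-10}$). A sphere stretched by the volume-preserving factor
$e^\varepsilon$ along one axis yields strain eigenvalues
$(\varepsilon, -\varepsilon/2, -\varepsilon/2)$; the tests recover this
within 5% after rasterization, for both the shape and the texture route.
Singular tensors (flat bubbles, isolated bubbles with no links) are flagged
rather than silently propagated.

The direct stress measure integrates the surface-tension stress over each
bubble's gas–liquid interface:

$$\sigma = \frac{\Gamma}{V} \sum_{\text{triangles}} A_t
\left( n_t n_t^{\mathsf T} - \tfrac{1}{3}\mathrm{Id} \right),$$

with $\Gamma$ the surface tension and $V$ the bubble volume. The isotropic
pressure part is deliberately excluded (pressure is not accessible from a
segmented image), so the tensor is deviatoric, with tension positive;
viscous stresses are out of scope. The interface is triangulated by
marching tetrahedra at the 0.5 level of the bubble's binary mask. A binary
mask meshed directly produces staircase normals that bias the deviatoric
integral severely (tens of percent on an ellipsoid), so the mesher
anti-aliases the mask with a fixed small Gaussian (`smooth_sigma = 1`
voxel) before extracting the level set; this is deterministic, computed
from the binary region only, and brings a rasterized 2:1 prolate ellipsoid
(semi-axes 32 and 16 voxels) within 2% of a dense analytic surface-integral
quadrature, while a rasterized sphere of radius 12 carries a residual
deviator below 3% of $\Gamma/R$. Because the integrand $n n^{\mathsf T}$ is
even in the normal, triangle orientation is immaterial — one reason
marching tetrahedra (no case tables) suffices here. The sphere bias
decreases monotonically with radius over 8–24 voxels, and a binning harness
in the tests quantifies the degradation under 2×/3× downsampling; the
magnitude of that bias is data-dependent, so no universal number is
asserted. Stresses are reported in units of $\Gamma$ / length given
`voxel_size`; edge-touching bubbles raise an error directing the user to
`remove_edge_bubbles()` first, since their interfaces are open.

# Tracking and topological events

`track_labels()` matches bubbles between consecutive frames by centroid
proximity — within `search_radius` (default: the Sauter radius of the
earlier frame) of the predicted position, optionally shifted by a
caller-supplied prior displacement field sampled at the centroids — and a
volume criterion $|V_{t+1}-V_t|/V_t \le$ `vol_tol` (default 0.3) that
rejects split or merged segmentation artifacts. Conflicts are resolved
greedily by ascending match distance with deterministic tie-breaking on
labels; an exact tie in both distance and volume is flagged `ambiguous`
rather than guessed. Greedy resolution is stable and near-optimal when
displacements are small compared to bubble spacing, which is the regime in
which centroid tracking is trustworthy at all; a global assignment solve
was considered and left out as it changes nothing in that regime.
`combine_tracking()` chains pairwise tables into trajectories that end at
the first lost or ambiguous link, and `group_frames()` returns the frames
over which a group (a contact pair, a T1 quadruplet, a cluster) is jointly
alive — the intersection of its members' chains.

T1 events (elementary plastic rearrangements) are detected from contact
topology: pairs of frame-t contacts are translated through the tracking,
lost contacts are translated pairs absent at t+1 and new contacts the
converse, both as sets of unordered pairs. For each lost pair, candidate
new pairs are sought among the common neighbors of its two members; the
same search runs backward from new toward lost, and an event is emitted
only when the forward and backward assignments agree one-to-one. Lost pairs
with zero or multiple agreeing candidates — higher-order rearrangements
involving five or more bubbles — are reported separately as non-bijective
cases, never silently coerced into T1s. Common neighborhood is evaluated on
the union of the two frames' topologies by default (a neighbor counts if
present at either end of the transition); strict at-t or at-t+1 evaluation
is a switch, since either end alone can miss a neighbor whose own contact
flickers during the swap. For cylindrical flow geometries, `pair_angle()`
projects the bar joining a pair's centroids into the vertical cylindrical
plane (z, rθ) at the bar midpoint and reports its angle from the horizontal
in [0°, 180°).

# Averaging and coordinate passage

`grid_average()` bins positioned scalars, vectors or tensors into Cartesian
grid cells (component-wise means, per-cell counts, `min_count` validity).
`to_cylindrical()` / `from_cylindrical()` and `to_spherical()` convert
points and conjugate vectors and tensors by the local orthonormal basis;
the azimuth is measured from +x toward +y and the cylinder axis is along z
— one fixed, documented convention. Round trips are exact to machine
precision and tensor invariants are preserved, which the tests assert at
$10^{-12}$. On-axis points, where the azimuth is undefined, are flagged.

# The synthetic-foam generator

All validation runs on synthetic foams with exact ground truth, generated
by `make_packing()`: non-overlapping spheres separated by at least the film
thickness of liquid, placed by random sequential addition (optionally with
a common radius growth until the tightest gap reaches the film thickness)
or on a jittered cubic grid whose spacing realizes the film gap exactly.
Spheres are rasterized by nearest-seed power-distance assignment, so
bubbles are convex and watershed-recoverable; because placement already
enforces the film gap, this reduces to per-sphere rasterization. Ground
truth (centroids, radii, exact voxel volumes, adjacency with a documented
1-voxel slack) is derived from the same geometry. All randomness flows from
the single integer seed in the spec, and generation is bit-identical under
a fixed seed. `render_tomogram()` maps the phases to two intensity levels,
applies Gaussian blur and additive noise — the default validation
conditions are a 64³ box, 27 bubbles of radius 8 voxels, 1-voxel films,
blur σ = 1 and noise at 5% of the gas/liquid contrast, a benign but
non-trivial imaging model. `deform_sequence()` advects label maps through
an affine map per frame with nearest-neighbor label resampling, and
`make_t1_fixture()` builds a four-bubble configuration whose two frames
realize exactly one contact swap, optionally embedded among static
background bubbles.

What the generator does *not* emulate — and hence what passing tests do not
show — includes curved Plateau-border geometry and surface-minimized films,
drainage and coarsening dynamics, reconstruction artifacts (rings, beam
hardening, phase-contrast fringes), and intensity-dependent noise. Results
on real tomograms depend on segmentation choices (the liquid fraction in
particular is threshold-sensitive), which is why the threshold and all
stage parameters are recorded in batch manifests.

# Batch processing and reproducibility

Every operation runs batch-wise over a frame series through `run_stage()` /
`run_pipeline()` (stages: synth, process, structure, contacts, mechanics,
track, plasticity, fields, report), with one deterministic artifact per
frame or frame pair, per-stage JSON manifests recording parameters and
per-frame status, skip-on-rerun, and per-frame failure containment
(a missing input frame fails that frame, not the batch). A thin command-line
front end over the same functions ships in `inst/cli/foamvox.R`. The whole
chain on a seeded synthetic series is bit-identical across runs, asserted
by hashing every output file.

Problem sizes in the test-suite and validation runs — 48³–80³ boxes, 10–50
bubbles, 2–5 frames — were chosen so each stage's error sources
(rasterization, meshing, resampling) are well inside their asymptotic
regime while a full run stays interactive on a laptop.

# Numerical choices and limitations

- Distance transforms are exact squared Euclidean (separable
  lower-envelope algorithm); the image boundary acts as background, i.e.
  volumes are implicitly padded with one background layer where that
  matters (watershed seeding, local thickness).
- Watershed ties, greedy-matching ties and film-normal signs all have fixed
  deterministic conventions (lowest label, ascending labels, positive
  z-component) so outputs are reproducible bit for bit.
- Nearest-neighbor label advection conserves per-bubble volume only up to
  rasterization discrepancy; for bubbles below ~12 voxels radius this
  jitter can exceed 2%, which also sets a floor for `vol_tol` in tracking.
- The planar-film area $A = \pi a b$ is an assumption, not a measurement;
  curved-film corrections are out of scope.
- The stress tensor omits pressure (deviatoric only) and viscous
  contributions by construction.
- Tracking assumes displacements small compared to the inter-bubble
  spacing; under violent flows an external displacement prior should be
  supplied.
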