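---
title: "Projecting 4D labeled data into a space-time cube: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting 4D labeled data into a space-time cube: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcube)
```

## The model

Segmented time-lapse data — one closed triangle surface per object per
frame, or one labeled voxel volume per frame — is treated as a 4D volume
over (x, y, z, t). A user-chosen cutting plane, held fixed while time
advances, defines a hyperplane in that 4D space. Restricting each frame to
the plane and stacking the resulting label images produces the space-time
cube (STC): an integer grid indexed (u, v, k), where (u, v) are in-plane
coordinates, k is the time step, and each voxel stores the identifier of
the object covering that point at that frame (0 = background).

Two assumptions make the STC readable:

1. **Small inter-frame motion.** Objects move per frame by much less than
   their own size, so the same object forms a connected tube along the
   time axis and a division appears as one tube splitting into two. The
   synthetic data generator enforces this regime.
2. **Identifiable objects.** Voxels store nominal ids, which lets any
   per-(id, t) quantity be color-mapped after the fact without touching
   the geometry, and lets selections propagate through a lineage.

Because the projection is an orthographic restriction to the plane,
distances between pixel centers equal distances between the corresponding
world points exactly; the package asserts this to 1e-9 in its tests.

## Projection conventions

* **Plane basis.** `define_plane(point, normal, up)` normalizes the
  normal, replaces `up` by its component orthogonal to the normal
  (Gram–Schmidt), and sets `u = up x normal`, `v = up`, so `(u, v,
  normal)` is right-handed. Degenerate inputs (zero normal, `up` parallel
  to the normal) are rejected.
* **Shared frame.** `fit_frame()` computes the (u, v) bounding rectangle
  of the plane/mesh intersection segments at every frame, takes the union
  over frames, expands it by `margin_fraction` (default 0.02) per side and
  pads to square pixels. One frame is used for all time steps — a
  per-frame refit would destroy the spatial alignment of the stack. If no
  geometry meets the plane's slab at any frame, an empty-frame error is
  raised.
* **Pixel lattice.** Pixel (i, j) (1-based) has world center
  `origin + (i - 0.5) px u + (j - 0.5) px v`; the STC index order is
  (u-column, v-row, time), and slice k of `build_stc()` is bit-identical
  to `rasterize_cross_section()` at frame k - 1.
* **Filled mode** labels a pixel with an object's id when the pixel
  center lies inside the closed mesh. For points on the cutting plane
  this equals a 2D parity test against the mesh/plane intersection
  curves, implemented as a scanline fill over the intersection segments;
  vertices exactly on the plane are classified to the positive side so
  each crossing triangle yields exactly one segment. Non-watertight
  meshes are skipped with a per-object warning.
* **Membrane mode** labels a pixel when the object's surface passes
  within `max(eps, half pixel diagonal)` (3D point-to-triangle distance)
  of the pixel center. `eps` is the slab half-thickness in world units;
  it defaults to one pixel's world size, which keeps the intended "thin
  slab around the plane" while remaining well-defined (defining it from
  the camera's near/far planes would be circular, since those are placed
  at `eps` themselves). Membrane is the default mode because surface-mesh
  datasets are hollow — the membrane is what exists; filled mode is
  first-class for label volumes and region-style figures.
* **Ties.** When several objects claim a pixel (abutting or overlapping
  segmentations), the smallest id wins. This is deterministic and
  independent of object iteration order.
* **Label volumes** are resampled at pixel centers by nearest neighbor in
  either mode; ids are nominal and must never be interpolated.

## Rendering conventions

* **Normals** are precomputed from the *binary occupancy* (label != 0) of
  the STC — ids are nominal and cannot be differentiated — optionally
  pre-smoothed with a separable Gaussian (sigma = 1 voxel, on by
  default), then differentiated with the 3x3x3 Sobel–Feldman operator
  along each axis with edge replication. The normal is the negated
  normalized gradient (pointing out of occupied space); vanishing
  gradients give the zero vector, which renders as ambient-only.
* **Raycasting** is orthographic, one ray per pixel, marching in
  0.5-voxel steps with samples at `(s + 0.5) * step` from the volume's
  near face. The first sampled voxel with a nonzero label that is not
  suppressed by the active filters or cut terminates the ray — opaque
  compositing, no semi-transparency, so color always encodes data rather
  than blended mixtures. Sampling at half-step offsets keeps axis-aligned
  rays off voxel boundaries, and the tests verify the resulting hit-voxel
  map against a 0.25-voxel brute-force marcher.
* **Shading** is Blinn–Phong:
  `ka*C + kd*max(N.L, 0)*C + ks*max(N.H, 0)^s`, clamped to [0, 1], with a
  movable point light (no distance attenuation) and defaults ka = 0.2,
  kd = 0.7, ks = 0.3, s = 16 — standard values, all configurable;
  `ka + kd > 1.2` is refused unless explicitly overridden. Moving the
  light never changes which voxel a pixel hits, only its shade.
* **Color lookup.** `build_lookup()` is a table keyed by (id, time):
  numeric values are clamped/normalized over a given or observed range
  and mapped through a 256-entry colormap (endpoints map to the first and
  last color); categorical values go through a stable string hash into a
  fixed categorical palette, so colors do not depend on level order or
  session state; missing entries map to a sentinel gray. Switching the
  displayed property rebuilds only this table.
* **Highlighting** renders the object pure red (a solid override, not a
  tint), matching the convention of marking tracked cells.
* The view camera is orthographic by default: perspective would distort
  the time axis relative to the spatial axes; a perspective option is
  deliberately out of scope.

## Cutting, filtering, querying

`cut_spec()` works in STC voxel coordinates at voxel centers
(i - 0.5, j - 0.5, k - 0.5). The boundary (signed distance exactly 0)
belongs to the positive side, so a cut and its complement partition the
volume — only voxels strictly on the discarded side are zeroed. A plane
perpendicular to the time axis gives time cutting; a plane containing the
time axis gives linear space cutting; tilted planes give the oblique cuts
useful for following a moving object.

One `filter_state()` object drives every view: a value range on the
currently mapped property, an inclusive time window, and per-object
states (normal / highlighted / hidden). The three masks are conjoined per
voxel; the stored STC is immutable and filtering happens at render/query
time, which is what makes switching filters cheap. Design choices here:

* The value filter is per-(id, t) *instance*: a cell whose mapped value
  drifts into the range reappears. Instances with no recorded value are
  **kept** (and rendered with the sentinel) — hiding data silently
  because it is unannotated would be misleading.
* `set_object_state()` propagates to all temporal instances of the seed
  and to all lineage *descendants*; ancestors are never touched. Hiding a
  daughter says nothing about the mother's earlier life.
* The preview time cursor is a plain `current_time` field, clamped into
  the time window.

## The synthetic embryo

`simulate_embryo()` emulates the statistical structure of a
cleavage-stage embryo recording: 1–100 sphere-like closed cells packed in
an ellipsoid, binary divisions on a fixed period with optional per-cell
asynchrony, small inter-frame motion, and per-cell `volume` (world
units^3, measured from each frame's mesh) and `remaining_lifespan`
(frames until the cell's scheduled division) annotations. Choices and
their rationale:

* **Cells are icospheres (subdivision 2)** with a small seeded low-
  frequency radial perturbation (amplitude 3% of the radius, mean-
  centered so volume is preserved to second order). Real blastomeres are
  convex-ish but never perfect spheres.
* **Division**: each daughter's radius is `parent * 2^(-1/3)` (volume
  conservation); the two daughters sit astride the parent center along a
  seeded random axis, separated by one daughter radius, so siblings
  overlap/abut the way dense segmentations do. Overlap resolution is the
  rasterizer's tie-break, exactly as with real abutting segmentations.
* **Motion** is an independent zero-mean Gaussian displacement about a
  persistent base position (total sd `jitter_sigma`, default 0.02 world
  units), not a random walk: cells wobble without secular drift, matching
  the small-motion premise, and inter-frame displacement stays below
  3 sigma in over 99% of instances.
* **remaining_lifespan** counts to the *scheduled* division, so it
  decreases by exactly 1 per frame and reaches 0 at `t_last` for cells
  that divide inside the recorded window; for cells truncated by the end
  of the simulation it is still positive at `t_last`.
* **Cavity deformation** (optional) pushes vertices radially away from
  the ellipsoid's vegetal pole with a Gaussian falloff ramping in over 5
  frames from the onset — a minimal stand-in for gastrulation-style
  indentation.
* All randomness flows from a single integer seed through a private RNG
  stream; identical seeds give byte-identical outputs and the caller's
  RNG state is untouched.

What the generator does **not** emulate: biophysical mechanics, cell
contact deformation, stereotyped cleavage geometry, apoptosis or
migration. Tests passing on this generator therefore demonstrate the
correctness of the projection/rendering/filtering machinery under the
embryo-like regime, not fidelity to any particular species' morphology.

## Measurement scenarios and problem sizes

The test suite and `scripts/acceptance.R` exercise the pipeline at sizes
chosen to keep every geometric effect visible while running in seconds:
slice identity on a 128 x 128 x 20 membrane STC of a two-round dividing
embryo; disc/annulus geometry at 128 x 128 against the analytic circle
(subdivision-3 icosphere, whose cross-section area is within a fraction
of a percent of the true disc); a 64 x 64 x 10 cylinder for normal
alignment; a 16^3 random label volume for the raycaster-versus-marcher
equivalence; 100 random lineages of up to 50 nodes for closure checks;
and the default 256 x 256 x 100 resolution once, for the full-size path.

One scenario deserves a note. The division-wave signature — the per-slice
count of distinct ids doubling at each multiple of the division period —
presupposes that *every* cell of the clone intersects the cutting plane.
With seeded random division axes, a second-generation daughter can sit up
to ~0.71 parent radii off a fixed plane while its polyhedral inradius is
~0.60, so over two rounds a fixed plane can miss one granddaughter for
some seeds (a genuinely partial cross-section, not a bug). The doubling
measurement is therefore taken over one division round of a two-root
embryo with the plane placed through both root centers — a placement the
user would naturally choose, and one where intersection is guaranteed for
every seed with a comfortable margin. Multi-round behaviour is exercised
separately by the slice-identity scenario, and the README's worked
example shows a two-round cross-section capturing 7 of 8 granddaughters
for exactly this reason.

## Degenerate inputs and edge cases

* Empty frames (no objects at a time step) rasterize to all-background
  slices; a plane missing the data entirely is an error at frame-fitting
  time.
* Non-watertight meshes: warned and skipped in filled mode; membrane mode
  does not require closedness and processes them.
* Zero-gradient voxels (interior of thick regions, isolated voxels) get
  zero normals and shade as ambient.
* Label ids must be positive and below 2^31 (32-bit storage); 0 is
  reserved for background everywhere.
* Lineages with temporal ordering violations are constructible on purpose
  — `validate_lineage()` reports them instead of refusing, so imperfect
  tracking output can be inspected.

## Known limitations

* The cutting plane is fixed over time; a plane tracking a moving
  structure frame by frame is out of scope (oblique *cuts of the STC*
  partially substitute).
* Rendering is CPU R code aimed at correctness and reproducibility, not
  interactive frame rates; typical renders (a few hundred pixels squared
  over a 128 x 128 x 100 volume) take seconds.
* Opaque-only compositing: semi-transparent transfer functions are
  deliberately excluded to keep color a faithful data channel.
* The value filter consults the currently mapped property only; filtering
  on one property while coloring by another requires two lookups and two
  passes.
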