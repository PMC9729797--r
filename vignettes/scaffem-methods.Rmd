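---
title: "Designing lattice implants for segmental bone defects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing lattice implants for segmental bone defects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scaffem)
```

## The problem

A large segmental defect of a load-bearing bone — the motivating case is
the mandibular body — cannot regenerate on its own. One clinical strategy
is a porous titanium lattice implant that bridges the defect, restores the
load path, and is packed with particulate bone graft so that new bone can
grow through its pores. Such an implant must satisfy two competing
requirements:

* **Biomechanics** — under worst-case mastication (an 800 N bite and the
  eight muscle groups per side acting simultaneously) the implant's
  von-Mises stress must stay below the Ti6Al4V yield strength of 897 MPa
  everywhere, at every stage of graft healing.
* **Mechanobiology** — by Frost's mechanostat, graft remodeling responds
  to local strain magnitude; the adaptation window used here is
  0--3000 microstrain. The more of the graft sits inside that window, the
  better the stimulus for regeneration. An over-stiff implant shields the
  graft (too little strain is never reached here, since the window starts
  at zero; in practice the soft early graft is over-strained, not
  under-strained).

scaffem implements the full design loop: parametric lattice generation,
linear-elastic finite-element evaluation across three healing stages,
binned stress/strain frequency statistics, and an iterative strut-diameter
optimization driven by both criteria.

## The implant model

The implant mimics the two-compartment structure of bone:

* a **trabecular-like core**: a wireframe of dodecahedral cells with a
  5 mm pore (large enough to pack 1--2 mm graft particles and keep blood
  supply). Regular dodecahedra are the textbook idealization of trabecular
  architecture but do not tessellate 3D space, so the default cell is the
  space-filling **rhombic dodecahedron** wireframe, which keeps the
  multi-strut nodes and the pore scale; a non-tessellating
  regular-dodecahedron option with vertex snapping (tolerance
  pore/10) is available for comparison. The cell frame is oriented along a
  configurable maximum-stiffness direction relative to the occlusal plane.
* a **grid-like shell**: a quadrilateral strut grid with the same opening
  size wrapped onto the outer surface, mimicking the cortical shell. It is
  built by voxelizing the region at the pore pitch, taking exposed voxel
  faces as quads and projecting nodes (and edge midpoints) onto the
  surface. Because projecting the voxel staircase onto a curved surface
  compresses the openings (by roughly 1.5x on a sphere), a second pass
  rescales the pitch so the mean opening area returns to
  `pore_diameter^2`; flat regions are unaffected.
* **gradient strut diameters** between 0.2 and 0.8 mm, linear in height:
  thinnest at the alveolar (top) side, thickest at the inferior border,
  matching the observation that implant stress grows from top to bottom.
  The linear law is the simplest monotone choice consistent with that
  statement.
* **fixation**: a 2 mm retainer strut frame on each residual-bone cut
  plane and 5--7 screws per side, modeled as 8 mm beam elements anchored
  into the bone voxels. Retainers and screws are never resized by the
  optimizer.

Strut solids are capsules (cylinders with spherical caps): the capsule has
a closed-form point distance, which makes the Boolean graft subtraction
and the STL export robust.

## The finite-element core

All materials are isotropic linear elastic (units mm / N / MPa):

| material | E (MPa) | nu |
|---|---|---|
| cortical bone | 15000 | 0.3 |
| cancellous bone | 1500 | 0.3 |
| articular disc | 44.1 | 0.4 |
| tooth | 20000 | 0.3 |
| Ti6Al4V (yield 897 MPa) | 110000 | 0.3 |
| granulation tissue (G-T) | 0.2 | 0.167 |
| immature bone (IM-B) | 1000 | 0.3 |
| mature bone (M-B) | 5000 | 0.3 |

Struts are 3D two-node **Timoshenko beams** with circular section (shear
correction 0.9): at 0.2--0.8 mm diameters over 2--5 mm spans the struts
are only moderately slender, and the Timoshenko element degrades
gracefully to Euler--Bernoulli behaviour for slender cases (the cantilever
benchmark reproduces `P L^3 / 3EI` to well under 1%). Bone, graft, disc
and tooth volumes are **trilinear hexahedral voxels** with full 2x2x2
Gauss integration — the Boolean graft region arrives voxelized anyway, and
the element passes the constant-strain patch test exactly. Beam nodes are
rigidly tied (translations) to the nearest voxel node within 1.8 voxel
edges; rotations remain beam DOFs. Each masticatory muscle contributes
both a point force (its maximum-bite magnitude along its direction vector)
and a grounded spring (temporalis 14, masseter 16.35, lateral pterygoid
12, medial pterygoid 15 N/mm) at its attachment node, because the
modeling convention states forces and spring stiffnesses simultaneously;
the springs ground at the attachment node since no far anchor is
specified. The condylar supports are fixed node layers separated from the
bone by one layer of articular-disc material, avoiding contact mechanics.

The solver is a sparse supernodal Cholesky factorization (via the Matrix
package); the equilibrium residual is checked against 1e-8 after every
solve. Stress recovery: voxel stress/strain at the element centre with
volume-weighted nodal averaging (the frequency statistics are node-based);
strut stress as the surface-fiber combination of axial, biaxial-bending
and torsional terms, maximized over the circumference and both ends.
Transverse shear is neglected in recovery (it vanishes at the extreme
bending fiber). The equivalent strain is the von-Mises-type deviatoric
measure `sqrt(2/3 e:e)`, reported in microstrain; the strain measure and
nodal averaging are deliberate choices documented here because the
reference workflow does not name its measure.

## Healing-stage sweep and frequency statistics

The graft continuum is assigned granulation tissue, immature bone and
mature bone properties in turn (G-T, IM-B, M-B); each stage is an
independent linear solve in which *only* the graft material changes.
Node-based percentages are computed over eight stress intervals (<50 to
>350 MPa in 50 MPa steps) and four strain intervals (0--3000, 3000--6000,
6000--10000, >10000 microstrain); bins are half-open `[lo, hi)`. The
**adaptation fraction** is the first strain bin: the share of graft nodes
inside the remodeling window. The stress criterion is inclusive
(max stress <= 897 MPa passes), since the design rule is phrased as
"cannot exceed".

Implant statistics are taken over strut end nodes, graft statistics over
graft voxel nodes: the reference meshes are unavailable, so the statistics
are defined self-consistently on scaffem's own discretization, and only
distribution shapes and orderings — not absolute percentages — transfer
between discretizations.

## The optimizer

The design objective is lexicographic: first stress feasibility at every
healing stage, then the G-T adaptation fraction (the early healing stage is
critical: the soft granulation tissue transfers the most load to the
implant and experiences the largest strains). The loop is deterministic;
re-voxelization after each diameter change reuses the same grid so that
statistics stay comparable.

The update law has a stress side and a mechanobiological side:

* **Stress (fully-stressed design)**: hotspot struts — equivalent stress
  above `max(90th percentile, yield/2)` — are resized by
  `d <- d * sqrt(stress/target)` with `target = yield/1.5`, clamped to
  0.9--1.25x per step and to the 0.2--0.8 mm bounds. A hotspot already at
  the 0.8 mm bound cannot be strengthened further, so its incident struts
  are thickened instead (load spreading).
* **Mechanobiology**: struts whose neighbouring graft strain (mean
  equivalent strain of graft nodes within half a pore of the strut
  midpoint) exceeds the 3000 microstrain window grow by 15% per step; the
  5% stress-shielding shrink of lightly loaded struts applies only where
  the local graft strain is also below half the window, so material is
  removed only where neither strength nor stimulus needs it.

Local rules alone converge to local optima in which stiff and compliant
regions coexist and concentrate stress at their interfaces. The loop
therefore runs in two phases: a **global phase** that scales all resizable
diameters by 1.1x per step while the G-T adaptation fraction improves by
at least the tolerance (0.5 percentage points per step by default) — the
dominant physical lever, since a globally stiffer cage pulls the soft
graft back into the window — followed by the **local phase** above. The
loop stops when the criteria are met outright (stress pass, no hotspots,
no over-window neighbourhood), when feasible improvement falls below the
tolerance, when nothing changes, or at `max_iterations` (default 20). The
returned design is the best seen under the lexicographic key, and
`converged = FALSE` flags that no stress-feasible design was found.

This two-sided law deviates deliberately from a pure fully-stressed-design
update: on the packaged fixture the initial design is already
stress-feasible, so a stress-only update has almost nothing to do and its
shielding shrink actively softens the implant, *reducing* the adaptation
fraction. The design loop is explicitly meant to weigh the implant's
biomechanics and the graft's mechanobiology together, which is exactly
what the added growth term does.

## The synthetic fixture: what it emulates, what it does not

`make_defect_fixture()` builds a curved swept prism (rounded-rectangle
section, configurable lateral bowing) of total length
`span + 2 * stump`: the middle span is the defect, the two ends are
residual-bone stumps with a 2 mm cortical shell classification around a
cancellous core, an occlusal tooth patch on the +x stump where the 800 N
bite acts (teeth sit on residual bone; no individual tooth geometry), one
articular-disc voxel layer at each fixed end (condylar support), and
eight muscle attachment sites per side. Default dimensions are a
40 x 20 x 10 mm defect with 10 mm stumps and curvature 0.15 — the scale
of a mandibular body segment. The muscle force magnitudes are the
published maximum-bite values; the direction vectors are **plausible
placeholders** (the published direction cosines are not part of the
packaged data) stored in the config so users can override them.

The fixture is watertight by construction and bit-identical for identical
parameters; the seed is recorded in every artifact. It is *not* an
anatomical mandible: absolute stress/strain values computed on it do not
transfer to any patient geometry. A green test on the fixture establishes
that the method behaves correctly (orderings across healing stages,
optimization direction, criteria logic) — not that any particular
clinical number is reproduced. For that reason the published
patient-specific maxima (1036.30 -> 697.35 MPa and 35.79% -> 93.36%) are
used in tests only as direction/ordering checks, never as numeric targets.

## Numerical choices and degenerate inputs

* Voxel size defaults to 1.25 mm (a quarter pore): the Boolean
  subtraction requires `voxel <= pore/4`, and 1.25 mm keeps the default
  pipeline around 24k DOF, solvable in seconds.
* Zero-extent gradient lattices get the mid diameter `(d_min+d_max)/2`;
  `d_min = d_max` collapses the gradient.
* Beam-voxel ties fail loudly: an untied strut node names itself in the
  assembly error rather than leaving a floating singularity.
* The surface exporter contours the capsule-union SDF with surface nets
  (cell size `pi*d_min/segments_per_circle`), then projects vertices onto
  the exact zero level; grids are capped at 3e6 cells, and a capped
  (coarsened) export can contain non-manifold edges at struts thinner
  than the cell — a manufacturing-export limitation only.
* STL files carry no topology or units; the lattice JSON (0-based
  indices, mm) is the authoritative geometry record.
* Ray-casting membership uses a fixed irrational direction to avoid
  grazing axis-aligned facets; meshes are assumed watertight.

## Known limitations

* Linear elasticity only: no contact at the condyles, no plasticity or
  fatigue, no large-deformation effects in the jelly-soft G-T stage
  (strains above ~10% there violate the small-strain assumption; the
  frequency statistics still rank designs consistently).
* The healing stages are three static snapshots, not a time-continuous
  remodeling simulation.
* The optimizer changes diameters only; it never adds, removes or moves
  struts.
* Nodal percentages depend on the discretization; compare percentages
  only within one pipeline run (one grid), not across resolutions.
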