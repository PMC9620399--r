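---
title: "Designing single-stranded RNA origami for wireframe meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing single-stranded RNA origami for wireframe meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaweave)
```

## The design problem

A wireframe nucleic-acid nanostructure renders each edge of a 3D mesh as
a double helix. For a *single-stranded* RNA design the strand must visit
every edge twice, in antiparallel directions, so that the two passes can
hybridize into the duplex. Complete antiparallel double routings that
keep all vertices intact exist only for special meshes (for the
tetrahedron none exists), so `rnaweave` follows the spanning-tree
strategy: route the strand twice around a spanning tree of the mesh, and
reintroduce every discarded edge with a kissing-loop connector — a
pseudoknot pairing between the loops of two hairpins extruded half-way
along the edge from its two end vertices. The 180° kissing-loop motif
coaxially stacks the two hairpin stems, so the reconstituted edge
behaves as one continuous helix. A connected mesh with `V` vertices and
`E` edges always needs exactly `E − V + 1` kissing-loop pairs (the cycle
rank); the tetrahedron, triangular bipyramid and side-triangulated
triangular prism need 3, 5 and 7.

## Unknotted routing

The strand, with its nick conceptually sealed, is a closed curve in
space; a knotted routing can trap folding kinetically. `rnaweave`
guarantees an unknot by construction. Each vertex is expanded into a
small sphere carrying two *ports* per incident strand pass; the routing
is computed by tracing the boundary of the spanning tree thickened into
bands (plus hairpin spikes along non-tree edges). At each sphere the
trace always exits through the angularly adjacent port not belonging to
its own band, so the connecting chords join neighbouring ports and can
never cross. The thickened complex deformation-retracts to a tree — it
is an embedded disk — and the boundary of an embedded disk is a single
unknotted curve. This argument does not require the mesh to be
polyhedral, which is why arbitrary straight-line meshes (the `grid`
fixture) work too.

Because the guarantee is constructive, the package also ships a
*diagnostic*: `knot_determinant()` projects the routed centerline onto a
generic plane, builds the crossing diagram, and evaluates the knot
determinant |Δ(−1)|. At `t = −1` the Wirtinger relation at a crossing
degenerates to `2·a(over) − a(under-in) − a(under-out) = 0` regardless
of crossing sign, so the determinant is the absolute determinant of any
maximal minor of that coloring matrix over the arcs. The unknot has
determinant 1; the trefoil 3; the figure-eight knot 5. Determinant 1 is
necessary but not sufficient for unknottedness — the check guards
regressions, the construction carries the proof. Degenerate projections
(collinear overlaps, endpoint hits, tangential crossings) are detected
and retried under seeded random rotations.

## Geometry model

Edges are embedded as idealized rigid A-form helices with defaults

| parameter | default | meaning |
|---|---|---|
| `rise_per_bp` | 0.281 nm | axial rise per base pair |
| `twist_per_bp` | 32.7° | ~11 bp per turn |
| `helix_radius` | 1.15 nm | backbone radius |
| `backbone_offset_deg` | 150° | inter-backbone angle within a rung |
| `kl_pair_len` | 6 bases | kissing-loop pairing region |
| `kl_flank_unpaired` | 3 bases | unpaired flank per loop side |
| `max_linkers_per_transition` | 6 | unpaired vertex linkers |

An edge of length `L` carries `round(L / rise)` bp, floored at
`kl_pair_len + 2` so every edge could host a connector. A kissing-loop
edge is split into two stems around the mid-edge 6-bp loop-loop duplex,
balanced to within one bp (the extra base pair goes to the stem at the
higher-numbered vertex). Both strands of a duplex are generated as
antiparallel helical traces sharing rung planes; unpaired flanks and
linkers are interpolated between their flanking backbone points. No
relaxation is attempted — that is deliberately delegated to oxDNA after
export, which is also why the model keeps perfectly straight axes.

**Phases and linkers.** The strand must hop between helices at each
vertex. The exact rule used by the original design software is not
published, so this package defines its own documented objective: over
all cross-vertex transitions,
`J = Σ |gap − (rise + 0.7·linkers)| + w·(angular mismatch)/180`,
where `gap` is the exit-to-entry backbone distance, 0.7 nm is the
effective span of one unpaired nucleotide, the angular mismatch is
between exit and entry strand tangents, and `w = 0.25` nm. Per-edge
phases (continuous, coordinate descent over a 5° grid with local
refinement) and per-transition linker counts (exact integer argmin given
the gap) are alternated until convergence; the cost is non-increasing by
construction and the tests assert both the descent invariant and
agreement with exhaustive search on small instances (a joint phase-grid
× linker enumeration on a two-edge path, and per-transition linker
enumeration — exact, because given phases the cost separates over
transitions — on the tetrahedron).

**Nick placement.** The 5′/3′ nick sits mid-way along the first-traversed
tree edge (the cyclic design is rotated there), which splits that edge's
first pass into two stem domains. Placing the nick mid-stem rather than
at a vertex keeps both strand ends hybridized.

## Sequence design

The designer is a constraint-satisfaction sampler, not a thermodynamic
optimizer; a pluggable `designer` function adapter preserves the route
to an external package such as NUPACK without making it a dependency.

* **Kissing loops** come from a seeded ensemble generator: 6-base loops
  with 2–4 G/C (a binding-strength proxy), no forbidden pattern, not
  self-complementary, and all-pairs Hamming distance ≥ 3 between every
  loop and every other loop *and its reverse complement*. The threshold
  3 quantifies "nonsimilar" — the literature gives no metric — and is
  configurable, as is importing validated literature pairs ahead of
  generated ones.
* **Stems** are sampled base-by-base so that no forbidden run can occur
  inside a stem; since complementation maps each IUPAC class run onto a
  class run (W→W, S→S, K↔M, R↔Y), the partner strand inherits
  cleanliness, leaving only junction effects for repair.
* **Wobbles.** Every 8th pair of each stem duplex (counting from the
  stem's 5′-most pair) becomes G·U, G on the first-traversed strand.
  In the DNA template these are G·T mismatches; their stated purpose is
  to keep the synthesized dsDNA template from being self-complementary,
  which the tests verify directly.
* **Repair.** Remaining violations (always at junctions: flanks,
  linkers, wobble neighbourhoods) are removed by seeded single-base
  mutations. Candidates must leave the violated letter class and are
  scored on the local neighbourhoods of both the mutated base and its
  partner; unpaired positions are preferred but paired neighbours remain
  mutable — a lone linker can sit in a context where *every* base choice
  violates some class. Kissing-loop regions, wobble pairs and the 5′ G
  are immutable.
* **Template.** `GAC` + `TAATACGACTCACTATAG` + body + 15-nt seeded tail.
  The promoter's final G is the transcription start and is identified
  with the RNA's first base (forced to G), so the junction base is not
  duplicated. The reverse primer is the reverse complement of the
  template 3′ end, extended beyond 15 nt until its Wallace-rule melting
  temperature (2(A+T) + 4(G+C), documented as approximate) reaches the
  58 °C annealing default.

## What the synthetic fixtures do and do not establish

The built-in meshes (tetrahedron, bipyramid, triangulated prism, cube,
dodecahedron, 3×2×2 grid) default to 10 nm edges because the physical
dimensions of the synthesized structures are not published; this yields
a 493-nt tetrahedron, the same order as the reported 435-nt design, but
printed strand lengths are explicitly not reproduction targets. A green
test suite establishes the combinatorial contracts (counts, pairing
maps, unknottedness, constraint satisfaction, file round-trips) and the
qualitative compactness ordering; it does not establish folding yields,
thermodynamic stability, or agreement with experimental radii of
gyration, which require simulation and wet-lab work outside this
package's scope.

The open-kissing-loop control variant (`embed_helices(..., open_kls =
TRUE)`) models a strand whose loops cannot pair: the spanning tree is
unfolded into an extended conformation (children fanning 35° around the
incoming direction) and hairpins point outward. Its design-model radius
of gyration exceeds the folded model's, mirroring the reported
compactness ordering between the functional tetrahedron and its
non-folding control — a qualitative, not quantitative, statement.

## Numerical choices and degenerate inputs

* Port angles use the projection plane orthogonal to the mean incident
  edge direction, falling back to the least-spread principal direction
  at balanced vertices; ties in port order break by edge index.
* The knot diagnostic treats a projection as degenerate when segment
  pairs are near-parallel and overlapping, or when a crossing parameter
  falls within 1e-7 of a segment endpoint, and retries (up to 20 seeded
  rotations) rather than guessing.
* Edges shorter than `(kl_pair_len + 2) · rise` are clamped to the
  structural minimum with a warning; zero-length edges are rejected at
  mesh validation.
* snac coordinates are written with 9 significant digits, so file
  round-trips are exact to well below 1e-6 nm; oxDNA files use
  fixed-point 8-decimal formatting for byte-reproducible diffs, and the
  reader's orthonormality tolerance (1e-6) accommodates that precision.
* All randomness (spanning trees, ensembles, stem sampling, tails,
  re-projections) flows through an internal seed-scoped RNG wrapper that
  restores the caller's RNG state.

## Known limitations

* The geometry is an idealized rigid model: vertex regions overlap
  slightly, flank/linker bases are straight-line interpolations, and no
  steric or electrostatic terms exist. oxDNA relaxation is the intended
  next step.
* `strand_model_from_structure()` (used by the `design` CLI stage on
  bare snac files) cannot distinguish tree stems from hairpin stems;
  wobble placement treats both identically, which matches the behaviour
  of the routed path anyway.
* The knot determinant cannot distinguish the unknot from determinant-1
  knots; full certification is out of scope.
* Kissing-loop binding free energies are not predicted; orthogonality is
  purely sequence-distance based.
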