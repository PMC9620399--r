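# rnaweave

Automated design of single-stranded RNA origami for 3D wireframe meshes.

`rnaweave` turns an arbitrary 3D wireframe mesh — a polyhedron, or any
connected straight-line graph in space — into a complete single-stranded
RNA design ready for in-vitro transcription and coarse-grained simulation:

1. **Routing.** The mesh's edge set is reduced to a spanning tree
   (`V − 1` edges) and one RNA strand is routed around the tree so that
   every tree edge is covered twice in antiparallel directions; the
   complementary passes later hybridize into duplex edges. Each of the
   `E − V + 1` discarded edges is reintroduced as a pair of half-edge
   hairpins whose loops pair through a 180° kissing-loop pseudoknot
   (modelled on the HIV-DIS motif), coaxially fusing the two half-helices
   into one effective edge. At every vertex the strand exits through the
   angularly adjacent port on a small vertex sphere, so the connecting
   chords never cross; the thickened tree-plus-hairpins complex is an
   embedded disk and its boundary — the strand — is therefore an unknot.
   A knot-determinant diagnostic (|Δ(−1)|, computed from the crossing
   diagram of the routed centerline) guards this guarantee: the unknot
   requires determinant 1 (trefoil 3, figure-eight 5).
2. **Embedding.** Every edge becomes an idealized A-form helix
   (0.281 nm rise/bp, 32.7°/bp, 1.15 nm backbone radius). Per-edge
   rotation phases and 0–6 unpaired linker nucleotides per vertex
   transition are chosen by coordinate descent to minimize the backbone
   strain cost `J = Σ (|gap − spanned| + w·angular mismatch)`. The result
   carries per-nucleotide 3D coordinates.
3. **Sequence design.** Kissing loops receive mutually orthogonal 6-base
   pairs (all-pairs Hamming distance ≥ 3, including reverse complements);
   stems are filled with complementary random bases under per-stem GC
   bounds; G·U wobbles are inserted every 8 bp so the dsDNA template is
   not self-complementary; the forbidden patterns AAAA, CCCC, GGGG, UUUU
   and 6-runs of the IUPAC classes K, M, R, S, W, Y are excluded
   everywhere. The DNA template is `GAC` + T7 promoter
   (`TAATACGACTCACTATAG`, whose final G is the transcript's required
   5′ G) + body + a 15-nt tail, with a Tm-matched reverse primer.
4. **Export.** Designs are written as `snac` text files (sequence,
   layered dot-bracket structure with pseudoknot brackets `[]{}<>Aa…`,
   per-nucleotide coordinates), FASTA/Vienna files, and classic oxDNA
   topology + configuration inputs for relaxation/simulation.

## Worked example

```r
library(rnaweave)
des <- design_wireframe("tetrahedron")
str(des$report)
#> $ name            : chr "tetrahedron"
#> $ V               : int 4
#> $ E               : int 6
#> $ tree_edges      : int 3
#> $ kissing_loops   : int 3
#> $ total_nt        : int 493
#> $ knot_determinant: int 1
#> $ embedding_cost  : num 2.32
```

The 4-vertex, 6-edge tetrahedron needs a 3-edge spanning tree and exactly
3 kissing-loop pairs (`E − V + 1`); with the default 10 nm edges the
strand is 493 nt and its routed centerline has knot determinant 1
(consistent with the unknot). The designed sequence and its layered
structure:

```r
substr(des$sequence, 1, 60)
#> "GUGACAGGCCGAAACGUCACGAGAACGCGACCCUAAACGAGAAUCAAGGGUCGUGUUCUC"
substr(des$doc$structure, 1, 60)
#> "((((((((((((((((((.(((((((((((((((...[[[[[[...))))))))))))))"
des$ensemble$pairs
#>   loop_a loop_b provenance
#> 1 AUGACA UGUCAU  generated
#> 2 CGAGAA UUCUCG  generated
#> 3 GUUUCU AGAAAC  generated
substr(des$template$template, 1, 40)
#> "GACTAATACGACTCACTATAGTGACAGGCCGAAACGTCAC"
radius_of_gyration(des$doc$coords)
#> 4.72  # nm
```

`[[[[[[` marks a kissing-loop pairing region (pseudoknot layer 1); the
template begins with the `GAC` cap and T7 promoter. Files for oxDNA:

```r
write_snac(des$doc, "tetrahedron.snac")
mdl <- snac_to_ox(des$doc)
write_ox_files(mdl, "tetrahedron.top", "tetrahedron.conf")
```

## Command line

```sh
inst/cli/rnaweave route  --builtin tetrahedron --out out/   # structure only
inst/cli/rnaweave design --snac out/tetrahedron.snac --out out/
inst/cli/rnaweave export --snac out/tetrahedron.designed.snac --out out/
inst/cli/rnaweave all    --builtin prism_triangulated --seed 3 --out out/
```

Built-in meshes: `tetrahedron`, `bipyramid`, `prism_triangulated`,
`cube`, `dodecahedron`, `grid` (a 3×2×2 vertex lattice demonstrating
non-polyhedral meshes). Arbitrary meshes are read from Wavefront OBJ
(`v`/`f`/`l` records, coordinates in nm, `--units` to rescale).

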