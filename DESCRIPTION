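Package: rnaweave
Title: Single-Stranded RNA Origami Design for 3D Wireframe Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated design of single-stranded RNA origami for arbitrary 3D
    wireframe meshes. Routes one RNA strand antiparallel-twice around a
    spanning tree of the mesh, reintroduces non-tree edges through orthogonal
    180-degree kissing-loop connectors, embeds the routing as A-form helices
    with per-nucleotide 3D coordinates, verifies unknottedness of the routing
    via the knot determinant, designs a constrained primary sequence with G-U
    wobbles for dsDNA template synthesis, builds the T7 transcription template
    with primers, and exports oxDNA topology/configuration files. Includes a
    line-oriented 'snac' interchange format (sequence, layered dot-bracket
    structure, coordinates) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
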