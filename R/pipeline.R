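#' Run the full wireframe-to-sequence design pipeline
#'
#' Convenience wrapper chaining the three stages: strand routing over a
#' spanning tree (with kissing-loop extrusion and unknot diagnostic),
#' A-form helix embedding with phase/linker optimization, and constrained
#' primary-sequence design with T7 template construction.
#'
#' @param mesh a [wire_mesh()] or the name of a built-in mesh.
#' @param params [helix_params()].
#' @param constraints [seq_constraints()].
#' @param tree_strategy passed to [spanning_tree()].
#' @param seeds named list of integer seeds: `routing` (spanning tree),
#'   `sequence`, `tail` and `ensemble`.
#' @param ensemble optional [generate_kl_ensemble()]; generated from
#'   `seeds$ensemble` when `NULL`.
#' @param edge_scale edge length (nm) when `mesh` is a built-in name.
#' @param with_sequence if `FALSE`, stop after routing/embedding and
#'   return a snac document with N placeholders.
#' @return list with elements `mesh`, `tree`, `plan`, `embedding`, `strand`,
#'   `doc` (snac document), `report` (V, E, tree size, kissing loops, total
#'   nt, knot determinant), and, when sequenced, `sequence`, `ensemble`,
#'   `template`.
#' @export
design_wireframe <- function(mesh, params = helix_params(),
                             constraints = seq_constraints(),
                             tree_strategy = "bfs",
                             seeds = list(routing = 1L, sequence = 1L,
                                          tail = 1L, ensemble = 1L),
                             ensemble = NULL, edge_scale = 10,
                             with_sequence = TRUE) {
  if (is.character(mesh)) mesh <- builtin_mesh(mesh, edge_scale = edge_scale)
  seeds <- utils::modifyList(list(routing = 1L, sequence = 1L, tail = 1L,
                                  ensemble = 1L), as.list(seeds))
  tree <- spanning_tree(mesh, strategy = tree_strategy,
                        seed = seeds$routing)
  plan <- route_strand(mesh, tree)
  emb <- embed_helices(mesh, plan, params)
  strand <- build_strand_model(plan, emb)
  det <- knot_determinant(routing_polyline(mesh, plan))
  struct <- to_dotbracket(strand)
  report <- list(name = mesh$name, V = n_vertices(mesh), E = n_edges(mesh),
                 tree_edges = length(plan$tree_edges),
                 kissing_loops = n_kissing_loops(plan),
                 total_nt = strand$length, knot_determinant = det,
                 embedding_cost = emb$J)
  out <- list(mesh = mesh, tree = tree, plan = plan, embedding = emb,
              strand = strand, report = report)
  if (!with_sequence) {
    out$doc <- snac_document(mesh$name, strrep("N", strand$length), struct,
                             nucleotide_coordinates(emb))
    return(out)
  }
  if (is.null(ensemble))
    ensemble <- generate_kl_ensemble(max(1L, n_kissing_loops(plan)),
                                     constraints, seed = seeds$ensemble)
  seqn <- design_sequence(strand, ensemble, constraints,
                          seed = seeds$sequence)
  out$sequence <- seqn
  out$ensemble <- ensemble
  out$doc <- snac_document(mesh$name, as.character(seqn), struct,
                           nucleotide_coordinates(emb))
  out$template <- build_dna_template(as.character(seqn),
                                     tail_seed = seeds$tail,
                                     constraints = constraints,
                                     wobble_pos = wobble_positions(
                                       strand, constraints))
  out
}
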