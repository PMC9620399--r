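#' Reconstruct a minimal strand model from a layered dot-bracket structure
#'
#' Enables sequence design on a bare snac document (no routing context):
#' layer-1 pairs (`()`) become stem duplexes, higher-layer (pseudoknot)
#' pairs become kissing-loop pairing regions grouped into partner pairs,
#' and unpaired positions are treated as linkers. Wobble placement and
#' kissing-loop assignment then work exactly as for a routed design;
#' the distinction between tree stems and hairpin stems (irrelevant to
#' sequence design) is not recovered.
#'
#' @param structure layered dot-bracket string.
#' @return a `strand_model` (without coordinates or routing annotations).
#' @export
strand_model_from_structure <- function(structure) {
  p <- parse_dotbracket(structure)
  n <- length(p)
  ch <- strsplit(structure, "")[[1L]]
  ab <- bracket_alphabet()
  layer1 <- ch %in% ab[[1L]]
  kl_paired <- !is.na(p) & !layer1
  dkind <- ifelse(is.na(p), "linker", ifelse(layer1, "stem", "kl_loop"))
  # stems break where the partner does not step antiparallel
  brk <- c(TRUE, dkind[-1L] != dkind[-n] |
                 (dkind[-1L] != "linker" & !is.na(p[-1L]) & !is.na(p[-n]) &
                  p[-1L] != p[-n] - 1L))
  dom_id <- cumsum(brk)
  starts <- which(brk)
  kinds <- dkind[starts]
  kinds[kinds == "stem"] <- ifelse(
    p[starts[kinds == "stem"]] > starts[kinds == "stem"], "stem5", "stem3")
  domains <- data.frame(id = seq_along(starts), kind = kinds, start = starts,
                        length = diff(c(starts, n + 1L)),
                        edge = NA_integer_)
  domains$partner <- vapply(seq_len(nrow(domains)), function(d) {
    rows <- domains$start[d] - 1L + seq_len(domains$length[d])
    pp <- p[rows]
    if (all(is.na(pp))) NA_integer_ else dom_id[pp[!is.na(pp)][1L]]
  }, 0L)
  # pair up kissing-loop domains as pseudo-edges for ensemble assignment
  kl <- which(domains$kind == "kl_loop")
  eid <- 0L
  for (d in kl) {
    if (!is.na(domains$edge[d])) next
    eid <- eid + 1L
    domains$edge[d] <- eid
    domains$edge[domains$partner[d]] <- eid
  }
  sm <- structure(list(domains = domains, pairing = p, length = n,
                       nucleotides = data.frame(pos = seq_len(n),
                                                dkind = dkind,
                                                domain = dom_id)),
                  class = "strand_model")
  validate_strand_model(sm)
  sm
}
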