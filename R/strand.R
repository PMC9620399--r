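#' Build the strand model from a routing and its embedding
#'
#' Derives the ordered domain list and the position-level pairing map of the
#' single strand: every tree edge contributes an antiparallel `stem5`/`stem3`
#' pair, every kissing-loop edge two hairpins
#' (`kl_stem5` + `kl_loop` + `kl_stem3`) whose loop pairing regions are
#' partnered across the edge; unpaired linkers sit at the vertex
#' transitions. The nick may split the stems of the first-traversed edge in
#' two, so that edge can contribute more than two stem domains.
#'
#' @param plan a [route_strand()] result.
#' @param embedded the matching [embed_helices()] result.
#' @return object of class `strand_model`: `domains` (data frame: `id`,
#'   `kind`, `start`, `length`, `edge`, `partner`), `pairing` (integer
#'   vector, `pairing[i] = j` iff i pairs j, `NA` if unpaired), `length`,
#'   and the per-nucleotide annotation table `nucleotides`.
#' @export
build_strand_model <- function(plan, embedded) {
  nuc <- embedded$nucleotides
  n <- nrow(nuc)
  paired_kind <- nuc$kind %in% c("stem", "kl_stem", "kl")
  key <- ifelse(paired_kind, paste(nuc$edge, nuc$slot), NA)
  pairing <- rep(NA_integer_, n)
  idx <- split(which(paired_kind), key[paired_kind])
  bad <- vapply(idx, length, 0L) != 2L
  if (any(bad)) stop("inconsistent routing/embedding: unpaired duplex slot")
  for (ii in idx) {
    pairing[ii[1L]] <- ii[2L]
    pairing[ii[2L]] <- ii[1L]
  }
  stopifnot(identical(pairing[pairing[!is.na(pairing)]],
                      which(!is.na(pairing))))

  # 5' pass of each duplex: the sense whose first position comes earlier
  kind <- nuc$kind
  grp_key <- ifelse(kind %in% c("kl", "kl_flank"),
                    paste0("L", nuc$event),
                    ifelse(kind == "stem", paste0("S", nuc$edge),
                    ifelse(kind == "kl_stem", paste0("K", nuc$event), "lnk")))
  kind_out <- kind
  for (g in unique(grp_key[kind %in% c("stem", "kl_stem")])) {
    rows <- which(grp_key == g)
    senses <- nuc$sense[rows]
    first_pos <- tapply(rows, senses, min)
    s5 <- as.integer(names(first_pos))[which.min(first_pos)]
    kind_out[rows] <- ifelse(senses == s5,
                             ifelse(kind[rows] == "stem", "stem5", "kl_stem5"),
                             ifelse(kind[rows] == "stem", "stem3", "kl_stem3"))
  }
  kind_out[kind %in% c("kl", "kl_flank")] <- "kl_loop"
  kind_out[kind == "linker"] <- "linker"

  brk <- c(TRUE, (kind_out[-1L] != kind_out[-n]) |
                 (grp_key[-1L] != grp_key[-n]) |
                 ((nuc$event[-1L] != nuc$event[-n]) & kind_out[-1L] != "linker"))
  dom_id <- cumsum(brk)
  starts <- which(brk)
  domains <- data.frame(id = seq_along(starts), kind = kind_out[starts],
                        start = starts,
                        length = diff(c(starts, n + 1L)),
                        edge = nuc$edge[starts])
  # partner domain: domain of the first paired position's partner
  dom_of <- dom_id
  domains$partner <- vapply(seq_len(nrow(domains)), function(d) {
    rows <- domains$start[d] - 1L + seq_len(domains$length[d])
    pp <- pairing[rows]
    if (all(is.na(pp))) NA_integer_ else dom_of[pp[!is.na(pp)][1L]]
  }, 0L)

  sm <- structure(list(domains = domains, pairing = pairing, length = n,
                       nucleotides = cbind(nuc, domain = dom_id,
                                           dkind = kind_out)),
                  class = "strand_model")
  validate_strand_model(sm)
  sm
}

validate_strand_model <- function(sm) {
  p <- sm$pairing
  i <- which(!is.na(p))
  stopifnot(all(p[p[i]] == i), all(p[i] != i))
  # antiparallel stems: within a domain, consecutive pairs step inward
  for (d in which(sm$domains$kind %in% c("stem5", "kl_stem5"))) {
    rows <- sm$domains$start[d] - 1L + seq_len(sm$domains$length[d])
    stopifnot(all(diff(p[rows]) == -1L))
  }
  invisible(TRUE)
}

#' @export
print.strand_model <- function(x, ...) {
  cat(sprintf("strand_model: %d nt, %d domains, %d base pairs\n",
              x$length, nrow(x$domains), sum(!is.na(x$pairing)) / 2L))
  invisible(x)
}

#' Number of kissing-loop partner pairs in a strand model
#' @param strand a [build_strand_model()] result.
#' @return integer count of partnered `kl_loop` domain pairs.
#' @export
n_kl_pairs <- function(strand) {
  kl <- strand$domains[strand$domains$kind == "kl_loop", ]
  nrow(kl) / 2L
}

bracket_alphabet <- function() {
  c(list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">")),
    lapply(seq_along(LETTERS), function(i) c(LETTERS[i], letters[i])))
}

#' Dot-bracket secondary structure with pseudoknot layers
#'
#' Nested Watson-Crick stem pairs are written with `()`. Kissing-loop pairs
#' cross the stem layer, so each is assigned a pseudoknot layer by greedy
#' first-fit interval coloring (same-layer pairs never cross) using the
#' bracket alphabet `[]`, `{}`, `<>`, `Aa`, `Bb`, ... Unpaired positions are
#' dots.
#'
#' @param strand a [build_strand_model()] result.
#' @return structure string of length `strand$length`.
#' @export
to_dotbracket <- function(strand) {
  n <- strand$length
  p <- strand$pairing
  open_of <- which(!is.na(p) & p > seq_len(n))
  is_kl <- strand$nucleotides$dkind[open_of] == "kl_loop"
  pairs <- data.frame(i = open_of, j = p[open_of], kl = is_kl)
  pairs <- pairs[order(pairs$i), ]
  ab <- bracket_alphabet()
  layer_i <- list()  # open positions per layer
  layer_j <- list()
  assign_layer <- function(i, j, from) {
    l <- from
    repeat {
      if (l > length(ab))
        stop("pseudoknot layers exceed bracket alphabet (need > ",
             length(ab), ")")
      li <- if (l <= length(layer_i)) layer_i[[l]] else integer()
      lj <- if (l <= length(layer_j)) layer_j[[l]] else integer()
      crossing <- FALSE
      if (length(li)) {
        ins_i <- li > i & li < j
        ins_j <- lj > i & lj < j
        crossing <- any(xor(ins_i, ins_j))
      }
      if (!crossing) return(l)
      l <- l + 1L
    }
  }
  out <- rep(".", n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    l <- assign_layer(i, j, from = if (pairs$kl[r]) 2L else 1L)
    if (l > length(layer_i)) {
      layer_i[[l]] <- integer(); layer_j[[l]] <- integer()
    }
    layer_i[[l]] <- c(layer_i[[l]], i)
    layer_j[[l]] <- c(layer_j[[l]], j)
    out[i] <- ab[[l]][1L]
    out[j] <- ab[[l]][2L]
  }
  paste(out, collapse = "")
}

#' Parse a layered dot-bracket string into a pairing map
#'
#' Inverse of [to_dotbracket()]: each bracket layer is matched with its own
#' stack, so crossing pairs in different layers are recovered exactly.
#'
#' @param structure dot-bracket string (layers `()`, `[]`, `{}`, `<>`,
#'   `Aa`...`Zz`).
#' @return integer pairing vector (`NA` = unpaired).
#' @export
parse_dotbracket <- function(structure) {
  ch <- strsplit(structure, "")[[1L]]
  n <- length(ch)
  p <- rep(NA_integer_, n)
  ab <- bracket_alphabet()
  for (l in seq_along(ab)) {
    op <- ab[[l]][1L]; cl <- ab[[l]][2L]
    if (!any(ch == op) && !any(ch == cl)) next
    stack <- integer()
    for (k in seq_len(n)) {
      if (ch[k] == op) stack <- c(stack, k)
      else if (ch[k] == cl) {
        if (!length(stack)) stop("unbalanced structure at position ", k)
        p[k] <- stack[[length(stack)]]
        p[stack[[length(stack)]]] <- k
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) stop("unbalanced structure: unmatched '", op, "'")
  }
  bad <- !(ch %in% c(".", unlist(ab)))
  if (any(bad)) stop("unknown structure character at position ", which(bad)[1L])
  p
}
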