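OX_UNIT_NM <- 0.8518  # nm per oxDNA simulation length unit

#' Convert a snac document to an oxDNA model
#'
#' Builds the coarse-grained nucleotide records for the classic two-file
#' oxDNA input: one strand, positions converted from nm to simulation units
#' (0.8518 nm per unit) and shifted into a padded bounding box, base vectors
#' pointing from the backbone toward the paired base (or an arbitrary
#' perpendicular of the local tangent for unpaired bases), base normals
#' along the local strand tangent orthogonalized against the base vector,
#' and zero initial velocities (relaxation is the simulator's job). File
#' base order is 3'->5' per oxDNA convention, the reverse of snac order.
#'
#' @param doc a fully sequenced [snac_document()] (no `N`).
#' @param pairing integer pairing vector in snac (5'->3') order, e.g. from
#'   [parse_dotbracket()] of the document structure.
#' @param box_padding padding added around the bounding box, nm.
#' @return object of class `ox_model`: `records` data frame (strand, base,
#'   n3, n5, position/base vector/normal/velocities) in file order and
#'   `box` (3 floats, simulation units).
#' @export
snac_to_ox <- function(doc, pairing = parse_dotbracket(doc$structure),
                       box_padding = 10) {
  if (grepl("N", doc$sequence))
    stop("sequence contains N placeholders; run sequence design first")
  n <- nchar(doc$sequence)
  if (length(pairing) != n) stop("pairing length mismatch")
  co <- doc$coords
  base_v <- matrix(NA_real_, n, 3L)
  norm_v <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    tang <- co[min(i + 1L, n), ] - co[max(i - 1L, 1L), ]
    if (vnorm(tang) < 1e-9) tang <- c(0, 0, 1)
    if (!is.na(pairing[i]) && vnorm(co[pairing[i], ] - co[i, ]) > 1e-9) {
      b <- unitv(co[pairing[i], ] - co[i, ])
    } else {
      b <- perp_unit(tang)
    }
    tn <- tang - sum(tang * b) * b
    if (vnorm(tn) < 1e-9) tn <- perp_unit(b)
    base_v[i, ] <- b
    norm_v[i, ] <- unitv(tn)
  }
  pos <- co / OX_UNIT_NM
  pad <- box_padding / OX_UNIT_NM
  mins <- apply(pos, 2L, min)
  maxs <- apply(pos, 2L, max)
  box <- (maxs - mins) + 2 * pad
  pos <- sweep(pos, 2L, mins - pad)
  ord <- n:1  # snac is 5'->3'; oxDNA files list 3'->5'
  k <- seq_len(n)
  rec <- data.frame(strand = 1L,
                    base = strsplit(doc$sequence, "")[[1L]][ord],
                    n3 = ifelse(k == 1L, -1L, k - 2L),
                    n5 = ifelse(k == n, -1L, k))
  rec <- cbind(rec, px = pos[ord, 1L], py = pos[ord, 2L], pz = pos[ord, 3L],
               bx = base_v[ord, 1L], by = base_v[ord, 2L],
               bz = base_v[ord, 3L],
               nx = norm_v[ord, 1L], ny = norm_v[ord, 2L],
               nz = norm_v[ord, 3L])
  m <- structure(list(records = rec, box = box, n = n, n_strands = 1L),
                 class = "ox_model")
  validate_ox_model(m)
  m
}

validate_ox_model <- function(m) {
  r <- m$records
  # single open chain per strand
  stopifnot(sum(r$n3 == -1L) == m$n_strands, sum(r$n5 == -1L) == m$n_strands)
  k <- which(r$n3 == -1L)
  seen <- 0L
  while (k != -1L && seen <= m$n) {
    seen <- seen + 1L
    k <- if (r$n5[k] == -1L) -1L else r$n5[k] + 1L
  }
  stopifnot(seen == m$n)
  bv <- as.matrix(r[, c("bx", "by", "bz")])
  nv <- as.matrix(r[, c("nx", "ny", "nz")])
  # 1e-6 accommodates the 8-decimal fixed-point file representation
  stopifnot(all(abs(rowSums(bv^2) - 1) < 1e-6),
            all(abs(rowSums(nv^2) - 1) < 1e-6),
            all(abs(rowSums(bv * nv)) < 1e-6))
  pos <- as.matrix(r[, c("px", "py", "pz")])
  stopifnot(all(pos >= -1e-9), all(sweep(pos, 2L, m$box) <= 1e-9))
  invisible(TRUE)
}

#' @export
print.ox_model <- function(x, ...) {
  cat(sprintf("ox_model: %d nucleotides, %d strand(s), box %.2f %.2f %.2f\n",
              x$n, x$n_strands, x$box[1L], x$box[2L], x$box[3L]))
  invisible(x)
}

#' Write oxDNA topology and configuration files
#'
#' Topology: header `<N> <n_strands>`, then one `<strand> <base> <n3> <n5>`
#' line per nucleotide. Configuration: `t = 0`, `b = bx by bz`,
#' `E = 0 0 0`, then 15 fixed-point 8-decimal floats per nucleotide
#' (position, base vector, base normal, velocity, angular velocity), for
#' reproducible byte-identical output.
#'
#' @param model an [snac_to_ox()] result.
#' @param topology_path,configuration_path output file paths.
#' @return invisible list of the two paths.
#' @export
write_ox_files <- function(model, topology_path, configuration_path) {
  r <- model$records
  writeLines(c(sprintf("%d %d", model$n, model$n_strands),
               sprintf("%d %s %d %d", r$strand, r$base, r$n3, r$n5)),
             topology_path)
  f8 <- function(x) sprintf("%.8f", x)
  rows <- paste(f8(r$px), f8(r$py), f8(r$pz), f8(r$bx), f8(r$by), f8(r$bz),
                f8(r$nx), f8(r$ny), f8(r$nz),
                f8(0), f8(0), f8(0), f8(0), f8(0), f8(0))
  writeLines(c("t = 0",
               paste("b =", f8(model$box[1L]), f8(model$box[2L]),
                     f8(model$box[3L])),
               "E = 0 0 0", rows), configuration_path)
  invisible(list(topology = topology_path, configuration = configuration_path))
}

#' Read back oxDNA files written by [write_ox_files()]
#' @param topology_path,configuration_path file paths.
#' @return an `ox_model`.
#' @export
read_ox_files <- function(topology_path, configuration_path) {
  top <- readLines(topology_path, warn = FALSE)
  hdr <- as.integer(strsplit(top[[1L]], " ")[[1L]])
  n <- hdr[[1L]]
  tt <- utils::read.table(text = top[-1L],
                          col.names = c("strand", "base", "n3", "n5"),
                          colClasses = c("integer", "character", "integer",
                                         "integer"))
  conf <- readLines(configuration_path, warn = FALSE)
  box <- as.numeric(strsplit(sub("^b = ", "", conf[[2L]]), " ")[[1L]])
  cc <- utils::read.table(text = conf[-(1:3)])
  rec <- cbind(tt, px = cc[[1L]], py = cc[[2L]], pz = cc[[3L]],
               bx = cc[[4L]], by = cc[[5L]], bz = cc[[6L]],
               nx = cc[[7L]], ny = cc[[8L]], nz = cc[[9L]])
  m <- structure(list(records = rec, box = box, n = n,
                      n_strands = hdr[[2L]]), class = "ox_model")
  validate_ox_model(m)
  m
}
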