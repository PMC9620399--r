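#' snac document: sequence + structure + coordinates
#'
#' The pipeline's interchange object: a name, the RNA sequence (with `N`
#' placeholders before sequence design), the layered dot-bracket structure,
#' and one 3D coordinate (nm) per nucleotide. The original tool's snac
#' grammar is unpublished, so this package defines a versioned dialect (see
#' [write_snac()]).
#'
#' @param name design name.
#' @param sequence RNA sequence over A/C/G/U/N.
#' @param structure layered dot-bracket string, same length.
#' @param coords numeric matrix, one row (x, y, z in nm) per nucleotide.
#' @return object of class `snac_document`.
#' @export
snac_document <- function(name, sequence, structure, coords) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  n <- nchar(sequence)
  if (nchar(structure) != n)
    stop("length mismatch: |structure| != |sequence|")
  if (nrow(coords) != n)
    stop("length mismatch: coordinate rows != |sequence|")
  if (ncol(coords) != 3L || any(!is.finite(coords)))
    stop("coordinates must be finite x y z triples")
  if (grepl("[^ACGUN]", sequence))
    stop("sequence must be over A/C/G/U/N")
  parse_dotbracket(structure)  # raises on unbalanced layers
  structure(list(name = name, sequence = sequence,
                 structure = structure, coords = coords),
            class = "snac_document")
}

#' @export
print.snac_document <- function(x, ...) {
  cat(sprintf("snac_document '%s': %d nt\n", x$name, nchar(x$sequence)))
  invisible(x)
}

#' Write / read the snac text format
#'
#' Line-oriented dialect (version 1.0):
#' \preformatted{
#' # snac 1.0
#' name <name>
#' length <n>
#' <sequence>
#' <structure>
#' <x> <y> <z>     (one line per nucleotide, nm, 9 significant digits)
#' }
#'
#' @param doc a [snac_document()].
#' @param path file path.
#' @return `write_snac`: `path` invisibly; `read_snac`: a validated
#'   [snac_document()].
#' @export
write_snac <- function(doc, path) {
  force(doc)  # doc may be read from `path` itself; evaluate before truncating
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# snac 1.0",
               paste("name", doc$name),
               paste("length", nchar(doc$sequence)),
               doc$sequence, doc$structure,
               sprintf("%.9g %.9g %.9g", doc$coords[, 1L],
                       doc$coords[, 2L], doc$coords[, 3L])), con)
  invisible(path)
}

#' @rdname write_snac
#' @export
read_snac <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L || !grepl("^# snac 1\\.", lines[[1L]]))
    stop("not a snac 1.x file: ", path)
  if (!startsWith(lines[[2L]], "name "))
    stop("snac parse error at line 2: expected 'name'")
  name <- sub("^name ", "", lines[[2L]])
  if (!startsWith(lines[[3L]], "length "))
    stop("snac parse error at line 3: expected 'length'")
  n <- as.integer(sub("^length ", "", lines[[3L]]))
  seqn <- lines[[4L]]
  struct <- lines[[5L]]
  if (nchar(seqn) != n)
    stop("snac parse error at line 4: sequence length != declared length")
  if (length(lines) < 5L + n)
    stop("snac parse error: expected ", n, " coordinate lines")
  co <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[[5L + k]]),
                                              "[[:space:]]+")[[1L]]))
    if (length(v) != 3L || any(is.na(v)))
      stop("snac parse error at line ", 5L + k, ": malformed coordinate line")
    co[k, ] <- v
  }
  snac_document(name, seqn, struct, co)
}

#' Write a Vienna-style dot-bracket file
#'
#' Plain interoperable export: a `>`-header line, the sequence line and the
#' structure line.
#'
#' @param doc a [snac_document()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(doc, path) {
  writeLines(c(paste0(">", doc$name), doc$sequence, doc$structure), path)
  invisible(path)
}
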