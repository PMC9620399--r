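#' Wireframe mesh
#'
#' A `wire_mesh` is the input object of the design pipeline: a set of 3D
#' vertices (nanometres) joined by undirected edges, optionally grouped into
#' faces. Every edge will be rendered as one RNA duplex, so the edge graph
#' must be connected and free of duplicate or degenerate edges.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in nm.
#' @param edges two-column integer matrix of 1-based vertex indices, one row
#'   per undirected edge.
#' @param faces optional list of integer vectors, each a vertex cycle.
#' @param name label for the mesh.
#' @return An object of class `wire_mesh` with elements `vertices`, `edges`
#'   (rows sorted, lower index first), `faces` and `name`.
#' @export
wire_mesh <- function(vertices, edges, faces = NULL, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  edges <- t(apply(edges, 1L, sort))
  if (nrow(edges) > 0L) {
    ord <- order(edges[, 1L], edges[, 2L])
    edges <- edges[ord, , drop = FALSE]
  }
  m <- structure(list(vertices = vertices, edges = edges,
                      faces = faces, name = name),
                 class = "wire_mesh")
  diag <- validate_mesh(m)
  if (length(diag)) stop("invalid mesh: ", paste(diag, collapse = "; "))
  m
}

#' @export
print.wire_mesh <- function(x, ...) {
  cat(sprintf("wire_mesh '%s': %d vertices, %d edges%s\n", x$name,
              nrow(x$vertices), nrow(x$edges),
              if (is.null(x$faces)) "" else sprintf(", %d faces",
                                                   length(x$faces))))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_edges <- function(mesh) nrow(mesh$edges)

edge_lengths <- function(mesh) {
  a <- mesh$vertices[mesh$edges[, 1L], , drop = FALSE]
  b <- mesh$vertices[mesh$edges[, 2L], , drop = FALSE]
  sqrt(rowSums((a - b)^2))
}

mesh_graph <- function(mesh) {
  igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
}

#' Validate a wireframe mesh
#'
#' Checks the `wire_mesh` invariants and returns human-readable diagnostics
#' instead of raising errors, one entry per violation. An empty character
#' vector means the mesh is valid.
#'
#' @param mesh a list with at least `vertices` and `edges` as in [wire_mesh()].
#' @return character vector of diagnostics (empty if valid).
#' @export
validate_mesh <- function(mesh) {
  out <- character()
  v <- nrow(mesh$vertices)
  e <- mesh$edges
  if (any(!is.finite(mesh$vertices))) out <- c(out, "non-finite vertex coordinate")
  if (nrow(e) == 0L) return(c(out, "mesh has no edges"))
  if (any(e < 1L) || any(e > v)) out <- c(out, "edge endpoint out of range")
  else {
    if (any(e[, 1L] == e[, 2L])) out <- c(out, "degenerate edge")
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    if (anyDuplicated(key)) out <- c(out, "duplicate edge")
    len <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                         mesh$vertices[e[, 2L], , drop = FALSE])^2))
    if (any(len <= 1e-12)) out <- c(out, "zero-length edge")
    g <- igraph::graph_from_edgelist(cbind(pmin(e[, 1L], e[, 2L]),
                                           pmax(e[, 1L], e[, 2L])),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, v - igraph::vcount(g)))
    if (!igraph::is_connected(g)) out <- c(out, "mesh not connected")
  }
  out
}

#' Load a mesh from a Wavefront OBJ file
#'
#' Reads the minimal interoperable OBJ subset: `v` (vertex), `f` (face) and
#' `l` (polyline) records. Faces are decomposed into their boundary edges and
#' duplicate edges are merged. Normals, textures and materials are ignored.
#' Coordinates are taken as nanometres unless rescaled with `units_scale`.
#'
#' @param path path to an OBJ file.
#' @param units_scale multiplicative factor mapping file units to nm
#'   (e.g. 0.1 for a file in Angstroms).
#' @param name mesh label; defaults to the file base name.
#' @return a [wire_mesh()].
#' @export
load_mesh <- function(path, units_scale = 1, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  verts <- list()
  edges <- list()
  faces <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    kind <- tok[[1L]]
    if (kind == "v") {
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (length(tok) < 4L || any(is.na(xyz)))
        stop(sprintf("OBJ format error at line %d: bad vertex record", i))
      verts[[length(verts) + 1L]] <- xyz
    } else if (kind == "f" || kind == "l") {
      # face/line indices may carry /vt/vn suffixes
      idx <- suppressWarnings(as.integer(sub("/.*$", "", tok[-1L])))
      if (length(idx) < 2L || any(is.na(idx)) || any(idx == 0L))
        stop(sprintf("OBJ format error at line %d: bad index record", i))
      if (any(idx < 0L)) idx <- length(verts) + idx + 1L  # relative indices
      if (kind == "f") {
        if (length(idx) < 3L)
          stop(sprintf("OBJ format error at line %d: face with < 3 vertices", i))
        faces[[length(faces) + 1L]] <- idx
        cyc <- cbind(idx, c(idx[-1L], idx[[1L]]))
        edges[[length(edges) + 1L]] <- cyc
      } else {
        edges[[length(edges) + 1L]] <- cbind(idx[-length(idx)], idx[-1L])
      }
    }
  }
  if (!length(verts)) stop("OBJ format error: no 'v' records")
  if (!length(edges)) stop("OBJ format error: no 'l' or 'f' records")
  vm <- do.call(rbind, verts) * units_scale
  em <- do.call(rbind, edges)
  if (any(em < 1L) || any(em > nrow(vm)))
    stop("OBJ format error: index out of range")
  em <- unique(cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L])))
  wire_mesh(vm, em, faces = if (length(faces)) faces else NULL,
            name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a mesh to a Wavefront OBJ file
#'
#' Faces (if present) are written as `f` records; edges not covered by any
#' face are written as `l` records, so `load_mesh(write_obj(m))` reproduces
#' the edge set exactly.
#'
#' @param mesh a [wire_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wire_mesh %s", mesh$name), con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  covered <- character()
  if (!is.null(mesh$faces)) {
    for (f in mesh$faces) {
      writeLines(paste("f", paste(f, collapse = " ")), con)
      cyc <- cbind(f, c(f[-1L], f[[1L]]))
      covered <- c(covered, paste(pmin(cyc[, 1L], cyc[, 2L]),
                                  pmax(cyc[, 1L], cyc[, 2L])))
    }
  }
  key <- paste(mesh$edges[, 1L], mesh$edges[, 2L])
  rest <- mesh$edges[!key %in% covered, , drop = FALSE]
  if (nrow(rest))
    writeLines(sprintf("l %d %d", rest[, 1L], rest[, 2L]), con)
  invisible(path)
}

#' Names of the built-in mesh fixtures
#' @return character vector of names accepted by [builtin_mesh()].
#' @export
builtin_mesh_names <- function() {
  c("tetrahedron", "bipyramid", "prism_triangulated", "cube",
    "dodecahedron", "grid")
}

#' Built-in wireframe meshes
#'
#' Canonical fixtures used throughout the package: the regular tetrahedron
#' (V=4, E=6), triangular bipyramid (V=5, E=9), triangular prism with
#' triangulated sides (V=6, E=12), cube (V=8, E=12), regular dodecahedron
#' (V=20, E=30) and a rectangular vertex lattice `grid` (default 3x2x2,
#' V=12, E=20) demonstrating non-polyhedral straight-line meshes. All are
#' scaled so the nominal edge length equals `edge_scale`.
#'
#' @param name one of [builtin_mesh_names()].
#' @param edge_scale nominal edge length in nm (default 10).
#' @param grid_dims integer vector of vertices per axis for `name = "grid"`.
#' @return a [wire_mesh()].
#' @export
builtin_mesh <- function(name, edge_scale = 10, grid_dims = c(3L, 2L, 2L)) {
  if (!is.numeric(edge_scale) || edge_scale <= 0)
    stop("edge_scale must be > 0")
  name <- match.arg(name, builtin_mesh_names())
  m <- switch(name,
    tetrahedron = {
      v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      e <- t(combn(4L, 2L))
      f <- list(c(1L, 2L, 3L), c(1L, 3L, 4L), c(1L, 4L, 2L), c(2L, 4L, 3L))
      list(v = v / (2 * sqrt(2)), e = e, f = f)
    },
    bipyramid = {
      s <- 1
      r <- s / sqrt(3)
      h <- s * sqrt(2 / 3)
      ang <- 2 * pi * (0:2) / 3
      v <- rbind(cbind(r * cos(ang), r * sin(ang), 0),
                 c(0, 0, h), c(0, 0, -h))
      e <- rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L),
                 cbind(1:3, 4L), cbind(1:3, 5L))
      f <- list(c(1L, 2L, 4L), c(2L, 3L, 4L), c(3L, 1L, 4L),
                c(2L, 1L, 5L), c(3L, 2L, 5L), c(1L, 3L, 5L))
      list(v = v, e = e, f = f)
    },
    prism_triangulated = {
      r <- 1 / sqrt(3)
      ang <- 2 * pi * (0:2) / 3
      v <- rbind(cbind(r * cos(ang), r * sin(ang), 0),
                 cbind(r * cos(ang), r * sin(ang), 1))
      tri <- rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L))
      e <- rbind(tri, tri + 3L, cbind(1:3, 4:6),
                 # one diagonal per rectangular side
                 c(1L, 5L), c(2L, 6L), c(3L, 4L))
      list(v = v, e = e, f = NULL)
    },
    cube = {
      v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
      colnames(v) <- NULL
      d2 <- as.matrix(dist(v))^2
      e <- which(upper.tri(d2) & abs(d2 - 1) < 1e-9, arr.ind = TRUE)
      f <- NULL
      list(v = v, e = cbind(e[, 1L], e[, 2L]), f = f)
    },
    dodecahedron = {
      phi <- (1 + sqrt(5)) / 2
      v <- rbind(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
                 cbind(0, c(-1, -1, 1, 1) / phi, c(-1, 1, -1, 1) * phi),
                 cbind(c(-1, -1, 1, 1) / phi, c(-1, 1, -1, 1) * phi, 0),
                 cbind(c(-1, 1, -1, 1) * phi, 0, c(-1, -1, 1, 1) / phi))
      colnames(v) <- NULL
      d <- as.matrix(dist(v))
      el <- 2 / phi
      e <- which(upper.tri(d) & abs(d - el) < 1e-9, arr.ind = TRUE)
      list(v = v / el, e = cbind(e[, 1L], e[, 2L]), f = NULL)
    },
    grid = {
      gd <- as.integer(grid_dims)
      if (length(gd) != 3L || any(gd < 1L) || prod(gd) < 2L)
        stop("grid_dims must be 3 positive integers with at least 2 vertices")
      v <- as.matrix(expand.grid(seq_len(gd[1L]) - 1L,
                                 seq_len(gd[2L]) - 1L,
                                 seq_len(gd[3L]) - 1L))
      colnames(v) <- NULL
      d2 <- as.matrix(dist(v))^2
      e <- which(upper.tri(d2) & abs(d2 - 1) < 1e-9, arr.ind = TRUE)
      list(v = v, e = cbind(e[, 1L], e[, 2L]), f = NULL)
    })
  # rescale so the shortest edge (the nominal edge) has length edge_scale
  len <- sqrt(rowSums((m$v[m$e[, 1L], , drop = FALSE] -
                       m$v[m$e[, 2L], , drop = FALSE])^2))
  wire_mesh(m$v * (edge_scale / min(len)), m$e, faces = m$f, name = name)
}
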