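#' Choose a spanning tree of a wireframe mesh
#'
#' The strand is routed twice around a spanning tree; the remaining
#' (non-tree) edges are later reintroduced as kissing-loop connectors.
#'
#' @param mesh a [wire_mesh()].
#' @param strategy `"bfs"` (breadth-first from vertex 1, edge-index
#'   tie-breaking; the deterministic default), `"prim_shortest"` (minimum
#'   spanning tree under Euclidean edge lengths) or `"seeded_random"`
#'   (minimum spanning tree under seeded uniform random weights).
#' @param seed integer seed, used by `"seeded_random"` only.
#' @return sorted integer vector of edge indices (rows of `mesh$edges`)
#'   of length `V - 1`.
#' @export
spanning_tree <- function(mesh, strategy = c("bfs", "prim_shortest",
                                             "seeded_random"), seed = 1L) {
  strategy <- match.arg(strategy)
  if (length(validate_mesh(mesh)))
    stop("invalid mesh: ", paste(validate_mesh(mesh), collapse = "; "))
  nv <- n_vertices(mesh)
  ne <- n_edges(mesh)
  if (strategy == "bfs") {
    adj <- vector("list", nv)
    for (i in seq_len(ne)) {
      u <- mesh$edges[i, 1L]; v <- mesh$edges[i, 2L]
      adj[[u]] <- rbind(adj[[u]], c(v, i))
      adj[[v]] <- rbind(adj[[v]], c(u, i))
    }
    seen <- rep(FALSE, nv)
    seen[1L] <- TRUE
    queue <- 1L
    tree <- integer()
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      for (k in seq_len(NROW(nb))) {
        w <- nb[k, 1L]
        if (!seen[w]) {
          seen[w] <- TRUE
          tree <- c(tree, nb[k, 2L])
          queue <- c(queue, w)
        }
      }
    }
    return(sort(tree))
  }
  g <- mesh_graph(mesh)
  igraph::E(g)$id <- seq_len(ne)
  w <- switch(strategy,
              prim_shortest = edge_lengths(mesh),
              seeded_random = with_seed(seed, stats::runif(ne)))
  mt <- igraph::mst(g, weights = w)
  sort(igraph::E(mt)$id)
}

# Canonical band offset vector (nm) for an edge: perpendicular to the edge
# axis, fixed global reference. The two antiparallel strand passes of an
# edge run on sides +offset and -offset of the axis.
edge_offset_vec <- function(mesh, ei, delta) {
  a <- mesh$vertices[mesh$edges[ei, 1L], ]
  b <- mesh$vertices[mesh$edges[ei, 2L], ]
  delta * perp_unit(b - a)
}

# Port table for one vertex: for every incident item (tree edge or
# kissing-loop spike) the two band-side end points on the vertex sphere,
# sorted into cyclic order by projected angle.
vertex_port_table <- function(mesh, v, items, s, delta) {
  dirs <- t(vapply(items, function(ei) {
    uv <- mesh$edges[ei, ]
    other <- if (uv[1L] == v) uv[2L] else uv[1L]
    unitv(mesh$vertices[other, ] - mesh$vertices[v, ])
  }, numeric(3L)))
  # projection plane: orthogonal to the mean incident direction, falling
  # back to the least-spread principal direction when the mean vanishes
  nrm <- colMeans(dirs)
  if (vnorm(nrm) < 1e-6) {
    ev <- eigen(crossprod(dirs), symmetric = TRUE)
    nrm <- ev$vectors[, 3L]
  }
  nrm <- unitv(nrm)
  ax <- perp_unit(nrm)
  ay <- cross3(nrm, ax)
  ang_of <- function(p) atan2(sum((p - mesh$vertices[v, ]) * ay),
                              sum((p - mesh$vertices[v, ]) * ax))
  item_ang <- vapply(seq_along(items), function(k)
    atan2(sum(dirs[k, ] * ay), sum(dirs[k, ] * ax)), 0)
  ord <- order(item_ang, items)
  rows <- list()
  for (k in ord) {
    ei <- items[[k]]
    ov <- edge_offset_vec(mesh, ei, delta)
    base <- mesh$vertices[v, ] + s * dirs[k, ]
    pp <- base + ov
    pm <- base - ov
    # order the item's two ports so the cyclic sequence increases ccw
    da <- ang_of(pp) - item_ang[k]
    da <- atan2(sin(da), cos(da))
    sides <- if (da >= 0) c(-1, 1) else c(1, -1)
    for (sg in sides) {
      p <- if (sg > 0) pp else pm
      rows[[length(rows) + 1L]] <- data.frame(
        edge = ei, side = sg, angle = ang_of(p),
        x = p[1L], y = p[2L], z = p[3L])
    }
  }
  do.call(rbind, rows)
}

#' Route a strand around a spanning tree
#'
#' Traces the boundary of the spanning tree thickened into bands, with a
#' half-edge hairpin spike extruded along each non-tree (kissing-loop) edge
#' at both of its end vertices. The boundary of this embedded disk is a
#' single closed curve that covers every tree edge twice in antiparallel
#' directions and visits every kissing-loop spike once, and it is an unknot
#' by construction: at each vertex sphere the strand always exits through
#' the angularly adjacent port, so the connecting chords never cross.
#'
#' @param mesh a [wire_mesh()].
#' @param tree integer vector of tree edge indices, e.g. [spanning_tree()].
#' @param sphere_frac vertex sphere radius as a fraction of the shortest
#'   edge length.
#' @param offset_frac band half-separation as a fraction of the shortest
#'   edge length.
#' @return An object of class `routing_plan`: `tree_edges`, `kl_edges`,
#'   `traversal` (data frame of events: `type` "tree"/"kl", `edge`, `from`,
#'   `to`, `side`), `vertex_ports`, `vertex_matchings` (port-index pairs per
#'   vertex, all non-crossing), and `nick` (event index 1, mid-edge).
#' @export
route_strand <- function(mesh, tree, sphere_frac = 0.25, offset_frac = 0.08) {
  nv <- n_vertices(mesh)
  ne <- n_edges(mesh)
  tree <- sort(as.integer(tree))
  if (length(tree) != nv - 1L || any(tree < 1L) || any(tree > ne) ||
      anyDuplicated(tree))
    stop("tree is not a spanning tree: wrong edge count")
  tg <- igraph::graph_from_edgelist(mesh$edges[tree, , drop = FALSE],
                                    directed = FALSE)
  tg <- igraph::add_vertices(tg, max(0L, nv - igraph::vcount(tg)))
  if (!igraph::is_connected(tg) || igraph::ecount(tg) != nv - 1L)
    stop("tree is not a spanning tree: not connected/acyclic")
  kl <- setdiff(seq_len(ne), tree)
  minlen <- min(edge_lengths(mesh))
  s <- sphere_frac * minlen
  delta <- offset_frac * minlen

  is_tree <- seq_len(ne) %in% tree
  ports <- vector("list", nv)
  for (v in seq_len(nv)) {
    inc <- which(mesh$edges[, 1L] == v | mesh$edges[, 2L] == v)
    ports[[v]] <- vertex_port_table(mesh, v, inc, s, delta)
  }
  port_idx <- function(v, ei, sg) which(ports[[v]]$edge == ei &
                                        ports[[v]]$side == sg)
  other_end <- function(ei, v) {
    uv <- mesh$edges[ei, ]
    if (uv[1L] == v) uv[2L] else uv[1L]
  }
  # exit through the cyclically adjacent port that is not our sibling
  next_port <- function(v, p) {
    np <- nrow(ports[[v]])
    nb1 <- if (p == np) 1L else p + 1L
    nb2 <- if (p == 1L) np else p - 1L
    if (ports[[v]]$edge[nb1] != ports[[v]]$edge[p]) nb1
    else if (ports[[v]]$edge[nb2] != ports[[v]]$edge[p]) nb2
    else nb1  # degree-1 vertex: U-turn through the sibling
  }

  e0 <- tree[[1L]]
  start <- c(e0, mesh$edges[e0, 1L], mesh$edges[e0, 2L], 1L)
  state <- start
  events <- list()
  chords <- lapply(seq_len(nv), function(v) NULL)
  repeat {
    ei <- state[[1L]]; from <- state[[2L]]; to <- state[[3L]]
    sg <- state[[4L]]
    events[[length(events) + 1L]] <-
      data.frame(type = "tree", edge = ei, from = from, to = to, side = sg)
    v <- to
    p <- port_idx(v, ei, sg)
    repeat {
      q <- next_port(v, p)
      chords[[v]] <- rbind(chords[[v]], c(p, q))
      qe <- ports[[v]]$edge[q]
      qs <- ports[[v]]$side[q]
      if (is_tree[qe]) break
      # kissing-loop spike: hairpin out and back, re-emerge at the sibling
      events[[length(events) + 1L]] <-
        data.frame(type = "kl", edge = qe, from = v, to = NA_integer_,
                   side = qs)
      p <- port_idx(v, qe, -qs)
      if (length(events) > 4L * (ne + nv) + 8L)
        stop("routing trace failed to close")  # defensive
    }
    state <- c(qe, v, other_end(qe, v), qs)
    if (all(state == start)) break
    if (length(events) > 4L * (ne + nv) + 8L)
      stop("routing trace failed to close")
  }
  trav <- do.call(rbind, events)
  rownames(trav) <- NULL

  # sanity: every tree edge twice (antiparallel), every kl spike once per end
  te <- trav[trav$type == "tree", ]
  stopifnot(nrow(te) == 2L * (nv - 1L),
            all(table(te$edge) == 2L),
            all(tapply(te$from, te$edge, function(x) length(unique(x))) == 2L))
  ke <- trav[trav$type == "kl", ]
  stopifnot(nrow(ke) == 2L * length(kl),
            all(table(ke$edge) == 2L),
            all(tapply(ke$from, ke$edge, function(x) length(unique(x))) == 2L))

  structure(list(tree_edges = tree, kl_edges = kl, traversal = trav,
                 vertex_ports = ports, vertex_matchings = chords,
                 nick = list(event = 1L, mode = "mid"),
                 sphere = s, offset = delta, mesh_name = mesh$name),
            class = "routing_plan")
}

#' @export
print.routing_plan <- function(x, ...) {
  cat(sprintf(paste0("routing_plan for '%s': %d tree edges, %d kissing-loop",
                     " edges, %d traversal events\n"),
              x$mesh_name, length(x$tree_edges), length(x$kl_edges),
              nrow(x$traversal)))
  invisible(x)
}

#' Number of kissing-loop pairs in a routing plan
#' @param plan a [route_strand()] result.
#' @return integer, equals the cycle rank `E - V + 1` of the source mesh.
#' @export
n_kissing_loops <- function(plan) length(plan$kl_edges)

#' Test whether a chord matching is non-crossing in cyclic port order
#'
#' @param pairs two-column matrix of port indices (chords).
#' @param n_ports number of ports on the circle.
#' @return `TRUE` if no two chords interleave.
#' @export
is_noncrossing_matching <- function(pairs, n_ports) {
  if (is.null(pairs) || nrow(pairs) < 2L) return(TRUE)
  pr <- t(apply(pairs, 1L, sort))
  for (i in seq_len(nrow(pr) - 1L)) {
    for (j in seq(i + 1L, nrow(pr))) {
      a <- pr[i, 1L]; b <- pr[i, 2L]
      inside <- (pr[j, ] > a) & (pr[j, ] < b)
      if (xor(inside[1L], inside[2L])) return(FALSE)
    }
  }
  TRUE
}

#' Non-crossing matching of in-ports to out-ports on a circle
#'
#' Given the cyclic order of strand ports at a vertex sphere, pairs every
#' in-port with an out-port such that no two connecting chords cross
#' (balanced-parentheses property). Such a matching always exists when the
#' numbers of in- and out-ports are equal.
#'
#' @param roles character vector in cyclic order, entries `"in"` or `"out"`.
#' @return two-column matrix of port indices; column 1 in-ports, column 2
#'   out-ports.
#' @export
vertex_matching <- function(roles) {
  roles <- match.arg(roles, c("in", "out"), several.ok = TRUE)
  n <- length(roles)
  if (n %% 2L || sum(roles == "in") != n / 2L)
    stop("need equally many in- and out-ports")
  for (off in 0:(n - 1L)) {
    idx <- ((seq_len(n) - 1L + off) %% n) + 1L
    stack <- integer()
    pairs <- NULL
    ok <- TRUE
    for (p in idx) {
      if (length(stack) && roles[stack[[length(stack)]]] != roles[p]) {
        q <- stack[[length(stack)]]
        stack <- stack[-length(stack)]
        pairs <- rbind(pairs, if (roles[p] == "out") c(q, p) else c(p, q))
      } else stack <- c(stack, p)
    }
    if (length(stack) == 0L) {
      stopifnot(is_noncrossing_matching(pairs, n))
      return(pairs)
    }
  }
  stop("no non-crossing matching exists for this port sequence")
}

#' Closed 3D centerline of a routing
#'
#' Builds the closed polyline traced by the routed strand: each tree pass as
#' a band-offset segment along its edge, each kissing-loop spike as an
#' out-and-back excursion to 45% of the edge length, with straight chords
#' at the vertex spheres. Input for [knot_determinant()].
#'
#' @param mesh the routed [wire_mesh()].
#' @param plan a [route_strand()] result for `mesh`.
#' @return numeric matrix of 3D points; the polyline closes from the last
#'   row back to the first.
#' @export
routing_polyline <- function(mesh, plan) {
  s <- plan$sphere
  pts <- list()
  for (i in seq_len(nrow(plan$traversal))) {
    ev <- plan$traversal[i, ]
    ov <- edge_offset_vec(mesh, ev$edge, plan$offset) * ev$side
    if (ev$type == "tree") {
      u <- mesh$vertices[ev$from, ]; w <- mesh$vertices[ev$to, ]
      d <- unitv(w - u)
      pts[[length(pts) + 1L]] <- rbind(u + s * d + ov, w - s * d + ov)
    } else {
      v <- mesh$vertices[ev$from, ]
      w <- mesh$vertices[other_vertex(mesh, ev$edge, ev$from), ]
      d <- unitv(w - v)
      L <- vnorm(w - v)
      tip <- v + 0.45 * L * d
      pts[[length(pts) + 1L]] <- rbind(v + s * d + ov, tip + ov,
                                       tip - ov, v + s * d - ov)
    }
  }
  out <- do.call(rbind, pts)
  dimnames(out) <- NULL
  out
}

other_vertex <- function(mesh, ei, v) {
  uv <- mesh$edges[ei, ]
  if (uv[1L] == v) uv[2L] else uv[1L]
}

# All transverse crossings of a closed 2D polyline with itself.
# Returns NULL on a degenerate projection.
polyline_crossings <- function(xy, z, tol = 1e-9) {
  n <- nrow(xy)
  nxt <- c(seq_len(n)[-1L], 1L)
  px <- xy[, 1L]; py <- xy[, 2L]
  rx <- px[nxt] - px; ry <- py[nxt] - py
  seglen <- sqrt(rx^2 + ry^2)
  if (any(seglen < tol * max(seglen))) return(NULL)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  adj <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adj]; j <- j[!adj]
  den <- rx[i] * ry[j] - ry[i] * rx[j]
  qpx <- px[j] - px[i]; qpy <- py[j] - py[i]
  cr1 <- qpx * ry[j] - qpy * rx[j]   # t * den
  cr2 <- qpx * ry[i] - qpy * rx[i]   # u * den
  near_par <- abs(den) < tol * seglen[i] * seglen[j]
  # collinear overlapping parallel segments make the projection degenerate
  if (any(near_par & abs(cr1) < tol * seglen[i] * seglen[j] * 10)) {
    ii <- which(near_par & abs(cr1) < tol * seglen[i] * seglen[j] * 10)
    for (k in ii) {  # overlap test along the shared direction
      d <- c(rx[i[k]], ry[i[k]]) / seglen[i[k]]
      a0 <- px[i[k]] * d[1L] + py[i[k]] * d[2L]
      a1 <- a0 + seglen[i[k]]
      b0 <- px[j[k]] * d[1L] + py[j[k]] * d[2L]
      b1 <- b0 + (rx[j[k]] * d[1L] + ry[j[k]] * d[2L])
      if (max(min(a0, a1), min(b0, b1)) < min(max(a0, a1), max(b0, b1)) - tol)
        return(NULL)
    }
  }
  keep <- !near_par
  i <- i[keep]; j <- j[keep]; den <- den[keep]
  tt <- (qpx[keep] * ry[j] - qpy[keep] * rx[j]) / den
  uu <- (qpx[keep] * ry[i] - qpy[keep] * rx[i]) / den
  eps <- 1e-7
  hit <- tt > -eps & tt < 1 + eps & uu > -eps & uu < 1 + eps
  if (any(hit & (abs(tt) < eps | abs(tt - 1) < eps |
                 abs(uu) < eps | abs(uu - 1) < eps)))
    return(NULL)  # crossing at a segment endpoint: not generic
  hit <- tt > eps & tt < 1 - eps & uu > eps & uu < 1 - eps
  if (!any(hit)) return(data.frame())
  i <- i[hit]; j <- j[hit]; tt <- tt[hit]; uu <- uu[hit]
  zi <- z[i] + tt * (z[nxt[i]] - z[i])
  zj <- z[j] + uu * (z[nxt[j]] - z[j])
  if (any(abs(zi - zj) < 1e-9 * (1 + max(abs(z))))) return(NULL)
  data.frame(s1 = i - 1 + tt, s2 = j - 1 + uu, over1 = zi > zj)
}

#' Knot determinant of a closed polyline
#'
#' Projects the closed curve onto a generic plane, builds the crossing
#' diagram, and evaluates the knot determinant (the Alexander polynomial at
#' -1, equivalently the Goeritz/coloring determinant). The determinant is 1
#' for the unknot, so a value of 1 is a necessary (not sufficient) condition
#' for unknottedness; 3 for the trefoil, 5 for the figure-eight knot.
#'
#' At t = -1 the Wirtinger relation at every crossing reduces to
#' 2 a(over) - a(under in) - a(under out) = 0 independent of crossing sign,
#' so the determinant is the absolute determinant of any (n-1) x (n-1) minor
#' of that coloring matrix over the n arcs.
#'
#' @param polyline numeric matrix of 3D points, implicitly closed.
#' @param max_attempts number of random re-projections tried when the
#'   projection is degenerate.
#' @param seed seed for the re-projection rotations.
#' @return non-negative integer determinant.
#' @export
knot_determinant <- function(polyline, max_attempts = 20L, seed = 1L) {
  pts <- as.matrix(polyline)
  stopifnot(ncol(pts) == 3L, nrow(pts) >= 3L)
  for (attempt in seq_len(max_attempts)) {
    rot <- if (attempt == 1L) diag(3L) else
      with_seed(seed + attempt, random_rotation())
    pr <- pts %*% t(rot)
    cr <- polyline_crossings(pr[, 1:2, drop = FALSE], pr[, 3L])
    if (is.null(cr)) next
    return(determinant_from_crossings(cr))
  }
  stop("no generic projection found after max perturbation attempts")
}

random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / vnorm(q)
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

determinant_from_crossings <- function(cr) {
  ncr <- nrow(cr)
  if (ncr == 0L) return(1L)
  # two passes per crossing, ordered along the curve
  ev <- data.frame(pos = c(cr$s1, cr$s2),
                   crossing = rep(seq_len(ncr), 2L),
                   under = c(!cr$over1, cr$over1))
  ev <- ev[order(ev$pos), ]
  upos <- ev$pos[ev$under]          # one underpass per crossing
  stopifnot(length(upos) == ncr)
  upos <- sort(upos)
  # arc k runs from underpass k to underpass k+1 (cyclically)
  arc_of <- function(pos) {
    k <- findInterval(pos, upos)
    ifelse(k == 0L, ncr, k)
  }
  M <- matrix(0, ncr, ncr)
  for (c_id in seq_len(ncr)) {
    sel <- ev$crossing == c_id
    pu <- ev$pos[sel & ev$under]
    po <- ev$pos[sel & !ev$under]
    over_arc <- arc_of(po)
    k <- match(TRUE, abs(upos - pu) < 1e-12)
    in_arc <- if (k == 1L) ncr else k - 1L
    out_arc <- k
    M[c_id, over_arc] <- M[c_id, over_arc] + 2
    M[c_id, in_arc] <- M[c_id, in_arc] - 1
    M[c_id, out_arc] <- M[c_id, out_arc] - 1
  }
  if (ncr == 1L) return(1L)
  dt <- det(M[-ncr, -ncr, drop = FALSE])
  res <- round(abs(dt))
  if (abs(abs(dt) - res) > 0.01)
    warning("knot determinant numerically marginal: ", dt)
  as.integer(res)
}
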