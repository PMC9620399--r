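#' A-form helix and kissing-loop geometry parameters
#'
#' Standard A-RNA values: 0.281 nm rise per base pair, 32.7 degrees twist
#' per base pair (~11 bp/turn) and a 1.15 nm backbone radius. The kissing
#' loop is modelled on the 180-degree HIV-DIS motif: a 6-bp loop-loop duplex
#' flanked by 3 unpaired bases on each side.
#'
#' @param rise_per_bp helical rise, nm/bp.
#' @param twist_per_bp helical twist, degrees/bp, in (0, 360).
#' @param helix_radius backbone radius, nm.
#' @param kl_pair_len kissing-loop pairing region length, bases (>= 4).
#' @param kl_flank_unpaired unpaired bases flanking the pairing region on
#'   each side of each loop.
#' @param max_linkers_per_transition cap on unpaired linker nucleotides
#'   inserted at a single cross-vertex strand transition.
#' @param backbone_offset_deg angular offset between the two backbones of a
#'   duplex within one base-pair plane, degrees.
#' @param linker_rise effective backbone span of one unpaired linker
#'   nucleotide, nm.
#' @param phase_weight weight w of the angular-mismatch term in the
#'   phase/linker cost (nm per half-turn-normalized degree mismatch).
#' @return object of class `helix_params`.
#' @export
helix_params <- function(rise_per_bp = 0.281, twist_per_bp = 32.7,
                         helix_radius = 1.15, kl_pair_len = 6L,
                         kl_flank_unpaired = 3L,
                         max_linkers_per_transition = 6L,
                         backbone_offset_deg = 150,
                         linker_rise = 0.7, phase_weight = 0.25) {
  p <- list(rise_per_bp = rise_per_bp, twist_per_bp = twist_per_bp,
            helix_radius = helix_radius, kl_pair_len = as.integer(kl_pair_len),
            kl_flank_unpaired = as.integer(kl_flank_unpaired),
            max_linkers_per_transition = as.integer(max_linkers_per_transition),
            backbone_offset_deg = backbone_offset_deg,
            linker_rise = linker_rise, phase_weight = phase_weight)
  if (any(vapply(p, function(x) !is.numeric(x) || x <= 0, TRUE)))
    stop("all helix parameters must be strictly positive")
  if (p$kl_pair_len < 4L) stop("kl_pair_len must be >= 4")
  if (p$twist_per_bp >= 360) stop("twist_per_bp must be in (0, 360)")
  structure(p, class = "helix_params")
}

#' Base pairs needed to span an edge
#'
#' Rounds `edge_length / rise_per_bp` to the nearest integer, floored at the
#' structural minimum `kl_pair_len + 2` (every edge must be able to carry a
#' kissing-loop connector with at least 1 bp of stem on each side).
#'
#' @param edge_length edge length, nm (> 0).
#' @param params [helix_params()].
#' @return integer base-pair count.
#' @export
bp_count_for_edge <- function(edge_length, params = helix_params()) {
  if (any(edge_length <= 0)) stop("edge_length must be > 0")
  n <- as.integer(round(edge_length / params$rise_per_bp))
  minbp <- params$kl_pair_len + 2L
  if (any(n < minbp)) {
    warning("edge too short; base-pair count clamped to the structural minimum")
    n <- pmax(n, minbp)
  }
  n
}

#' Split a kissing-loop edge into stems and pairing region
#'
#' The loop-loop duplex of `kl_pair_len` bp sits mid-edge, coaxially joining
#' the two hairpin stems into one effective helix. The split is balanced;
#' when the remainder is odd the stem attached at the lower-index vertex
#' (`stem_a`, returned first) gets the shorter half.
#'
#' @param edge_bp total base pairs along the edge.
#' @param params [helix_params()].
#' @return integer vector `c(stem_a, stem_b)` with
#'   `stem_a + kl_pair_len + stem_b == edge_bp`.
#' @export
split_kl_edge <- function(edge_bp, params = helix_params()) {
  edge_bp <- as.integer(edge_bp)
  if (edge_bp < params$kl_pair_len + 2L)
    stop("edge too short for a kissing-loop connector")
  rest <- edge_bp - params$kl_pair_len
  a <- rest %/% 2L
  c(stem_a = a, stem_b = rest - a)
}

# ---- internal embedding machinery -----------------------------------------

# A segment frame maps duplex slot indices to 3D axis points and holds the
# transverse basis used to wind the backbones. Axial index = smap[1] +
# smap[2] * slot (the affine map lets a hairpin frame at the far vertex
# count slots inward from its own end).
make_frame <- function(origin, direction, h, smap = c(0, 1)) {
  u <- unitv(direction)
  n0 <- perp_unit(u)
  list(O = origin, u = u, n0 = n0, m0 = cross3(u, n0), h = h, smap = smap)
}

# Backbone position(s) for duplex slots on a frame. sense +1 is the strand
# running in slot-increasing direction, -1 its antiparallel partner.
frame_positions <- function(frame, slots, sense, phase, params) {
  i <- frame$smap[1L] + frame$smap[2L] * slots
  th <- deg2rad(phase + slots * params$twist_per_bp +
                ifelse(sense < 0, params$backbone_offset_deg, 0))
  ax <- outer(i + 0.5, frame$u * frame$h)
  ax <- sweep(ax, 2L, frame$O, "+")
  R <- params$helix_radius
  ax + R * (outer(cos(th), frame$n0) + outer(sin(th), frame$m0))
}

# Analytic strand tangent at a slot (direction of increasing slot index),
# before accounting for travel direction.
frame_tangent <- function(frame, slot, sense, phase, params) {
  th <- deg2rad(phase + slot * params$twist_per_bp +
                if (sense < 0) params$backbone_offset_deg else 0)
  tau <- deg2rad(params$twist_per_bp)
  di <- frame$smap[2L]
  unitv(frame$u * frame$h * di +
        params$helix_radius * tau * (-sin(th) * frame$n0 + cos(th) * frame$m0))
}

# Unfold the spanning tree into an extended conformation (used for the
# open-kissing-loop variant): children fan out around the incoming direction.
unfold_tree <- function(mesh, plan, cone_deg = 35) {
  nv <- n_vertices(mesh)
  pos <- matrix(NA_real_, nv, 3L)
  dir_in <- matrix(NA_real_, nv, 3L)
  pos[1L, ] <- c(0, 0, 0)
  dir_in[1L, ] <- c(0, 0, 1)
  lens <- edge_lengths(mesh)
  # adjacency over tree edges + kl half-edges needing outward directions
  kl_dir <- list()
  queue <- 1L
  visited <- rep(FALSE, nv)
  visited[1L] <- TRUE
  alpha <- deg2rad(cone_deg)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    inc_tree <- plan$tree_edges[apply(
      mesh$edges[plan$tree_edges, , drop = FALSE] == v, 1L, any)]
    kids <- inc_tree[vapply(inc_tree, function(e)
      !visited[other_vertex(mesh, e, v)], TRUE)]
    inc_kl <- plan$kl_edges[apply(
      mesh$edges[plan$kl_edges, , drop = FALSE] == v, 1L, any)]
    items <- c(kids, inc_kl)
    m <- length(items)
    if (m) {
      d0 <- unitv(dir_in[v, ])
      p1 <- perp_unit(d0); p2 <- cross3(d0, p1)
      for (k in seq_len(m)) {
        beta <- 2 * pi * (k - 1L) / max(m, 1L) + 0.5
        dk <- cos(alpha) * d0 + sin(alpha) * (cos(beta) * p1 + sin(beta) * p2)
        e <- items[[k]]
        if (k <= length(kids)) {
          w <- other_vertex(mesh, e, v)
          pos[w, ] <- pos[v, ] + lens[e] * dk
          dir_in[w, ] <- dk
          visited[w] <- TRUE
          queue <- c(queue, w)
        } else {
          kl_dir[[paste(e, v)]] <- dk
        }
      }
    }
  }
  list(pos = pos, kl_dir = kl_dir)
}

# Build per-edge (and per-hairpin, when open) segment frames.
build_frames <- function(mesh, plan, params, open_kls) {
  lens <- edge_lengths(mesh)
  bp <- bp_count_for_edge(lens, params)
  verts <- mesh$vertices
  unf <- NULL
  if (open_kls) {
    unf <- unfold_tree(mesh, plan)
    verts <- unf$pos
  }
  frames <- list()
  splits <- list()
  for (e in seq_len(n_edges(mesh))) {
    a <- mesh$edges[e, 1L]; b <- mesh$edges[e, 2L]
    h <- lens[e] / bp[e]
    if (e %in% plan$kl_edges) {
      splits[[e]] <- split_kl_edge(bp[e], params)
      if (open_kls) {
        da <- unf$kl_dir[[paste(e, a)]]
        db <- unf$kl_dir[[paste(e, b)]]
        frames[[paste0(e, ":a")]] <- make_frame(verts[a, ], da, h)
        frames[[paste0(e, ":b")]] <- make_frame(verts[b, ], db, h,
                                                smap = c(bp[e] - 1, -1))
        next
      }
    }
    fr <- make_frame(verts[a, ], verts[b, ] - verts[a, ], h)
    frames[[paste0(e, ":a")]] <- fr
    frames[[paste0(e, ":b")]] <- fr
  }
  list(frames = frames, bp = bp, splits = splits, verts = verts)
}

# Per-event slot/sense layout (cyclic order, before nick rotation).
# Returns a list of data.frames with columns kind, edge, slot, sense, hp.
event_layout <- function(mesh, plan, geo, params) {
  fl <- params$kl_flank_unpaired
  kl <- params$kl_pair_len
  lapply(seq_len(nrow(plan$traversal)), function(i) {
    ev <- plan$traversal[i, ]
    e <- ev$edge
    nb <- geo$bp[e]
    if (ev$type == "tree") {
      fwd <- ev$from < ev$to
      slots <- if (fwd) 0:(nb - 1L) else (nb - 1L):0
      data.frame(kind = "stem", edge = e, slot = slots,
                 sense = if (fwd) 1L else -1L, hp = "a")
    } else {
      sa <- geo$splits[[e]][[1L]]
      at_a <- ev$from == mesh$edges[e, 1L]
      if (at_a) {
        sl_out <- seq_len(sa) - 1L
        sl_kl <- sa:(sa + kl - 1L)
        sn <- 1L; hp <- "a"
      } else {
        sl_out <- (nb - 1L):(sa + kl)
        sl_kl <- (sa + kl - 1L):sa
        sn <- -1L; hp <- "b"
      }
      rbind(
        data.frame(kind = "kl_stem", edge = e, slot = sl_out, sense = sn,
                   hp = hp),
        data.frame(kind = "kl_flank", edge = e, slot = NA_integer_,
                   sense = sn, hp = hp)[rep(1L, fl), ],
        data.frame(kind = "kl", edge = e, slot = sl_kl, sense = sn, hp = hp),
        data.frame(kind = "kl_flank", edge = e, slot = NA_integer_,
                   sense = sn, hp = hp)[rep(1L, fl), ],
        data.frame(kind = "kl_stem", edge = e, slot = rev(sl_out),
                   sense = -sn, hp = hp))
    }
  })
}

event_frame <- function(geo, ev) geo$frames[[paste0(ev$edge, ":", ev$hp)]]

# Compact descriptor of an event's two strand ends (precomputed once so the
# phase optimizer's inner loop avoids data-frame access).
event_desc <- function(layout_i, geo) {
  first <- layout_i[1L, ]
  last <- layout_i[nrow(layout_i), ]
  sl <- layout_i$slot[!is.na(layout_i$slot)]
  list(edge = as.integer(first$edge),
       fr1 = geo$frames[[paste0(first$edge, ":", first$hp)]],
       fr2 = geo$frames[[paste0(last$edge, ":", last$hp)]],
       s1 = first$slot, sn1 = first$sense,
       s2 = last$slot, sn2 = last$sense,
       d1 = if (length(sl) > 1L) sign(sl[2L] - sl[1L]) else 1,
       d2 = if (length(sl) > 1L)
         sign(sl[length(sl)] - sl[length(sl) - 1L]) else 1)
}

# First/last backbone points and travel tangents of an event, given a phase.
event_boundary <- function(de, phi, params) {
  end_at <- function(fr, slot, sense, dtrav) {
    i <- fr$smap[1L] + fr$smap[2L] * slot
    th <- deg2rad(phi + slot * params$twist_per_bp +
                  if (sense < 0) params$backbone_offset_deg else 0)
    P <- fr$O + (i + 0.5) * fr$h * fr$u +
      params$helix_radius * (cos(th) * fr$n0 + sin(th) * fr$m0)
    tau <- deg2rad(params$twist_per_bp)
    Tv <- fr$u * fr$h * fr$smap[2L] +
      params$helix_radius * tau * (-sin(th) * fr$n0 + cos(th) * fr$m0)
    list(P = P, T = Tv / vnorm(Tv) * dtrav)
  }
  a <- end_at(de$fr1, de$s1, de$sn1, de$d1)
  b <- end_at(de$fr2, de$s2, de$sn2, de$d2)
  list(P_first = a$P, T_first = a$T, P_last = b$P, T_last = b$T)
}

transition_cost <- function(gap, angmis, params) {
  lk <- round((gap - params$rise_per_bp) / params$linker_rise)
  lk <- max(0L, min(params$max_linkers_per_transition, as.integer(lk)))
  span <- params$rise_per_bp + lk * params$linker_rise
  list(cost = abs(gap - span) + params$phase_weight * angmis / 180,
       linkers = lk)
}

#' Embed a routing as A-form helices with optimized phases and linkers
#'
#' Converts a routing plan into a nucleotide-level model: every edge becomes
#' an A-form duplex along its axis (kissing-loop edges as two hairpin
#' half-helices joined by the mid-edge loop-loop duplex), and the strand
#' transitions between helices at the vertices. Per-edge rotation phases
#' (continuous) and per-transition unpaired linker counts (integer, 0 to
#' `max_linkers_per_transition`) are chosen by coordinate descent to
#' minimize the total strain cost
#' `J = sum over transitions [ |gap - spanned| + w * angular mismatch / 180 ]`,
#' where `gap` is the backbone exit-to-entry distance and the angular
#' mismatch is between exit and entry strand tangents. The cost never
#' increases across iterations.
#'
#' @param mesh the routed [wire_mesh()].
#' @param plan a [route_strand()] result.
#' @param params [helix_params()].
#' @param seed integer; reserved for reproducibility of any stochastic
#'   restarts (the default optimizer is deterministic).
#' @param open_kls if `TRUE`, embed the open-kissing-loop control variant:
#'   the spanning tree is unfolded into an extended conformation and the
#'   hairpins point outward, so the loop-loop duplexes are not in contact.
#'   Mirrors the non-folding control structures.
#' @param max_sweeps maximum coordinate-descent sweeps.
#' @return object of class `embedded_design`: `nucleotides` (data frame with
#'   kind/edge/slot/sense and x/y/z in strand 5'->3' order), `phases`,
#'   `transitions` (linker counts and residual gaps), `J` (final cost),
#'   `J_trace` (per-sweep costs), `bp`, `splits`, `params`, `plan`.
#' @export
embed_helices <- function(mesh, plan, params = helix_params(), seed = 1L,
                          open_kls = FALSE, max_sweeps = 50L) {
  geo <- build_frames(mesh, plan, params, open_kls)
  layout <- event_layout(mesh, plan, geo, params)
  ne_ev <- length(layout)
  nphase <- n_edges(mesh)
  phases <- rep(0, nphase)

  descs <- lapply(layout, event_desc, geo = geo)
  bounds <- lapply(seq_len(ne_ev), function(k)
    event_boundary(descs[[k]], phases[descs[[k]]$edge], params))
  eval_transition <- function(k, bnds) {
    k2 <- if (k == ne_ev) 1L else k + 1L
    g <- vnorm(bnds[[k2]]$P_first - bnds[[k]]$P_last)
    am <- angle_deg(bnds[[k]]$T_last, bnds[[k2]]$T_first)
    transition_cost(g, am, params)
  }
  total_J <- function(bnds)
    sum(vapply(seq_len(ne_ev), function(k) eval_transition(k, bnds)$cost, 0))

  # transitions touched by each edge's phase
  ev_edge <- vapply(descs, function(d) d$edge, 0L)
  touch <- lapply(seq_len(nphase), function(e) {
    ks <- which(ev_edge == e)
    sort(unique(c(ks, ifelse(ks == 1L, ne_ev, ks - 1L))))
  })

  J <- total_J(bounds)
  J_trace <- J
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (e in seq_len(nphase)) {
      ks <- touch[[e]]
      if (!length(ks)) next
      e_evs <- which(ev_edge == e)
      local_J <- function(phi) {
        bl <- bounds
        for (k in e_evs)
          bl[[k]] <- event_boundary(descs[[k]], phi, params)
        sum(vapply(ks, function(k) eval_transition(k, bl)$cost, 0))
      }
      cur <- local_J(phases[e])
      grid <- seq(0, 355, by = 5)
      gv <- vapply(grid, local_J, 0)
      best <- which.min(gv)
      opt <- stats::optimize(local_J, lower = grid[best] - 5,
                             upper = grid[best] + 5)
      if (min(opt$objective, gv[best]) < cur - 1e-10) {
        phases[e] <- if (opt$objective < gv[best]) opt$minimum else grid[best]
        for (k in e_evs)
          bounds[[k]] <- event_boundary(descs[[k]], phases[e], params)
        improved <- TRUE
      }
    }
    Jnew <- total_J(bounds)
    stopifnot(Jnew <= J + 1e-9)
    J <- Jnew
    J_trace <- c(J_trace, J)
    if (!improved || (length(J_trace) > 1L &&
                      J_trace[[length(J_trace) - 1L]] - J < 1e-8)) break
  }
  if (improved && sweep == max_sweeps)
    warning("phase optimizer stopped at max_sweeps; returning best found")

  trans <- do.call(rbind, lapply(seq_len(ne_ev), function(k) {
    k2 <- if (k == ne_ev) 1L else k + 1L
    g <- vnorm(bounds[[k2]]$P_first - bounds[[k]]$P_last)
    am <- angle_deg(bounds[[k]]$T_last, bounds[[k2]]$T_first)
    tc <- transition_cost(g, am, params)
    data.frame(after_event = k, linkers = tc$linkers, gap = g,
               ang_mismatch = am, cost = tc$cost)
  }))

  # full cyclic nucleotide table with coordinates
  nuc <- list()
  for (k in seq_len(ne_ev)) {
    li <- layout[[k]]
    li$event <- k
    paired <- !is.na(li$slot)
    co <- matrix(NA_real_, nrow(li), 3L)
    if (any(paired)) {
      fr <- geo$frames[[paste0(li$edge[[1L]], ":", li$hp[[1L]])]]
      co[paired, ] <- frame_positions(fr, li$slot[paired], li$sense[paired],
                                      phases[li$edge[[1L]]], params)
    }
    # interpolate unpaired flank runs between their paired neighbours
    runs <- rle(paired)
    idx <- cumsum(c(1L, runs$lengths))
    for (r in which(!runs$values)) {
      a <- idx[r] - 1L; b <- idx[r + 1L]
      n <- runs$lengths[r]
      pa <- co[max(a, 1L), ]
      pb <- co[min(b, nrow(li)), ]
      for (q in seq_len(n))
        co[a + q, ] <- pa + (q / (n + 1)) * (pb - pa)
    }
    li$x <- co[, 1L]; li$y <- co[, 2L]; li$z <- co[, 3L]
    nuc[[length(nuc) + 1L]] <- li
    lk <- trans$linkers[[k]]
    if (lk > 0L) {
      k2 <- if (k == ne_ev) 1L else k + 1L
      pa <- bounds[[k]]$P_last
      pb <- bounds[[k2]]$P_first
      q <- seq_len(lk) / (lk + 1)
      nuc[[length(nuc) + 1L]] <- data.frame(
        kind = "linker", edge = NA_integer_, slot = NA_integer_,
        sense = 0L, hp = NA_character_, event = k,
        x = pa[1L] + q * (pb[1L] - pa[1L]),
        y = pa[2L] + q * (pb[2L] - pa[2L]),
        z = pa[3L] + q * (pb[3L] - pa[3L]))
    }
  }
  nuc <- do.call(rbind, nuc)
  rownames(nuc) <- NULL

  # nick: rotate the cyclic strand so the 5' end sits mid-way along the
  # first-traversed tree edge
  e1_rows <- which(nuc$event == 1L & nuc$kind == "stem")
  m <- floor(length(e1_rows) / 2)
  startrow <- e1_rows[[1L]] + m
  ordr <- c(startrow:nrow(nuc), seq_len(startrow - 1L))
  nuc <- nuc[ordr, ]
  nuc$pos <- seq_len(nrow(nuc))
  rownames(nuc) <- NULL

  structure(list(nucleotides = nuc, phases = phases, transitions = trans,
                 J = J, J_trace = J_trace, bp = geo$bp, splits = geo$splits,
                 params = params, open_kls = open_kls,
                 mesh_name = mesh$name),
            class = "embedded_design")
}

#' @export
print.embedded_design <- function(x, ...) {
  cat(sprintf(paste0("embedded_design for '%s': %d nt, %d helices, ",
                     "J = %.3f%s\n"), x$mesh_name, nrow(x$nucleotides),
              length(x$bp), x$J,
              if (x$open_kls) " (open kissing loops)" else ""))
  invisible(x)
}

#' Per-nucleotide coordinates of an embedded design
#' @param embedded an [embed_helices()] result.
#' @return numeric matrix (nm), one row per nucleotide in 5'->3' order.
#' @export
nucleotide_coordinates <- function(embedded) {
  as.matrix(embedded$nucleotides[, c("x", "y", "z")])
}

#' Radius of gyration of a point cloud
#'
#' Root mean squared distance to the centroid, a compactness diagnostic for
#' design models.
#'
#' @param coords numeric matrix, one 3D point per row (nm).
#' @return radius of gyration, nm.
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("empty coordinate set")
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2L, ctr)^2)))
}
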