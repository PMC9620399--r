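tetra_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- builtin_mesh("tetrahedron")
      plan <- route_strand(m, spanning_tree(m))
      cache <<- list(mesh = m, plan = plan,
                     emb = embed_helices(m, plan))
    }
    cache
  }
})

test_that("helix_params validates its invariants", {
  p <- helix_params()
  expect_equal(p$rise_per_bp, 0.281)
  expect_equal(p$twist_per_bp, 32.7)
  expect_error(helix_params(rise_per_bp = -1), "positive")
  expect_error(helix_params(kl_pair_len = 3), "kl_pair_len")
  expect_error(helix_params(twist_per_bp = 400), "twist")
})

test_that("bp_count_for_edge rounds, clamps and bounds the residual", {
  p <- helix_params()
  expect_equal(bp_count_for_edge(2.81, p), 10L)
  expect_warning(n <- bp_count_for_edge(0.1, p), "clamped")
  expect_equal(n, p$kl_pair_len + 2L)
  lens <- rnaweave:::with_seed(5L, stats::runif(50, 3, 30))
  bp <- bp_count_for_edge(lens, p)
  expect_true(all(abs(bp * p$rise_per_bp - lens) <= p$rise_per_bp / 2 + 1e-12))
})

test_that("split_kl_edge balances stems around the mid-edge duplex", {
  p <- helix_params()
  expect_equal(unname(split_kl_edge(20L, p)), c(7L, 7L))
  expect_equal(unname(split_kl_edge(21L, p)), c(7L, 8L))
  expect_equal(sum(split_kl_edge(35L, p)) + p$kl_pair_len, 35L)
  expect_error(split_kl_edge(7L, p), "too short")
})

test_that("nucleotide geometry follows the A-form closed forms", {
  p <- helix_params()
  fr <- rnaweave:::make_frame(c(0, 0, 0), c(0, 0, 1), p$rise_per_bp)
  # paired backbones in one rung: distance 2 R sin(offset/2)
  a <- rnaweave:::frame_positions(fr, 0L, 1L, 0, p)
  b <- rnaweave:::frame_positions(fr, 0L, -1L, 0, p)
  expect_equal(sqrt(sum((a - b)^2)),
               2 * p$helix_radius * sin(rnaweave:::deg2rad(
                 p$backbone_offset_deg) / 2), tolerance = 1e-12)
  # 11 steps at 32.7 deg/bp accumulate ~359.7 deg: one full turn
  pts <- rnaweave:::frame_positions(fr, 0:11, 1L, 0, p)
  ang <- atan2(pts[, 2L], pts[, 1L]) * 180 / pi
  expect_equal((ang[12L] - ang[1L]) %% 360, (11 * 32.7) %% 360,
               tolerance = 1e-9)
  # consecutive intra-strand distance = sqrt(rise^2 + (2R sin(twist/2))^2)
  d <- sqrt(rowSums(diff(pts)^2))
  chord <- sqrt(p$rise_per_bp^2 +
                (2 * p$helix_radius * sin(rnaweave:::deg2rad(
                  p$twist_per_bp) / 2))^2)
  expect_equal(d, rep(chord, 11L), tolerance = 1e-9)
})

test_that("embedding satisfies the nucleotide-count identity", {
  td <- tetra_design()
  emb <- td$emb
  p <- emb$params
  tree_bp <- sum(emb$bp[td$plan$tree_edges])
  kl_terms <- sum(vapply(td$plan$kl_edges, function(e)
    2L * sum(emb$splits[[e]]) +
    2L * (p$kl_pair_len + 2L * p$kl_flank_unpaired), 0L))
  total <- 2L * tree_bp + kl_terms + sum(emb$transitions$linkers)
  expect_equal(nrow(emb$nucleotides), total)
  expect_equal(nrow(nucleotide_coordinates(emb)), total)
  expect_true(all(is.finite(nucleotide_coordinates(emb))))
})

test_that("paired bases sit at the duplex backbone separation", {
  td <- tetra_design()
  strand <- build_strand_model(td$plan, td$emb)
  co <- nucleotide_coordinates(td$emb)
  p <- td$emb$params
  i <- which(!is.na(strand$pairing) & strand$pairing > seq_len(strand$length))
  d <- sqrt(rowSums((co[i, , drop = FALSE] -
                     co[strand$pairing[i], , drop = FALSE])^2))
  sep <- 2 * p$helix_radius * sin(rnaweave:::deg2rad(
    p$backbone_offset_deg) / 2)
  expect_true(all(abs(d - sep) < 1e-6))
  expect_lt(mean(d), 2 * p$helix_radius + 0.1)
  expect_gt(mean(d), 2 * p$helix_radius - 0.2)
})

test_that("optimizer cost never increases and beats a forced-bad start", {
  td <- tetra_design()
  expect_true(all(diff(td$emb$J_trace) <= 1e-9))
  expect_lte(td$emb$J, td$emb$J_trace[[1L]])
})

test_that("phase/linker optimum matches exhaustive search on small instances", {
  p <- helix_params(max_linkers_per_transition = 3L)
  # two-edge path: joint exhaustive search over a coarse phase grid with
  # per-transition linker enumeration
  m <- wire_mesh(cbind(c(0, 5, 10), 0, 0), rbind(c(1L, 2L), c(2L, 3L)),
                 name = "path2")
  plan <- route_strand(m, spanning_tree(m))
  emb <- embed_helices(m, plan, p)
  geo <- rnaweave:::build_frames(m, plan, p, FALSE)
  layout <- rnaweave:::event_layout(m, plan, geo, p)
  descs <- lapply(layout, rnaweave:::event_desc, geo = geo)
  ne <- length(descs)
  cost_at <- function(phases) {
    bl <- lapply(seq_len(ne), function(k)
      rnaweave:::event_boundary(descs[[k]], phases[descs[[k]]$edge], p))
    sum(vapply(seq_len(ne), function(k) {
      k2 <- if (k == ne) 1L else k + 1L
      g <- sqrt(sum((bl[[k2]]$P_first - bl[[k]]$P_last)^2))
      am <- rnaweave:::angle_deg(bl[[k]]$T_last, bl[[k2]]$T_first)
      best <- Inf  # exhaustive over linker counts 0..3
      for (lk in 0:3) best <- min(best, abs(g - (p$rise_per_bp +
                                                 lk * p$linker_rise)) +
                                          p$phase_weight * am / 180)
      best
    }, 0))
  }
  grid <- seq(0, 350, by = 10)
  Jbest <- Inf
  for (a in grid) for (b in grid) Jbest <- min(Jbest, cost_at(c(a, b)))
  expect_lte(emb$J, Jbest + 1e-6)

  # tetrahedron: at the optimizer's phases the cost separates over
  # transitions, so per-transition linker enumeration is the exact optimum
  td <- tetra_design()
  tr <- td$emb$transitions
  pp <- td$emb$params
  for (k in seq_len(nrow(tr))) {
    enum <- vapply(0:pp$max_linkers_per_transition, function(lk)
      abs(tr$gap[k] - (pp$rise_per_bp + lk * pp$linker_rise)) +
        pp$phase_weight * tr$ang_mismatch[k] / 180, 0)
    expect_lte(tr$cost[k], min(enum) + 1e-9)
  }
})

test_that("radius of gyration matches the direct-formula oracle", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1L)), 0)
  two <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(radius_of_gyration(two), 3)
  cloud <- rnaweave:::with_seed(11L, matrix(stats::rnorm(300), 100L))
  expect_equal(radius_of_gyration(cloud), oracle_rg(cloud), tolerance = 1e-9)
})

test_that("closed kissing loops give a more compact model than open ones", {
  td <- tetra_design()
  open <- embed_helices(td$mesh, td$plan, open_kls = TRUE)
  expect_lt(radius_of_gyration(nucleotide_coordinates(td$emb)),
            radius_of_gyration(nucleotide_coordinates(open)))
})
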