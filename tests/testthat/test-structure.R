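fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- builtin_mesh("tetrahedron")
      plan <- route_strand(m, spanning_tree(m))
      emb <- embed_helices(m, plan)
      cache <<- list(mesh = m, plan = plan, emb = emb,
                     strand = build_strand_model(plan, emb))
    }
    cache
  }
})

test_that("strand model pairing is a fixed-point-free involution", {
  for (nm in c("tetrahedron", "bipyramid", "grid")) {
    m <- builtin_mesh(nm)
    plan <- route_strand(m, spanning_tree(m))
    strand <- build_strand_model(plan, embed_helices(m, plan))
    p <- strand$pairing
    i <- which(!is.na(p))
    # brute-force check: map o map = identity, no fixed points
    expect_true(all(p[p[i]] == i), info = nm)
    expect_true(all(p[i] != i), info = nm)
    expect_equal(n_kl_pairs(strand),
                 nrow(m$edges) - nrow(m$vertices) + 1L, info = nm)
  }
})

test_that("single-edge mesh reduces to one antiparallel stem block", {
  m <- wire_mesh(rbind(c(0, 0, 0), c(10, 0, 0)), cbind(1L, 2L), name = "e1")
  plan <- route_strand(m, 1L)
  strand <- build_strand_model(plan, embed_helices(m, plan))
  kinds <- unique(strand$domains$kind)
  expect_setequal(kinds, c("stem5", "stem3", "linker"))
  # nested stems only (the nick may split the 5\' pass in two domains)
  db <- to_dotbracket(strand)
  expect_true(all(strsplit(db, "")[[1L]] %in% c("(", ")", ".")))
  expect_identical(parse_dotbracket(db), strand$pairing)
})

test_that("tetrahedron has exactly 3 kl_loop partner pairs", {
  strand <- fixture()$strand
  kl <- strand$domains[strand$domains$kind == "kl_loop", ]
  expect_equal(nrow(kl), 6L)
  expect_equal(n_kl_pairs(strand), 3L)
  # partnered across the same source edge
  expect_true(all(kl$edge[match(kl$partner, kl$id)] == kl$edge))
})

test_that("to_dotbracket writes layered brackets and round-trips", {
  strand <- fixture()$strand
  db <- to_dotbracket(strand)
  expect_equal(nchar(db), strand$length)
  # round-trip through the package parser and an independent oracle parser
  expect_identical(parse_dotbracket(db), strand$pairing)
  expect_identical(oracle_parse_db(db), strand$pairing)
  # kissing-loop pairs never use the stem layer
  klpos <- which(strand$nucleotides$dkind == "kl_loop" &
                 !is.na(strand$pairing))
  expect_true(all(!substr(db, klpos, klpos) %in% c("(", ")")))
  expect_equal(sum(strsplit(db, "")[[1L]] == "."),
               sum(is.na(strand$pairing)))
})

test_that("simple hairpins produce the expected strings", {
  hp <- function() {
    # tiny synthetic strand model: one 4-bp hairpin with 4-nt loop
    p <- rep(NA_integer_, 12L)
    p[1:4] <- 12:9; p[9:12] <- 4:1
    doms <- data.frame(id = 1:3, kind = c("stem5", "linker", "stem3"),
                       start = c(1L, 5L, 9L), length = c(4L, 4L, 4L),
                       edge = c(1L, NA, 1L), partner = c(3L, NA, 1L))
    structure(list(domains = doms, pairing = p, length = 12L,
                   nucleotides = data.frame(pos = 1:12,
                                            dkind = rep(c("stem5", "linker",
                                                          "stem3"),
                                                        each = 4L))),
              class = "strand_model")
  }
  expect_equal(to_dotbracket(hp()), "((((....))))")

  # two hairpins whose 6-nt loops kiss: loop pairing in layer "[]"
  n <- 28L
  p <- rep(NA_integer_, n)
  p[1:4] <- 14:11; p[11:14] <- 4:1
  p[15:18] <- 28:25; p[25:28] <- 18:15
  p[5:10] <- 24:19; p[19:24] <- 10:5
  dk <- rep("linker", n)
  dk[c(1:4, 11:14, 15:18, 25:28)] <- rep(c("stem5", "stem3",
                                           "stem5", "stem3"), each = 4L)
  dk[c(5:10, 19:24)] <- "kl_loop"
  doms <- data.frame(id = 1:6,
                     kind = c("stem5", "kl_loop", "stem3",
                              "stem5", "kl_loop", "stem3"),
                     start = c(1L, 5L, 11L, 15L, 19L, 25L),
                     length = c(4L, 6L, 4L, 4L, 6L, 4L),
                     edge = c(1L, 9L, 1L, 2L, 9L, 2L),
                     partner = c(3L, 5L, 1L, 6L, 2L, 4L))
  sm <- structure(list(domains = doms, pairing = p, length = n,
                       nucleotides = data.frame(pos = 1:n, dkind = dk)),
                  class = "strand_model")
  db <- to_dotbracket(sm)
  expect_equal(db, "(((([[[[[[))))((((]]]]]]))))")
  expect_identical(parse_dotbracket(db), p)
})

test_that("parse_dotbracket rejects malformed structures", {
  expect_error(parse_dotbracket("(((."), "unbalanced")
  expect_error(parse_dotbracket(".))"), "unbalanced")
  expect_error(parse_dotbracket("..!.."), "unknown structure character")
})

test_that("snac documents round-trip exactly", {
  # minimal 1-nt document: bit-identical file round-trip
  d1 <- snac_document("mini", "G", ".", matrix(c(1.25, -2, 0.5), 1L))
  tmp <- withr::local_tempfile(fileext = ".snac")
  write_snac(d1, tmp)
  first <- readLines(tmp)
  write_snac(read_snac(tmp), tmp)
  expect_identical(readLines(tmp), first)

  fx <- fixture()
  db <- to_dotbracket(fx$strand)
  doc <- snac_document("tetrahedron", strrep("N", fx$strand$length), db,
                       nucleotide_coordinates(fx$emb))
  write_snac(doc, tmp)
  d2 <- read_snac(tmp)
  expect_identical(d2$sequence, doc$sequence)
  expect_identical(d2$structure, doc$structure)
  expect_equal(d2$coords, doc$coords, tolerance = 1e-6)
})

test_that("snac reader rejects tampered files with line numbers", {
  d <- snac_document("x", "GACU", "(..)", matrix(0, 4L, 3L))
  tmp <- withr::local_tempfile(fileext = ".snac")
  write_snac(d, tmp)
  lines <- readLines(tmp)
  bad <- lines; bad[4L] <- "GAC"  # |sequence| != declared length
  writeLines(bad, tmp)
  expect_error(read_snac(tmp), "line 4")
  bad <- lines; bad[7L] <- "0 zero 0"
  writeLines(bad, tmp)
  expect_error(read_snac(tmp), "line 7")
  expect_error(snac_document("x", "GACU", "(.))", matrix(0, 4L, 3L)),
               "unbalanced")
  expect_error(snac_document("x", "GACU", "(..)", matrix(0, 3L, 3L)),
               "length mismatch")
})

test_that("vienna export has header/sequence/structure lines", {
  d <- snac_document("v1", "GACU", "(..)", matrix(0, 4L, 3L))
  tmp <- withr::local_tempfile(fileext = ".dbn")
  write_vienna(d, tmp)
  expect_identical(readLines(tmp), c(">v1", "GACU", "(..)"))
})

test_that("strand_model_from_structure recovers pairing and kl pairs", {
  fx <- fixture()
  db <- to_dotbracket(fx$strand)
  sm <- strand_model_from_structure(db)
  expect_identical(sm$pairing, fx$strand$pairing)
  expect_equal(n_kl_pairs(sm), n_kl_pairs(fx$strand))
})
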