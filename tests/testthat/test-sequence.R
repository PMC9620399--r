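test_that("violates_constraints reports maximal forbidden windows", {
  cs <- seq_constraints()
  v <- violates_constraints("GAAAAC", cs)
  expect_equal(v$pattern, "AAAA")
  expect_equal(v$start, 2L)  # 1-based
  v <- violates_constraints("AUAUAU", cs)
  expect_equal(v$pattern, "WWWWWW")
  expect_equal(v$start, 1L)
  expect_equal(nrow(violates_constraints("GACUGACU", cs)), 0L)
  # maximal window: a 5-run reported once with its full length
  v <- violates_constraints("GGGGG", cs)
  expect_equal(v$pattern, "GGGG")
  expect_equal(v$start, 1L)
  expect_equal(v$length, 5L)
  # all ten patterns detectable
  for (s in c("AAAA", "CCCC", "GGGG", "UUUU"))
    expect_equal(violates_constraints(s, cs)$pattern, s)
  for (s in list(c("GUGUGU", "KKKKKK"), c("ACACAC", "MMMMMM"),
                 c("AGAGAG", "RRRRRR"), c("CGCGCG", "SSSSSS"),
                 c("AUAUAU", "WWWWWW"), c("CUCUCU", "YYYYYY")))
    expect_true(s[[2L]] %in% violates_constraints(s[[1L]], cs)$pattern)
  expect_error(violates_constraints("ACGT", cs), "alphabet")
  expect_equal(nrow(violates_constraints("ACGTTT", cs, alphabet = "DNA")), 0L)
})

test_that("kissing-loop ensembles are orthogonal and reproducible", {
  cs <- seq_constraints()
  e1 <- generate_kl_ensemble(1L, cs, seed = 3L)
  expect_equal(nrow(e1$pairs), 1L)
  # loop_b = revcomp(loop_a), via the Biostrings oracle
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(e1$pairs$loop_a)))
  expect_identical(e1$pairs$loop_b, rc)

  # prism requirement: 7 pairs; exhaustive all-pairs Hamming check
  e7 <- generate_kl_ensemble(7L, cs, seed = 5L)
  loops <- c(e7$pairs$loop_a, e7$pairs$loop_b)
  expect_length(loops, 14L)
  expect_true(all(nchar(loops) == 6L))
  for (i in seq_along(loops)) for (j in seq_along(loops)) if (i < j)
    expect_gte(hamming_str(loops[[i]], loops[[j]]), cs$min_hamming)
  for (l in loops)
    expect_equal(nrow(violates_constraints(l, cs)), 0L)

  expect_identical(generate_kl_ensemble(4L, cs, seed = 9L)$pairs,
                   generate_kl_ensemble(4L, cs, seed = 9L)$pairs)
  expect_error(generate_kl_ensemble(3L, seq_constraints(min_hamming = 6L),
                                    max_tries = 300L), "infeasible")
})

test_that("ensemble TSV round-trips and literature pairs are validated", {
  e <- generate_kl_ensemble(3L, seed = 2L)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_kl_ensemble(e, tmp)
  e2 <- read_kl_ensemble(tmp)
  expect_identical(e2$pairs$loop_a, e$pairs$loop_a)
  lit <- data.frame(loop_a = "GCAUCG", loop_b = "CGAUGC")
  e3 <- generate_kl_ensemble(3L, seed = 2L, literature = lit)
  expect_equal(e3$pairs$provenance[[1L]], "literature")
  expect_equal(e3$pairs$loop_a[[1L]], "GCAUCG")
  badlit <- data.frame(loop_a = "GCAUCG", loop_b = "AAAAAA")
  expect_error(generate_kl_ensemble(2L, literature = badlit), "revcomp")
})

strand_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- builtin_mesh("tetrahedron")
      plan <- route_strand(m, spanning_tree(m))
      cache <<- build_strand_model(plan, embed_helices(m, plan))
    }
    cache
  }
})

test_that("wobbles land at 8-bp intervals and break DNA self-complementarity", {
  strand <- strand_fixture()
  cs <- seq_constraints()
  # draft with plain complementary stems, no wobbles
  p <- strand$pairing
  ch <- rep("A", strand$length)
  for (i in which(!is.na(p) & p > seq_along(p))) {
    ch[i] <- "G"; ch[p[i]] <- "C"
  }
  draft <- paste(ch, collapse = "")
  wob <- apply_wobbles(strand, draft, cs)
  wch <- strsplit(wob, "")[[1L]]
  # within every 16+ bp stem the wobbled pairs sit at indices 8, 16, ...
  doms <- strand$domains
  for (d in which(doms$kind %in% c("stem5", "kl_stem5"))) {
    rows <- doms$start[d] - 1L + seq_len(doms$length[d])
    changed <- which(wch[rows] != ch[rows] | wch[p[rows]] != ch[p[rows]])
    expect_equal(changed, seq_len(doms$length[d] %/% 8L) * 8L,
                 info = paste("domain", d))
    for (k in changed) {
      expect_equal(wch[rows[k]], "G")
      expect_equal(wch[p[rows[k]]], "U")
    }
  }
  # a 7-bp stem gets none
  short <- strand_model_from_structure("(((((((....)))))))"[1])
  expect_identical(apply_wobbles(short, strrep("A", 18L), cs),
                   strrep("A", 18L))
  # stated purpose: the dsDNA template is no longer self-complementary
  d <- which(doms$kind == "stem5")[1L]
  rows <- doms$start[d] - 1L + seq_len(doms$length[d])
  s5 <- chartr("U", "T", paste(wch[rows], collapse = ""))
  s3 <- chartr("U", "T", paste(wch[rev(p[rows])], collapse = ""))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s3)))
  expect_false(identical(s5, rc))
})

test_that("design_sequence satisfies all contracts on the tetrahedron", {
  strand <- strand_fixture()
  cs <- seq_constraints()
  ens <- generate_kl_ensemble(5L, cs, seed = 4L)
  s <- design_sequence(strand, ens, cs, seed = 11L)
  sq <- strsplit(as.character(s), "")[[1L]]
  expect_length(sq, strand$length)
  expect_equal(sq[[1L]], "G")  # T7 requirement
  expect_equal(nrow(violates_constraints(as.character(s), cs)), 0L)
  # pairing consistency: WC or G-U everywhere (independent re-check)
  p <- strand$pairing
  for (i in which(!is.na(p)))
    expect_true(paste0(sq[i], sq[p[i]]) %in%
                c("AU", "UA", "GC", "CG", "GU", "UG"))
  # exactly 3 ensemble pairs consumed, loops match their assignment
  kl <- attr(s, "kl_pairs")
  expect_equal(nrow(kl), 3L)
  doms <- strand$domains
  for (k in seq_len(nrow(kl))) {
    dd <- which(doms$kind == "kl_loop" & doms$edge == kl$edge[k])
    d5 <- dd[which.min(doms$start[dd])]
    rows <- doms$start[d5] - 1L + seq_len(doms$length[d5])
    rows <- rows[!is.na(p[rows])]
    expect_equal(paste(sq[rows], collapse = ""), kl$loop_a[k])
  }
  # reproducibility
  expect_identical(as.character(design_sequence(strand, ens, cs, seed = 11L)),
                   as.character(s))
  expect_error(design_sequence(strand, generate_kl_ensemble(2L), cs),
               "ensemble too small")
})

test_that("a 4-bp stem hairpin designs to an exact reverse complement", {
  sm <- strand_model_from_structure("((((....))))")
  ens <- generate_kl_ensemble(1L)
  s <- strsplit(as.character(design_sequence(sm, ens, seed = 2L)), "")[[1L]]
  stem5 <- paste(s[1:4], collapse = "")
  stem3 <- paste(s[9:12], collapse = "")
  expect_identical(as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(stem5))), stem3)
})

test_that("external designer adapter is honoured", {
  sm <- strand_model_from_structure("((((....))))")
  ens <- generate_kl_ensemble(1L)
  fixed <- function(len, seed) strrep("G", len)  # deliberately dirty
  s <- design_sequence(sm, ens, designer = fixed, seed = 1L)
  # repair keeps contracts even for an adversarial adapter
  expect_equal(nrow(violates_constraints(as.character(s))), 0L)
})

test_that("DNA template carries cap+promoter, 15-nt tail and Tm-extended primer", {
  strand <- strand_fixture()
  s <- design_sequence(strand, generate_kl_ensemble(3L), seed = 1L)
  tpl <- build_dna_template(as.character(s), tail_seed = 7L)
  expect_true(startsWith(tpl$template, "GACTAATACGACTCACTATAG"))
  expect_identical(tpl$fwd_primer, "GACTAATACGACTCACTATAG")
  expect_equal(nchar(tpl$tail), 15L)
  expect_true(endsWith(tpl$template, tpl$tail))
  expect_equal(nrow(violates_constraints(tpl$tail, alphabet = "DNA")), 0L)
  # promoter G is the transcript's 5' G: no doubled base at the junction
  expect_equal(nchar(tpl$template),
               3L + 18L + nchar(s) - 1L + 15L)
  expect_gte(rnaweave:::wallace_tm(tpl$rev_primer), 58)
  expect_gte(nchar(tpl$rev_primer), 15L)
  # reverse primer is the revcomp of the template 3' end
  tail_end <- substr(tpl$template, nchar(tpl$template) -
                     nchar(tpl$rev_primer) + 1L, nchar(tpl$template))
  expect_identical(tpl$rev_primer, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tail_end))))
  expect_error(build_dna_template("AGGC"), "T7 requires 5' G")
})
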