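RNA_BASES <- c("A", "C", "G", "U")
WC_RNA <- c(A = "U", C = "G", G = "C", U = "A")

revcomp_rna <- function(x) {
  vapply(x, function(s) paste(rev(WC_RNA[strsplit(s, "")[[1L]]]),
                              collapse = ""), "", USE.NAMES = FALSE)
}
revcomp_dna <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) paste(rev(comp[strsplit(s, "")[[1L]]]),
                              collapse = ""), "", USE.NAMES = FALSE)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Primary-sequence design constraints
#'
#' The forbidden patterns are the homopolymer runs AAAA, CCCC, GGGG, UUUU
#' and six-base runs of the IUPAC two-letter classes K = \{G,U\},
#' M = \{A,C\}, R = \{A,G\}, S = \{C,G\}, W = \{A,U\}, Y = \{C,U\}
#' (KKKKKK, MMMMMM, RRRRRR, SSSSSS, WWWWWW, YYYYYY). G-U wobbles are
#' introduced at `wobble_interval` base-pair intervals within every stem so
#' the dsDNA template (where they become G-T mismatches) is not
#' self-complementary.
#'
#' @param wobble_interval base pairs between wobbles within a stem (>= 2).
#' @param gc_bounds admissible per-stem GC fraction range.
#' @param min_hamming minimum Hamming distance between any two kissing-loop
#'   sequences (and their reverse complements) in an ensemble.
#' @return object of class `seq_constraints`.
#' @export
seq_constraints <- function(wobble_interval = 8L, gc_bounds = c(0.4, 0.65),
                            min_hamming = 3L) {
  if (wobble_interval < 2L) stop("wobble_interval must be >= 2")
  structure(list(wobble_interval = as.integer(wobble_interval),
                 gc_bounds = gc_bounds,
                 min_hamming = as.integer(min_hamming),
                 homopolymer_len = 4L, class_run_len = 6L),
            class = "seq_constraints")
}

iupac_classes <- function(alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  u <- if (alphabet == "RNA") "U" else "T"
  list(K = c("G", u), M = c("A", "C"), R = c("A", "G"),
       S = c("C", "G"), W = c("A", u), Y = c("C", u))
}

#' Scan a sequence for forbidden patterns
#'
#' Reports every maximal window violating the constraint set: homopolymer
#' runs of length >= 4 and runs of length >= 6 of the two-letter IUPAC
#' classes K/M/R/S/W/Y.
#'
#' @param seq RNA (or, with `alphabet = "DNA"`, DNA) sequence string.
#' @param constraints a [seq_constraints()].
#' @param alphabet `"RNA"` or `"DNA"`.
#' @return data frame with columns `pattern` (e.g. `"AAAA"` or `"WWWWWW"`),
#'   `start` (1-based) and `length` of the maximal violating run; zero rows
#'   iff the sequence is clean.
#' @export
violates_constraints <- function(seq, constraints = seq_constraints(),
                                 alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  bases <- if (alphabet == "RNA") RNA_BASES else c("A", "C", "G", "T")
  ch <- strsplit(seq, "")[[1L]]
  if (any(!ch %in% bases))
    stop("invalid ", alphabet, " alphabet: ",
         paste(unique(ch[!ch %in% bases]), collapse = ""))
  out <- list()
  scan_runs <- function(member, pat_char, minlen) {
    r <- rle(member)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- r$values & r$lengths >= minlen
    if (any(hit))
      data.frame(pattern = strrep(pat_char, minlen),
                 start = starts[hit], length = r$lengths[hit])
  }
  for (b in bases)
    out[[b]] <- scan_runs(ch == b,
                          if (alphabet == "RNA") b else b,
                          constraints$homopolymer_len)
  cls <- iupac_classes(alphabet)
  for (cn in names(cls))
    out[[cn]] <- scan_runs(ch %in% cls[[cn]], cn, constraints$class_run_len)
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    return(data.frame(pattern = character(), start = integer(),
                      length = integer()))
  rownames(res) <- NULL
  res[order(res$start), ]
}

#' Kissing-loop sequence ensemble
#'
#' A set of mutually orthogonal 6-base loop pairs. Within a pair, `loop_b`
#' is the reverse complement of `loop_a` (the loop-loop duplex is fully
#' complementary); across the ensemble, every loop differs from every other
#' loop and from every other loop's reverse complement by at least
#' `min_hamming` substitutions, and no loop is self-complementary.
#'
#' @param n number of pairs to generate.
#' @param constraints a [seq_constraints()].
#' @param seed integer seed; the ensemble is deterministic given the seed.
#' @param literature optional data frame with columns `loop_a`, `loop_b`
#'   of validated literature pairs injected ahead of generated ones.
#' @param kl_len loop length in bases.
#' @param max_tries sampling budget before declaring infeasibility.
#' @return object of class `kl_ensemble`: data frame `pairs` (`loop_a`,
#'   `loop_b`, `provenance`) plus the `min_hamming` used.
#' @export
generate_kl_ensemble <- function(n, constraints = seq_constraints(),
                                 seed = 1L, literature = NULL, kl_len = 6L,
                                 max_tries = 50000L) {
  if (n < 1L) stop("n must be >= 1")
  pairs <- data.frame(loop_a = character(), loop_b = character(),
                      provenance = character())
  loops <- character()
  add_pair <- function(a, prov) {
    b <- revcomp_rna(a)
    pairs <<- rbind(pairs, data.frame(loop_a = a, loop_b = b,
                                      provenance = prov))
    loops <<- c(loops, a, b)
  }
  ok_loop <- function(a) {
    b <- revcomp_rna(a)
    if (a == b) return(FALSE)                       # self-complementary
    if (nrow(violates_constraints(a, constraints))) return(FALSE)
    gc <- sum(strsplit(a, "")[[1L]] %in% c("G", "C"))
    if (gc < 2L || gc > nchar(a) - 1L) return(FALSE)  # binding-strength proxy
    mh <- constraints$min_hamming
    for (x in c(a, b)) {
      if (hamming(x, revcomp_rna(x)) < mh) return(FALSE)
      for (l in loops)
        if (hamming(x, l) < mh) return(FALSE)
    }
    TRUE
  }
  if (!is.null(literature)) {
    for (k in seq_len(nrow(literature))) {
      a <- literature$loop_a[[k]]
      if (!identical(revcomp_rna(a), literature$loop_b[[k]]))
        stop("literature pair ", k, ": loop_b is not revcomp(loop_a)")
      if (!ok_loop(a)) stop("literature pair ", k,
                            " violates ensemble invariants")
      add_pair(a, "literature")
    }
  }
  with_seed(seed, {
    tries <- 0L
    while (nrow(pairs) < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("kissing-loop ensemble infeasible: could not reach n = ", n,
             " pairs at min_hamming = ", constraints$min_hamming)
      a <- paste(sample(RNA_BASES, kl_len, replace = TRUE), collapse = "")
      if (ok_loop(a)) add_pair(a, "generated")
    }
  })
  structure(list(pairs = pairs[seq_len(n), ],
                 min_hamming = constraints$min_hamming),
            class = "kl_ensemble")
}

#' @export
print.kl_ensemble <- function(x, ...) {
  cat(sprintf("kl_ensemble: %d pairs, min Hamming distance %d\n",
              nrow(x$pairs), x$min_hamming))
  invisible(x)
}

#' Read / write a kissing-loop ensemble as tab-separated text
#' @param x a `kl_ensemble`.
#' @param path file path (columns loop_a, loop_b, provenance).
#' @param constraints a [seq_constraints()] used for re-validation on read.
#' @return `write_kl_ensemble`: `path` invisibly; `read_kl_ensemble`: a
#'   `kl_ensemble`.
#' @export
write_kl_ensemble <- function(x, path) {
  utils::write.table(x$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_kl_ensemble
#' @export
read_kl_ensemble <- function(path, constraints = seq_constraints()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  for (k in seq_len(nrow(df)))
    if (!identical(revcomp_rna(df$loop_a[[k]]), df$loop_b[[k]]))
      stop("ensemble row ", k, ": loop_b is not revcomp(loop_a)")
  loops <- c(df$loop_a, df$loop_b)
  for (i in seq_along(loops))
    for (j in seq_along(loops))
      if (i < j && hamming(loops[[i]], loops[[j]]) < constraints$min_hamming)
        stop("ensemble not orthogonal at min_hamming = ",
             constraints$min_hamming)
  structure(list(pairs = df, min_hamming = constraints$min_hamming),
            class = "kl_ensemble")
}

# positions (5'-side, 3'-side) of every wobble pair implied by the strand
# model: every wobble_interval-th pair of each stem duplex, counting from
# the stem's 5'-most pair; kissing-loop pairing regions are never wobbled.
wobble_positions <- function(strand, constraints) {
  iv <- constraints$wobble_interval
  out <- NULL
  for (d in which(strand$domains$kind %in% c("stem5", "kl_stem5"))) {
    len <- strand$domains$length[d]
    ks <- seq_len(len %/% iv) * iv
    if (!length(ks)) next
    i <- strand$domains$start[d] - 1L + ks
    out <- rbind(out, cbind(i, strand$pairing[i]))
  }
  out
}

#' Introduce G-U wobbles at fixed base-pair intervals
#'
#' Within each stem duplex, every `wobble_interval`-th pair (counting from
#' the stem's 5'-most pair) is converted to a G-U wobble, G on the
#' first-traversed strand. In the dsDNA template these become G-T
#' mismatches, which keeps the template from being self-complementary.
#' Kissing-loop pairing regions are never wobbled; stems shorter than the
#' interval receive none.
#'
#' @param strand a [build_strand_model()] result.
#' @param sequence draft RNA sequence satisfying pairing complementarity.
#' @param constraints a [seq_constraints()].
#' @return the wobbled sequence string.
#' @export
apply_wobbles <- function(strand, sequence, constraints = seq_constraints()) {
  ch <- strsplit(sequence, "")[[1L]]
  wp <- wobble_positions(strand, constraints)
  if (!is.null(wp)) {
    ch[wp[, 1L]] <- "G"
    ch[wp[, 2L]] <- "U"
  }
  paste(ch, collapse = "")
}

valid_rna_pair <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Design the primary RNA sequence of a strand model
#'
#' Kissing-loop pairing regions are taken from the ensemble (one pair per
#' kissing-loop edge, in edge order); stems are filled with random
#' complementary bases under per-stem GC bounds, G-U wobbles are inserted at
#' the constraint interval, the first base is forced to G (T7 requirement),
#' and a deterministic repair loop mutates free (non-loop, non-wobble)
#' positions until no forbidden pattern remains.
#'
#' @param strand a [build_strand_model()] result.
#' @param ensemble a [generate_kl_ensemble()] with at least as many pairs as
#'   the design has kissing loops.
#' @param constraints a [seq_constraints()].
#' @param seed integer seed; the result is deterministic given
#'   (structure, seed, constraints).
#' @param designer `"internal"` for the built-in rejection sampler, or a
#'   function `(length, seed) -> RNA string` acting as an external
#'   thermodynamic-designer adapter for stem sequences (same contract).
#' @param max_restarts bound on repair iterations.
#' @return RNA sequence string; attribute `kl_pairs` records the ensemble
#'   rows used per kissing-loop edge.
#' @export
design_sequence <- function(strand, ensemble, constraints = seq_constraints(),
                            seed = 1L, designer = "internal",
                            max_restarts = 5000L) {
  n <- strand$length
  p <- strand$pairing
  nuc <- strand$nucleotides
  doms <- strand$domains
  kl_doms <- which(doms$kind == "kl_loop")
  kl_edges <- sort(unique(doms$edge[kl_doms]))
  if (nrow(ensemble$pairs) < length(kl_edges))
    stop("ensemble too small: need ", length(kl_edges), " pairs")

  ch <- rep(NA_character_, n)
  # kissing-loop regions from the ensemble, one pair per kl edge
  kl_locked <- rep(FALSE, n)
  for (k in seq_along(kl_edges)) {
    e <- kl_edges[[k]]
    dd <- kl_doms[doms$edge[kl_doms] == e]
    d5 <- dd[which.min(doms$start[dd])]
    rows <- doms$start[d5] - 1L + seq_len(doms$length[d5])
    paired_rows <- rows[!is.na(p[rows])]
    loop <- strsplit(ensemble$pairs$loop_a[[k]], "")[[1L]]
    stopifnot(length(paired_rows) == length(loop))
    ch[paired_rows] <- loop
    ch[p[paired_rows]] <- WC_RNA[loop]
    kl_locked[paired_rows] <- TRUE
    kl_locked[p[paired_rows]] <- TRUE
  }
  # unpaired defaults: purine flanks, linkers
  ch[is.na(ch) & nuc$dkind == "kl_loop"] <- "A"
  ch[is.na(ch) & nuc$dkind == "linker"] <- "A"

  # constraint-aware sampler: never emits a forbidden run within the stem.
  # Complementation maps each IUPAC class run to a class run (W->W, S->S,
  # K<->M, R<->Y), so the partner strand inherits cleanliness.
  cls <- iupac_classes("RNA")
  sample_clean <- function(len) {
    s <- character(len)
    for (k in seq_len(len)) {
      ok <- RNA_BASES
      if (k >= constraints$homopolymer_len) {
        tail3 <- s[(k - constraints$homopolymer_len + 1L):(k - 1L)]
        if (length(unique(tail3)) == 1L) ok <- setdiff(ok, tail3[[1L]])
      }
      if (k >= constraints$class_run_len) {
        tail5 <- s[(k - constraints$class_run_len + 1L):(k - 1L)]
        for (cn in names(cls))
          if (all(tail5 %in% cls[[cn]])) ok <- setdiff(ok, cls[[cn]])
      }
      s[k] <- ok[[sample.int(length(ok), 1L)]]
    }
    s
  }
  design_stem <- function(len) {
    if (is.function(designer)) return(designer(len, seed))
    for (try in seq_len(100L)) {
      s <- sample_clean(len)
      gc <- mean(s %in% c("G", "C"))
      if (len < 4L || (gc >= constraints$gc_bounds[[1L]] &&
                       gc <= constraints$gc_bounds[[2L]])) break
    }
    paste(s, collapse = "")
  }

  wp <- wobble_positions(strand, constraints)
  locked <- kl_locked
  if (!is.null(wp)) locked[c(wp)] <- TRUE
  locked[1L] <- TRUE
  if (!is.na(p[1L])) locked[p[1L]] <- TRUE

  seqn <- with_seed(seed, {
    for (d in which(doms$kind %in% c("stem5", "kl_stem5"))) {
      rows <- doms$start[d] - 1L + seq_len(doms$length[d])
      s <- strsplit(design_stem(length(rows)), "")[[1L]]
      ch[rows] <- s
      ch[p[rows]] <- WC_RNA[s]
    }
    ch[1L] <- "G"
    if (!is.na(p[1L])) ch[p[1L]] <- "C"
    draft <- apply_wobbles(strand, paste(ch, collapse = ""), constraints)
    ch <- strsplit(draft, "")[[1L]]

    # repair sweeps: mutate one free position inside every violating window.
    # Candidate bases are scored on the local neighbourhood of BOTH the
    # mutated position and its partner (the complementary write can
    # otherwise recreate a run on the far side indefinitely).
    local_score <- function(chv, pos) {
      lo <- max(1L, pos - 7L); hi <- min(length(chv), pos + 7L)
      nrow(violates_constraints(paste(chv[lo:hi], collapse = ""),
                                constraints))
    }
    for (it in seq_len(max_restarts)) {
      vio <- violates_constraints(paste(ch, collapse = ""), constraints)
      if (!nrow(vio)) break
      {
        v <- vio[sample.int(nrow(vio), 1L), ]
        win <- seq(v$start, v$start + v$length - 1L)
        free <- win[!locked[win]]
        if (!length(free))
          stop("cannot repair forbidden pattern ", v$pattern,
               " at position ", v$start, ": all positions locked")
        # bias toward unpaired positions (linkers/flanks) but keep paired
        # ones reachable: a lone linker can sit in a context where every
        # base choice violates some class, so neighbours must stay mutable
        unp <- free[is.na(p[free])]
        pool <- c(free, unp, unp)
        pos <- pool[[sample.int(length(pool), 1L)]]
        pc <- substr(v$pattern, 1L, 1L)
        bad <- if (pc %in% RNA_BASES) pc else iupac_classes("RNA")[[pc]]
        cand <- setdiff(RNA_BASES, c(bad, ch[[pos]]))
        score <- vapply(cand, function(b) {
          tmp <- ch
          tmp[pos] <- b
          sc <- 0
          if (!is.na(p[pos])) {
            tmp[p[pos]] <- WC_RNA[b]
            sc <- local_score(tmp, p[pos])
          }
          sc + local_score(tmp, pos)
        }, 0)
        best <- cand[score == min(score)]
        ch[pos] <- best[[sample.int(length(best), 1L)]]
        if (!is.na(p[pos])) ch[p[pos]] <- WC_RNA[ch[pos]]
      }
    }
    vfin <- violates_constraints(paste(ch, collapse = ""), constraints)
    if (nrow(vfin))
      stop("constraint satisfaction failed after max restarts: ",
           paste(vfin$pattern, "@", vfin$start, collapse = ", "))
    paste(ch, collapse = "")
  })

  # post-hoc consistency: every paired position WC or G-U
  chf <- strsplit(seqn, "")[[1L]]
  pi <- which(!is.na(p))
  stopifnot(all(valid_rna_pair(chf[pi], chf[p[pi]])))
  attr(seqn, "kl_pairs") <- data.frame(edge = kl_edges,
                                       loop_a = ensemble$pairs$loop_a[
                                         seq_along(kl_edges)])
  seqn
}

T7_PROMOTER <- "TAATACGACTCACTATAG"
T7_CAP <- "GAC"

wallace_tm <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

#' Build the T7 transcription DNA template with primers
#'
#' The template begins with the cap `GAC` followed by the T7 promoter
#' `TAATACGACTCACTATAG`, whose final G is the transcription start and hence
#' the RNA's required 5' G; the transcribed body (RNA with U -> T) follows,
#' then a seeded 15-nt tail passing the DNA-alphabet pattern constraints.
#' The forward primer is cap + promoter; the reverse primer is the reverse
#' complement of the template 3' end, extended from 15 nt until its
#' Wallace-rule melting temperature reaches `target_tm`.
#'
#' @param rna designed RNA sequence; must start with G.
#' @param tail_seed seed for tail generation.
#' @param target_tm reverse-primer melting temperature target, Celsius
#'   (Wallace rule 2(A+T) + 4(G+C); approximate by design).
#' @param constraints a [seq_constraints()].
#' @param wobble_pos optional wobble-position metadata carried through.
#' @return object of class `dna_template`: `template`, `cap`, `promoter`,
#'   `body` (full RNA as DNA, first base shared with the promoter G),
#'   `tail`, `fwd_primer`, `rev_primer`, `wobble_positions`.
#' @export
build_dna_template <- function(rna, tail_seed = 1L, target_tm = 58,
                               constraints = seq_constraints(),
                               wobble_pos = NULL) {
  if (substr(rna, 1L, 1L) != "G") stop("T7 requires 5' G")
  body <- chartr("U", "T", rna)
  tail <- with_seed(tail_seed, {
    repeat {
      t15 <- paste(sample(c("A", "C", "G", "T"), 15L, replace = TRUE),
                   collapse = "")
      probe <- paste0(substr(body, nchar(body) - 6L, nchar(body)), t15)
      if (!nrow(violates_constraints(probe, constraints,
                                     alphabet = "DNA"))) break
    }
    t15
  })
  template <- paste0(T7_CAP, T7_PROMOTER, substr(body, 2L, nchar(body)), tail)
  len <- 15L
  repeat {
    rp <- revcomp_dna(substr(template, nchar(template) - len + 1L,
                             nchar(template)))
    if (wallace_tm(rp) >= target_tm || len >= min(40L, nchar(template))) break
    len <- len + 1L
  }
  structure(list(template = template, cap = T7_CAP, promoter = T7_PROMOTER,
                 body = body, tail = tail,
                 fwd_primer = paste0(T7_CAP, T7_PROMOTER),
                 rev_primer = rp, wobble_positions = wobble_pos),
            class = "dna_template")
}

#' @export
print.dna_template <- function(x, ...) {
  cat(sprintf("dna_template: %d nt (tail %d nt, primers %d/%d nt)\n",
              nchar(x$template), nchar(x$tail), nchar(x$fwd_primer),
              nchar(x$rev_primer)))
  invisible(x)
}
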