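# Independent oracles used across the test suite. These deliberately avoid
# the package's own implementations of the quantities they check.

# Brute-force enumeration of all perfect matchings of 1..n (n even),
# returned as a list of 2-column matrices.
enumerate_matchings <- function(n) enumerate_matchings_of(seq_len(n))
enumerate_matchings_of <- function(v) {
  if (!length(v)) return(list(matrix(integer(), 0L, 2L)))
  out <- list()
  for (k in seq_along(v[-1L]) + 1L) {
    sub <- enumerate_matchings_of(v[-c(1L, k)])
    for (s in sub) out[[length(out) + 1L]] <- rbind(c(v[[1L]], v[[k]]), s)
  }
  out
}

# Independent crossing test for a chord set on a circle of n points.
oracle_noncrossing <- function(pairs) {
  if (nrow(pairs) < 2L) return(TRUE)
  pr <- t(apply(pairs, 1L, sort))
  for (i in seq_len(nrow(pr) - 1L)) for (j in (i + 1L):nrow(pr)) {
    a <- pr[i, ]; b <- pr[j, ]
    if ((b[1L] > a[1L] && b[1L] < a[2L]) != (b[2L] > a[1L] && b[2L] < a[2L]))
      return(FALSE)
  }
  TRUE
}

# Minimal independent dot-bracket parser (stack per bracket type).
oracle_parse_db <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  opens <- c("(", "[", "{", "<", LETTERS)
  closes <- c(")", "]", "}", ">", letters)
  p <- rep(NA_integer_, length(ch))
  for (t in seq_along(opens)) {
    st <- integer()
    for (k in seq_along(ch)) {
      if (ch[k] == opens[t]) st <- c(st, k)
      else if (ch[k] == closes[t]) {
        p[k] <- st[length(st)]; p[st[length(st)]] <- k
        st <- st[-length(st)]
      }
    }
    stopifnot(length(st) == 0L)
  }
  p
}

# Direct double-loop radius of gyration (O(n^2) pairwise identity:
# Rg^2 = (1/2n^2) * sum_ij |ri - rj|^2).
oracle_rg <- function(x) {
  n <- nrow(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + sum((x[i, ] - x[j, ])^2)
  sqrt(s / (2 * n^2))
}

# Cycle rank by brute-force independent-cycle counting: remove edges one by
# one if their removal keeps the graph connected.
oracle_cycle_rank <- function(edges, nv) {
  removed <- 0L
  es <- edges
  connected <- function(e) {
    adj <- lapply(seq_len(nv), function(i) integer())
    for (r in seq_len(nrow(e))) {
      adj[[e[r, 1L]]] <- c(adj[[e[r, 1L]]], e[r, 2L])
      adj[[e[r, 2L]]] <- c(adj[[e[r, 2L]]], e[r, 1L])
    }
    seen <- rep(FALSE, nv); seen[1L] <- TRUE; q <- 1L
    while (length(q)) {
      v <- q[[1L]]; q <- q[-1L]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; q <- c(q, w) }
    }
    all(seen)
  }
  repeat {
    done <- TRUE
    for (r in seq_len(nrow(es))) {
      if (connected(es[-r, , drop = FALSE])) {
        es <- es[-r, , drop = FALSE]
        removed <- removed + 1L
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  removed
}

# Standard knot fixtures as closed polylines.
trefoil_polyline <- function(n = 120L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(sin(t) + 2 * sin(2 * t), cos(t) - 2 * cos(2 * t), -sin(3 * t))
}
figure8_polyline <- function(n = 160L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind((2 + cos(2 * t)) * cos(3 * t), (2 + cos(2 * t)) * sin(3 * t),
        sin(4 * t))
}

# Small OBJ fixtures written on the fly.
write_tetra_obj <- function(path) {
  writeLines(c("# tetrahedron", "v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1",
               "f 1 2 3", "f 1 2 4", "f 1 3 4", "f 2 3 4"), path)
  path
}

hamming_str <- function(a, b)
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
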