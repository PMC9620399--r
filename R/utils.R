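# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All user-facing randomness goes
# through this so library calls never perturb the session RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# A unit vector perpendicular to `d`, deterministic, robust to axis-aligned d.
perp_unit <- function(d) {
  refs <- list(c(0.28108924, 0.57496187, 0.76837927),
               c(1, 0, 0), c(0, 1, 0))
  for (r in refs) {
    p <- cross3(d, r)
    if (vnorm(p) > 1e-8 * vnorm(d)) return(unitv(p))
  }
  stop("degenerate direction")
}

deg2rad <- function(x) x * pi / 180

# Angle between two vectors, degrees, in [0, 180].
angle_deg <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
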