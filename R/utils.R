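## Small numerical helpers shared across modules. Not exported.

rowNorms <- function(m) sqrt(rowSums(m * m))

normalizeRows <- function(m) {
  n <- rowNorms(m)
  if (any(n == 0)) stop("cannot normalize zero-length vector")
  m / n
}

crossProduct <- function(u, v) {
  ## u, v: n x 3 matrices (or length-3 vectors)
  if (is.null(dim(u))) u <- matrix(u, 1L, 3L)
  if (is.null(dim(v))) v <- matrix(v, 1L, 3L)
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

## Orthonormal tangent frame for unit normal `n`: e1 is the tangent
## projection of `ref` (global +x by default, +y fallback near the x-axis),
## e2 = n x e1.  A shared convention so in-plane angles are comparable
## across cells of a common patch.
tangentFrame <- function(n, ref = c(1, 0, 0)) {
  n <- n / sqrt(sum(n^2))
  e1 <- ref - sum(ref * n) * n
  if (sqrt(sum(e1^2)) < 1e-6) {
    ref <- c(0, 1, 0)
    e1 <- ref - sum(ref * n) * n
  }
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2L] * e1[3L] - n[3L] * e1[2L],
          n[3L] * e1[1L] - n[1L] * e1[3L],
          n[1L] * e1[2L] - n[2L] * e1[1L])
  list(e1 = e1, e2 = e2, n = n)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("rng seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Deterministic per-stage seed derivation: a root seed plus a stage name
## always map to the same 31-bit seed, so adding a stage never perturbs
## the draws of earlier stages.
deriveSeed <- function(seed, stage) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

## Axial (sign-free) angle in degrees between 2D directions given as angles.
axialDiffDeg <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
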