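# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and an index, kept inside 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %%
               (.Machine$integer.max - 1L)) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

# Row-wise Euclidean norms of a matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n == 0) stopf("cannot normalize a zero vector")
  v / n
}

# Rotation matrix taking unit vector `a` onto unit vector `b` (Rodrigues).
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- vcross(a, b)
  s2 <- sum(v * v)
  cth <- sum(a * b)
  if (s2 < 1e-16) {
    if (cth > 0) return(diag(3))
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(vcross(a, p))
    K <- matrix(c(0, ax[3L], -ax[2L], -ax[3L], 0, ax[1L], ax[2L], -ax[1L], 0), 3L, 3L)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + K + K %*% K * ((1 - cth) / s2)
}

# Linear interpolation of a (possibly multi-column) set of values sampled at
# increasing abscissae `x` onto `xout` (clamped to range).
interp_cols <- function(x, y, xout) {
  xout <- pmin(pmax(xout, x[1L]), x[length(x)])
  if (is.null(dim(y))) {
    return(approx(x, y, xout, ties = "ordered")$y)
  }
  out <- matrix(NA_real_, length(xout), ncol(y))
  for (j in seq_len(ncol(y))) {
    out[, j] <- approx(x, y[, j], xout, ties = "ordered")$y
  }
  out
}
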