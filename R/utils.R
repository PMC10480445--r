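# internal helpers shared across modules

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# session RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# scalar validators used by configuration checks; `name` feeds the error
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("field '%s' must be an integer >= %d (got %s)", name, min,
                 deparse(x)), call. = FALSE)
  as.integer(x)
}

check_real <- function(x, name, lower = -Inf, upper = Inf,
                       strict_lower = FALSE, strict_upper = FALSE) {
  ok <- length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok)
    stop(sprintf("field '%s' out of range (got %s)", name, deparse(x)),
         call. = FALSE)
  as.numeric(x)
}

# Truncated SVD with deterministic output: dense LAPACK SVD for small
# problems, irlba (seeded internally, fixed start) for large ones.  Signs are
# fixed afterwards by the caller where required.
truncated_svd <- function(x, k) {
  x <- as.matrix(x)
  k <- min(k, dim(x))
  if (min(dim(x)) <= 500L || k >= 0.5 * min(dim(x))) {
    s <- svd(x, nu = k, nv = k)
    list(u = s$u[, seq_len(k), drop = FALSE], d = s$d[seq_len(k)],
         v = s$v[, seq_len(k), drop = FALSE])
  } else {
    s <- with_seed(1L, irlba::irlba(x, nv = k, tol = 1e-10))
    list(u = s$u, d = s$d, v = s$v)
  }
}

# Fix per-component sign: the largest-magnitude loading is made positive.
fix_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}
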