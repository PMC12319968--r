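# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a label
#'
#' Hashes the master seed together with an arbitrary set of labels (condition
#' levels, source indices, ...) into a 31-bit integer seed. The hash is a
#' plain FNV-1a over the formatted label string, so a given condition tuple
#' always maps to the same child seed regardless of which other conditions
#' are present in a sweep.
#'
#' @param master integer master seed.
#' @param ... atomic values identifying the consumer (coerced to character).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  parts <- vapply(list(master, ...), function(x) paste(format(x, digits = 15), collapse = ","),
                  character(1))
  key <- paste(parts, collapse = "|")
  bytes <- utf8ToInt(key)
  # multiplicative string hash kept below 2^31 (R integer range)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

row_norms <- function(x) sqrt(rowSums(x^2))

normalize_rows <- function(x) {
  n <- row_norms(x)
  x / pmax(n, .Machine$double.xmin)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product of two n x 3 matrices
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite scalar in [%g, %g]", name, lower, upper))
  invisible(x)
}
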