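#' Jaccard index of two membership vectors
#'
#' @param a,b character or integer vectors of member ids.
#' @return Scalar in \[0, 1\]; 1 when both sets are empty.
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

# Derive a reproducible child seed from a base seed and a stream label.
# Keeps results independent across pipeline stages while driven by one seed.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# standardize a numeric vector to mean 0, sd 1 (error on constant input)
standardize <- function(x, what = "input") {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop(what, " is constant; cannot standardize")
  (x - mean(x)) / s
}

assert_fraction <- function(x, name, lo = 0, hi = 1, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > lo && x < hi else x >= lo && x <= hi)
  if (!ok) stop(name, " must be a fraction in [", lo, ", ", hi, "]")
  invisible(x)
}
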