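# Numerical helpers shared across modules.

# Smallest probability admitted before taking a log.
PROB_FLOOR <- 1e-16

#' Numerically stable softmax
#'
#' Exponentiates and normalises a vector of log-scores after subtracting the
#' maximum, so that very large or small scores do not overflow.
#'
#' @param x Numeric vector of (unnormalised) log-scores.
#' @return A probability vector of the same length summing to 1.
#' @export
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Floored natural log: probabilities are clamped at PROB_FLOOR first.
ln_safe <- function(p) log(pmax(p, PROB_FLOOR))

# Normalise a non-negative vector to sum to 1.
normalise <- function(x) {
  s <- sum(x)
  if (s <= 0) stop("cannot normalise a vector with non-positive sum")
  x / s
}

# Shannon entropy of a probability vector (nats), flooring before the log.
entropy <- function(p) -sum(p * ln_safe(p))

# Slice an array along its first dimension, returning an array over the
# remaining dimensions (a scalar-free drop: length-1 remainders stay arrays).
slice_first <- function(arr, i) {
  d <- dim(arr)
  if (is.null(d)) return(arr[i])
  m <- matrix(arr, nrow = d[1])
  rest <- d[-1]
  if (length(rest) == 0L) return(m[i, ])
  array(m[i, ], dim = rest)
}

# Multiply an array by a probability vector along every dimension except
# `keep`, then sum those dimensions out. With `keep = 0` all dimensions are
# contracted and a scalar is returned. `qs` is a list of vectors, one per
# dimension of `arr`.
contract_dims <- function(arr, qs, keep = 0L) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  nf <- length(d)
  for (f in seq_len(nf)) {
    if (f == keep) next
    arr <- sweep(array(arr, dim = d), f, qs[[f]], `*`)
  }
  if (keep == 0L) return(sum(arr))
  as.vector(apply(array(arr, dim = d), keep, sum))
}

# Outer product of a list of vectors, returned as an array with one
# dimension per vector.
outer_list <- function(vs) {
  out <- vs[[1]]
  if (length(vs) > 1L) {
    for (v in vs[-1]) out <- outer(out, v)
  }
  array(out, dim = vapply(vs, length, integer(1)))
}

# Check that `x` is a single number satisfying a predicate.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (x < lower || x > upper || (strict_lower && x <= lower))
    stop(sprintf("'%s' = %g is out of range", name, x))
  invisible(x)
}
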