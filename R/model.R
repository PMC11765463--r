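# Generative-model construction: the five component sets of a discrete
# state-space POMDP (observation model A, transition model B, preference
# prior C, state prior D, habit prior E), their Dirichlet priors, and the
# policy space.
#
# Conventions used throughout the package:
#   * A is a list with one array per observation modality m, of dimension
#     num_obs[m] x num_states[1] x ... x num_states[F]; each "column" (the
#     observation axis at a fixed state combination) is a categorical
#     distribution.
#   * B is a list with one array per state factor f, of dimension
#     num_states[f] x num_states[f] x num_controls[f]; B[[f]][to, from, u]
#     is the probability of moving to state `to` from state `from` under
#     action `u`.
#   * C is a list of per-modality numeric vectors on the (unnormalised)
#     log-preference scale; it is passed through a softmax only inside
#     pragmatic-value / risk computations.
#   * D is a list of per-factor prior probability vectors; E is a single
#     probability vector over policies.
#   * All user-facing category and action indices are 1-based.

STOCH_TOL <- 1e-10

#' Model shape descriptor
#'
#' Collects the dimensions of a discrete POMDP generative model: the number
#' of observation categories per modality, hidden states per factor,
#' allowable actions per factor, and the planning horizon.
#'
#' @param num_obs Integer vector, observations per modality.
#' @param num_states Integer vector, hidden states per factor.
#' @param num_controls Integer vector, one entry per factor; a factor with
#'   no controllable action has entry 1. Defaults to all-1.
#' @param policy_length Positive integer, temporal depth of planning.
#' @return An object of class `aif_shape`.
#' @export
model_shape <- function(num_obs, num_states,
                        num_controls = rep(1L, length(num_states)),
                        policy_length = 1L) {
  check_dims <- function(x, name) {
    if (length(x) < 1L || any(x < 1) || any(x != round(x)))
      stop(sprintf("'%s' must be positive integers", name))
    as.integer(x)
  }
  num_obs <- check_dims(num_obs, "num_obs")
  num_states <- check_dims(num_states, "num_states")
  num_controls <- check_dims(num_controls, "num_controls")
  if (length(num_controls) != length(num_states))
    stop("'num_controls' must have one entry per state factor")
  check_scalar(policy_length, "policy_length", lower = 1)
  structure(
    list(num_obs = num_obs, num_states = num_states,
         num_controls = num_controls,
         policy_length = as.integer(policy_length)),
    class = "aif_shape")
}

#' @export
print.aif_shape <- function(x, ...) {
  cat("POMDP model shape\n")
  cat("  modalities:", paste(x$num_obs, collapse = ", "), "observations\n")
  cat("  factors:   ", paste(x$num_states, collapse = ", "), "states\n")
  cat("  controls:  ", paste(x$num_controls, collapse = ", "), "\n")
  cat("  policy length:", x$policy_length, "\n")
  invisible(x)
}

#' One-hot probability vector
#'
#' @param index Position of the unit entry (1-based).
#' @param length Length of the vector.
#' @return A vector with 1 at `index`, 0 elsewhere.
#' @examples
#' onehot(2, 4)
#' @export
onehot <- function(index, length) {
  check_scalar(length, "length", lower = 1)
  check_scalar(index, "index", lower = 1, upper = length)
  v <- numeric(length)
  v[index] <- 1
  v
}

#' Create model component templates
#'
#' Builds the A/B/C/D/E containers with the correct dimensions so that they
#' can be populated by hand, or used directly as a maximally uninformative
#' model when `fill = "uniform"`.
#'
#' C is returned as zero log-preferences under both fills (zero is the
#' neutral preference on the log scale).
#'
#' @param shape An [model_shape()] object.
#' @param fill `"zeros"` (populate later) or `"uniform"` (normalised
#'   columns, uniform D and E).
#' @return A list with elements `A`, `B`, `C`, `D`, `E`.
#' @export
create_templates <- function(shape, fill = c("zeros", "uniform")) {
  fill <- match.arg(fill)
  stopifnot(inherits(shape, "aif_shape"))
  ns <- shape$num_states
  A <- lapply(shape$num_obs, function(no) {
    val <- if (fill == "uniform") 1 / no else 0
    array(val, dim = c(no, ns))
  })
  B <- lapply(seq_along(ns), function(f) {
    val <- if (fill == "uniform") 1 / ns[f] else 0
    array(val, dim = c(ns[f], ns[f], shape$num_controls[f]))
  })
  C <- lapply(shape$num_obs, numeric)
  D <- lapply(ns, function(n) {
    if (fill == "uniform") rep(1 / n, n) else numeric(n)
  })
  n_pol <- prod(shape$num_controls)^shape$policy_length
  E <- if (fill == "uniform") rep(1 / n_pol, n_pol) else numeric(n_pol)
  list(A = A, B = B, C = C, D = D, E = E)
}

#' Enumerate the policy space
#'
#' Exhaustively enumerates all action sequences of length `policy_length`,
#' in deterministic lexicographic order over (time step, factor, action
#' index): the action at the first step of the first factor varies slowest.
#'
#' @param num_controls Integer vector of actions per factor.
#' @param policy_length Planning horizon.
#' @return A list of `policy_length` x `num_factors` integer matrices; the
#'   list has `prod(num_controls)^policy_length` elements.
#' @export
construct_policies <- function(num_controls, policy_length) {
  shape <- model_shape(num_obs = 1L, num_states = rep(1L, length(num_controls)),
                       num_controls = num_controls,
                       policy_length = policy_length)
  nf <- length(num_controls)
  L <- shape$policy_length
  dims <- rep(shape$num_controls, times = L)   # t1f1, t1f2, ..., tLfF
  # expand.grid varies its first column fastest; feed coordinates reversed
  # so the (t1, f1) coordinate becomes the slowest (lexicographic order).
  g <- expand.grid(rev(lapply(dims, seq_len)), KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g[, rev(seq_len(ncol(g))), drop = FALSE])
  lapply(seq_len(nrow(g)), function(i) {
    matrix(as.integer(g[i, ]), nrow = L, ncol = nf, byrow = TRUE)
  })
}

# --- validation ------------------------------------------------------------

# Column-stochasticity check along the first axis of an array; returns a
# character vector of violation messages (one per offending column).
check_stochastic <- function(arr, label, tol = STOCH_TOL) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  m <- matrix(arr, nrow = d[1])
  out <- character(0)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    out <- c(out, sprintf("%s: negative entry at flat position (%d, column %d)",
                          label, neg[1, 1], neg[1, 2]))
  }
  cs <- colSums(m)
  bad <- which(abs(cs - 1) > tol)
  if (length(bad) > 0) {
    out <- c(out, sprintf("%s: column %d sums to %.6g (expected 1)",
                          label, bad, cs[bad]))
  }
  out
}

#' Validate model components against a shape
#'
#' Checks dimensions, column stochasticity of A and B, validity of D and E,
#' and finiteness of C. Violations are returned (not raised) so that all
#' problems can be reported at once.
#'
#' @param A,B,C,D,E Model components as produced by [create_templates()].
#' @param shape An [model_shape()] object.
#' @return Character vector of human-readable violations; empty when the
#'   model is valid.
#' @export
validate_model <- function(A, B, C = NULL, D = NULL, E = NULL, shape) {
  v <- character(0)
  ns <- shape$num_states
  if (length(A) != length(shape$num_obs)) {
    v <- c(v, sprintf("A: expected %d modalities, got %d",
                      length(shape$num_obs), length(A)))
  } else {
    for (m in seq_along(A)) {
      want <- c(shape$num_obs[m], ns)
      got <- dim(A[[m]])
      if (is.null(got)) got <- length(A[[m]])
      if (!identical(as.integer(got), as.integer(want))) {
        v <- c(v, sprintf("A[%d]: dimensions (%s) != expected (%s)", m,
                          paste(got, collapse = "x"), paste(want, collapse = "x")))
      } else {
        v <- c(v, check_stochastic(A[[m]], sprintf("A[%d]", m)))
      }
    }
  }
  if (length(B) != length(ns)) {
    v <- c(v, sprintf("B: expected %d factors, got %d", length(ns), length(B)))
  } else {
    for (f in seq_along(B)) {
      want <- c(ns[f], ns[f], shape$num_controls[f])
      got <- dim(B[[f]])
      if (is.null(got)) got <- length(B[[f]])
      if (!identical(as.integer(got), as.integer(want))) {
        v <- c(v, sprintf("B[%d]: dimensions (%s) != expected (%s)", f,
                          paste(got, collapse = "x"), paste(want, collapse = "x")))
      } else {
        v <- c(v, check_stochastic(B[[f]], sprintf("B[%d]", f)))
      }
    }
  }
  if (!is.null(C)) {
    if (length(C) != length(shape$num_obs)) {
      v <- c(v, "C: wrong number of modalities")
    } else {
      for (m in seq_along(C)) {
        if (length(C[[m]]) != shape$num_obs[m])
          v <- c(v, sprintf("C[%d]: length %d != %d", m, length(C[[m]]),
                            shape$num_obs[m]))
        else if (any(!is.finite(C[[m]])))
          v <- c(v, sprintf("C[%d]: non-finite log-preference", m))
      }
    }
  }
  if (!is.null(D)) {
    if (length(D) != length(ns)) {
      v <- c(v, "D: wrong number of factors")
    } else {
      for (f in seq_along(D)) {
        if (length(D[[f]]) != ns[f])
          v <- c(v, sprintf("D[%d]: length %d != %d", f, length(D[[f]]), ns[f]))
        else
          v <- c(v, check_stochastic(D[[f]], sprintf("D[%d]", f)))
      }
    }
  }
  if (!is.null(E)) {
    n_pol <- prod(shape$num_controls)^shape$policy_length
    if (length(E) != n_pol)
      v <- c(v, sprintf("E: length %d != number of policies %d", length(E), n_pol))
    else
      v <- c(v, check_stochastic(E, "E"))
  }
  v
}

# --- Dirichlet counts ------------------------------------------------------

#' Dirichlet concentration parameters over model components
#'
#' Bundles pseudo-count arrays with the same shapes as A, B and D. Their
#' normalised means (see [dirichlet_expected()]) give the expected model
#' used for inference when parameter learning is enabled.
#'
#' @param A,B,D Lists of non-negative count arrays matching the shapes of
#'   the corresponding model components, or `NULL` when that component is
#'   not learned.
#' @return An object of class `aif_counts`.
#' @export
dirichlet_counts <- function(A = NULL, B = NULL, D = NULL) {
  chk <- function(x, name) {
    if (is.null(x)) return(NULL)
    for (i in seq_along(x)) {
      if (any(x[[i]] < 0))
        stop(sprintf("negative Dirichlet count in %s[%d]", name, i))
    }
    x
  }
  structure(list(A = chk(A, "A"), B = chk(B, "B"), D = chk(D, "D")),
            class = "aif_counts")
}

#' Scaled Dirichlet prior from a normalised model
#'
#' The conventional way to build a Dirichlet prior: multiply a normalised
#' component by a scaling factor (larger scale = more precise prior,
#' requiring more evidence to move).
#'
#' @param model A list with elements `A`, `B`, `D` (any may be absent).
#' @param scale Positive scaling factor applied to every component.
#' @param components Character subset of `c("A","B","D")` to include.
#' @return An `aif_counts` object.
#' @export
dirichlet_prior_from_model <- function(model, scale = 1,
                                       components = c("A", "B", "D")) {
  check_scalar(scale, "scale", lower = 0, strict_lower = TRUE)
  sc <- function(x) lapply(x, function(a) a * scale)
  dirichlet_counts(
    A = if ("A" %in% components && !is.null(model$A)) sc(model$A),
    B = if ("B" %in% components && !is.null(model$B)) sc(model$B),
    D = if ("D" %in% components && !is.null(model$D)) sc(model$D))
}

#' Flat Dirichlet counts for a model shape
#'
#' The default, maximally agnostic prior when no scaled copy of a model
#' component is wanted: every concentration parameter set to 1 (a uniform
#' Dirichlet on each column).
#'
#' @param shape An [model_shape()] object.
#' @param components Character subset of `c("A","B","D")`.
#' @return An `aif_counts` object.
#' @export
flat_dirichlet_counts <- function(shape, components = c("A", "B", "D")) {
  tpl <- create_templates(shape, "zeros")
  one <- function(x) lapply(x, function(a) a + 1)
  dirichlet_counts(
    A = if ("A" %in% components) one(tpl$A),
    B = if ("B" %in% components) one(tpl$B),
    D = if ("D" %in% components) lapply(tpl$D, function(d) d + 1))
}

# Normalise an array over its first axis (each column to its count sum).
normalise_first_axis <- function(arr, label = "counts") {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  m <- matrix(arr, nrow = d[1])
  cs <- colSums(m)
  if (any(cs <= 0))
    stop(sprintf("degenerate Dirichlet counts: all-zero column in %s", label))
  array(sweep(m, 2, cs, `/`), dim = d)
}

#' Expected model under Dirichlet counts
#'
#' Returns the mean of the Dirichlet distributions defined by the counts:
#' each column (observation axis for A, next-state axis for B) normalised
#' to its column sum.
#'
#' @param counts An [dirichlet_counts()] object (or plain list with
#'   elements `A`, `B`, `D`).
#' @return A list with elements `A`, `B`, `D` (those present in `counts`).
#' @export
dirichlet_expected <- function(counts) {
  norm_set <- function(x, name) {
    if (is.null(x)) return(NULL)
    lapply(seq_along(x), function(i) {
      out <- normalise_first_axis(x[[i]], sprintf("%s[%d]", name, i))
      if (is.null(dim(x[[i]]))) out <- as.vector(out)
      out
    })
  }
  list(A = norm_set(counts$A, "counts_A"),
       B = norm_set(counts$B, "counts_B"),
       D = norm_set(counts$D, "counts_D"))
}
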