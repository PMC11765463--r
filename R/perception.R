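# Perception: variational inference of per-factor posteriors over hidden
# states from an observation, by coordinate-ascent fixed-point iteration
# (FPI) on the time-specific variational free energy.
#
# Beliefs are plain lists with one probability vector per state factor.

#' Settings for fixed-point state inference
#'
#' @param max_iterations Maximum number of full FPI sweeps (default 10).
#' @param tolerance Convergence threshold on the change in free energy
#'   between sweeps (default 0.001).
#' @return An object of class `aif_inference_settings`.
#' @export
inference_settings <- function(max_iterations = 10L, tolerance = 0.001) {
  check_scalar(max_iterations, "max_iterations", lower = 1)
  check_scalar(tolerance, "tolerance", lower = 0, strict_lower = TRUE)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "aif_inference_settings")
}

#' Joint log-likelihood of an observation over the full state space
#'
#' For each state combination s, computes the sum over modalities of
#' `ln A[[m]][o_m, s]`: modalities are conditionally independent given the
#' full state combination, so their log-likelihoods add. Probabilities are
#' floored at 1e-16 before the log.
#'
#' @param A Observation model (list of per-modality arrays).
#' @param obs Integer vector of observed category indices, one per modality.
#' @return An array over the full state space (one dimension per factor).
#' @export
joint_log_likelihood <- function(A, obs) {
  if (length(obs) != length(A))
    stop("observation must have one index per modality")
  d <- dim(A[[1]])
  ns <- if (is.null(d)) length(A[[1]]) else d[-1]
  total <- array(0, dim = ns)
  for (m in seq_along(A)) {
    no <- if (is.null(dim(A[[m]]))) length(A[[m]]) else dim(A[[m]])[1]
    if (obs[m] < 1 || obs[m] > no)
      stop(sprintf("observation index %d out of bounds for modality %d",
                   obs[m], m))
    lik <- slice_first(A[[m]], obs[m])
    total <- total + array(ln_safe(lik), dim = ns)
  }
  total
}

#' Predictive prior over next states
#'
#' Pushes the previous posterior through the action-conditioned transition
#' model, factor by factor: `prior_f = B[[f]][, , u_f] %*% q_prev_f`. At the
#' first time step the state prior D plays this role instead.
#'
#' @param B Transition model (list of per-factor arrays).
#' @param previous List of per-factor posterior vectors from the last step.
#' @param action Integer vector of action indices, one per factor.
#' @return List of per-factor prior probability vectors.
#' @export
transition_prior <- function(B, previous, action) {
  if (length(action) != length(B))
    stop("action must have one index per factor")
  lapply(seq_along(B), function(f) {
    nu <- dim(B[[f]])[3]
    if (action[f] < 1 || action[f] > nu)
      stop(sprintf("action index %d out of bounds for factor %d", action[f], f))
    as.vector(B[[f]][, , action[f]] %*% previous[[f]])
  })
}

#' Variational free energy of a mean-field belief
#'
#' Evaluates the time-specific free energy
#' `F = E_q[ln q(s) - ln p(o|s) - ln p(s)]` under the product of per-factor
#' posteriors, and exposes its complexity/accuracy decomposition:
#' complexity is the KL divergence of the posterior from the prior, accuracy
#' the expected log-likelihood, and `F = complexity - accuracy`.
#'
#' @param q,prior Lists of per-factor probability vectors.
#' @param loglik Log-likelihood array from [joint_log_likelihood()].
#' @return A list with elements `F`, `accuracy`, `complexity`.
#' @export
free_energy <- function(q, prior, loglik) {
  accuracy <- contract_dims(loglik, q, keep = 0L)
  complexity <- sum(vapply(seq_along(q), function(f) {
    sum(q[[f]] * (ln_safe(q[[f]]) - ln_safe(prior[[f]])))
  }, numeric(1)))
  list(F = complexity - accuracy, accuracy = accuracy, complexity = complexity)
}

#' Infer hidden states by fixed-point iteration
#'
#' Minimises the time-specific variational free energy over the mean-field
#' posterior by coordinate ascent: each factor's posterior is updated to
#' `softmax(E_{q\\f}[ln p(o|s)] + ln prior_f)` in ascending factor order,
#' sweeping until the change in free energy falls below `tolerance` or
#' `max_iterations` sweeps are exhausted. The sweep is initialised at the
#' prior, so a single-factor model converges (to the exact posterior) in
#' one sweep.
#'
#' @param A Observation model (expected likelihood when learning).
#' @param prior List of per-factor prior vectors (the predictive prior from
#'   [transition_prior()], or D at the first time step).
#' @param obs Integer observation vector, one entry per modality.
#' @param settings An [inference_settings()] object.
#' @return A list with elements `qs` (posterior list), `F` (free energy at
#'   the fixed point), `iterations`, and `degenerate` (TRUE when the
#'   observation had zero likelihood under every state and the posterior
#'   fell back to the prior, with a warning).
#' @export
infer_states <- function(A, prior, obs, settings = inference_settings()) {
  loglik <- joint_log_likelihood(A, obs)
  nf <- length(prior)
  ns <- vapply(prior, length, integer(1))
  # all-floored likelihood: no state explains the observation at all
  if (max(loglik) <= length(A) * log(PROB_FLOOR) + 1e-9) {
    warning("observation has zero likelihood under all states; posterior falls back to the prior")
    fe <- free_energy(prior, prior, loglik)
    return(list(qs = prior, F = fe$F, iterations = 0L, degenerate = TRUE))
  }
  qs <- lapply(prior, normalise)
  F_prev <- free_energy(qs, prior, loglik)$F
  iters <- 0L
  for (it in seq_len(settings$max_iterations)) {
    for (f in seq_len(nf)) {
      lnq <- contract_dims(loglik, qs, keep = f) + ln_safe(prior[[f]])
      qs[[f]] <- softmax(lnq)
    }
    iters <- it
    F_now <- free_energy(qs, prior, loglik)$F
    if (abs(F_prev - F_now) < settings$tolerance) {
      F_prev <- F_now
      break
    }
    F_prev <- F_now
  }
  list(qs = qs, F = F_prev, iterations = iters, degenerate = FALSE)
}
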