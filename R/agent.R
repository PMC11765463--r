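# The agent: bundles model components, Dirichlet counts, dynamic beliefs,
# hyper-parameters and settings, and runs the per-step action-perception
# cycle (state inference -> parameter learning -> policy inference ->
# action sampling), recording histories.

#' Initialise an active inference agent
#'
#' A and B are the only mandatory model components; omitted C, D and E
#' default to uninformative priors (zero log-preferences, uniform state
#' prior, uniform habit prior). Supplying Dirichlet counts (`pA`, `pB`,
#' `pD`) switches on parameter learning for that component: the expected
#' (normalised) counts then stand in for the corresponding component during
#' inference and are updated at every step.
#'
#' @param A Observation model: list of per-modality likelihood arrays.
#' @param B Transition model: list of per-factor transition arrays.
#' @param C Preference prior (list of log-preference vectors) or `NULL`.
#' @param D State prior (list of probability vectors) or `NULL`.
#' @param E Habit prior over policies or `NULL`.
#' @param pA,pB,pD Dirichlet count lists for learned components, or `NULL`.
#' @param hyper An [hyperparameters()] object.
#' @param settings An [planning_settings()] object.
#' @param inference An [inference_settings()] object.
#' @return An object of class `aif_agent`.
#' @export
init_agent <- function(A, B, C = NULL, D = NULL, E = NULL,
                       pA = NULL, pB = NULL, pD = NULL,
                       hyper = hyperparameters(),
                       settings = planning_settings(),
                       inference = inference_settings()) {
  num_obs <- vapply(A, function(a) dim(a)[1], integer(1))
  num_states <- vapply(B, function(b) dim(b)[1], integer(1))
  num_controls <- vapply(B, function(b) dim(b)[3], integer(1))
  shape <- model_shape(num_obs, num_states, num_controls,
                       settings$policy_length)
  if (is.null(C)) C <- lapply(num_obs, numeric)
  if (is.null(D)) D <- lapply(num_states, function(n) rep(1 / n, n))
  policies <- construct_policies(num_controls, settings$policy_length)
  if (is.null(E)) E <- rep(1 / length(policies), length(policies))
  viol <- validate_model(A, B, C, D, E, shape)
  if (length(viol) > 0)
    stop("invalid model components:\n  ", paste(viol, collapse = "\n  "))
  counts <- dirichlet_counts(A = pA, B = pB, D = pD)
  agent <- structure(list(
    shape = shape, A = A, B = B, C = C, D = D, E = E,
    counts = counts, policies = policies,
    hyper = hyper, settings = settings, inference = inference,
    qs = NULL, prev_action = NULL, q_pi = NULL, t = 0L,
    history = list(beliefs = list(), actions = list(),
                   observations = list(), free_energy = numeric(0),
                   action_probs = list())),
    class = "aif_agent")
  refresh_expected(agent)
}

# Recompute the expected model components from the Dirichlet counts.
refresh_expected <- function(agent) {
  exp_m <- dirichlet_expected(agent$counts)
  agent$A_eff <- if (!is.null(exp_m$A)) exp_m$A else agent$A
  agent$B_eff <- if (!is.null(exp_m$B)) exp_m$B else agent$B
  agent$D_eff <- if (!is.null(exp_m$D)) exp_m$D else agent$D
  agent
}

# Indices of modalities/factors actually learned this step.
learned_idx <- function(setting, counts_part) {
  if (is.null(counts_part)) return(integer(0))
  if (is.null(setting)) seq_along(counts_part) else as.integer(setting)
}

#' @export
print.aif_agent <- function(x, ...) {
  cat("Active inference agent\n")
  print(x$shape)
  cat("  policies:", length(x$policies), "\n")
  cat("  learning:",
      paste(c("A", "B", "D")[!vapply(x$counts[c("A", "B", "D")], is.null,
                                     logical(1))], collapse = " "),
      "\n")
  cat("  steps taken:", x$t, "\n")
  invisible(x)
}

# Policy inference: EFE for every policy, policy posterior, action
# marginals. Returns list(G, q_pi, action_probs, efe) without mutating.
infer_policies <- function(agent) {
  n_pol <- length(agent$policies)
  G <- numeric(n_pol)
  efe <- vector("list", n_pol)
  for (i in seq_len(n_pol)) {
    efe[[i]] <- expected_free_energy(
      agent$A_eff, agent$B_eff, agent$C, agent$qs, agent$policies[[i]],
      settings = agent$settings, counts_A = agent$counts$A)
    G[i] <- efe[[i]]$G
  }
  q_pi <- policy_posterior(G, agent$E, agent$hyper$gamma)
  action_probs <- marginal_action_probabilities(q_pi, agent$policies,
                                                agent$shape$num_controls)
  list(G = G, q_pi = q_pi, action_probs = action_probs, efe = efe)
}

#' Update an agent with an observation, without sampling an action
#'
#' Runs one action-perception cycle up to (but not including) action
#' sampling: state inference, parameter learning and policy inference. The
#' returned agent carries the marginal action probabilities in
#' `$last_action_probs` (and the policy posterior in `$q_pi`), which is
#' what the fitting module scores observed actions against. [step_agent()]
#' is this plus action sampling and history bookkeeping.
#'
#' @param agent An `aif_agent`.
#' @param obs Integer observation vector.
#' @return The updated agent.
#' @export
agent_update <- function(agent, obs) {
  first <- is.null(agent$prev_action)
  prior <- if (first) {
    agent$D_eff
  } else {
    transition_prior(agent$B_eff, agent$qs, agent$prev_action)
  }
  q_prev <- agent$qs
  inf <- infer_states(agent$A_eff, prior, obs, agent$inference)
  agent$qs <- inf$qs
  # learning (counts present => learned), before policy inference
  if (!is.null(agent$counts$A)) {
    agent$counts$A <- update_A_counts(
      agent$counts$A, obs, agent$qs, agent$hyper$eta_A, agent$hyper$omega,
      learned_idx(agent$settings$learned_modalities, agent$counts$A))
  }
  if (!is.null(agent$counts$B) && !first) {
    agent$counts$B <- update_B_counts(
      agent$counts$B, agent$qs, q_prev, agent$prev_action,
      agent$hyper$eta_B, agent$hyper$omega,
      learned_idx(agent$settings$learned_factors_B, agent$counts$B))
  }
  if (!is.null(agent$counts$D) && first) {
    agent$counts$D <- update_D_counts(
      agent$counts$D, agent$qs, agent$hyper$eta_D, agent$hyper$omega,
      learned_idx(agent$settings$learned_factors_D, agent$counts$D))
  }
  agent <- refresh_expected(agent)
  pol <- infer_policies(agent)
  agent$q_pi <- pol$q_pi
  agent$last_G <- pol$G
  agent$last_action_probs <- pol$action_probs
  agent$last_F <- inf$F
  agent$last_obs <- obs
  agent
}

# Record the completed step in the histories and advance time.
agent_commit <- function(agent, action) {
  agent$prev_action <- action
  agent$t <- agent$t + 1L
  h <- agent$history
  h$beliefs[[agent$t]] <- agent$qs
  h$actions[[agent$t]] <- action
  h$observations[[agent$t]] <- agent$last_obs
  h$free_energy[agent$t] <- agent$last_F
  h$action_probs[[agent$t]] <- agent$last_action_probs
  agent$history <- h
  agent
}

#' Reset an agent's dynamic beliefs at a trial boundary
#'
#' Clears the current posterior and previous action so that the next
#' observation is inferred against the state prior D, exactly as at the
#' agent's very first step. Learned Dirichlet counts and all histories are
#' kept: this is the within-task trial structure of episodic paradigms
#' (each trial restarts the state, not the agent's knowledge).
#'
#' @param agent An `aif_agent`.
#' @return The agent with trial-local state cleared.
#' @export
reset_beliefs <- function(agent) {
  agent$qs <- NULL
  agent$prev_action <- NULL
  agent
}

#' Run one step of the action-perception loop
#'
#' Given an observation, performs state inference (fixed-point iteration),
#' Dirichlet parameter updates for any learned components, expected free
#' energy evaluation over all policies, the policy posterior and action
#' marginals, then samples an action under the action precision. Histories
#' of beliefs, observations, actions, free energies and action marginals
#' grow by one record. Uses R's global random number stream for the action
#' sample.
#'
#' @param agent An [init_agent()] object.
#' @param obs Integer observation vector, one entry per modality.
#' @return A list with elements `action` (integer vector, one entry per
#'   factor) and `agent` (the updated agent).
#' @export
step_agent <- function(agent, obs) {
  agent <- agent_update(agent, obs)
  action <- sample_action(agent$last_action_probs, agent$hyper$alpha)
  agent <- agent_commit(agent, action)
  list(action = action, agent = agent)
}

#' Get an agent hyper-parameter or setting
#'
#' @param agent An `aif_agent`.
#' @param name One of `"gamma"`, `"alpha"`, `"eta_A"`, `"eta_B"`,
#'   `"eta_D"`, `"omega"`, `"policy_length"`.
#' @return The parameter value.
#' @export
get_parameter <- function(agent, name) {
  if (name %in% names(agent$hyper)) return(agent$hyper[[name]])
  if (name %in% names(agent$settings)) return(agent$settings[[name]])
  stop(sprintf("unknown parameter '%s'", name))
}

#' Set an agent hyper-parameter
#'
#' Re-validates through the [hyperparameters()] constructor, so out-of-range
#' values (e.g. a negative precision) raise an error.
#'
#' @param agent An `aif_agent`.
#' @param name Hyper-parameter name (see [hyperparameters()]).
#' @param value New value.
#' @return The updated agent.
#' @export
set_parameter <- function(agent, name, value) {
  if (!name %in% names(agent$hyper))
    stop(sprintf("unknown parameter '%s'", name))
  h <- unclass(agent$hyper)
  h[[name]] <- value
  agent$hyper <- do.call(hyperparameters, h)
  agent
}

#' Extract a recorded history from an agent
#'
#' @param agent An `aif_agent`.
#' @param what One of `"beliefs"`, `"actions"`, `"observations"`,
#'   `"free_energy"`, `"action_probs"`.
#' @return The requested history (a list or numeric vector with one entry
#'   per completed step).
#' @export
get_history <- function(agent, what = c("beliefs", "actions", "observations",
                                        "free_energy", "action_probs")) {
  what <- match.arg(what)
  agent$history[[what]]
}
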