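# Planning: score policies by expected free energy (EFE), form the policy
# posterior under the policy precision gamma, marginalise to per-factor
# action probabilities and sample an action under the action precision
# alpha.
#
# Sign convention: G is stored as the expected free energy (lower is
# better); the policy posterior softmax uses -gamma * G.

#' Agent hyper-parameters
#'
#' @param gamma Policy precision: inverse temperature of the softmax over
#'   (negative) expected free energies. Default 16.
#' @param alpha Action precision: inverse temperature of the softmax over
#'   marginal action probabilities; higher values give more deterministic
#'   action selection. Default 16.
#' @param eta_A,eta_B,eta_D Learning rates in (0, 1] for the Dirichlet
#'   updates of A, B and D. Default 1.
#' @param omega Forgetting rate in (0, 1] multiplying existing counts at
#'   each update. Default 1 (no forgetting).
#' @return An object of class `aif_hyper`.
#' @export
hyperparameters <- function(gamma = 16, alpha = 16,
                            eta_A = 1, eta_B = 1, eta_D = 1, omega = 1) {
  check_scalar(gamma, "gamma", lower = 0, strict_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0, strict_lower = TRUE)
  for (nm in c("eta_A", "eta_B", "eta_D", "omega")) {
    check_scalar(get(nm), nm, lower = 0, upper = 1, strict_lower = TRUE)
  }
  structure(list(gamma = gamma, alpha = alpha, eta_A = eta_A, eta_B = eta_B,
                 eta_D = eta_D, omega = omega),
            class = "aif_hyper")
}

#' Planning settings
#'
#' @param policy_length Planning horizon (length of the enumerated
#'   policies).
#' @param use_state_info_gain Include the epistemic (state information
#'   gain) term in the EFE. Default TRUE.
#' @param use_param_info_gain Include the Dirichlet-novelty (parameter
#'   information gain) term. Default FALSE; only meaningful when A counts
#'   are being learned.
#' @param learned_modalities Integer indices of the A modalities subject to
#'   learning (and contributing parameter information gain). `NULL` means
#'   all modalities whenever A counts are present.
#' @param learned_factors_B,learned_factors_D Integer indices of the
#'   factors whose B / D counts are learned; `NULL` means all.
#' @return An object of class `aif_planning_settings`.
#' @export
planning_settings <- function(policy_length = 1L,
                              use_state_info_gain = TRUE,
                              use_param_info_gain = FALSE,
                              learned_modalities = NULL,
                              learned_factors_B = NULL,
                              learned_factors_D = NULL) {
  check_scalar(policy_length, "policy_length", lower = 1)
  structure(list(policy_length = as.integer(policy_length),
                 use_state_info_gain = isTRUE(use_state_info_gain),
                 use_param_info_gain = isTRUE(use_param_info_gain),
                 learned_modalities = learned_modalities,
                 learned_factors_B = learned_factors_B,
                 learned_factors_D = learned_factors_D),
            class = "aif_planning_settings")
}

#' Roll out expected states under a policy
#'
#' Applies the action-conditioned transition model step by step, starting
#' from the current posterior, to obtain the predicted state distribution
#' at each step of the policy.
#'
#' @param B Transition model.
#' @param current List of per-factor posterior vectors.
#' @param policy A `policy_length` x `num_factors` integer matrix of action
#'   indices.
#' @return A list of belief lists, one per roll-out step.
#' @export
expected_states <- function(B, current, policy) {
  out <- vector("list", nrow(policy))
  q <- current
  for (t in seq_len(nrow(policy))) {
    q <- transition_prior(B, q, policy[t, ])
    out[[t]] <- q
  }
  out
}

#' Predicted observation distributions
#'
#' Marginalises the observation model over a (mean-field) state belief:
#' `q(o_m) = sum_s A_m[o_m, s] prod_f q(s^f)`.
#'
#' @param A Observation model.
#' @param predicted List of per-factor state probability vectors.
#' @return List of per-modality observation probability vectors.
#' @export
expected_observations <- function(A, predicted) {
  lapply(A, function(Am) {
    d <- dim(Am)
    qs_full <- c(list(rep(1, d[1])), predicted)
    qo <- contract_dims(Am, qs_full, keep = 1L)
    qo / sum(qo)
  })
}

# Per-state-combination entropy of each modality's likelihood columns,
# contracted with the predicted state belief: E_{q(s)} H[p(o|s)].
expected_ambiguity <- function(A, predicted) {
  sum(vapply(A, function(Am) {
    d <- dim(Am)
    m <- matrix(Am, nrow = d[1])
    ent <- -colSums(m * ln_safe(m) * (m > 0))
    ent_arr <- array(ent, dim = d[-1])
    contract_dims(ent_arr, predicted, keep = 0L)
  }, numeric(1)))
}

#' Expected state information gain
#'
#' The mutual information between hidden states and observations implied by
#' a predicted state belief: per modality, `H[q(o)] - E_{q(s)} H[p(o|s)]`,
#' summed over modalities. Always non-negative; zero when observations are
#' uninformative (column-constant A) or when the state belief is already a
#' delta.
#'
#' @param A Observation model.
#' @param predicted List of per-factor state probability vectors.
#' @return A non-negative scalar.
#' @export
state_info_gain <- function(A, predicted) {
  qo <- expected_observations(A, predicted)
  h_obs <- sum(vapply(qo, entropy, numeric(1)))
  max(h_obs - expected_ambiguity(A, predicted), 0)
}

#' Pragmatic value of predicted observations
#'
#' Expected log-preference of the predicted observations:
#' `sum_m sum_o q(o_m) ln softmax(C_m)[o_m]`. C is stored as unnormalised
#' log-preferences and normalised through a softmax only here.
#'
#' @param q_obs List of per-modality predicted observation distributions.
#' @param C Preference prior (list of log-preference vectors).
#' @return A scalar (non-positive, since log-probabilities are negative).
#' @export
pragmatic_value <- function(q_obs, C) {
  sum(vapply(seq_along(q_obs), function(m) {
    sum(q_obs[[m]] * ln_safe(softmax(C[[m]])))
  }, numeric(1)))
}

#' Parameter (Dirichlet novelty) information gain
#'
#' Expected reduction in uncertainty about the learned likelihood
#' parameters. For each learned modality the novelty of entry (o, s) is
#' `w(o, s) = (1/theta(o,s) - 1/sum_o' theta(o',s)) / 2`, and the value is
#' the expectation of `w` under the predicted observation and state
#' distributions. Entries with zero counts (within a positive column)
#' contribute nothing. Non-negative, and vanishing as counts grow.
#'
#' @param counts_A List of per-modality Dirichlet count arrays.
#' @param predicted List of per-factor predicted state vectors.
#' @param q_obs List of per-modality predicted observation vectors.
#' @param learned_modalities Integer indices of learned modalities.
#' @return A non-negative scalar (subtracted from G by the caller).
#' @export
param_info_gain <- function(counts_A, predicted, q_obs, learned_modalities) {
  total <- 0
  for (m in learned_modalities) {
    th <- counts_A[[m]]
    d <- dim(th)
    mt <- matrix(th, nrow = d[1])
    cs <- colSums(mt)
    if (any(cs <= 0))
      stop(sprintf("degenerate Dirichlet counts: all-zero column in counts_A[%d]", m))
    w <- 0.5 * (1 / mt - matrix(1 / cs, nrow = d[1], ncol = ncol(mt), byrow = TRUE))
    w[mt == 0] <- 0
    w_over_o <- array(0, dim = d[-1])
    for (o in seq_len(d[1])) {
      w_o <- array(w[o, ], dim = d[-1])
      w_over_o <- w_over_o + q_obs[[m]][o] * w_o
    }
    total <- total + contract_dims(w_over_o, predicted, keep = 0L)
  }
  total
}

#' Expected free energy of one policy
#'
#' Rolls predicted states and observations out over the policy and
#' accumulates, per step, the negative state information gain, negative
#' pragmatic value and negative parameter information gain (terms disabled
#' in `settings` contribute zero). The equivalent risk + ambiguity
#' decomposition is computed alongside: risk is the KL divergence of
#' predicted observations from the (softmax-normalised) preference prior,
#' ambiguity the expected entropy of the likelihood.
#'
#' @param A,B,C Model components (the expected A under learning).
#' @param current List of per-factor posterior vectors at the current step.
#' @param policy Integer action matrix (steps x factors).
#' @param settings An [planning_settings()] object.
#' @param counts_A Dirichlet counts over A (required when
#'   `use_param_info_gain` is on).
#' @return A list with elements `G`, `info_gain`, `pragmatic_value`,
#'   `param_info_gain`, `risk`, `ambiguity`, `states`, `observations`.
#' @export
expected_free_energy <- function(A, B, C, current, policy,
                                 settings = planning_settings(nrow(policy)),
                                 counts_A = NULL) {
  states <- expected_states(B, current, policy)
  observations <- lapply(states, function(qs) expected_observations(A, qs))
  lm <- settings$learned_modalities
  if (is.null(lm) && !is.null(counts_A)) lm <- seq_along(counts_A)
  ig_tot <- pv_tot <- pig_tot <- risk_tot <- amb_tot <- 0
  for (t in seq_along(states)) {
    qs <- states[[t]]
    qo <- observations[[t]]
    ig <- if (settings$use_state_info_gain) state_info_gain(A, qs) else 0
    pv <- pragmatic_value(qo, C)
    pig <- if (settings$use_param_info_gain && !is.null(counts_A) &&
               length(lm) > 0) {
      param_info_gain(counts_A, qs, qo, lm)
    } else 0
    ig_tot <- ig_tot + ig
    pv_tot <- pv_tot + pv
    pig_tot <- pig_tot + pig
    amb_tot <- amb_tot + expected_ambiguity(A, qs)
    risk_tot <- risk_tot + sum(vapply(seq_along(qo), function(m) {
      sum(qo[[m]] * (ln_safe(qo[[m]]) - ln_safe(softmax(C[[m]]))) * (qo[[m]] > 0))
    }, numeric(1)))
  }
  list(G = -ig_tot - pv_tot - pig_tot,
       info_gain = ig_tot, pragmatic_value = pv_tot,
       param_info_gain = pig_tot, risk = risk_tot, ambiguity = amb_tot,
       states = states, observations = observations)
}

#' Posterior over policies
#'
#' `q(pi) = softmax(ln E - gamma * G)`: the habit prior enters on the log
#' scale, so that `gamma = 0` recovers the habit prior exactly, and lower
#' expected free energy makes a policy more likely.
#'
#' @param G Numeric vector of expected free energies, one per policy.
#' @param E Habit prior (probability vector over policies).
#' @param gamma Policy precision (non-negative).
#' @return Probability vector over policies.
#' @export
policy_posterior <- function(G, E, gamma) {
  if (length(G) != length(E)) stop("G and E must have the same length")
  check_scalar(gamma, "gamma", lower = 0)
  softmax(ln_safe(E) - gamma * G)
}

#' Marginal action probabilities
#'
#' Marginalises the policy posterior onto the first-step action of each
#' controllable factor.
#'
#' @param q_pi Probability vector over policies.
#' @param policies List of policy matrices (as from [construct_policies()]).
#' @param num_controls Integer vector of actions per factor.
#' @return List of per-factor probability vectors over actions.
#' @export
marginal_action_probabilities <- function(q_pi, policies, num_controls) {
  if (length(q_pi) != length(policies))
    stop("policy posterior and policy list lengths differ")
  lapply(seq_along(num_controls), function(f) {
    p <- numeric(num_controls[f])
    for (i in seq_along(policies)) {
      u <- policies[[i]][1, f]
      p[u] <- p[u] + q_pi[i]
    }
    p / sum(p)
  })
}

#' Sample an action under the action precision
#'
#' Per factor, samples from `softmax(alpha * ln p)` (proportional to
#' `p^alpha`): `alpha = 1` reproduces the marginal probabilities, large
#' `alpha` approaches the argmax. Uses R's global random number stream;
#' seed with [set.seed()] for reproducibility.
#'
#' @param action_probs List of per-factor action probability vectors.
#' @param alpha Action precision (> 0).
#' @return Integer vector of sampled action indices, one per factor.
#' @export
sample_action <- function(action_probs, alpha) {
  check_scalar(alpha, "alpha", lower = 0, strict_lower = TRUE)
  vapply(action_probs, function(p) {
    sharp <- softmax(alpha * ln_safe(p))
    sample.int(length(p), 1L, prob = sharp)
  }, integer(1))
}
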