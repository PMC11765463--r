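# Dirichlet parameter learning: concentration-parameter updates for the
# observation model (A), transition model (B) and state prior (D).
#
# All updates follow theta' = omega * theta + eta * chi, where chi is the
# observed-data count realised as an outer product of the relevant onehot /
# posterior vectors. Forgetting (omega < 1) applies to the entire learned
# component at each update; non-learned components are never touched.

#' Update A counts from an observation and state posterior
#'
#' For each learned modality m the count slice for the observed category
#' receives the joint (product-of-factors) state posterior:
#' `counts[o_m, s] <- omega * counts[o_m, s] + eta * prod_f q(s^f)`; all
#' other entries of the learned modality are scaled by `omega`.
#'
#' @param counts_A List of per-modality count arrays.
#' @param obs Integer observation vector.
#' @param q List of per-factor posterior vectors (the beliefs that
#'   generated the observation).
#' @param eta Learning rate in (0, 1].
#' @param omega Forgetting rate in (0, 1].
#' @param learned_modalities Integer indices of modalities to update.
#' @return The updated list of count arrays.
#' @export
update_A_counts <- function(counts_A, obs, q, eta = 1, omega = 1,
                            learned_modalities = seq_along(counts_A)) {
  joint <- outer_list(q)
  for (m in learned_modalities) {
    d <- dim(counts_A[[m]])
    if (obs[m] < 1 || obs[m] > d[1])
      stop(sprintf("observation index %d out of bounds for modality %d",
                   obs[m], m))
    cnt <- counts_A[[m]] * omega
    mt <- matrix(cnt, nrow = d[1])
    mt[obs[m], ] <- mt[obs[m], ] + eta * as.vector(joint)
    counts_A[[m]] <- array(mt, dim = d)
  }
  counts_A
}

#' Update B counts from consecutive state posteriors
#'
#' For each learned factor f, the slice of the action taken receives the
#' outer product of the current and previous posteriors:
#' `counts[, , u_f] <- omega * counts[, , u_f] + eta * q_now q_prev^T`
#' (with the rest of the learned factor scaled by `omega`).
#'
#' @param counts_B List of per-factor count arrays.
#' @param q_now,q_prev Posterior lists at the current and previous step.
#' @param action Integer action vector (one entry per factor).
#' @param eta,omega Learning and forgetting rates.
#' @param learned_factors Integer indices of factors to update.
#' @return The updated list of count arrays.
#' @export
update_B_counts <- function(counts_B, q_now, q_prev, action, eta = 1,
                            omega = 1, learned_factors = seq_along(counts_B)) {
  for (f in learned_factors) {
    nu <- dim(counts_B[[f]])[3]
    if (action[f] < 1 || action[f] > nu)
      stop(sprintf("action index %d out of bounds for factor %d", action[f], f))
    cnt <- counts_B[[f]] * omega
    cnt[, , action[f]] <- cnt[, , action[f]] +
      eta * (q_now[[f]] %o% q_prev[[f]])
    counts_B[[f]] <- cnt
  }
  counts_B
}

#' Update D counts from the first-step posterior
#'
#' `counts <- omega * counts + eta * q_first`, per learned factor. Applied
#' once per episode, at the first time step.
#'
#' @param counts_D List of per-factor count vectors.
#' @param q_first Posterior list at the first time step.
#' @param eta,omega Learning and forgetting rates.
#' @param learned_factors Integer indices of factors to update.
#' @return The updated list of count vectors.
#' @export
update_D_counts <- function(counts_D, q_first, eta = 1, omega = 1,
                            learned_factors = seq_along(counts_D)) {
  for (f in learned_factors) {
    counts_D[[f]] <- omega * counts_D[[f]] + eta * q_first[[f]]
  }
  counts_D
}
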