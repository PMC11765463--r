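# Independent brute-force oracles used to check the variational machinery,
# plus random-model generators. All enumeration here works on the flat
# joint state space, independently of the package's mean-field code paths.

# Random column-stochastic array with first-axis categories.
rand_stochastic <- function(dims) {
  arr <- array(stats::rgamma(prod(dims), shape = 1), dim = dims)
  m <- matrix(arr, nrow = dims[1])
  array(sweep(m, 2, colSums(m), `/`), dim = dims)
}

rand_prob <- function(n) {
  x <- stats::rgamma(n, shape = 1)
  x / sum(x)
}

# A random multi-modality, multi-factor model of given dimensions.
rand_model <- function(num_obs, num_states) {
  list(A = lapply(num_obs, function(no) rand_stochastic(c(no, num_states))),
       prior = lapply(num_states, rand_prob))
}

# Joint likelihood p(o | s) over the flat state space, by direct product.
enum_likelihood <- function(A, obs, num_states) {
  lik <- array(1, dim = num_states)
  for (m in seq_along(A)) {
    sel <- matrix(A[[m]], nrow = dim(A[[m]])[1])[obs[m], ]
    lik <- lik * array(sel, dim = num_states)
  }
  lik
}

# Exact joint posterior and evidence by enumeration.
enum_posterior <- function(A, prior, obs) {
  num_states <- vapply(prior, length, integer(1))
  lik <- enum_likelihood(A, obs, num_states)
  joint_prior <- prior[[1]]
  if (length(prior) > 1) for (p in prior[-1]) joint_prior <- outer(joint_prior, p)
  joint <- array(joint_prior, dim = num_states) * lik
  evidence <- sum(joint)
  list(posterior = joint / evidence, evidence = evidence)
}

# Marginal of a joint array onto one factor.
enum_marginal <- function(joint, f) {
  as.vector(apply(joint, f, sum))
}

# Brute-force variational free energy: sum over the flat state space of
# q(s) [ln q(s) - ln p(o, s)] with q the product of per-factor beliefs.
enum_free_energy <- function(q, prior, A, obs) {
  num_states <- vapply(prior, length, integer(1))
  qj <- q[[1]]
  if (length(q) > 1) for (v in q[-1]) qj <- outer(qj, v)
  qj <- array(qj, dim = num_states)
  pj <- prior[[1]]
  if (length(prior) > 1) for (v in prior[-1]) pj <- outer(pj, v)
  pj <- array(pj, dim = num_states)
  lik <- enum_likelihood(A, obs, num_states)
  joint <- pj * lik
  lj <- log(pmax(joint, 1e-300))
  sum(qj * (log(pmax(qj, 1e-300)) - lj), na.rm = TRUE)
}

# A tiny deterministic two-state model used in several tests.
two_state_A <- function(p = 0.9) list(matrix(c(p, 1 - p, 1 - p, p), 2, 2))
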