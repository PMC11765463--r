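# Policy evaluation: roll-outs, predicted observations, information gain,
# pragmatic value, Dirichlet novelty, the two EFE decompositions, policy
# posterior, action marginals and action sampling.

test_that("expected states roll the transition model forward", {
  B <- list(array(diag(3), c(3, 3, 2)))
  q <- list(c(0.2, 0.5, 0.3))
  roll <- expected_states(B, q, matrix(c(1, 2), 2, 1))
  expect_equal(roll[[1]][[1]], q[[1]])
  expect_equal(roll[[2]][[1]], q[[1]])

  # T-maze: (cue, left arm) from centre visits cue then the left arm
  mod <- tmaze_model()
  roll <- expected_states(mod$B, list(onehot(1, 4), c(0.5, 0.5)),
                          matrix(c(4, 3, 1, 1), 2, 2))
  expect_equal(roll[[1]][[1]], onehot(4, 4))
  expect_equal(roll[[2]][[1]], onehot(3, 4))

  # 2-state chain equals the repeated matrix product
  P <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2)
  B2 <- list(array(P, c(2, 2, 1)))
  q0 <- c(1, 0)
  roll <- expected_states(B2, list(q0), matrix(1, 2, 1))
  expect_equal(roll[[1]][[1]], as.vector(P %*% q0))
  expect_equal(roll[[2]][[1]], as.vector(P %*% P %*% q0))
})

test_that("predicted observations marginalise the likelihood", {
  expect_equal(expected_observations(list(diag(3)), list(onehot(2, 3)))[[1]],
               onehot(2, 3))
  expect_equal(expected_observations(list(matrix(0.25, 4, 3)),
                                     list(rand_prob(3)))[[1]], rep(0.25, 4))
  expect_equal(expected_observations(two_state_A(0.9),
                                     list(c(0.5, 0.5)))[[1]], c(0.5, 0.5))
  # multi-factor tensor against direct enumeration
  set.seed(5)
  A <- list(rand_stochastic(c(3, 4, 2)))
  qs <- list(rand_prob(4), rand_prob(2))
  direct <- numeric(3)
  for (o in 1:3) for (i in 1:4) for (j in 1:2) {
    direct[o] <- direct[o] + A[[1]][o, i, j] * qs[[1]][i] * qs[[2]][j]
  }
  expect_equal(expected_observations(A, qs)[[1]], direct, tolerance = 1e-12)
})

test_that("state information gain is the state-observation mutual information", {
  expect_equal(state_info_gain(list(matrix(0.2, 5, 3)), list(rand_prob(3))), 0)
  expect_equal(state_info_gain(list(diag(3)), list(onehot(1, 3))), 0)
  expect_equal(state_info_gain(list(diag(2)), list(c(0.5, 0.5))), log(2),
               tolerance = 1e-12)
  # non-negative on random models
  set.seed(13)
  for (i in 1:50) {
    A <- list(rand_stochastic(c(3, 4)))
    expect_gte(state_info_gain(A, list(rand_prob(4))), 0)
  }
})

test_that("pragmatic value scores predicted observations on softmax(C)", {
  for (m in c(2, 4)) {
    qo <- list(rand_prob(m))
    expect_equal(pragmatic_value(qo, list(numeric(m))), -log(m),
                 tolerance = 1e-12)
  }
  C <- list(c(0, 3, -3))
  expect_equal(pragmatic_value(list(onehot(2, 3)), C),
               log(exp(3) / (exp(0) + exp(3) + exp(-3))), tolerance = 1e-12)
  # additivity across modalities
  qo <- list(rep(1 / 3, 3), rep(0.25, 4))
  expect_equal(pragmatic_value(qo, list(numeric(3), numeric(4))),
               -log(3) - log(4), tolerance = 1e-12)
})

test_that("parameter info gain follows the Dirichlet novelty formula", {
  mod <- tmaze_model()
  counts <- lapply(mod$A, function(a) a * 2)
  qs <- list(rep(0.25, 4), c(0.5, 0.5))
  qo <- expected_observations(mod$A, qs)
  got <- param_info_gain(counts, qs, qo, 2L)
  # brute-force evaluation of E[w(o,s)] with zero-count entries inert
  th <- counts[[2]]
  csum <- apply(th, c(2, 3), sum)
  w <- array(0, dim(th))
  for (o in 1:3) for (i in 1:4) for (j in 1:2) {
    if (th[o, i, j] > 0)
      w[o, i, j] <- 0.5 * (1 / th[o, i, j] - 1 / csum[i, j])
  }
  want <- 0
  for (o in 1:3) for (i in 1:4) for (j in 1:2) {
    want <- want + qo[[2]][o] * qs[[1]][i] * qs[[2]][j] * w[o, i, j]
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_gte(got, 0)
  # vanishes in the well-learned limit
  big <- lapply(counts, function(a) a * 1e6)
  expect_lt(param_info_gain(big, qs, qo, 2L), 1e-5)
  # unlearned modalities contribute exactly zero
  expect_equal(param_info_gain(counts, qs, qo, integer(0)), 0)
  zero <- counts
  zero[[2]][, 1, 1] <- 0
  expect_error(param_info_gain(zero, qs, qo, 2L), "degenerate")
})

test_that("EFE closed forms hold and both decompositions agree", {
  # uniform A, neutral C: G is pure ambiguity, T * sum_m ln m
  for (L in 1:2) {
    A <- list(matrix(1 / 3, 3, 2), matrix(1 / 4, 4, 2))
    B <- list(array(diag(2), c(2, 2, 1)))
    C <- list(numeric(3), numeric(4))
    res <- expected_free_energy(A, B, C, list(c(0.5, 0.5)),
                                matrix(1, L, 1),
                                planning_settings(policy_length = L))
    expect_equal(res$G, L * (log(3) + log(4)), tolerance = 1e-10)
    expect_equal(res$risk, 0, tolerance = 1e-10)
    expect_equal(res$info_gain, 0, tolerance = 1e-10)
  }
  # identity A, neutral C, delta beliefs: nothing to gain, nothing to risk
  res <- expected_free_energy(list(diag(2)), list(array(diag(2), c(2, 2, 1))),
                              list(c(0, 0)), list(onehot(1, 2)),
                              matrix(1, 1, 1))
  expect_equal(res$G, log(2), tolerance = 1e-10)  # neutral C: -ln(1/2)
  expect_equal(res$info_gain + res$ambiguity, 0, tolerance = 1e-10)

  # epistemic-pragmatic and risk-ambiguity forms agree on random models
  set.seed(17)
  for (i in 1:200) {
    ns <- sample(2:4, sample(1:2, 1), replace = TRUE)
    no <- sample(2:4, sample(1:2, 1), replace = TRUE)
    mod <- rand_model(no, ns)
    B <- lapply(ns, function(n) {
      nu <- sample(1:2, 1)
      arr <- array(0, c(n, n, nu))
      for (u in seq_len(nu)) arr[, , u] <- rand_stochastic(c(n, n))
      arr
    })
    C <- lapply(no, function(n) log(rand_prob(n)))  # normalised preferences
    L <- sample(1:2, 1)
    pol <- matrix(vapply(seq_along(B), function(f)
      sample(dim(B[[f]])[3], L, replace = TRUE), integer(L)), L)
    res <- expected_free_energy(mod$A, B, C, mod$prior, pol,
                                planning_settings(policy_length = L))
    lhs <- -res$info_gain - res$pragmatic_value
    expect_equal(lhs, res$risk + res$ambiguity, tolerance = 1e-10)
    expect_equal(res$G, lhs, tolerance = 1e-12)
  }
})

test_that("policy posterior composes habits and precision-weighted EFE", {
  E <- c(0.7, 0.3)
  expect_equal(policy_posterior(c(5, 1), E, 0), E, tolerance = 1e-12)
  expect_equal(policy_posterior(c(2, 2, 2), rep(1 / 3, 3), 16),
               rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(policy_posterior(c(1, 2), c(0.5, 0.5), 1),
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-4)
  expect_equal(round(policy_posterior(c(1, 2), c(0.5, 0.5), 1), 4),
               c(0.7311, 0.2689))
})

test_that("sharper preferences never demote preference-seeking policies", {
  set.seed(29)
  for (i in 1:30) {
    mod <- rand_model(num_obs = 3, num_states = 3)
    B <- list(array(0, c(3, 3, 3)))
    for (u in 1:3) B[[1]][, , u] <- rand_stochastic(c(3, 3))
    pols <- construct_policies(3, 1)
    C0 <- list(c(0, 0, 0))
    target <- 2L
    Cd <- list(onehot(target, 3) * 2)
    score <- function(C) {
      G <- vapply(pols, function(p) {
        expected_free_energy(mod$A, B, C, mod$prior, p)$G
      }, numeric(1))
      policy_posterior(G, rep(1 / 3, 3), 16)
    }
    q0 <- score(C0)
    q1 <- score(Cd)
    # the policy whose predicted observations favour the target most
    po <- vapply(pols, function(p) {
      expected_observations(mod$A,
                            expected_states(B, mod$prior, p)[[1]])[[1]][target]
    }, numeric(1))
    best <- which.max(po)
    expect_gte(q1[best], q0[best] - 1e-12)
  }
})

test_that("action marginals pool policies by first-step action", {
  pols <- construct_policies(c(4, 1), 2)
  m <- marginal_action_probabilities(rep(1 / 16, 16), pols, c(4, 1))
  expect_equal(m[[1]], rep(0.25, 4))
  expect_equal(m[[2]], 1)

  q <- numeric(16)
  q[c(1, 2)] <- 0.5   # both start with location action 1
  m <- marginal_action_probabilities(q, pols, c(4, 1))
  expect_equal(m[[1]], c(1, 0, 0, 0))

  single <- construct_policies(c(2), 1)
  m <- marginal_action_probabilities(c(0, 1), single, 2)
  expect_equal(m[[1]], c(0, 1))
})

test_that("action sampling follows softmax(alpha * ln p)", {
  set.seed(97)
  # symmetric probabilities stay symmetric at any alpha
  draws <- replicate(2000, sample_action(list(c(0.5, 0.5)), 16))
  expect_gt(stats::binom.test(sum(draws == 1), 2000, 0.5)$p.value, 0.001)
  # huge alpha: argmax almost surely
  draws <- replicate(2000, sample_action(list(c(0.6, 0.4)), 1e6))
  expect_equal(mean(draws == 1), 1)
  # alpha = 1 reproduces the marginal distribution
  p <- c(0.2, 0.3, 0.5)
  draws <- replicate(10000, sample_action(list(p), 1))
  tab <- tabulate(draws, 3)
  expect_gt(stats::chisq.test(tab, p = p)$p.value, 0.01)
  expect_error(sample_action(list(p), 0), "out of range")
})
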