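# Replay likelihood, Metropolis sampling, posterior summaries, recovery
# reporting and PSIS-LOO.

test_that("replay likelihood handles empty and single-step sequences", {
  ag <- tmaze_agent()
  expect_equal(action_sequence_loglik(list(alpha = 1), ag,
                                      matrix(integer(0), 0, 3),
                                      matrix(integer(0), 0, 2)), 0)

  # gamma -> 0 with a uniform habit prior: the 16 policies marginalise to
  # a uniform distribution over the 4 location actions
  ll <- action_sequence_loglik(list(alpha = 1, gamma = 1e-12), ag,
                               matrix(c(1L, 1L, 1L), 1, 3),
                               matrix(c(4L, 1L), 1, 2))
  expect_equal(ll, log(1 / 4), tolerance = 1e-6)
})

test_that("the generative alpha is more likely than a distant one", {
  set.seed(123)
  ag <- tmaze_agent()
  sim <- run_tmaze(tmaze_agent(alpha = 16),
                   tmaze_config(reward_condition = "left"), 120)
  obs <- as.matrix(sim$records[, c("Location", "Reward", "Cue")])
  act <- as.matrix(sim$records[, c("Action_Location", "Action_Reward")])
  ll_true <- action_sequence_loglik(list(alpha = 16), ag, obs, act)
  ll_far <- action_sequence_loglik(list(alpha = 0.5), ag, obs, act)
  expect_gt(ll_true, ll_far)

  # cached-marginal evaluation agrees with the full replay
  cache <- aifpomdp:::replay_action_marginals(ag, obs, act)
  ll_cached <- sum(aifpomdp:::cached_pointwise_loglik(16, cache, act))
  expect_equal(ll_cached, ll_true, tolerance = 1e-10)
})

test_that("prior-only sampling reproduces the prior", {
  draws <- sample_posterior(function(params) 0,
                            list(alpha = prior_trunc_normal(5, 5, 0, 20)),
                            n_chains = 2, n_draws = 2000, n_warmup = 500,
                            seed = 31)
  v <- as.vector(draws[, , 1])
  prior_draws <- prior_trunc_normal(5, 5, 0, 20)$sample(2e5)
  expect_equal(mean(v), mean(prior_draws), tolerance = 0.3)
  expect_equal(stats::sd(v), stats::sd(prior_draws), tolerance = 0.3)
  expect_true(all(v >= 0 & v <= 20))
})

test_that("a single subject's action precision is recovered", {
  sim <- simulate_dataset(list(list(n_agents = 1, alpha_mean = 8,
                                    alpha_sd = 0.001)),
                          n_steps = 100, seed = 7)
  fit <- fit_subjects(sim$data, tmaze_agent(),
                      priors = list(alpha = prior_trunc_normal(5, 5, 0, 20)),
                      sampler = list(n_chains = 2, n_draws = 1000,
                                     n_warmup = 500, seed = 7))
  summ <- summarize_posterior(fit)
  expect_equal(nrow(summ), 1)
  expect_gt(summ$median, 5)
  expect_lt(summ$median, 12)
  expect_lt(summ$rhat, 1.05)
  expect_lte(summ$ess_bulk, 2000)
})

test_that("fit_subjects validates its inputs", {
  sim <- simulate_dataset(list(list(n_agents = 1, alpha_mean = 8,
                                    alpha_sd = 1)), n_steps = 3, seed = 1)
  expect_error(fit_subjects(sim$data[, -2], tmaze_agent(),
                            priors = list(alpha = prior_normal(5, 5))),
               "lacks declared columns")
  expect_error(fit_subjects(sim$data, tmaze_agent(), priors = list()),
               "named list")
})

test_that("posterior summaries report the standard statistics", {
  # constant chains: zero spread, rhat exactly 1
  const <- matrix(3.5, nrow = 200, ncol = 4)
  s <- summarize_posterior(const)
  expect_equal(s$std, 0)
  expect_equal(s$rhat, 1)

  # i.i.d. standard normal: mean within 3 mcse, ess below the draw count
  set.seed(44)
  x <- matrix(stats::rnorm(4000), ncol = 4)
  s <- summarize_posterior(x)
  expect_lt(abs(s$mean), 3 * s$mcse)
  expect_equal(s$std, 1, tolerance = 0.1)
  expect_lte(s$ess_bulk, 4000)
  expect_gt(s$ess_bulk, 1000)   # independent draws mix well
  expect_lt(s$rhat, 1.02)
})

test_that("recovery reports rank correlation between truth and medians", {
  truth <- data.frame(SubjectID = 1:8, group = rep(1:2, each = 4),
                      alpha = c(4, 5, 6, 7, 20, 21, 22, 23))
  perfect <- data.frame(subject = 1:8, parameter = "alpha",
                        median = truth$alpha, mean = truth$alpha, std = 0.1)
  rep1 <- recovery_report(truth, perfect)
  expect_equal(rep1$spearman, 1)
  expect_equal(rep1$table$true, truth$alpha)

  set.seed(2)
  shuffled <- perfect
  shuffled$median <- sample(shuffled$median)
  rep2 <- recovery_report(truth, shuffled)
  expect_lt(abs(rep2$spearman), 0.8)
})

test_that("PSIS-LOO handles degenerate and analytic cases", {
  # constant pointwise log-likelihood across draws: elpd is the plain sum
  ll <- matrix(rep(c(-1.2, -0.7, -2.1), each = 400), nrow = 400)
  res <- psis_loo(ll)
  expect_equal(res$elpd_loo, sum(c(-1.2, -0.7, -2.1)), tolerance = 1e-10)

  # identical models give identical elpd
  set.seed(55)
  ll2 <- matrix(stats::rnorm(400 * 3, -1), 400, 3)
  expect_equal(psis_loo(ll2)$elpd_loo, psis_loo(ll2)$elpd_loo)

  # Gaussian conjugate toy model against the analytic LOO predictive
  set.seed(66)
  n <- 30
  y <- stats::rnorm(n, 1, 1)
  S <- 4000
  mu_draws <- stats::rnorm(S, mean(y), 1 / sqrt(n))  # flat-prior posterior
  ll3 <- vapply(seq_len(n), function(i) {
    stats::dnorm(y[i], mu_draws, 1, log = TRUE)
  }, numeric(S))
  res <- psis_loo(ll3)
  loo_exact <- sum(vapply(seq_len(n), function(i) {
    m_i <- mean(y[-i])
    stats::dnorm(y[i], m_i, sqrt(1 + 1 / (n - 1)), log = TRUE)
  }, numeric(1)))
  expect_equal(res$elpd_loo, loo_exact, tolerance = 0.2)
  expect_true(all(res$pareto_k < 0.7, na.rm = TRUE))
})

test_that("pointwise log-likelihoods feed PSIS-LOO from a fit", {
  sim <- simulate_dataset(list(list(n_agents = 1, alpha_mean = 12,
                                    alpha_sd = 0.001)),
                          n_steps = 30, seed = 17)
  fit <- fit_subjects(sim$data, tmaze_agent(),
                      priors = list(alpha = prior_trunc_normal(5, 5, 0, 20)),
                      sampler = list(n_chains = 2, n_draws = 200,
                                     n_warmup = 200, seed = 17))
  pw <- pointwise_loglik(fit, 1)
  expect_equal(dim(pw), c(400L, 30L))
  res <- psis_loo(pw)
  expect_true(is.finite(res$elpd_loo))
  expect_length(res$pareto_k, 30)
})
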