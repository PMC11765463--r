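# Per-subject Bayesian estimation of agent hyper-parameters from
# observation-action data. The likelihood is a deterministic replay of the
# agent along the observed sequence ("teacher forcing"): at each step the
# agent's marginal action probabilities are computed, the observed action
# is scored under the alpha-sharpened softmax, and the agent is then
# advanced with the observed action. Sampling is by random-walk Metropolis
# (the replay likelihood is not assumed differentiable).

# --- prior specification ---------------------------------------------------

#' Prior distribution descriptors
#'
#' Constructors for the prior families supported by [fit_subjects()]:
#' normal, truncated normal, gamma and uniform.
#'
#' @param mean,sd Location and scale of the (truncated) normal.
#' @param lower,upper Truncation bounds.
#' @param shape,rate Gamma parameters.
#' @param min,max Uniform bounds.
#' @return A `prior_dist` object with `log_density` and `sample` closures
#'   and the support bounds.
#' @name prior_dist
NULL

new_prior <- function(family, log_density, sample, lower, upper, pars) {
  structure(list(family = family, log_density = log_density,
                 sample = sample, lower = lower, upper = upper, pars = pars),
            class = "prior_dist")
}

#' @rdname prior_dist
#' @export
prior_normal <- function(mean, sd) {
  new_prior("normal",
            function(x) stats::dnorm(x, mean, sd, log = TRUE),
            function(n) stats::rnorm(n, mean, sd),
            -Inf, Inf, list(mean = mean, sd = sd))
}

#' @rdname prior_dist
#' @export
prior_trunc_normal <- function(mean, sd, lower, upper) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  new_prior("trunc_normal",
            function(x) {
              ifelse(x < lower | x > upper, -Inf,
                     stats::dnorm(x, mean, sd, log = TRUE) - log(z))
            },
            function(n) {
              u <- stats::runif(n, stats::pnorm(lower, mean, sd),
                                stats::pnorm(upper, mean, sd))
              stats::qnorm(u, mean, sd)
            },
            lower, upper, list(mean = mean, sd = sd))
}

#' @rdname prior_dist
#' @export
prior_gamma <- function(shape, rate) {
  new_prior("gamma",
            function(x) stats::dgamma(x, shape, rate, log = TRUE),
            function(n) stats::rgamma(n, shape, rate),
            0, Inf, list(shape = shape, rate = rate))
}

#' @rdname prior_dist
#' @export
prior_uniform <- function(min, max) {
  new_prior("uniform",
            function(x) stats::dunif(x, min, max, log = TRUE),
            function(n) stats::runif(n, min, max),
            min, max, list(min = min, max = max))
}

# --- replay likelihood -----------------------------------------------------

#' Log-likelihood of an observed action sequence
#'
#' Deterministically replays the agent through one subject's time-ordered
#' data. For each time step the agent's per-factor action marginals are
#' computed (after state inference, learning and policy inference), the
#' observed action of every controllable factor is scored under
#' `softmax(alpha * ln p)`, and the agent is advanced with the observed
#' action. Actions with (floored) zero probability contribute `ln(1e-16)`.
#'
#' @param params Named list of hyper-parameter values to impose on the
#'   agent (e.g. `list(alpha = 8)`).
#' @param agent A fresh `aif_agent` template (not yet stepped).
#' @param observations Integer matrix, one row per time step, one column
#'   per modality.
#' @param actions Integer matrix, one row per time step, one column per
#'   factor.
#' @param trial_length Episodic structure of the task, if any: every
#'   `trial_length` rows the agent's trial-local beliefs are reset (see
#'   [reset_beliefs()]), matching how the data were generated. `NULL`
#'   treats the whole sequence as one episode.
#' @return The total log-likelihood (0 for an empty sequence).
#' @export
action_sequence_loglik <- function(params, agent, observations, actions,
                                   trial_length = NULL) {
  for (nm in names(params)) agent <- set_parameter(agent, nm, params[[nm]])
  nT <- nrow(observations)
  if (is.null(nT) || nT == 0L) return(0)
  ctrl <- which(agent$shape$num_controls > 1L)
  ll <- 0
  for (t in seq_len(nT)) {
    if (!is.null(trial_length) && t > 1L && (t - 1L) %% trial_length == 0L)
      agent <- reset_beliefs(agent)
    agent <- agent_update(agent, as.integer(observations[t, ]))
    for (f in ctrl) {
      p <- softmax(agent$hyper$alpha * ln_safe(agent$last_action_probs[[f]]))
      ll <- ll + log(max(p[actions[t, f]], PROB_FLOOR))
    }
    agent <- agent_commit(agent, as.integer(actions[t, ]))
  }
  ll
}

# Replay once and cache the per-step action marginals of the controllable
# factors. Valid whenever the sampled parameters do not alter the belief /
# policy trajectory under teacher forcing (true for alpha, which only
# sharpens the final marginals).
replay_action_marginals <- function(agent, observations, actions,
                                    trial_length = NULL) {
  nT <- nrow(observations)
  ctrl <- which(agent$shape$num_controls > 1L)
  marg <- vector("list", nT)
  for (t in seq_len(nT)) {
    if (!is.null(trial_length) && t > 1L && (t - 1L) %% trial_length == 0L)
      agent <- reset_beliefs(agent)
    agent <- agent_update(agent, as.integer(observations[t, ]))
    marg[[t]] <- agent$last_action_probs[ctrl]
    agent <- agent_commit(agent, as.integer(actions[t, ]))
  }
  list(marginals = marg, ctrl = ctrl)
}

# Per-time-step log-likelihood for a given alpha from a replay cache.
cached_pointwise_loglik <- function(alpha, cache, actions) {
  nT <- length(cache$marginals)
  out <- numeric(nT)
  for (t in seq_len(nT)) {
    for (j in seq_along(cache$ctrl)) {
      p <- softmax(alpha * ln_safe(cache$marginals[[t]][[j]]))
      out[t] <- out[t] + log(max(p[actions[t, cache$ctrl[j]]], PROB_FLOOR))
    }
  }
  out
}

# --- random-walk Metropolis ------------------------------------------------

# One chain of adaptive random-walk Metropolis. loglik takes a named list
# of parameter values. Returns a draws matrix (n_draws x n_params) plus the
# per-draw log-likelihood.
metropolis_chain <- function(loglik, priors, n_draws, n_warmup,
                             init = NULL) {
  pnames <- names(priors)
  np <- length(pnames)
  log_prior <- function(x) {
    sum(vapply(seq_len(np),
               function(j) priors[[j]]$log_density(x[j]), numeric(1)))
  }
  as_list <- function(x) stats::setNames(as.list(x), pnames)
  # initialise from the prior until the likelihood is finite
  if (is.null(init)) {
    for (attempt in seq_len(100L)) {
      cand <- vapply(priors, function(p) p$sample(1), numeric(1))
      ll <- loglik(as_list(cand))
      if (is.finite(ll)) { init <- cand; break }
    }
    if (is.null(init)) stop("could not initialise chain: non-finite likelihood in 100 prior draws")
  } else {
    ll <- loglik(as_list(init))
  }
  scale <- vapply(priors, function(p) {
    s <- p$pars$sd %||% p$pars$shape %||% 1
    max(s / 2, 0.1)
  }, numeric(1))
  x <- init
  lp <- log_prior(x) + ll
  draws <- matrix(NA_real_, nrow = n_draws, ncol = np,
                  dimnames = list(NULL, pnames))
  draw_ll <- numeric(n_draws)
  acc_window <- 0L
  total <- n_warmup + n_draws
  for (i in seq_len(total)) {
    prop <- x + stats::rnorm(np, 0, scale)
    lpr <- log_prior(prop)
    if (is.finite(lpr)) {
      llp <- loglik(as_list(prop))
      lpp <- lpr + llp
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
        x <- prop; lp <- lpp; ll <- llp
        acc_window <- acc_window + 1L
      }
    }
    # adapt the proposal scale towards ~0.35 acceptance during warmup
    if (i <= n_warmup && i %% 50L == 0L) {
      rate <- acc_window / 50
      scale <- scale * exp(rate - 0.35)
      acc_window <- 0L
    }
    if (i > n_warmup) {
      draws[i - n_warmup, ] <- x
      draw_ll[i - n_warmup] <- ll
    }
  }
  list(draws = draws, loglik = draw_ll)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a posterior with random-walk Metropolis
#'
#' Direct access to the sampler used by [fit_subjects()]: adaptive
#' random-walk Metropolis over a user-supplied log-likelihood. With a
#' constant log-likelihood (e.g. `function(params) 0`) this samples the
#' prior, which is useful for prior-predictive checks.
#'
#' @param loglik Function taking a named list of parameter values and
#'   returning a log-likelihood.
#' @param priors Named list of [prior_dist] objects.
#' @param n_chains,n_draws,n_warmup Sampler dimensions.
#' @param seed Integer seed.
#' @return An iterations x chains x parameters array of draws.
#' @export
sample_posterior <- function(loglik, priors, n_chains = 2L, n_draws = 1000L,
                             n_warmup = 500L, seed = 1L) {
  set.seed(seed)
  chains <- lapply(seq_len(n_chains), function(ch) {
    metropolis_chain(loglik, priors, n_draws, n_warmup)
  })
  arr <- array(NA_real_, dim = c(n_draws, n_chains, length(priors)),
               dimnames = list(NULL, NULL, names(priors)))
  for (ch in seq_len(n_chains)) arr[, ch, ] <- chains[[ch]]$draws
  arr
}

# --- per-subject fitting ---------------------------------------------------

#' Fit agent hyper-parameters to behavioural data, per subject
#'
#' Estimates the posterior over the named hyper-parameters independently
#' for every subject in a long-format behavioural table, using adaptive
#' random-walk Metropolis on the replay likelihood. When the only free
#' parameter is the action precision `alpha`, each subject is replayed
#' once and the per-step action marginals are cached, making likelihood
#' evaluations inside the sampler essentially free; other free parameters
#' trigger a full replay per proposal.
#'
#' @param dataset Long-format data frame (e.g. from [simulate_dataset()]
#'   or [read_behavioural_csv()]).
#' @param agent A fresh `aif_agent` template shared by all subjects.
#' @param priors Named list of [prior_dist] objects, one per free
#'   parameter.
#' @param sampler List of sampler options: `n_chains` (default 2),
#'   `n_draws` (default 1000), `n_warmup` (default 500), `seed`
#'   (default 1).
#' @param grouping Name of the subject-identifier column. Default
#'   `"SubjectID"`.
#' @param observation_cols,action_cols Column names holding the observation
#'   modalities and action factors, in model order.
#' @param trial_length Episodic structure used when the data were
#'   generated (see [simulate_dataset()]); the replay resets trial-local
#'   beliefs at the same boundaries. Default 3, matching
#'   [simulate_dataset()]; use `NULL` for continuous data.
#' @return An object of class `aif_fit`: per-subject lists of chain draws,
#'   plus the replay caches needed for pointwise log-likelihoods.
#' @export
fit_subjects <- function(dataset, agent, priors,
                         sampler = list(),
                         grouping = "SubjectID",
                         observation_cols = c("Location", "Reward", "Cue"),
                         action_cols = c("Action_Location", "Action_Reward"),
                         trial_length = 3L) {
  opts <- utils::modifyList(
    list(n_chains = 2L, n_draws = 1000L, n_warmup = 500L, seed = 1L),
    sampler)
  missing_cols <- setdiff(c(grouping, observation_cols, action_cols),
                          names(dataset))
  if (length(missing_cols) > 0)
    stop("dataset lacks declared columns: ",
         paste(missing_cols, collapse = ", "))
  if (length(priors) == 0 || is.null(names(priors)))
    stop("'priors' must be a named list of prior_dist objects")
  set.seed(opts$seed)
  subjects <- unique(dataset[[grouping]])
  fast_alpha <- identical(names(priors), "alpha")
  fits <- vector("list", length(subjects))
  caches <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    sub <- dataset[dataset[[grouping]] == subjects[si], , drop = FALSE]
    obs <- as.matrix(sub[, observation_cols, drop = FALSE])
    act <- as.matrix(sub[, action_cols, drop = FALSE])
    if (fast_alpha) {
      cache <- replay_action_marginals(agent, obs, act, trial_length)
      caches[[si]] <- list(cache = cache, actions = act)
      loglik <- function(params) {
        sum(cached_pointwise_loglik(params$alpha, cache, act))
      }
    } else {
      loglik <- function(params) {
        action_sequence_loglik(params, agent, obs, act, trial_length)
      }
    }
    chains <- lapply(seq_len(opts$n_chains), function(ch) {
      metropolis_chain(loglik, priors, opts$n_draws, opts$n_warmup)
    })
    fits[[si]] <- chains
  }
  structure(list(subjects = subjects, chains = fits, priors = priors,
                 sampler = opts, caches = caches,
                 parameters = names(priors)),
            class = "aif_fit")
}

#' @export
print.aif_fit <- function(x, ...) {
  cat("Posterior fit:", length(x$subjects), "subjects,",
      x$sampler$n_chains, "chains x", x$sampler$n_draws, "draws,",
      "parameters:", paste(x$parameters, collapse = ", "), "\n")
  invisible(x)
}

#' Extract posterior draws for one subject
#'
#' @param fit An `aif_fit`.
#' @param subject Subject identifier (as in the grouping column).
#' @return A 3-d array: iterations x chains x parameters.
#' @export
posterior_draws <- function(fit, subject) {
  si <- match(subject, fit$subjects)
  if (is.na(si)) stop("unknown subject")
  chains <- fit$chains[[si]]
  arr <- array(NA_real_,
               dim = c(nrow(chains[[1]]$draws), length(chains),
                       length(fit$parameters)),
               dimnames = list(NULL, NULL, fit$parameters))
  for (ch in seq_along(chains)) arr[, ch, ] <- chains[[ch]]$draws
  arr
}

#' Pointwise log-likelihood matrix for PSIS-LOO
#'
#' Evaluates the per-time-step log-likelihood at every saved posterior
#' draw, using the replay cache (available when `alpha` was the only free
#' parameter).
#'
#' @param fit An `aif_fit` produced with `alpha` as the only free
#'   parameter.
#' @param subject Subject identifier.
#' @return Matrix (total draws x time steps) of log-likelihood values.
#' @export
pointwise_loglik <- function(fit, subject) {
  si <- match(subject, fit$subjects)
  if (is.na(si)) stop("unknown subject")
  if (is.null(fit$caches[[si]]))
    stop("pointwise log-likelihoods require the cached (alpha-only) fit")
  cache <- fit$caches[[si]]$cache
  act <- fit$caches[[si]]$actions
  draws <- posterior_draws(fit, subject)[, , "alpha"]
  alphas <- as.vector(draws)
  t(vapply(alphas, function(a) cached_pointwise_loglik(a, cache, act),
           numeric(length(cache$marginals))))
}
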