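# Posterior summaries and diagnostics: split-chain rhat, bulk/tail
# effective sample sizes (rank-normalisation + Geyer initial monotone
# autocorrelation sums), Monte Carlo standard errors, parameter-recovery
# reporting, and PSIS-LOO model comparison.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Split each chain of an iterations x chains matrix in half.
split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

# Rank-normalise all draws jointly (fractional offset as in common
# practice), preserving the matrix layout.
rank_normalise <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(x), ncol = ncol(x))
}

# Potential scale reduction factor on split chains.
rhat_of <- function(x) {
  x <- split_chains(x)
  n <- nrow(x); m <- ncol(x)
  if (stats::var(as.vector(x)) < 1e-12) return(1)
  cm <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(cm)
  var_plus <- W * (n - 1) / n + B / n
  if (W < 1e-12) return(1)
  sqrt(var_plus / W)
}

# Effective sample size on split chains via Geyer's initial monotone
# positive sequence, combined across chains.
ess_of <- function(x) {
  x <- split_chains(x)
  n <- nrow(x); m <- ncol(x)
  S <- n * m
  if (stats::var(as.vector(x)) < 1e-12) return(S)
  cm <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(cm)
  var_plus <- W * (n - 1) / n + B / n
  # per-chain autocovariances (1/n normalisation, as stats::acf provides)
  max_lag <- n - 1L
  acov <- vapply(seq_len(m), function(j) {
    stats::acf(x[, j], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(max_lag + 1L))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer pairs: sum while the paired autocorrelations stay positive,
  # enforcing monotone decrease.
  tau <- rho[1]
  k <- 2L
  prev_pair <- Inf
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    k <- k + 2L
  }
  min(S, S / max(tau, 1 / S))
}

ess_bulk_of <- function(x) ess_of(rank_normalise(x))

ess_tail_of <- function(x) {
  qs <- stats::quantile(as.vector(x), c(0.05, 0.95), names = FALSE)
  e1 <- ess_of(rank_normalise((x <= qs[1]) * 1))
  e2 <- ess_of(rank_normalise((x >= qs[2]) * 1))
  min(e1, e2)
}

#' Summarise posterior draws
#'
#' For every subject and parameter, reports the posterior mean, standard
#' deviation, Monte Carlo standard error of the mean, bulk and tail
#' effective sample sizes, split-chain rhat, and the 5/50/95 percent
#' quantiles.
#'
#' @param fit An `aif_fit` object, or a single iterations x chains matrix
#'   of draws for one parameter.
#' @return A data frame with one row per subject x parameter.
#' @export
summarize_posterior <- function(fit) {
  summarise_matrix <- function(x, subject, parameter) {
    v <- as.vector(x)
    ess_b <- ess_bulk_of(x)
    data.frame(
      subject = subject, parameter = parameter,
      mean = mean(v), std = stats::sd(v),
      mcse = stats::sd(v) / sqrt(ess_b),
      ess_bulk = ess_b, ess_tail = ess_tail_of(x),
      rhat = rhat_of(x),
      q5 = stats::quantile(v, 0.05, names = FALSE),
      median = stats::median(v),
      q95 = stats::quantile(v, 0.95, names = FALSE))
  }
  if (is.matrix(fit)) {
    return(summarise_matrix(fit, subject = NA, parameter = "parameter"))
  }
  stopifnot(inherits(fit, "aif_fit"))
  out <- list()
  for (si in seq_along(fit$subjects)) {
    draws <- posterior_draws(fit, fit$subjects[si])
    for (p in fit$parameters) {
      out[[length(out) + 1L]] <-
        summarise_matrix(draws[, , p, drop = TRUE], fit$subjects[si], p)
    }
  }
  do.call(rbind, out)
}

#' Parameter-recovery report
#'
#' Joins generative parameter values with posterior summaries and reports
#' estimated-versus-true scatter data plus the Spearman rank correlation.
#'
#' @param truth Data frame with columns `SubjectID`, `group` and one column
#'   per recovered parameter (e.g. `alpha`), as from [simulate_dataset()].
#' @param summaries Posterior summary data frame from
#'   [summarize_posterior()].
#' @param parameter Name of the recovered parameter. Default `"alpha"`.
#' @return A list with `table` (SubjectID, group, true value, posterior
#'   median and mean) and `spearman` (rank correlation between true values
#'   and posterior medians).
#' @export
recovery_report <- function(truth, summaries, parameter = "alpha") {
  s <- summaries[summaries$parameter == parameter, , drop = FALSE]
  tab <- merge(truth, s[, c("subject", "median", "mean", "std")],
               by.x = "SubjectID", by.y = "subject")
  tab <- tab[order(tab$SubjectID), , drop = FALSE]
  names(tab)[names(tab) == parameter] <- "true"
  rho <- stats::cor(tab$true, tab$median, method = "spearman")
  list(table = tab, spearman = rho)
}

# --- PSIS-LOO --------------------------------------------------------------

# Generalised Pareto fit to tail exceedances (profile-likelihood grid
# method with a weak prior on k), as is standard for Pareto-smoothed
# importance sampling.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  prior_k <- 10
  M <- 30L + floor(sqrt(n))
  jj <- seq_len(M)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  if (xstar <= 0) xstar <- min(x[x > 0])
  theta <- 1 / x[n] + (1 - sqrt(M / (jj - 0.5))) / (prior_bs * xstar)
  k_of <- function(t) mean(log1p(-t * x))
  l_theta <- vapply(theta, function(t) {
    k <- k_of(t)
    n * (log(-t / k) - k - 1)
  }, numeric(1))
  w <- exp(l_theta - log_sum_exp(l_theta))
  theta_hat <- sum(theta * w)
  k <- k_of(theta_hat)
  sigma <- -k / theta_hat
  # weakly informative prior pulls k towards 0.5 for small tails
  k <- (n * k + prior_k * 0.5) / (n + prior_k)
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of (unnormalised) log importance weights.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  tail_len <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  if (tail_len < 5) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - tail_len + 1):S]
  cut <- lw[ord[S - tail_len]]
  exceed <- exp(lw[tail_ids]) - exp(cut)
  if (max(exceed) <= 0) return(list(lw = lw, k = NA_real_))
  fit <- gpd_fit(exceed)
  if (is.finite(fit$k)) {
    pr <- (seq_len(tail_len) - 0.5) / tail_len
    smoothed <- log(exp(cut) + vapply(pr, gpd_quantile, numeric(1),
                                      k = fit$k, sigma = fit$sigma))
    lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  }
  lw <- pmin(lw, 0)
  list(lw = lw, k = fit$k)
}

#' PSIS-LOO cross-validation
#'
#' Pareto-smoothed importance-sampling approximation to leave-one-out
#' cross-validation from a pointwise log-likelihood matrix. Raw importance
#' ratios `1 / p(y_i | theta_s)` have their tails replaced by expected
#' order statistics of a fitted generalised Pareto distribution; the
#' Pareto shape `k` per observation diagnoses the reliability of the
#' approximation (values above ~0.7 are unreliable).
#'
#' @param loglik Matrix of pointwise log-likelihood values, draws in rows,
#'   observations in columns.
#' @return A list with `elpd_loo`, `se_elpd_loo`, `pointwise` (per-
#'   observation elpd contributions) and `pareto_k`.
#' @export
psis_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  S <- nrow(loglik)
  N <- ncol(loglik)
  pointwise <- numeric(N)
  ks <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-loglik[, i])
    lw <- sm$lw - log_sum_exp(sm$lw)
    pointwise[i] <- log_sum_exp(lw + loglik[, i])
    ks[i] <- sm$k
  }
  list(elpd_loo = sum(pointwise),
       se_elpd_loo = sqrt(N * stats::var(pointwise)),
       pointwise = pointwise,
       pareto_k = ks)
}
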