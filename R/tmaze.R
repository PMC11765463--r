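# T-maze generative process and whole-dataset simulation.
#
# State coding (1-based, shared by environment and agent):
#   locations  1 = centre, 2 = right arm, 3 = left arm, 4 = cue location
#   conditions 1 = reward right, 2 = reward left
#   reward observations 1 = no reward, 2 = reward, 3 = loss
#   cue observations    1 = cue right, 2 = cue left
#   actions    1..4 = move to centre / right arm / left arm / cue location

TMAZE_CENTRE <- 1L
TMAZE_RIGHT <- 2L
TMAZE_LEFT <- 3L
TMAZE_CUE <- 4L

#' T-maze configuration
#'
#' @param reward_probability Probability that the rewarding arm emits a
#'   reward (the other arm emits a loss with the same probability).
#'   Default 0.95.
#' @param cue_validity Probability that the cue, observed at the cue
#'   location, reveals the true reward condition. Default 1 (perfectly
#'   informative cue).
#' @param reward_condition `"right"`, `"left"`, or `"sampled"` (drawn
#'   uniformly at reset).
#' @return An object of class `tmaze_config`.
#' @export
tmaze_config <- function(reward_probability = 0.95, cue_validity = 1,
                         reward_condition = c("sampled", "right", "left")) {
  check_scalar(reward_probability, "reward_probability", lower = 0, upper = 1)
  check_scalar(cue_validity, "cue_validity", lower = 0, upper = 1)
  reward_condition <- match.arg(reward_condition)
  structure(list(reward_probability = reward_probability,
                 cue_validity = cue_validity,
                 reward_condition = reward_condition),
            class = "tmaze_config")
}

#' Reset the T-maze
#'
#' Places the agent at the centre location and fixes the reward condition
#' for the episode (sampling it uniformly when the configuration says so).
#'
#' @param config A [tmaze_config()] object.
#' @return Environment state: a list with `location`, `condition` and the
#'   configuration.
#' @export
tmaze_reset <- function(config = tmaze_config()) {
  condition <- switch(config$reward_condition,
                      right = 1L, left = 2L,
                      sampled = sample.int(2L, 1L))
  list(location = TMAZE_CENTRE, condition = condition, config = config)
}

#' Generate the observation for the current T-maze state
#'
#' Location is observed exactly. The reward observation is "no reward" at
#' the centre and cue locations; in the arms a reward (rewarding arm) or
#' loss (other arm) is emitted with the configured reward probability,
#' mirrored between the arms. The cue reveals the reward condition only at
#' the cue location (with the configured validity) and is uniform noise
#' elsewhere.
#'
#' @param state Environment state from [tmaze_reset()] / [tmaze_step()].
#' @return Integer observation vector `c(location, reward, cue)`.
#' @export
tmaze_observe <- function(state) {
  p <- state$config$reward_probability
  loc <- state$location
  reward_obs <- if (loc %in% c(TMAZE_CENTRE, TMAZE_CUE)) {
    1L
  } else {
    rewarding <- (loc == TMAZE_RIGHT && state$condition == 1L) ||
      (loc == TMAZE_LEFT && state$condition == 2L)
    hit <- stats::runif(1) < p
    if (rewarding) (if (hit) 2L else 3L) else (if (hit) 3L else 2L)
  }
  cue_obs <- if (loc == TMAZE_CUE) {
    if (stats::runif(1) < state$config$cue_validity) state$condition
    else 3L - state$condition
  } else {
    sample.int(2L, 1L)
  }
  c(loc, reward_obs, cue_obs)
}

#' Advance the T-maze by one action
#'
#' The location follows the movement action deterministically; the reward
#' condition never changes within an episode.
#'
#' @param state Environment state.
#' @param action Movement action in 1..4 (or an integer vector whose first
#'   entry is the movement action, as produced by [step_agent()]).
#' @return A list with the new `state` and the resulting `obs`.
#' @export
tmaze_step <- function(state, action) {
  u <- as.integer(action[1])
  if (u < 1L || u > 4L) stop("T-maze action must lie in 1..4")
  state$location <- u
  list(state = state, obs = tmaze_observe(state))
}

#' Generative model for the T-maze agent
#'
#' Builds the standard two-factor (location x reward condition), three-
#' modality (location, reward, cue) model: exact location observations, an
#' agnostic 50/50 reward likelihood in the arms (to be learned), a cue that
#' is informative only at the cue location, deterministic location control,
#' a fixed reward condition, a centre-start state prior and a uniform habit
#' prior over the 16 two-step policies.
#'
#' @param reward_preference Log-preference for the reward observation (and
#'   aversion, with opposite sign, for the loss). Default 3.
#' @param policy_length Planning horizon. Default 2.
#' @return A list with `shape`, `A`, `B`, `C`, `D`, `E`.
#' @export
tmaze_model <- function(reward_preference = 3, policy_length = 2L) {
  shape <- model_shape(num_obs = c(4L, 3L, 2L), num_states = c(4L, 2L),
                       num_controls = c(4L, 1L),
                       policy_length = policy_length)
  tpl <- create_templates(shape, "zeros")
  A <- tpl$A
  # location modality: identity in each reward condition
  for (cond in 1:2) A[[1]][, , cond] <- diag(4)
  # reward modality: certain "no reward" off-arm, agnostic 50/50 in arms
  for (cond in 1:2) {
    A[[2]][1, c(TMAZE_CENTRE, TMAZE_CUE), cond] <- 1
    A[[2]][2:3, c(TMAZE_RIGHT, TMAZE_LEFT), cond] <- 0.5
  }
  # cue modality: uninformative except at the cue location
  for (cond in 1:2) {
    A[[3]][, , cond] <- 0.5
    A[[3]][, TMAZE_CUE, cond] <- onehot(cond, 2)
  }
  B <- tpl$B
  for (u in 1:4) B[[1]][u, , u] <- 1   # movement is fully controllable
  B[[2]][, , 1] <- diag(2)             # reward condition never changes
  C <- list(numeric(4), c(0, reward_preference, -reward_preference),
            numeric(2))
  D <- list(onehot(TMAZE_CENTRE, 4), c(0.5, 0.5))
  n_pol <- prod(shape$num_controls)^shape$policy_length
  E <- rep(1 / n_pol, n_pol)
  list(shape = shape, A = A, B = B, C = C, D = D, E = E)
}

#' A ready-made T-maze agent
#'
#' Instantiates the [tmaze_model()] agent with reward-modality A learning:
#' the Dirichlet prior over A is a scaled copy of the (agnostic) likelihood
#' with the given scale, learning is restricted to the reward modality, and
#' both the state and parameter information gains contribute to the
#' expected free energy.
#'
#' @param alpha,gamma Action and policy precisions. Default 16.
#' @param eta_A Learning rate for A. Default 1.
#' @param reward_preference Passed to [tmaze_model()].
#' @param dirichlet_scale Scaling of the Dirichlet prior over A. Default 2.
#' @param policy_length Planning horizon. Default 2.
#' @param learn_A Enable reward-modality A learning. Default TRUE.
#' @return An `aif_agent`.
#' @export
tmaze_agent <- function(alpha = 16, gamma = 16, eta_A = 1,
                        reward_preference = 3, dirichlet_scale = 2,
                        policy_length = 2L, learn_A = TRUE) {
  mod <- tmaze_model(reward_preference, policy_length)
  pA <- if (learn_A) lapply(mod$A, function(a) a * dirichlet_scale) else NULL
  init_agent(
    A = mod$A, B = mod$B, C = mod$C, D = mod$D, E = mod$E, pA = pA,
    hyper = hyperparameters(gamma = gamma, alpha = alpha, eta_A = eta_A),
    settings = planning_settings(
      policy_length = policy_length,
      use_state_info_gain = TRUE,
      use_param_info_gain = learn_A,
      learned_modalities = if (learn_A) 2L))
}

#' Run an agent in the T-maze
#'
#' Runs the full action-perception loop for `n_steps` steps: the agent
#' receives the observation for the current maze state, infers states,
#' learns, selects an action, and the maze advances. Uses R's global
#' random number stream.
#'
#' @param agent An `aif_agent` (typically from [tmaze_agent()]).
#' @param config A [tmaze_config()].
#' @param n_steps Number of time steps.
#' @param trial_length Optional episodic structure: every `trial_length`
#'   steps the maze is reset (location to centre, and the reward condition
#'   resampled when the configuration says `"sampled"`) and the agent's
#'   trial-local beliefs are cleared with [reset_beliefs()]. `NULL` (the
#'   default) runs one continuous episode.
#' @return A list with the final `agent`, the final environment `state`,
#'   and `records`: a data frame with one row per step (Time, Location,
#'   Reward, Cue, Action_Location, Action_Reward).
#' @export
run_tmaze <- function(agent, config = tmaze_config(), n_steps = 100L,
                      trial_length = NULL) {
  state <- tmaze_reset(config)
  obs <- tmaze_observe(state)
  rec <- matrix(0L, nrow = n_steps, ncol = 6L)
  colnames(rec) <- c("Time", "Location", "Reward", "Cue",
                     "Action_Location", "Action_Reward")
  for (t in seq_len(n_steps)) {
    if (!is.null(trial_length) && t > 1L && (t - 1L) %% trial_length == 0L) {
      # new trial: back to the centre, same reward condition as drawn at
      # the first reset (the condition is a property of the agent's run)
      condition <- state$condition
      state <- tmaze_reset(config)
      state$condition <- condition
      obs <- tmaze_observe(state)
      agent <- reset_beliefs(agent)
    }
    res <- step_agent(agent, obs)
    agent <- res$agent
    rec[t, ] <- c(t, obs, res$action)
    nxt <- tmaze_step(state, res$action[1])
    state <- nxt$state
    obs <- nxt$obs
  }
  list(agent = agent, state = state, records = as.data.frame(rec))
}

#' Simulate a multi-group behavioural dataset
#'
#' For each group, draws per-agent action precisions from a Gaussian
#' (negative draws rejected and redrawn), runs each agent in a fresh
#' T-maze for `n_steps` steps, and stacks the records into one long-format
#' behavioural table. Fully reproducible from `seed`.
#'
#' By default the task is episodic, as T-maze paradigms are: trials of
#' `trial_length` steps (one trial-initial observation plus the actions of
#' the two-step planning horizon), with the maze reset and the reward
#' condition redrawn between trials while learning carries over. This is
#' what keeps the behavioural record informative about the action
#' precision; in one continuous episode the agent settles into the
#' rewarding arm and its choices become deterministic. Set
#' `trial_length = NULL` for a single continuous episode.
#'
#' @param group_specs List of groups, each a list/vector with elements
#'   `n_agents`, `alpha_mean`, `alpha_sd`.
#' @param n_steps Time steps per agent.
#' @param config A [tmaze_config()].
#' @param seed Integer seed.
#' @param trial_length Steps per trial (default 3); `NULL` disables the
#'   trial structure.
#' @param ... Further arguments passed to [tmaze_agent()] (e.g. `gamma`).
#' @return A list with `data` (rows = `n_steps` x total agents; columns
#'   Time, Location, Reward, Cue, Action_Location, Action_Reward,
#'   SubjectID) and `truth` (SubjectID, group, alpha).
#' @export
simulate_dataset <- function(group_specs, n_steps,
                             config = tmaze_config(), seed = 1L,
                             trial_length = 3L, ...) {
  set.seed(seed)
  check_scalar(n_steps, "n_steps", lower = 1)
  data_rows <- list()
  truth <- list()
  sid <- 0L
  for (g in seq_along(group_specs)) {
    spec <- group_specs[[g]]
    for (i in seq_len(spec$n_agents)) {
      sid <- sid + 1L
      alpha <- -1
      while (alpha <= 0) {
        alpha <- stats::rnorm(1, spec$alpha_mean, spec$alpha_sd)
      }
      agent <- tmaze_agent(alpha = alpha, ...)
      sim <- run_tmaze(agent, config, n_steps, trial_length = trial_length)
      df <- sim$records
      df$SubjectID <- sid
      data_rows[[sid]] <- df
      truth[[sid]] <- data.frame(SubjectID = sid, group = g, alpha = alpha)
    }
  }
  list(data = do.call(rbind, data_rows), truth = do.call(rbind, truth))
}
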