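---
title: "Active inference in discrete state spaces: models, inference and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active inference in discrete state spaces: models, inference and fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aifpomdp)
```

# The generative model

`aifpomdp` implements agents that perceive, act and learn in discrete
state-space partially observable Markov decision processes (POMDPs) by
minimising variational free energy. A model is specified by five component
sets:

* **A** (observation model): per observation modality $m$, a tensor
  $A_m[o, s^1, \dots, s^F]$ whose observation-axis columns are categorical
  distributions $p(o_m \mid s)$;
* **B** (transition model): per state factor $f$, a tensor
  $B_f[s', s, u]$ of action-conditioned transition distributions
  $p(s'_f \mid s_f, u_f)$;
* **C** (preference prior): per modality, *unnormalised log-preferences*
  over observations. We keep C on the log scale throughout (the T-maze
  example uses 0 / +3 / −3) and normalise through a softmax only inside
  pragmatic-value and risk computations;
* **D** (state prior): per factor, the prior over states at the first time
  step of an episode or trial;
* **E** (habit prior): a probability vector over the enumerated policies.

Policies are exhaustive action sequences of length `policy_length`,
enumerated in lexicographic order over (time step, factor, action index) so
that policy lists are reproducible. All user-facing indices are 1-based.

Two hyper-parameters govern stochasticity: the policy precision $\gamma$
(inverse temperature of the softmax over expected free energies, default
16) and the action precision $\alpha$ (inverse temperature over marginal
action probabilities, default 16). Learning is governed by a learning rate
$\eta \in (0,1]$ and a forgetting rate $\omega \in (0,1]$ (both default 1).

# Perception: fixed-point iteration

Given an observation $o_t$, the time-specific variational free energy

$$F_t = E_{q(s_t)}\left[\ln q(s_t) - \ln p(o_t \mid s_t)
        - \ln p(s_t \mid s_{t-1}, u_{t-1})\right]$$

is minimised over a mean-field posterior $q(s_t) = \prod_f q(s_t^f)$ by
coordinate ascent: each factor is updated to
$\mathrm{softmax}(E_{q \setminus f}[\ln p(o_t \mid s_t)] + \ln prior_f)$ in
ascending factor order. Convergence is declared when the change in $F_t$
between sweeps falls below `tolerance` (default 0.001), with at most
`max_iterations` sweeps (default 10). Numerical choices:

* probabilities are floored at $10^{-16}$ before every logarithm;
* softmaxes subtract the maximum before exponentiation;
* the sweep is initialised at the predictive prior, so single-factor
  models converge to the *exact* posterior in one sweep (this is tested
  against brute-force enumeration);
* an observation with zero likelihood under every state (after flooring)
  degenerates to the prior with a warning rather than producing NaNs.

$F_t$ is also exposed through its complexity − accuracy split, and the
test suite verifies $F_t \ge -\ln p(o_t)$ against enumerated evidence.

# Action: expected free energy

Each policy $\pi$ is scored by rolling predicted states and observations
forward and accumulating, per step,

$$G_\pi = \sum_t \left(-\text{info gain} - \text{pragmatic value}
          - \text{parameter info gain}\right),$$

where the state information gain is the mutual information
$H[q(o)] - E_{q(s)}H[p(o \mid s)]$ summed over modalities, the pragmatic
value is $\sum_m q(o_m) \cdot \ln \mathrm{softmax}(C_m)$, and the
risk + ambiguity decomposition is computed alongside (the two forms agree
to $10^{-10}$ on a thousand random models in the tests). The policy
posterior is $q(\pi) = \mathrm{softmax}(\ln E - \gamma G)$ — with
$\gamma = 0$ the habit prior is recovered exactly — and actions are
sampled from $\mathrm{softmax}(\alpha \ln p)$ applied to the first-step
action marginals.

**Parameter information gain.** The Dirichlet-novelty bonus for a learned
modality uses $w(o,s) = \tfrac12\left(1/\theta(o,s) -
1/\sum_{o'}\theta(o',s)\right)$, taken in expectation under the predicted
observation and state distributions; entries with zero counts inside a
positive column are inert. This form is non-negative and vanishes as
counts grow. The exact novelty expression used by other implementations in
this family is not standardised; only these qualitative properties are
asserted.

Roll-outs condition on predicted states only — the agent does not simulate
changes to its own future beliefs (no sophisticated inference), so the
epistemic value of an observation for a *later* decision is invisible to a
single policy evaluation and enters only through the enumerated two-step
policies.

# Learning

Dirichlet concentration parameters over A, B and D are updated as
$\theta_{t+1} = \omega\,\theta_t + \eta\,\chi_t$, where $\chi$ is the
outer product of the observation one-hot with the joint state posterior
(A), of consecutive posteriors for the action taken (B), or the first-step
posterior itself (D). With $\omega < 1$, forgetting applies to the entire
learned component at each update (the simplest deterministic reading;
per-column forgetting was rejected to keep updates order-independent
within a step). Updates run after state inference and before policy
inference within a time step. With $\omega = 1, \eta = 1$ each A update
adds exactly unit mass per learned modality, a conservation property the
tests check, along with recovery of generating frequencies to within 0.02
per entry after 10,000 supervised draws.

When counts are supplied for a component, its expected (column-normalised)
value stands in for that component during inference. Omitted C/D/E default
to neutral log-preferences, uniform state priors and a uniform habit
prior; when a maximally agnostic count prior is wanted without a reference
model, `flat_dirichlet_counts()` provides all-ones counts.

# The T-maze

The bundled environment is the classic four-location T-maze: centre, right
arm, left arm and cue location, with a latent reward condition (right or
left). The rewarding arm emits a reward with probability 0.95 (mirrored in
the other arm); the centre and cue locations emit "no reward"; the cue
reveals the condition only at the cue location. The matching agent
(`tmaze_agent()`) observes its location exactly, starts agnostic (50/50)
about rewards in the arms, has preference +3 for rewards and −3 for
losses, plans two steps ahead over 16 policies, and learns the reward
modality of A from a scale-2 Dirichlet prior.

Because the cue resolves the reward-condition uncertainty, the epistemic
term makes "move to the cue" the dominant first action (>90% of episodes),
after which the posterior over the cued condition exceeds 0.99 and the
agent exploits the cued arm. Over a 300-step run the learned likelihood of
reward in the visited arm approaches the generative 0.95 from its agnostic
prior — about 0.94 after 300 steps, since the scale-2 prior contributes
two pseudo-counts. One caveat the package makes visible: with probability
about 0.05 the *first* arm visit yields a chance loss, after which the
pessimistic learned likelihood can keep a high-precision agent away from
that arm indefinitely. The acceptance script therefore summarises the
learned value by the median over seven replicate runs.

## Trial structure and the synthetic datasets

`simulate_dataset()` generates multi-subject behavioural tables for
parameter-recovery studies: per group, per-agent action precisions are
drawn from a Gaussian (negative draws redrawn), and each agent runs in its
own maze. The task is *episodic* by default — trials of three time steps
(the trial-initial centre observation plus the two actions of the planning
horizon), with the maze location and the agent's trial-local beliefs reset
between trials while Dirichlet learning persists and the reward condition
stays fixed for the agent's whole run. This is the structure of T-maze
paradigms, and it is what keeps behaviour informative: in one continuous
episode the agent settles into the rewarding arm after a handful of steps
and its action marginals become one-hot, leaving nothing for a fitted
action precision to explain. `trial_length = NULL` gives the continuous
single-episode variant used for the likelihood-learning demonstration.

What the generator deliberately does not emulate: within-trial variation
in cue validity, condition switches (reversal learning), response
omissions or timing, and any hierarchical structure across subjects.
Passing recovery tests therefore speak to the estimator, not to the
robustness of these settings on real behavioural data.

# Fitting

`fit_subjects()` estimates hyper-parameters per subject by replaying the
agent along the observed sequence with teacher forcing: at each step the
agent's marginal action probabilities are computed, the observed action is
scored under $\mathrm{softmax}(\alpha \ln p)$ (floored at $10^{-16}$), and
the agent is advanced with the observed action. The replay honours the
trial boundaries the data were generated with. Sampling uses adaptive
random-walk Metropolis — the replay likelihood is a black-box simulation,
so no gradients are assumed — with initialisation from the prior (up to
100 attempts for a finite likelihood) and proposal scales adapted towards
a 35% acceptance rate during warmup only.

A consequential implementation choice: when $\alpha$ is the only free
parameter, the belief and policy trajectory under teacher forcing does not
depend on it, so each subject is replayed once and the per-step action
marginals are cached; likelihood evaluations inside the sampler then cost
microseconds. This is algebraically exact, not an approximation, and the
tests verify cached and full-replay likelihoods agree to $10^{-10}$. Other
free parameters (e.g. $\gamma$) trigger a full replay per proposal.

Summaries report mean, sd, MCSE, bulk/tail effective sample sizes and
split-chain $\widehat R$ (rank-normalised, Geyer initial-monotone
autocorrelation sums). `psis_loo()` implements Pareto-smoothed importance
sampling LOO from a pointwise log-likelihood matrix, with the standard
profile-likelihood generalised-Pareto tail fit and per-observation shape
diagnostics; it is checked against the analytic leave-one-out predictive
of a conjugate Gaussian toy model.

## Identifiability of the action precision

A limitation users should know before designing a study with these
defaults: with $\gamma = 16$ and preferences of magnitude 3, expected
free energy differences of order one nat make the policy posterior — and
hence the action marginals — nearly deterministic once the reward
likelihood has been learned (a trial or two). Since
$\mathrm{softmax}(\alpha \ln p)$ of a near-one-hot $p$ is the same for
$\alpha = 8$ and $\alpha = 24$, two such agents generate almost
indistinguishable behaviour, and the replay likelihood is essentially flat
in $\alpha$ above the sharpness scale (about 4 here). Single-subject
recovery of a moderate $\alpha$ against a truncated-normal(5, 5, [0, 20])
prior succeeds (the posterior median lands near the generative value and
$\widehat R < 1.05$), but separating groups at $\alpha \approx 8$ versus
$\alpha \approx 24$ under these generative settings is not reliably
possible at realistic run lengths — the information is not in the data.
Recovering a precision parameter requires a regime where it actually
modulates behaviour: softer preferences, lower $\gamma$, or more residual
uncertainty per trial.

# Problem sizes used in the tests

The suite works at the scale of the bundled example: the 4×2-state,
three-modality T-maze (16 policies), oracle checks on randomly drawn
models up to six states and three modalities (500 inference-exactness
draws, 1,000 EFE-identity draws), 300-step learning runs, 10,000-draw
supervised learning checks, and recovery fits of six subjects at 100 steps
with 2 chains × 1,000 draws after 500 warmup iterations. These sizes were
chosen to exercise every code path at full fidelity while keeping the
default test run in the minutes range.
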