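---
title: "Models and methods for Pavlovian-bias analysis of the orthogonalized go/no-go task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for Pavlovian-bias analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavbias)
```

## The task and what it measures

The orthogonalized go/no-go task crosses required action (go / no-go)
with outcome valence (win reward / avoid punishment), producing four cue
conditions: go-to-win, go-to-avoid, no-go-to-win, no-go-to-avoid. Because
action and valence are decorrelated, the design separates *instrumental*
learning (emit whichever action the contingency rewards) from *Pavlovian
bias* (act toward reward-predictive cues, withhold toward
punishment-predictive ones). The bias helps in the two congruent
conditions and hurts in the two incongruent ones, so the
congruent-minus-incongruent accuracy difference is a behavioural bias
index, computable per valence domain:

* reward domain: `go_to_win − nogo_to_win`
* punishment domain: `nogo_to_avoid − go_to_avoid`
* overall: the sum of the two (equivalently
  `(go_to_win + nogo_to_avoid) − (nogo_to_win + go_to_avoid)`; the
  parenthesization is forced by requiring the overall index to decompose
  into the two domain indices).

A standard session has 45 trials per condition (180 total) and a 0.7
action–outcome contingency: the optimal response earns the beneficial
outcome (+1 in the reward domain; 0, i.e. no shock, in the punishment
domain) with probability 0.7, and the roles reverse for the suboptimal
response. Feedback is coded −1/0/+1, with reward cues confined to
{0, +1} and punishment cues to {−1, 0}; the validator enforces this.

## The model family

All three variants share the same machinery. Action values `Q(a, s)` and
stimulus values `V(s)` start at zero, making the first choice depend only
on the go bias and noise. Per trial:

1. action weights: `W(go,s) = Q(go,s) + b + pi_d * V(s)`,
   `W(nogo,s) = Q(nogo,s)`, where `pi_d` is the Pavlovian weight for the
   cue's valence domain;
2. choice rule: `p(go) = logistic(W(go,s) − W(nogo,s)) (1 − xi) + xi/2`
   — the two-option softmax written as a logistic of the weight
   difference (algebraically identical, numerically stable), mixed with
   uniform noise `xi`;
3. learning: `Q(a,s) += eps (rho_d r − Q(a,s))` for the chosen action,
   and `V(s) += eps (rho_d r − V(s))` every trial regardless of action,
   with `rho_d` the outcome sensitivity for the cue's domain.

Variant m1 shares `pi` and `rho` across domains (5 parameters), m2 splits
`rho` (6), and m3 splits both (7). Because reward cues only ever deliver
`r ∈ {0, +1}` and punishment cues `r ∈ {−1, 0}`, assigning `rho` by cue
domain and by feedback sign are numerically identical in this task; the
test suite asserts this equivalence rather than leaving it as a remark.

Parameter ranges: `xi, eps ∈ [0,1]` (probit-transformed from the
unconstrained scale), `rho > 0` (log-transformed), `b` and the `pi`
family unconstrained. Leaving `pi` unconstrained is deliberate: empirical
group-level Pavlovian-bias estimates in this paradigm can be negative,
and a positivity constraint would silently truncate exactly the effects
of interest.

## The generative study template

`generate_study()` emulates a two-group stimulation-style study. The
default hyperparameters encode the qualitative group structure such
studies report: a *control* group with natural-scale group means near
`xi = 0.09`, `eps = 0.32`, `b = 1.27`, `pi_rew = −0.14`, `pi_pun = 0.41`,
`rho_rew = 12.3`, `rho_pun = 8.8`, and an *active* group with lower
noise (0.03), near-zero go bias (−0.17) and near-zero punishment-domain
Pavlovian bias (−0.06), with similar learning rates and sensitivities.
Group SDs on the unconstrained scale (0.4–0.7 depending on parameter)
were chosen once as moderate between-subject heterogeneity typical of
hierarchical fits in this model family, and are not tuned thereafter.
Default group sizes are 17 and 14.

All randomness flows from a single integer seed through one sequential
RNG stream consumed in a fixed order (parameters, then per subject a
schedule, then trial-by-trial actions and feedback). This is
bit-reproducible; a splittable per-subject stream hierarchy would add
machinery base R does not provide without changing any scientific
property of the data.

What the generator does *not* emulate: reaction times, missing or late
responses (the trial record forces a binary action), session or practice
effects, drift or lapses over time, and any mechanistic effect of the
stimulation itself — group differences enter only through the parameter
hyperpriors. Passing tests on synthetic data therefore demonstrate that
the estimator recovers the model's own truth, not that the model is true
of any particular empirical population.

## Hierarchical estimation

The hierarchy is non-centered: subject `i`'s unconstrained parameter `k`
is `mu_k + sigma_k z_ik`, `z ~ N(0,1)`. Priors are weakly informative:
`mu_k ~ N(0,1)` for `xi`, `eps` and the `rho` family (on the log scale,
so the prior median sensitivity is 1 with long upper tail), `N(0,10)` for
`b` and the `pi` family, and `sigma_k ~ half-N(0,1)`. All scales are
exposed through `gng_priors()`.

The sampler is an interweaved scheme implemented in C++:

* **subject step** — adaptive random-walk Metropolis on each scalar
  `z_ik`, using only that subject's session likelihood; proposal scales
  adapt in batches of 50 during warmup toward the standard 0.44
  componentwise acceptance target, with adaptation frozen afterward;
* **group-mean step** — given the subject-level unconstrained values
  (held fixed), the conditional for `mu_k` under its normal prior is
  conjugate and is drawn exactly (a centered-parameterization Gibbs
  update); offsets are then recomputed;
* **group-SD step** — Metropolis on `log sigma_k` against the
  half-normal prior, the subject-level normal likelihood and the
  Jacobian, again with the subject values held fixed.

Alternating centered and non-centered conditionals in this way breaks
the mean/offset and scale/offset posterior correlations that make either
parameterization alone mix slowly. Because scalar-update samplers remain
autocorrelated, retained draws are thinned (default: every 5th sweep);
the defaults (4 chains, 2000 warmup, 2000 kept) retain 8000 draws. Chains
start from a common modest initialization (low noise, mid learning rate,
neutral biases, `rho ≈ 4.5`) jittered per chain for overdispersion, with
chain seeds derived deterministically from the fit seed.

Convergence is summarized by split-Rhat (each chain halved, classic
between/within variance ratio) computed for *every* sampled quantity —
group means, group SDs, and all subject-level parameters. A fit whose
maximum exceeds 1.1 is flagged and warns; it is never a silent success.
The sampler performs no Hamiltonian integration, so the divergence count
reported by `gng_diagnostics()` is structurally zero.

The likelihood floors per-trial probabilities at 1e−300 before the log —
reachable only at `xi = 0` with extreme weights — so the sampler sees
−∞-free arithmetic without altering any realistic likelihood value.

## Model comparison

PSIS-LOO is computed from the per-subject pointwise log-likelihood
(each subject's session summed per retained draw). The subject is the
cross-validation unit because subjects are the exchangeable units of the
hierarchy. Importance ratios `1/p(y_i | theta_s)` have their upper tail
(the smaller of S/5 and 3·sqrt(S) weights) replaced by expected order
statistics of a generalized Pareto distribution fitted by the
profile-likelihood grid method with a weak prior pulling the shape
toward 0.5, then truncated at the raw maximum. The implementation is
validated against a conjugate normal-mean model whose leave-one-out
predictive densities are available in closed form.

Per-unit Pareto shapes are reported, and values above 0.7 are flagged but
not refit. With ~180 informative trials per subject and small cohorts,
high shapes are common — each subject materially moves the posterior —
so subject-level LOOIC differences between models should be read
alongside their standard errors, as the ranking table reports.
`looic = −2·elpd_loo` by construction.

## Group inference and prediction

Group differences subtract the natural-scale group-mean posteriors of
two *separately fitted* groups. Separate fits have no natural draw
pairing, so draws are paired by index after a seeded permutation of each
fit's pooled draws — the arbitrary pairing made explicit and
reproducible. The difference's mean is exactly pairing-invariant; HDI
endpoints are invariant up to Monte-Carlo error. A difference is credible
when its 95% HDI excludes zero.

The HDI is the shortest window of `ceiling(mass·n)` consecutive sorted
draws; ties in window width resolve to the leftmost window, a
tie-break that only matters for discrete or duplicated draws.

One-step-ahead prediction rolls the latent state forward per posterior
draw conditioning on the subject's *actual* actions and feedback, so the
prediction for trial `t` uses history `1..t−1` only (truncating a
session leaves earlier predictions untouched; a test asserts this prefix
property). Predictions average over draws, and each subject's Pearson
correlation between predicted p(go) and observed go frequency is
computed across the four condition-level pairs by default — the
condition-level construction mirrors how such predictive checks are
summarized for this task; a consecutive-trial-bin variant
(`method = "bins"`) is provided because the condition-level reading is
not the only defensible one. With only four points per subject the
condition-level correlation is coarse; treat it as a calibration summary,
not an effect size.

Behavioural condition comparisons use the two-sided pooled-variance
Student's t-test, unpaired by default. Unpaired comparison of two
conditions *within* a group is a documented convention of this
literature's reporting (its degrees of freedom are `n_A + n_B − 2` even
when both samples come from the same subjects); the paired mode is
available and preferable when subject pairing is real. No
multiple-testing correction is applied; per-test p-values are reported
as-is.

## Problem sizes used for validation

The test suite and acceptance script validate at sizes a reviewer can
rerun at a desk: likelihood oracle equivalence on 100 random sessions
per variant at 1e−10; convergence and recovery on cohorts of 15–20
subjects × 180 trials with 2–4 chains and 1000 warmup / 1000 kept
(thinned) draws; model recovery (split-bias data selecting the
split-bias model by LOOIC) at 15 subjects; and the two-group
punishment-bias pipeline at 20 subjects per group. These sizes were
chosen as the smallest at which the respective claims are
Monte-Carlo-stable, and they match or exceed the cohort sizes of typical
single-site studies with this task.

## Known limitations

* No reaction-time modelling; the likelihood is purely choice-based.
* Missing responses are not representable; rows without a binary action
  are rejected at validation.
* The random-walk sampler trades gradient information for implementation
  transparency; it needs thinning and is best suited to the moderate
  dimensionalities of this model family (it has been validated up to
  ~40 subjects × 7 parameters, where a full fit takes tens of seconds).
* Subject-level PSIS-LOO shapes frequently exceed 0.7 at small N, an
  intrinsic property of highly informative units; the package reports
  rather than hides this.
* The exclusion rule (go-to-win accuracy < 0.1) presumes every subject
  has go-to-win trials; cohorts without them error out rather than guess.
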