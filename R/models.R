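#' Model specifications for the go/no-go action-weight family
#'
#' Three nested Rescorla-Wagner action-weight models of go/no-go behaviour:
#'
#' * `"m1"` (5 parameters: xi, eps, b, pi, rho) — RW learning with
#'   irreducible noise, go bias, a single Pavlovian bias weight and a
#'   single outcome sensitivity.
#' * `"m2"` (6 parameters) — splits outcome sensitivity into `rho_rew` and
#'   `rho_pun` for reward- and punishment-domain cues.
#' * `"m3"` (7 parameters) — additionally splits the Pavlovian bias into
#'   `pi_rew` and `pi_pun`.
#'
#' Parameter meanings: `xi` (irreducible noise, in \[0,1\]) mixes the
#' softmax choice with uniform randomness; `eps` (learning rate, \[0,1\])
#' scales prediction-error updates; `b` (go bias, unconstrained) is added
#' to the go action weight; the `pi` family (unconstrained) weights the
#' stimulus value V(s) into the go action weight; the `rho` family
#' (positive) scales feedback before updating. `b` and `pi` are
#' unconstrained reals: fitted group means for Pavlovian bias can be
#' negative, so no positivity constraint is imposed.
#'
#' @param variant `"m1"`, `"m2"` or `"m3"`.
#' @return A `gng_model` object with fields `variant`, `code` (1..3),
#'   `parameters` and per-parameter `transform` (`"unit_interval"`,
#'   `"unconstrained"` or `"positive"`).
#' @examples
#' gng_model("m3")
#' @export
gng_model <- function(variant = c("m3", "m2", "m1")) {
  variant <- match.arg(tolower(variant[1]), c("m3", "m2", "m1"))
  pars <- switch(variant,
    m1 = c("xi", "eps", "b", "pi", "rho"),
    m2 = c("xi", "eps", "b", "pi", "rho_rew", "rho_pun"),
    m3 = c("xi", "eps", "b", "pi_rew", "pi_pun", "rho_rew", "rho_pun"))
  tr <- ifelse(pars %in% c("xi", "eps"), "unit_interval",
        ifelse(grepl("^rho", pars), "positive", "unconstrained"))
  structure(list(variant = variant,
                 code = match(variant, c("m1", "m2", "m3")),
                 parameters = pars,
                 transform = stats::setNames(tr, pars)),
            class = "gng_model")
}

#' @export
print.gng_model <- function(x, ...) {
  cat("Go/no-go action-weight model", toupper(x$variant), "-",
      length(x$parameters), "parameters\n  ")
  cat(paste0(x$parameters, " (", unname(x$transform), ")"), sep = "\n  ")
  invisible(x)
}

#' Map unconstrained parameters to the natural scale and back
#'
#' Hierarchical sampling operates on an unconstrained scale; natural-scale
#' parameters are obtained by the standard-normal CDF for unit-interval
#' parameters (xi, eps), the exponential for positive parameters (rho
#' family), and the identity for unconstrained ones (b, pi family).
#' `untransform_params()` is the exact inverse.
#'
#' @param u numeric vector on the unconstrained scale, length equal to the
#'   model's parameter count.
#' @param model a [gng_model].
#' @return Named numeric vector on the natural scale (or unconstrained
#'   scale for `untransform_params`).
#' @export
transform_params <- function(u, model) {
  if (length(u) != length(model$parameters))
    stop("expected ", length(model$parameters), " values, got ", length(u))
  out <- as.numeric(u)
  ui <- model$transform == "unit_interval"
  pos <- model$transform == "positive"
  out[ui] <- stats::pnorm(out[ui])
  out[pos] <- exp(out[pos])
  stats::setNames(out, model$parameters)
}

#' @rdname transform_params
#' @param p numeric vector on the natural scale.
#' @export
untransform_params <- function(p, model) {
  if (length(p) != length(model$parameters))
    stop("expected ", length(model$parameters), " values, got ", length(p))
  out <- as.numeric(p)
  ui <- model$transform == "unit_interval"
  pos <- model$transform == "positive"
  out[ui] <- stats::qnorm(out[ui])
  out[pos] <- log(out[pos])
  stats::setNames(out, model$parameters)
}

# expand any variant's natural parameter vector to the common 7-slot layout
# (xi, eps, b, pi_rew, pi_pun, rho_rew, rho_pun)
expand_params <- function(p, model) {
  p <- as.numeric(p)
  switch(model$variant,
    m1 = c(p[1:3], p[4], p[4], p[5], p[5]),
    m2 = c(p[1:3], p[4], p[4], p[5], p[6]),
    m3 = p)
}

#' Latent state of a learning agent
#'
#' `Q` is a 2 x 4 matrix of action values (rows: no-go, go; columns: cues
#' 1..4) and `V` a length-4 vector of stimulus values; both start at zero,
#' so the first choice depends only on the go bias and noise.
#'
#' @return A list with matrices `Q` and vector `V`, all zero.
#' @export
init_state <- function() {
  list(Q = matrix(0, 2, 4, dimnames = list(c("nogo", "go"), NULL)),
       V = rep(0, 4))
}

#' Action weights for one cue
#'
#' The go weight is `Q(go,s) + b + pi * V(s)` with `pi` the Pavlovian bias
#' for the cue's domain (split by domain under m3, shared otherwise); the
#' no-go weight is `Q(nogo,s)` alone.
#'
#' @param state a latent state from [init_state] / [update_state].
#' @param params named natural-scale parameter vector for `model`.
#' @param cue cue id 1..4.
#' @param model a [gng_model].
#' @return Numeric `c(W_go, W_nogo)`.
#' @export
action_weights <- function(state, params, cue, model) {
  e <- expand_params(params, model)
  pi_eff <- if (cue_domain(cue) == "reward") e[4] else e[5]
  c(W_go = state$Q["go", cue] + e[3] + pi_eff * state$V[cue],
    W_nogo = state$Q["nogo", cue])
}

#' Squashed-softmax probability of a go response
#'
#' The two-option softmax of the action weights, mixed with uniform noise:
#' `p(go) = logistic(W_go - W_nogo) * (1 - xi) + xi/2`. Probabilities are
#' therefore bounded inside `[xi/2, 1 - xi/2]`.
#'
#' @param W_go,W_nogo action weights.
#' @param xi irreducible noise in \[0,1\].
#' @return Probability of a go response.
#' @export
choice_prob_go <- function(W_go, W_nogo, xi) {
  stopifnot(xi >= 0, xi <= 1)
  stats::plogis(W_go - W_nogo) * (1 - xi) + xi / 2
}

#' Rescorla-Wagner update of the latent state
#'
#' Applies the delta rule to the chosen action's Q value and to the
#' stimulus value V (which updates every trial regardless of action):
#' `Q(a,s) <- Q(a,s) + eps * (rho * r - Q(a,s))` and likewise for `V(s)`,
#' with `rho` the outcome sensitivity for the cue's domain (split under
#' m2/m3; because reward cues only yield feedback in \{0,+1\} and
#' punishment cues in \{-1,0\}, domain- and outcome-sign-based assignment
#' coincide in this task).
#'
#' @inheritParams action_weights
#' @param action 1 = go, 0 = no-go.
#' @param feedback -1, 0 or +1.
#' @return The updated latent state.
#' @export
update_state <- function(state, cue, action, feedback, params, model) {
  e <- expand_params(params, model)
  rho_eff <- if (cue_domain(cue) == "reward") e[6] else e[7]
  eps <- e[2]
  a <- if (action == 1) "go" else "nogo"
  pe <- rho_eff * feedback
  state$Q[a, cue] <- state$Q[a, cue] + eps * (pe - state$Q[a, cue])
  state$V[cue] <- state$V[cue] + eps * (pe - state$V[cue])
  state
}

#' Log-likelihood of one subject's session
#'
#' Deterministic forward pass over the subject's ordered trials: per trial
#' the action weights are computed from the current state, the squashed
#' softmax gives p(go), the observed action's log-probability accumulates,
#' and the state is updated with the observed action and feedback.
#'
#' @param params named natural-scale parameter vector for `model`.
#' @param trials one subject's trials: a data frame with columns `trial`,
#'   `cue`, `keyPressed`, `outcome` (a single-subject `trial_table` slice).
#' @param model a [gng_model].
#' @return A list with `total` (sum of log-probabilities, always <= 0) and
#'   `pointwise` (per-trial log-probabilities).
#' @export
subject_loglik <- function(params, trials, model) {
  if (!is.null(trials$subjID) && length(unique(trials$subjID)) > 1)
    stop("subject_loglik expects a single subject's trials")
  if (!identical(as.integer(trials$trial), seq_len(nrow(trials))))
    stop("trials must be the complete ordered session (trial = 1, 2, ...)")
  cpp_subject_loglik(as.integer(trials$cue), as.integer(trials$keyPressed),
                     as.integer(trials$outcome), as.numeric(params),
                     model$code)
}
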