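#' Group-level hyperparameters on the unconstrained scale
#'
#' A hierarchical cohort is described by a per-parameter group mean and
#' group SD on the unconstrained scale; subject-level unconstrained values
#' are drawn Normal(mean, sd) and mapped to the natural scale with
#' [transform_params].
#'
#' @param model a [gng_model].
#' @param mean named numeric vector of unconstrained group means (names
#'   must match `model$parameters`).
#' @param sd named numeric vector of positive group SDs.
#' @return A `gng_hyperparams` object.
#' @export
group_hyperparams <- function(model, mean, sd) {
  pars <- model$parameters
  stopifnot(all(pars %in% names(mean)), all(pars %in% names(sd)))
  mean <- mean[pars]; sd <- sd[pars]
  if (any(sd < 0)) stop("group SDs must be non-negative")
  structure(list(model = model, mean = mean, sd = sd),
            class = "gng_hyperparams")
}

#' Default study hyperparameters
#'
#' Two hyperparameter templates emulating a stimulation study's
#' qualitative group structure under model m3: a `"control"` group with
#' moderate noise, positive go bias and positive punishment-domain
#' Pavlovian bias, and an `"active"` group with lower noise, near-zero go
#' bias and near-zero punishment-domain Pavlovian bias. Learning rate and
#' outcome sensitivities are similar across groups. Values for m1/m2 are
#' obtained by collapsing the split parameters.
#'
#' @param group `"control"` or `"active"`.
#' @param model a [gng_model].
#' @return A `gng_hyperparams` object.
#' @export
default_hyperparams <- function(group = c("control", "active"),
                                model = gng_model("m3")) {
  group <- match.arg(group)
  m3mean <- if (group == "control") {
    c(xi = stats::qnorm(0.09), eps = stats::qnorm(0.32), b = 1.27,
      pi_rew = -0.14, pi_pun = 0.41, rho_rew = log(12.3),
      rho_pun = log(8.8))
  } else {
    c(xi = stats::qnorm(0.03), eps = stats::qnorm(0.43), b = -0.17,
      pi_rew = 0.05, pi_pun = -0.06, rho_rew = log(12.4),
      rho_pun = log(6.2))
  }
  m3sd <- c(xi = 0.4, eps = 0.5, b = 0.7, pi_rew = 0.5, pi_pun = 0.5,
            rho_rew = 0.4, rho_pun = 0.4)
  mean <- switch(model$variant,
    m3 = m3mean,
    m2 = c(m3mean[c("xi", "eps", "b")],
           pi = unname(base::mean(m3mean[c("pi_rew", "pi_pun")])),
           m3mean[c("rho_rew", "rho_pun")]),
    m1 = c(m3mean[c("xi", "eps", "b")],
           pi = unname(base::mean(m3mean[c("pi_rew", "pi_pun")])),
           rho = unname(base::mean(m3mean[c("rho_rew", "rho_pun")]))))
  sd <- switch(model$variant,
    m3 = m3sd,
    m2 = c(m3sd[c("xi", "eps", "b")], pi = 0.5,
           m3sd[c("rho_rew", "rho_pun")]),
    m1 = c(m3sd[c("xi", "eps", "b")], pi = 0.5, rho = 0.4))
  group_hyperparams(model, mean, sd)
}

#' @export
print.gng_hyperparams <- function(x, ...) {
  cat("Group hyperparameters (unconstrained scale), model",
      toupper(x$model$variant), "\n")
  print(rbind(mean = x$mean, sd = x$sd))
  cat("natural-scale group means:\n")
  print(round(transform_params(x$mean, x$model), 3))
  invisible(x)
}

#' Draw subject parameters from a hierarchical group
#'
#' @param hyper a [group_hyperparams] object.
#' @param n number of subjects.
#' @return A list with `unconstrained` (n x K matrix) and `natural` (n x K
#'   matrix) subject parameters, drawn from the current RNG stream.
#' @export
sample_group_params <- function(hyper, n) {
  stopifnot(n >= 1)
  K <- length(hyper$mean)
  u <- matrix(stats::rnorm(n * K, rep(hyper$mean, each = n),
                           rep(hyper$sd, each = n)),
              n, K, dimnames = list(NULL, names(hyper$mean)))
  nat <- t(apply(u, 1, transform_params, model = hyper$model))
  colnames(nat) <- names(hyper$mean)
  list(unconstrained = u, natural = nat)
}

#' Simulate one agent's session
#'
#' Runs the model generatively over a cue schedule: per trial the choice
#' probability is computed from the current latent state, an action is
#' sampled, feedback is sampled from the task contingency, and the state
#' is updated.
#'
#' @param params named natural-scale parameter vector.
#' @param schedule cue sequence from [make_schedule].
#' @param model a [gng_model].
#' @param design a [task_design].
#' @param subject_id id string for the output table.
#' @return A single-subject `trial_table`.
#' @export
simulate_subject <- function(params, schedule, model = gng_model("m3"),
                             design = task_design(), subject_id = "sim") {
  e <- expand_params(params, model)
  n <- length(schedule)
  action <- integer(n); feedback <- integer(n)
  state <- init_state()
  for (t in seq_len(n)) {
    s <- schedule[t]
    w <- action_weights(state, params, s, model)
    p <- choice_prob_go(w[1], w[2], e[1])
    action[t] <- as.integer(stats::runif(1) < p)
    feedback[t] <- sample_feedback(s, action[t], design)
    state <- update_state(state, s, action[t], feedback[t], params, model)
  }
  trial_table(rep(subject_id, n), seq_len(n), schedule, action, feedback)
}

#' Configure and generate a synthetic two-group study
#'
#' `generate_study()` emulates a two-group (active vs control) study:
#' subject parameters are drawn from each group's hyperparameters, every
#' subject gets an independent uniformly shuffled schedule, and sessions
#' are simulated generatively. All randomness flows from `seed` through a
#' single sequential RNG stream consumed in a fixed order, so identical
#' configs reproduce identical studies bit-for-bit.
#'
#' @param n_per_group integer vector of length 2, subjects in groups A and
#'   B (default `c(17, 14)`, an active/control allocation).
#' @param hyper_A,hyper_B [group_hyperparams] for the two groups.
#' @param design a [task_design].
#' @param seed integer seed.
#' @param model a [gng_model] (must match both hyperparameter sets).
#' @return A `gng_study`: list with `tables` (named list of two
#'   `trial_table`s, `A` and `B`), and `manifest` recording true subject
#'   parameters, hyperparameters, design, and seed.
#' @export
generate_study <- function(n_per_group = c(17, 14),
                           hyper_A = default_hyperparams("active"),
                           hyper_B = default_hyperparams("control"),
                           design = task_design(), seed = 1,
                           model = hyper_A$model) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 1))
  set.seed(seed)
  sim_group <- function(hyper, n, prefix) {
    pars <- sample_group_params(hyper, n)
    tabs <- lapply(seq_len(n), function(i) {
      sched <- sample(rep(1:4, each = design$n_trials_per_condition))
      simulate_subject(pars$natural[i, ], sched, model, design,
                       subject_id = sprintf("%s%02d", prefix, i))
    })
    tab <- do.call(rbind, lapply(tabs, as.data.frame))
    list(table = validate_trials(tab), params = pars)
  }
  gA <- sim_group(hyper_A, n_per_group[1], "A")
  gB <- sim_group(hyper_B, n_per_group[2], "B")
  structure(list(
    tables = list(A = gA$table, B = gB$table),
    manifest = list(seed = seed, design = design, model = model$variant,
                    n_per_group = n_per_group,
                    hyper = list(A = hyper_A[c("mean", "sd")],
                                 B = hyper_B[c("mean", "sd")]),
                    true_params = list(A = gA$params, B = gB$params))),
    class = "gng_study")
}

#' @export
print.gng_study <- function(x, ...) {
  cat("Synthetic two-group go/no-go study (model",
      toupper(x$manifest$model), ")\n")
  cat("  group A:", x$manifest$n_per_group[1], "subjects x",
      x$manifest$design$n_trials, "trials\n")
  cat("  group B:", x$manifest$n_per_group[2], "subjects x",
      x$manifest$design$n_trials, "trials\n")
  cat("  seed:", x$manifest$seed, "\n")
  invisible(x)
}

#' Write a study's artifacts to disk
#'
#' Writes the two trial-table CSVs plus a JSON manifest (true parameters,
#' hyperparameters, seed, design) into `dir`.
#'
#' @param study a `gng_study` from [generate_study].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pA <- file.path(dir, "group_A_trials.csv")
  pB <- file.path(dir, "group_B_trials.csv")
  pM <- file.path(dir, "manifest.json")
  write_trials(study$tables$A, pA)
  write_trials(study$tables$B, pB)
  m <- study$manifest
  m$design <- m$design[c("n_trials_per_condition", "contingency")]
  m$true_params <- lapply(m$true_params, function(g)
    list(unconstrained = as.data.frame(g$unconstrained),
         natural = as.data.frame(g$natural)))
  jsonlite::write_json(m, pM, auto_unbox = TRUE, digits = NA)
  invisible(c(pA, pB, pM))
}
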