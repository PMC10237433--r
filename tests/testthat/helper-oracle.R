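# Independent trial-by-trial reference implementation of the action-weight
# model likelihood, written against the equations directly (explicit
# two-option softmax, its own state bookkeeping) and kept free of package
# internals so it can serve as an oracle.
oracle_loglik <- function(pars, cue, action, feedback, variant) {
  Q <- matrix(0, 4, 2)  # rows: cue; columns: action+1 (1 = nogo, 2 = go)
  V <- numeric(4)
  pw <- numeric(length(cue))
  for (t in seq_along(cue)) {
    s <- cue[t]
    rew <- s == 1 || s == 3
    pi_eff <- if (variant == "m3") {
      if (rew) pars[["pi_rew"]] else pars[["pi_pun"]]
    } else pars[["pi"]]
    rho_eff <- if (variant == "m1") pars[["rho"]] else {
      if (rew) pars[["rho_rew"]] else pars[["rho_pun"]]
    }
    w_go <- Q[s, 2] + pars[["b"]] + pi_eff * V[s]
    w_ng <- Q[s, 1]
    p_go <- exp(w_go) / (exp(w_go) + exp(w_ng)) *
      (1 - pars[["xi"]]) + pars[["xi"]] / 2
    pw[t] <- log(if (action[t] == 1) p_go else 1 - p_go)
    r <- rho_eff * feedback[t]
    a <- action[t] + 1
    Q[s, a] <- Q[s, a] + pars[["eps"]] * (r - Q[s, a])
    V[s] <- V[s] + pars[["eps"]] * (r - V[s])
  }
  list(total = sum(pw), pointwise = pw)
}

# random natural-scale parameters for a given variant, in realistic ranges
random_params <- function(variant) {
  base <- c(xi = runif(1, 0, 0.4), eps = runif(1, 0.05, 0.9),
            b = rnorm(1, 0, 1))
  switch(variant,
    m1 = c(base, pi = rnorm(1, 0, 1), rho = exp(runif(1, -0.5, 2.5))),
    m2 = c(base, pi = rnorm(1, 0, 1), rho_rew = exp(runif(1, -0.5, 2.5)),
           rho_pun = exp(runif(1, -0.5, 2.5))),
    m3 = c(base, pi_rew = rnorm(1, 0, 1), pi_pun = rnorm(1, 0, 1),
           rho_rew = exp(runif(1, -0.5, 2.5)),
           rho_pun = exp(runif(1, -0.5, 2.5))))
}

# random valid session (feedback respects the cue-domain coding)
random_session <- function(n = 80) {
  cue <- sample(1:4, n, replace = TRUE)
  action <- sample(0:1, n, replace = TRUE)
  feedback <- ifelse(cue %in% c(1, 3), sample(0:1, n, replace = TRUE),
                     sample(c(-1L, 0L), n, replace = TRUE))
  data.frame(subjID = "s", trial = seq_len(n), cue = cue,
             keyPressed = action, outcome = feedback,
             stringsAsFactors = FALSE)
}

# small synthetic cohort for fitting tests
make_cohort <- function(n_subj, hyper = default_hyperparams("control"),
                        seed = 1, design = task_design()) {
  set.seed(seed)
  pars <- sample_group_params(hyper, n_subj)
  tabs <- lapply(seq_len(n_subj), function(i)
    simulate_subject(pars$natural[i, ], make_schedule(design),
                     hyper$model, design,
                     subject_id = sprintf("s%02d", i)))
  list(table = validate_trials(do.call(rbind, lapply(tabs, as.data.frame))),
       params = pars, hyper = hyper)
}
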