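#' Priors for the hierarchical model
#'
#' Weakly informative defaults: unconstrained group means ~ Normal(0, 1)
#' for xi, eps and the rho family (whose unconstrained scale is the log),
#' Normal(0, 10) for the go bias and the pi family; group SDs ~
#' half-Normal(0, 1); subject offsets ~ Normal(0, 1).
#'
#' @param model a [gng_model].
#' @param mu_sd optional named vector overriding prior SDs of the
#'   unconstrained group means.
#' @param sigma_sd scale of the half-Normal prior on group SDs.
#' @return A `gng_priors` list.
#' @export
gng_priors <- function(model = gng_model("m3"), mu_sd = NULL, sigma_sd = 1) {
  default <- ifelse(model$parameters %in% c("b", "pi", "pi_rew", "pi_pun"),
                    10, 1)
  names(default) <- model$parameters
  if (!is.null(mu_sd)) default[names(mu_sd)] <- mu_sd
  structure(list(mu_sd = default, sigma_sd = sigma_sd),
            class = "gng_priors")
}

#' Fit a hierarchical Bayesian go/no-go model
#'
#' Estimates group-level means and SDs and subject-level parameters of a
#' go/no-go action-weight model by MCMC. The hierarchy is non-centered:
#' each subject's unconstrained parameter is `mu_k + sigma_k * z_ik` with
#' standard-normal offsets `z`, mapped to the natural scale per the model's
#' transforms. The sampler interweaves adaptive random-walk Metropolis
#' updates of the subject offsets with conjugate Gibbs updates of the group
#' means and Metropolis updates of the group SDs conditional on the
#' subject-level values; scalar proposals adapt toward 0.44 acceptance
#' during warmup. Because scalar-update samplers are autocorrelated, kept
#' draws are thinned (default every 5th sweep).
#'
#' Convergence is assessed by split-Rhat over every sampled quantity; a fit
#' with any Rhat > 1.1 is flagged (`fit$converged`) and a warning is
#' emitted, never a silent success.
#'
#' @param table a `trial_table` (>= 2 subjects, already past exclusions).
#' @param model a [gng_model].
#' @param chains number of independent chains (default 4).
#' @param warmup adaptation sweeps discarded per chain (default 2000).
#' @param keep retained draws per chain (default 2000, so defaults retain
#'   `4 x 2000 = 8000` draws).
#' @param thin sweeps between retained draws (default 5).
#' @param seed integer seed; chain streams are derived from it.
#' @param priors a [gng_priors].
#' @return A `gng_fit` with elements `mu`, `sigma` (draw arrays,
#'   `chains x keep x K`, unconstrained scale), `theta` (subject-level
#'   unconstrained draws, `chains x keep x (N*K)`), `pointwise`
#'   (`(chains*keep) x N` per-subject log-likelihoods), `rhat`,
#'   `converged`, `subjects`, `model`, `config`.
#' @export
gng_fit <- function(table, model = gng_model("m3"), chains = 4,
                    warmup = 2000, keep = 2000, thin = 5, seed = 1,
                    priors = gng_priors(model)) {
  stopifnot(chains >= 1, warmup >= 1, keep >= 1, thin >= 1)
  table <- validate_trials(table)
  ids <- unique(table$subjID)
  if (length(ids) < 2) stop("hierarchical fitting needs at least 2 subjects")
  K <- length(model$parameters)

  # concatenate per-subject sessions in first-appearance order
  cue <- integer(0); act <- integer(0); fb <- integer(0)
  start <- integer(length(ids)); len <- integer(length(ids))
  for (i in seq_along(ids)) {
    s <- table[table$subjID == ids[i], ]
    s <- s[order(s$trial), ]
    start[i] <- length(cue)
    len[i] <- nrow(s)
    cue <- c(cue, s$cue); act <- c(act, s$keyPressed); fb <- c(fb, s$outcome)
  }

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  # initial group means: low noise, mid learning rate, neutral biases,
  # moderate sensitivity; jittered per chain for overdispersed starts
  mu0 <- ifelse(model$parameters == "xi", -1.5,
         ifelse(model$parameters == "eps", -0.5,
         ifelse(grepl("^rho", model$parameters), 1.5, 0)))

  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    res[[ch]] <- cpp_mcmc_chain(cue, act, fb, start, len, model$code,
                                as.integer(warmup), as.integer(keep),
                                as.integer(thin), unname(priors$mu_sd),
                                priors$sigma_sd,
                                mu0 + stats::rnorm(K, 0, 0.4),
                                exp(stats::rnorm(K, log(0.3), 0.3)))
  }

  arr <- function(field, p) {
    a <- array(NA_real_, c(chains, keep, p))
    for (ch in seq_len(chains)) a[ch, , ] <- res[[ch]][[field]]
    a
  }
  N <- length(ids)
  fit <- structure(list(
    mu = arr("mu", K), sigma = arr("sigma", K), theta = arr("theta", N * K),
    pointwise = do.call(rbind, lapply(res, `[[`, "pointwise")),
    subjects = ids, model = model, priors = priors, data = table,
    config = list(chains = chains, warmup = warmup, keep = keep,
                  thin = thin, seed = seed)),
    class = "gng_fit")
  colnames(fit$pointwise) <- ids

  d <- gng_diagnostics(fit)
  fit$rhat <- d$rhat
  fit$converged <- d$max_rhat <= 1.1
  if (!fit$converged)
    warning("sampler may not have converged: max split-Rhat = ",
            round(d$max_rhat, 3), " > 1.1", call. = FALSE)
  fit
}

#' Posterior draws of a group-level mean on the natural scale
#'
#' @param fit a [gng_fit].
#' @param parameter parameter name (one of `fit$model$parameters`).
#' @return Numeric vector of length `chains * keep`: the transformed group
#'   mean `transform(mu_k)` per retained draw.
#' @export
extract_group_means <- function(fit, parameter) {
  k <- match(parameter, fit$model$parameters)
  if (is.na(k))
    stop("unknown parameter '", parameter, "'; valid names: ",
         paste(fit$model$parameters, collapse = ", "))
  u <- as.vector(t(fit$mu[, , k]))  # chain-major flatten
  tr <- fit$model$transform[[k]]
  if (tr == "unit_interval") stats::pnorm(u)
  else if (tr == "positive") exp(u) else u
}

# subject-level natural-scale draws for one subject: (chains*keep) x K
subject_draws <- function(fit, i) {
  K <- length(fit$model$parameters)
  idx <- (i - 1) * K + seq_len(K)
  u <- do.call(rbind, lapply(seq_len(dim(fit$theta)[1]),
                             function(ch) fit$theta[ch, , idx]))
  nat <- t(apply(u, 1, transform_params, model = fit$model))
  colnames(nat) <- fit$model$parameters
  nat
}

#' @export
print.gng_fit <- function(x, ...) {
  cat("Hierarchical Bayesian go/no-go fit, model",
      toupper(x$model$variant), "\n")
  cat("  subjects:", length(x$subjects), " chains:", x$config$chains,
      " retained draws:", x$config$chains * x$config$keep, "\n")
  cat("  max split-Rhat:", round(max(x$rhat$rhat, na.rm = TRUE), 3),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.gng_fit <- function(object, prob = 0.95, ...) {
  pars <- object$model$parameters
  tab <- do.call(rbind, lapply(pars, function(p) {
    d <- extract_group_means(object, p)
    h <- hdi(d, prob)
    data.frame(parameter = p, mean = mean(d), sd = stats::sd(d),
               hdi_low = h[1], hdi_high = h[2])
  }))
  rownames(tab) <- NULL
  mu_rhat <- object$rhat$rhat[match(paste0("mu_", pars),
                                    object$rhat$parameter)]
  tab$rhat <- mu_rhat
  out <- list(table = tab, model = object$model,
              config = object$config, converged = object$converged,
              max_rhat = max(object$rhat$rhat, na.rm = TRUE))
  class(out) <- "summary.gng_fit"
  out
}

#' @export
print.summary.gng_fit <- function(x, ...) {
  cat("Group-level posterior (natural scale), model",
      toupper(x$model$variant), "\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  cat("retained draws:", x$config$chains * x$config$keep,
      " max split-Rhat:", round(x$max_rhat, 3), "\n")
  invisible(x)
}

#' @export
coef.gng_fit <- function(object, level = c("group", "subject"), ...) {
  level <- match.arg(level)
  if (level == "group") {
    vapply(object$model$parameters,
           function(p) mean(extract_group_means(object, p)), numeric(1))
  } else {
    out <- t(vapply(seq_along(object$subjects),
                    function(i) colMeans(subject_draws(object, i)),
                    numeric(length(object$model$parameters))))
    rownames(out) <- object$subjects
    out
  }
}

#' @export
plot.gng_fit <- function(x, parameters = x$model$parameters, ...) {
  op <- graphics::par(mfrow = c(ceiling(length(parameters) / 2), 2),
                      mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (p in parameters) {
    k <- match(p, x$model$parameters)
    graphics::matplot(t(x$mu[, , k]), type = "l", lty = 1,
                      main = paste0("mu[", p, "] (unconstrained)"),
                      xlab = "", ylab = "")
  }
  invisible(x)
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws one posterior sample of each subject's parameters per replicate
#' and simulates a fresh session on a new schedule, giving replicated
#' datasets for posterior-predictive checking.
#'
#' @param object a [gng_fit].
#' @param nsim number of replicated studies.
#' @param seed integer seed.
#' @param design a [task_design].
#' @param ... unused.
#' @return A list of `nsim` `trial_table`s.
#' @export
simulate.gng_fit <- function(object, nsim = 1, seed = 1,
                             design = task_design(), ...) {
  set.seed(seed)
  S <- nrow(object$pointwise)
  lapply(seq_len(nsim), function(r) {
    tabs <- lapply(seq_along(object$subjects), function(i) {
      draw <- subject_draws(object, i)[sample.int(S, 1), ]
      simulate_subject(draw, make_schedule(design), object$model, design,
                       subject_id = object$subjects[i])
    })
    validate_trials(do.call(rbind, lapply(tabs, as.data.frame)))
  })
}
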