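#' One-step-ahead posterior prediction
#'
#' For every posterior draw and subject, the latent state is rolled
#' forward conditioning on the subject's actual actions and feedback, so
#' the predicted p(go) for trial t uses only trials 1..t-1; predictions
#' are averaged over draws. Predictions are aggregated per subject and
#' condition, and each subject's Pearson correlation between predicted
#' p(go) and observed go frequency is computed, either across the four
#' condition-level pairs (`method = "condition"`, the default) or across
#' consecutive within-condition trial bins (`method = "bins"`).
#'
#' @param fit a [gng_fit].
#' @param table the trial table the fit was produced on (defaults to the
#'   data stored in the fit); subjects must match.
#' @param max_draws optional cap on posterior draws used (a deterministic
#'   thinned subset), to bound compute; `NULL` uses all retained draws.
#' @param method correlation construction, `"condition"` or `"bins"`.
#' @param bins number of consecutive trial bins per condition when
#'   `method = "bins"`.
#' @return A `gng_prediction`: `trial` (per-trial predicted p(go)),
#'   `by_condition` (subject x condition predicted and observed),
#'   `subject_r` (per-subject correlation), `mean_r` (cohort mean).
#' @export
one_step_ahead <- function(fit, table = fit$data, max_draws = NULL,
                           method = c("condition", "bins"), bins = 9) {
  method <- match.arg(method)
  table <- validate_trials(table)
  ids <- unique(table$subjID)
  if (!identical(sort(ids), sort(fit$subjects)))
    stop("subjects in 'table' do not match the subjects the model was fit to")
  trial_rows <- vector("list", length(ids))
  for (i in seq_along(fit$subjects)) {
    id <- fit$subjects[i]
    s <- table[table$subjID == id, ]
    s <- s[order(s$trial), ]
    draws <- subject_draws(fit, i)
    if (!is.null(max_draws) && nrow(draws) > max_draws)
      draws <- draws[round(seq(1, nrow(draws), length.out = max_draws)), ,
                     drop = FALSE]
    pgo <- cpp_onestep_mean(as.integer(s$cue), as.integer(s$keyPressed),
                            as.integer(s$outcome), unname(draws),
                            fit$model$code)
    trial_rows[[i]] <- data.frame(subjID = id, trial = s$trial,
                                  cue = s$cue, observed = s$keyPressed,
                                  predicted = pgo,
                                  stringsAsFactors = FALSE)
  }
  tr <- do.call(rbind, trial_rows)

  conds <- cue_conditions()
  by_cond <- do.call(rbind, lapply(fit$subjects, function(id) {
    s <- tr[tr$subjID == id, ]
    data.frame(subjID = id, cue = conds$id, label = conds$label,
               predicted = vapply(conds$id, function(cc)
                 mean(s$predicted[s$cue == cc]), 1),
               observed = vapply(conds$id, function(cc)
                 mean(s$observed[s$cue == cc]), 1),
               stringsAsFactors = FALSE)
  }))

  subject_r <- vapply(fit$subjects, function(id) {
    if (method == "condition") {
      b <- by_cond[by_cond$subjID == id, ]
      pred <- b$predicted; obs <- b$observed
    } else {
      s <- tr[tr$subjID == id, ]
      cell <- interaction(s$cue,
                          stats::ave(s$trial, s$cue, FUN = function(v)
                            ceiling(seq_along(v) / (length(v) / bins))))
      pred <- tapply(s$predicted, cell, mean)
      obs <- tapply(s$observed, cell, mean)
      keep <- !is.na(pred)
      pred <- pred[keep]; obs <- obs[keep]
    }
    if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
    stats::cor(pred, obs)
  }, numeric(1))

  structure(list(trial = tr, by_condition = by_cond,
                 subject_r = subject_r,
                 mean_r = mean(subject_r, na.rm = TRUE), method = method),
            class = "gng_prediction")
}

#' @export
print.gng_prediction <- function(x, ...) {
  cat("One-step-ahead posterior prediction (", x$method, " correlations)\n",
      sep = "")
  cat(sprintf("  %d subjects, mean r = %.3f\n", length(x$subject_r),
              x$mean_r))
  invisible(x)
}

#' @rdname one_step_ahead
#' @param object a [gng_fit].
#' @param ... passed to [one_step_ahead].
#' @export
predict.gng_fit <- function(object, ...) one_step_ahead(object, ...)

#' Trial-level prediction residuals
#'
#' Observed action (0/1) minus one-step-ahead predicted p(go) per trial.
#'
#' @param object a [gng_fit].
#' @param ... passed to [one_step_ahead].
#' @return Numeric vector of residuals, one per trial of the fitted data.
#' @export
residuals.gng_fit <- function(object, ...) {
  p <- one_step_ahead(object, ...)
  p$trial$observed - p$trial$predicted
}
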