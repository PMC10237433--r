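log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalized Pareto fit to exceedances (profile-likelihood grid method
# with a weak prior pulling the shape toward 0.5), returning shape k and
# scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  N <- length(x)
  prior_bs <- 3; prior_k <- 10
  M <- 30 + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(1L, floor(N / 4 + 0.5))]
  bs <- 1 - sqrt(M / (jj - 0.5))
  bs <- bs / (prior_bs * xstar) + 1 / x[N]
  ks <- vapply(bs, function(b) mean(log1p(-b * x)), numeric(1))
  L <- N * (log(-bs / ks) - ks - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(L - L[j])), numeric(1))
  b <- sum(bs * w) / sum(w)
  k <- mean(log1p(-b * x))
  sigma <- -k / b
  k <- (N * k + prior_k * 0.5) / (N + prior_k)
  c(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smoothed importance sampling for one unit's log-likelihood draws.
# Returns smoothed, shifted log-weights and the Pareto shape estimate.
psis_unit <- function(ll) {
  S <- length(ll)
  if (stats::sd(ll) == 0)
    stop("degenerate importance weights: identical log-likelihood draws")
  lw <- -ll
  lw <- lw - max(lw)
  M <- ceiling(min(S / 5, 3 * sqrt(S)))
  ord <- order(lw)
  khat <- NA_real_
  if (M >= 5) {
    tail_ids <- ord[(S - M + 1):S]
    cutoff <- lw[ord[S - M]]
    exceed <- exp(lw[tail_ids]) - exp(cutoff)
    if (stats::sd(exceed) > 0) {
      fit <- gpd_fit(exceed)
      khat <- fit["k"]
      if (is.finite(khat)) {
        p <- (seq_len(M) - 0.5) / M
        smoothed <- log(qgpd(p, fit["k"], fit["sigma"]) + exp(cutoff))
        # restore the original rank order within the tail
        lw[tail_ids[order(lw[tail_ids])]] <- smoothed
      }
    }
  }
  lw[lw > 0] <- 0  # truncate at the raw maximum
  list(lw = lw, khat = unname(khat))
}

#' PSIS-LOO estimate of out-of-sample predictive accuracy
#'
#' Computes Pareto-smoothed importance-sampling leave-one-out
#' cross-validation from a matrix of pointwise log-likelihoods. The unit
#' of cross-validation is whatever the matrix columns are; in this
#' package's pipeline the unit is the subject (each column holds a
#' subject's session log-likelihood per posterior draw), matching the
#' exchangeable units of the hierarchy. Importance weights `1/p(y_i |
#' theta_s)` have their upper tail replaced by expected order statistics
#' of a fitted generalized Pareto distribution and are truncated at the
#' raw maximum; the tail shape `k` is reported per unit (values > 0.7
#' indicate an unreliable estimate for that unit).
#'
#' @param pointwise `draws x units` matrix of log-likelihoods (>= 100
#'   draws).
#' @return A `gng_loo` object: `elpd_loo`, `looic` (`-2 * elpd_loo`), `se`
#'   (of elpd_loo), `se_looic`, `pareto_k` (per unit), `pointwise` (per-unit
#'   elpd contributions), `n_units`, `n_draws`.
#' @export
compute_looic <- function(pointwise) {
  pointwise <- as.matrix(pointwise)
  if (!all(is.finite(pointwise))) stop("non-finite log-likelihoods")
  S <- nrow(pointwise); n <- ncol(pointwise)
  if (S < 100) stop("need at least 100 draws for PSIS-LOO, got ", S)
  elpd_i <- numeric(n); khat <- numeric(n)
  for (i in seq_len(n)) {
    ll <- pointwise[, i]
    ps <- psis_unit(ll)
    elpd_i[i] <- log_sum_exp(ps$lw + ll) - log_sum_exp(ps$lw)
    khat[i] <- ps$khat
  }
  elpd <- sum(elpd_i)
  se <- sqrt(n * stats::var(elpd_i))
  structure(list(elpd_loo = elpd, looic = -2 * elpd, se = se,
                 se_looic = 2 * se, pareto_k = khat, pointwise = elpd_i,
                 n_units = n, n_draws = S),
            class = "gng_loo")
}

#' @export
print.gng_loo <- function(x, ...) {
  cat("PSIS-LOO:", x$n_units, "units,", x$n_draws, "draws\n")
  cat(sprintf("  elpd_loo %.1f (se %.1f)   looic %.1f (se %.1f)\n",
              x$elpd_loo, x$se, x$looic, x$se_looic))
  nbad <- sum(x$pareto_k > 0.7, na.rm = TRUE)
  if (nbad) cat("  warning:", nbad, "unit(s) with Pareto k > 0.7\n")
  invisible(x)
}

#' Rank models by LOOIC
#'
#' @param loos a named list of [compute_looic] results (>= 2 entries) fit
#'   to the same units.
#' @return A data frame sorted ascending by LOOIC with columns `model`,
#'   `elpd_loo`, `looic`, `se`, `d_looic` (difference from the best) and
#'   `best`; ties keep the input order.
#' @export
compare_models <- function(loos) {
  if (length(loos) < 2) stop("need at least two models to compare")
  if (is.null(names(loos)) || any(names(loos) == ""))
    stop("'loos' must be a fully named list")
  n_units <- vapply(loos, `[[`, numeric(1), "n_units")
  if (length(unique(n_units)) > 1)
    stop("models were fit to different numbers of units: ",
         paste(n_units, collapse = ", "))
  tab <- data.frame(model = names(loos),
                    elpd_loo = vapply(loos, `[[`, 1, "elpd_loo"),
                    looic = vapply(loos, `[[`, 1, "looic"),
                    se = vapply(loos, `[[`, 1, "se_looic"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$looic), ]
  tab$d_looic <- tab$looic - tab$looic[1]
  tab$best <- seq_len(nrow(tab)) == 1
  rownames(tab) <- NULL
  tab
}

#' LOO for a fitted model
#'
#' Convenience wrapper: runs [compute_looic] on a fit's pointwise
#' per-subject log-likelihood matrix.
#'
#' @param fit a [gng_fit].
#' @return A `gng_loo`.
#' @export
loo_gng <- function(fit) compute_looic(fit$pointwise)
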