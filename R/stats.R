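#' Highest density interval of a sample
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws — for unimodal posteriors, the highest-density credible
#' interval.
#'
#' @param draws numeric sample (>= 100 values by default contract; smaller
#'   vectors are rejected unless `min_n` is lowered).
#' @param mass probability mass, in (0, 1) (default 0.95).
#' @param min_n minimum sample size accepted.
#' @return Numeric `c(low, high)`.
#' @export
hdi <- function(draws, mass = 0.95, min_n = 100) {
  stopifnot(mass > 0, mass < 1)
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < min_n)
    stop("need at least ", min_n, " draws for an HDI, got ", n)
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  j <- which.min(widths)
  c(x[j], x[j + m])
}

#' Posterior difference of a group-level parameter between two fits
#'
#' Subtracts the posterior of `parameter`'s natural-scale group mean in
#' `fitB` from that in `fitA`. Because the groups are fitted separately,
#' their draws have no natural pairing; draws are paired by index after a
#' seeded permutation of each fit's pooled draws, making the pairing
#' explicit and reproducible (the difference's mean is invariant to it).
#' The difference is credible when its 95% HDI excludes zero.
#'
#' @param fitA,fitB [gng_fit] objects sharing a model variant.
#' @param parameter group-level parameter name.
#' @param seed integer seed for the pairing permutation.
#' @param mass HDI mass (default 0.95).
#' @return A `gng_group_diff`: `parameter`, `draws` (A - B), `mean`,
#'   `hdi_low`, `hdi_high`, `credible`.
#' @export
group_difference <- function(fitA, fitB, parameter, seed = 1, mass = 0.95) {
  if (!identical(fitA$model$variant, fitB$model$variant))
    stop("fits use different model variants")
  dA <- extract_group_means(fitA, parameter)
  dB <- extract_group_means(fitB, parameter)
  S <- min(length(dA), length(dB))
  set.seed(seed)
  diff <- dA[sample.int(length(dA), S)] - dB[sample.int(length(dB), S)]
  h <- hdi(diff, mass)
  structure(list(parameter = parameter, draws = diff, mean = mean(diff),
                 hdi_low = h[1], hdi_high = h[2],
                 credible = h[1] > 0 || h[2] < 0, mass = mass),
            class = "gng_group_diff")
}

#' @export
print.gng_group_diff <- function(x, ...) {
  cat(sprintf("Posterior group difference in %s: %.3f [%.3f, %.3f]%s\n",
              x$parameter, x$mean, x$hdi_low, x$hdi_high,
              if (x$credible) " *credible*" else ""))
  invisible(x)
}

#' Group-comparison table across all parameters
#'
#' Runs [group_difference] for every group-level parameter of the shared
#' model, yielding a posterior-difference table (mean, HDI, credibility
#' flag per parameter).
#'
#' @inheritParams group_difference
#' @return Data frame: `parameter`, `mean_A`, `mean_B`, `diff`, `hdi_low`,
#'   `hdi_high`, `credible`.
#' @export
group_comparison_table <- function(fitA, fitB, seed = 1, mass = 0.95) {
  do.call(rbind, lapply(fitA$model$parameters, function(p) {
    d <- group_difference(fitA, fitB, p, seed = seed, mass = mass)
    data.frame(parameter = p,
               mean_A = mean(extract_group_means(fitA, p)),
               mean_B = mean(extract_group_means(fitB, p)),
               diff = d$mean, hdi_low = d$hdi_low, hdi_high = d$hdi_high,
               credible = d$credible, stringsAsFactors = FALSE)
  }))
}

#' Per-subject accuracy in each condition
#'
#' Accuracy is the proportion of trials on which the emitted action equals
#' the condition's correct action.
#'
#' @param table a `trial_table`; every subject must have trials in all
#'   four conditions.
#' @return Data frame with columns `subjID`, `go_to_win`, `go_to_avoid`,
#'   `nogo_to_win`, `nogo_to_avoid`.
#' @export
accuracy_by_condition <- function(table) {
  table <- validate_trials(table)
  ids <- unique(table$subjID)
  conds <- cue_conditions()
  out <- data.frame(subjID = ids, stringsAsFactors = FALSE)
  for (j in seq_len(4)) {
    correct <- cue_correct_action(conds$id[j])
    out[[conds$label[j]]] <- vapply(ids, function(id) {
      rows <- table$subjID == id & table$cue == conds$id[j]
      if (!any(rows))
        stop("subject '", id, "' has no trials in condition ",
             conds$label[j], "; accuracy undefined")
      mean(table$keyPressed[rows] == correct)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Behavioural Pavlovian-bias indices
#'
#' Accuracy differences between Pavlovian-congruent and -incongruent
#' conditions: `reward = go_to_win - nogo_to_win`, `punishment =
#' nogo_to_avoid - go_to_avoid`, and `overall = (go_to_win +
#' nogo_to_avoid) - (nogo_to_win + go_to_avoid)` (which equals reward +
#' punishment). Positive values indicate behaviour pulled toward the
#' Pavlovian tendency.
#'
#' @param acc output of [accuracy_by_condition] (or any data frame with
#'   the four condition columns).
#' @return The input with added columns `bias_reward`, `bias_punishment`,
#'   `bias_overall`.
#' @export
bias_indices <- function(acc) {
  need <- c("go_to_win", "go_to_avoid", "nogo_to_win", "nogo_to_avoid")
  stopifnot(all(need %in% names(acc)))
  acc$bias_reward <- acc$go_to_win - acc$nogo_to_win
  acc$bias_punishment <- acc$nogo_to_avoid - acc$go_to_avoid
  acc$bias_overall <- (acc$go_to_win + acc$nogo_to_avoid) -
    (acc$nogo_to_win + acc$go_to_avoid)
  acc
}

#' Student's t-test
#'
#' Two-sided Student's t-test: pooled-variance unpaired by default (the
#' convention used for the behavioural condition comparisons), or paired.
#'
#' @param x,y numeric samples (each n >= 2; equal lengths if paired).
#' @param paired logical.
#' @return A list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, paired = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both samples have zero variance; t undefined")
  res <- stats::t.test(x, y, paired = paired, var.equal = TRUE,
                       alternative = "two.sided")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
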