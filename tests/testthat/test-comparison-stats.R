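test_that("HDI matches normal quantiles, handles skew, and is shortest", {
  x <- rep(3.2, 200)
  expect_equal(hdi(x), c(3.2, 3.2))

  set.seed(12)
  z <- rnorm(1e5)
  h <- hdi(z, 0.95)
  expect_equal(h[1], -1.96, tolerance = 0.05)
  expect_equal(h[2], 1.96, tolerance = 0.05)

  # right-skewed draws: HDI hugs zero and beats the equal-tailed interval
  e <- rexp(1e5)
  he <- hdi(e, 0.95)
  eq <- quantile(e, c(0.025, 0.975))
  expect_lt(he[2] - he[1], unname(eq[2] - eq[1]))
  expect_lt(he[1], 0.05)

  # brute-force shortest-window equivalence on small vectors
  set.seed(13)
  for (rep in 1:20) {
    v <- switch(1 + rep %% 3, rnorm(500), rexp(500), rbeta(500, 2, 5))
    h <- hdi(v, 0.9)
    s <- sort(v)
    m <- ceiling(0.9 * 500)
    widths <- s[(m + 1):500] - s[1:(500 - m)]
    expect_equal(h[2] - h[1], min(widths), tolerance = 1e-12)
    expect_equal(sum(v >= h[1] & v <= h[2]) >= m, TRUE)
  }
  expect_error(hdi(rnorm(20)), "at least")
})

test_that("accuracy by condition counts correct actions", {
  # forced go responder: perfect on go conditions, zero on no-go
  sch <- rep(1:4, each = 10)
  tab <- trial_table("g", seq_along(sch), sch, rep(1L, 40),
                     ifelse(sch %in% c(1, 3), 1L, 0L))
  acc <- accuracy_by_condition(tab)
  expect_equal(unlist(acc[1, c("go_to_win", "go_to_avoid", "nogo_to_win",
                               "nogo_to_avoid")], use.names = FALSE),
               c(1, 1, 0, 0))
  # hand count: 36/45 correct go-to-win
  act <- c(rep(1L, 36), rep(0L, 9))
  tab2 <- trial_table("h", 1:49, c(rep(1L, 45), 2L, 2L, 3L, 4L),
                      c(act, 1L, 1L, 0L, 0L),
                      c(ifelse(act == 1, 1L, 0L), 0L, 0L, 0L, 0L))
  expect_equal(accuracy_by_condition(tab2)$go_to_win, 0.8)
  # permutation invariance within subject
  s <- random_session(80)
  set.seed(14)
  perm <- s[sample(nrow(s)), ]
  perm$trial <- seq_len(nrow(perm))
  ord <- table(s$cue)
  if (all(1:4 %in% s$cue)) {
    a1 <- accuracy_by_condition(validate_trials(s))
    a2 <- accuracy_by_condition(validate_trials(perm))
    expect_equal(a1[-1], a2[-1])
  }
  # missing condition cell is an error
  only1 <- trial_table("x", 1:5, rep(1L, 5), rep(1L, 5), rep(1L, 5))
  expect_error(accuracy_by_condition(only1), "undefined")
})

test_that("bias indices follow the congruent-minus-incongruent formulas", {
  acc <- data.frame(subjID = "s", go_to_win = 0.9, nogo_to_win = 0.8,
                    go_to_avoid = 0.7, nogo_to_avoid = 0.85)
  b <- bias_indices(acc)
  expect_equal(b$bias_reward, 0.1)
  expect_equal(b$bias_punishment, 0.15)
  expect_equal(b$bias_overall, 0.25)
  # overall decomposes into the two domains
  expect_equal(b$bias_overall, b$bias_reward + b$bias_punishment)
  # all-equal accuracies give zero everywhere
  flat <- bias_indices(data.frame(go_to_win = 0.6, nogo_to_win = 0.6,
                                  go_to_avoid = 0.6, nogo_to_avoid = 0.6))
  expect_equal(unlist(flat[c("bias_reward", "bias_punishment",
                             "bias_overall")], use.names = FALSE),
               c(0, 0, 0))
  # swapping the reward-domain accuracies flips the reward index sign
  sw <- bias_indices(data.frame(go_to_win = 0.8, nogo_to_win = 0.9,
                                go_to_avoid = 0.7, nogo_to_avoid = 0.85))
  expect_equal(sw$bias_reward, -b$bias_reward)
})

test_that("Student's t-test gives the unpaired dfs of two-sample designs", {
  set.seed(15)
  x <- rnorm(17); y <- rnorm(17)
  r <- two_sample_t(x, y)
  expect_equal(r$df, 32)
  expect_equal(two_sample_t(rnorm(14), rnorm(14))$df, 26)
  # identical samples: t = 0, p = 1
  same <- rnorm(10)
  r0 <- two_sample_t(same, same)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # agrees with the pooled-variance reference implementation
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r$p, ref$p.value, tolerance = 1e-9)
  # paired mode and error cases
  expect_equal(two_sample_t(x, y, paired = TRUE)$df, 16)
  expect_error(two_sample_t(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("group differences are null for identical fits and linear in means", {
  co <- make_cohort(5, seed = 501)
  f <- suppressWarnings(gng_fit(co$table, gng_model("m1"), chains = 2,
                                warmup = 400, keep = 400, thin = 2,
                                seed = 501))
  d <- group_difference(f, f, "eps", seed = 1)
  expect_false(d$credible)
  expect_lt(abs(d$mean), 0.05)
  expect_lte(d$hdi_low, 0)
  expect_gte(d$hdi_high, 0)
  # the mean difference equals the difference of means for any pairing
  co2 <- make_cohort(5, hyper = default_hyperparams("active",
                                                    gng_model("m1")),
                     seed = 502)
  g <- suppressWarnings(gng_fit(co2$table, gng_model("m1"), chains = 2,
                                warmup = 400, keep = 400, thin = 2,
                                seed = 502))
  d1 <- group_difference(f, g, "b", seed = 1)
  d2 <- group_difference(f, g, "b", seed = 999)
  want <- mean(extract_group_means(f, "b")) -
    mean(extract_group_means(g, "b"))
  expect_equal(d1$mean, want, tolerance = 1e-9)
  expect_equal(d2$mean, want, tolerance = 1e-9)
  # HDI endpoints approximately pairing-invariant
  expect_equal(d1$hdi_low, d2$hdi_low, tolerance = 0.15)
  expect_equal(d1$hdi_high, d2$hdi_high, tolerance = 0.15)
  expect_error(group_difference(f, g, "pi_pun"), "valid names")
  # comparison table covers every parameter
  tab <- group_comparison_table(f, g)
  expect_equal(tab$parameter, gng_model("m1")$parameters)
  expect_type(tab$credible, "logical")
})
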