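# Similarity measures, paired t / dz / BF10, power solver, mixed ANOVA.

test_that("Fisher Z is atanh with an exact tanh round trip", {
  expect_equal(fisher_z(0.9), 0.5 * log(1.9 / 0.1))
  expect_equal(fisher_z(0.9), 1.4722, tolerance = 1e-4)
  r <- seq(-0.999999, 0.999999, length.out = 101)
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
})

test_that("cell summaries match longhand Pearson on a hand-built cell", {
  prime <- c(210, 180, 260, 240, 200, 190, 230, 250)
  probe <- c(215, 190, 255, 235, 205, 185, 240, 245)
  rows <- lapply(seq_len(8), function(i)
    make_trial_row(prime_dur = prime[i], probe_dur = probe[i]))
  trials <- do.call(make_trials, rows)
  s <- prime_probe_summary(trials, "duration")
  expect_equal(nrow(s), 1)
  expect_equal(s$r, oracle_pearson(prime, probe))
  expect_equal(s$z_r, atanh(s$r))
  expect_equal(s$mean_abs_diff, mean(abs(probe - prime)))
  expect_equal(s$mean_prime, mean(prime))
  expect_equal(s$mean_probe, mean(probe))
  expect_equal(s$n_trials, 8L)
})

test_that("identical prime and probe values give r = 1, |diff| = 0", {
  x <- c(200, 220, 260, 180, 240)
  rows <- lapply(x, function(v) make_trial_row(prime_dur = v, probe_dur = v))
  trials <- do.call(make_trials, rows)
  expect_warning(s <- prime_probe_summary(trials, "duration"), "Fisher")
  expect_equal(s$r, 1)
  expect_true(is.infinite(s$z_r))
  expect_equal(s$mean_abs_diff, 0)
})

test_that("degenerate cells (n < 3 or zero variance) yield NA r with warning", {
  trials <- make_trials(make_trial_row(), make_trial_row())
  expect_warning(s <- prime_probe_summary(trials, "duration"), "undefined")
  expect_true(is.na(s$r))
  # zero variance in one part
  rows <- lapply(c(200, 210, 220, 230), function(v)
    make_trial_row(prime_dur = 150, probe_dur = v))
  trials2 <- do.call(make_trials, rows)
  expect_warning(s2 <- prime_probe_summary(trials2, "duration"), "undefined")
  expect_true(is.na(s2$r))
  expect_false(is.na(s2$mean_abs_diff))  # retained for difference tests
})

test_that("paired t: zero mean difference gives t = 0, p = 1", {
  y <- c(10, 20, 30, 40)
  x <- y + c(1, -1, 2, -2)
  res <- paired_t(x, y)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$dz, 0)
  expect_equal(res$df, 3)
})

test_that("paired t equals the longhand one-sample t on differences", {
  set.seed(808)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- paired_t(x, y)
    ref <- oracle_paired_t(x, y)
    expect_equal(got$t, ref$t)
    expect_equal(got$df, ref$df)
    expect_equal(got$p, ref$p)
    expect_equal(got$dz, abs(ref$t) / sqrt(n))
  }
})

test_that("paired t rejects degenerate input", {
  expect_error(paired_t(1:5, 1:5 + 2), "zero variance")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("JZS BF matches an independent fixed-grid quadrature", {
  for (case in list(c(0.5, 12), c(2.1, 19), c(-3.3, 34), c(4.97, 53))) {
    got <- jzs_bf10(case[1], case[2])
    ref <- oracle_jzs_bf10(case[1], case[2])
    expect_equal(got, ref, tolerance = 1e-4)
  }
})

test_that("JZS BF favours the null at t = 0 and increases in |t|", {
  for (n in c(2, 5, 19, 53, 200)) expect_lt(jzs_bf10(0, n), 1)
  ts <- seq(0, 6, by = 0.5)
  bfs <- vapply(ts, jzs_bf10, 0, n = 19)
  expect_true(all(diff(bfs) > 0))
  # symmetry in the sign of t
  expect_equal(jzs_bf10(-2.3, 19), jzs_bf10(2.3, 19))
})

test_that("power solver is self-consistent and matches power.t.test", {
  s <- solve_power(d = 0.5, power = 0.80)
  expect_gte(solve_power(n = s$n, d = 0.5)$power, 0.80)
  expect_lt(solve_power(n = s$n - 1, d = 0.5)$power, 0.80)
  # independent oracle: stats::power.t.test one-sample = paired on dz scale
  ref_d <- power.t.test(n = 19, power = 0.80, sig.level = 0.05,
                        type = "one.sample")$delta
  expect_equal(solve_power(n = 19, power = 0.80)$d, ref_d, tolerance = 1e-5)
  # power.t.test drops the opposite-tail rejection term (~2e-5 here), the
  # exact noncentral-t power keeps it
  ref_p <- power.t.test(n = 53, delta = 0.30, sd = 1, sig.level = 0.05,
                        type = "one.sample")$power
  expect_equal(solve_power(n = 53, d = 0.30)$power, ref_p, tolerance = 1e-4)
})

test_that("power solver validates its contract", {
  expect_error(solve_power(n = 19, d = 0.5, power = 0.8), "exactly one")
  expect_error(solve_power(n = 19), "exactly one")
  expect_error(solve_power(n = 2, power = 0.03), "no solution")
  expect_error(solve_power(n = 1.5, power = 0.8), "integer")
})

test_that("bonferroni_alpha divides the family alpha", {
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 4), 0.0025)
  expect_error(bonferroni_alpha(0.05, 0))
})

test_that("mixed ANOVA reproduces a hand sums-of-squares decomposition", {
  # 6 subjects, 3 per group, balanced 2x2
  d <- data.frame(
    subject = rep(1:6, each = 2),
    group = rep(c("A", "B"), each = 6),
    part = rep(c("prime", "probe"), 6),
    value = c(10, 12, 11, 15, 9, 12,    # A
              14, 13, 16, 18, 15, 14))  # B
  got <- mixed_anova_2x2(d)

  # longhand decomposition
  y <- matrix(d$value, ncol = 2, byrow = TRUE)  # subjects x part
  grp <- rep(c("A", "B"), each = 3)
  grand <- mean(y)
  subj_m <- rowMeans(y)
  grp_m <- tapply(subj_m, grp, mean)
  part_m <- colMeans(y)
  ss_group <- 2 * sum(3 * (grp_m - grand)^2)
  ss_subj <- 2 * sum((subj_m - grp_m[grp])^2)
  ss_part <- 6 * sum((part_m - grand)^2)
  cell_m <- rbind(colMeans(y[1:3, ]), colMeans(y[4:6, ]))
  ss_int <- 3 * sum((cell_m - outer(grp_m - grand, part_m - grand, "+") -
                       grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_part - ss_int

  expect_equal(got$F[got$effect == "group"],
               (ss_group / 1) / (ss_subj / 4))
  expect_equal(got$F[got$effect == "part"], (ss_part / 1) / (ss_err / 4))
  expect_equal(got$F[got$effect == "interaction"],
               (ss_int / 1) / (ss_err / 4))
  expect_equal(got$ges[got$effect == "group"],
               ss_group / (ss_group + ss_subj + ss_err))
  expect_equal(got$ges[got$effect == "part"],
               ss_part / (ss_part + ss_subj + ss_err))
  expect_equal(got$df2, c(4, 4, 4))
  expect_true(all(got$ges >= 0 & got$ges <= 1))
})

test_that("identical groups give a between-groups F of zero", {
  base <- data.frame(subject = rep(1:4, each = 2),
                     part = rep(c("prime", "probe"), 4),
                     value = c(5, 8, 6, 9, 7, 9, 5, 7))
  d <- rbind(cbind(base, group = "A"),
             cbind(transform(base, subject = subject + 4), group = "B"))
  got <- mixed_anova_2x2(d)
  expect_equal(got$F[got$effect == "group"], 0)
  expect_equal(got$F[got$effect == "interaction"], 0)
})

test_that("one-group within F equals the squared paired t", {
  set.seed(909)
  n <- 12
  prime <- rnorm(n, 5); probe <- rnorm(n, 6)
  d <- data.frame(subject = rep(1:n, each = 2), group = "only",
                  part = rep(c("prime", "probe"), n),
                  value = as.vector(rbind(prime, probe)))
  got <- mixed_anova_2x2(d)
  tt <- paired_t(prime, probe)
  expect_equal(got$F, tt$t^2, tolerance = 1e-9)
  expect_equal(got$df2, n - 1)
})

test_that("mixed ANOVA rejects unbalanced input", {
  d <- data.frame(subject = c(1, 1, 2), group = "A",
                  part = c("prime", "probe", "prime"), value = 1:3)
  expect_error(mixed_anova_2x2(d), "unbalanced|2 levels")
})

test_that("dz confidence interval is symmetric at t = 0 and covers ~95%", {
  ci0 <- dz_ci(0, 19)
  expect_equal(ci0$dz, 0)
  expect_equal(ci0$lower, -ci0$upper, tolerance = 1e-6)
  set.seed(1010)
  n <- 19
  cover <- mean(vapply(1:2000, function(i) {
    d <- rnorm(n)
    t <- mean(d) / (sd(d) / sqrt(n))
    ci <- dz_ci(t, n)
    ci$lower <= 0 && 0 <= ci$upper
  }, TRUE))
  expect_gt(cover, 0.935)
  expect_lt(cover, 0.965)
})
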