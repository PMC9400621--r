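# Outcome classification and the rejection cascade.

test_that("outcome classification matches a hand enumeration of branches", {
  d <- design_preset("exp1")
  trials <- make_trials(
    make_trial_row(probe_rt = 300),                               # ok
    make_trial_row(probe_rt = 1300),                              # miss: late
    make_trial_row(probe_rt = NA),                                # miss: none
    make_trial_row(probe_rt = -100),                              # false alarm
    make_trial_row(condition = "catch", probe_rt = NA),           # catch ok
    make_trial_row(condition = "catch", probe_rt = 250),          # catch error
    make_trial_row(condition = "incongruent", probe_rt = 1200),   # ok: at limit
    make_trial_row(condition = "incongruent", probe_rt = 1201),   # miss
    make_trial_row(probe_rt = 1),                                 # ok (floor is screening, not outcome)
    make_trial_row(probe_rt = NA, outcome = "restart")            # restart kept
  )
  trials$prime_onset_ms[10] <- NA  # restarts have no events
  out <- classify_outcomes(trials, d)$outcome
  expect_identical(out, c("ok", "miss", "miss", "false_alarm",
                          "catch_correct", "catch_error", "ok", "miss",
                          "ok", "restart"))
})

test_that("missing prime event on a non-restart trial is a data error", {
  tr <- make_trial_row()
  tr$prime_onset_ms <- NA
  expect_error(classify_outcomes(tr, design_preset("exp1")), "prime")
})

test_that("RT floor removes a 50 ms trial under any preset", {
  rows <- lapply(c(50, 150, 200, 250, 300, 350), function(rt)
    make_trial_row(probe_rt = rt))
  trials <- do.call(make_trials, rows)
  for (preset in c("exp1", "exp2")) {
    scr <- screen(trials, screening_preset(preset))
    expect_false(50 %in% scr$trials$probe_rt_ms)
    expect_true(150 %in% scr$trials$probe_rt_ms)
  }
})

test_that("the absolute 3 s ceiling removes a 3200 ms response", {
  rows <- lapply(c(300, 320, 340, 360, 3200), function(rt)
    make_trial_row(probe_rt = rt))
  trials <- do.call(make_trials, rows)
  scr <- screen(trials, screening_preset("exp2"))
  expect_false(3200 %in% scr$trials$probe_rt_ms)
  log <- scr$report$rule_log
  expect_equal(log$n_rejected[log$rule == "rt_ceiling_absolute_3000"], 1)
})

test_that("the duration cap is inclusive: exactly 600 ms is rejected", {
  trials <- make_trials(
    make_trial_row(prime_dur = 600),
    make_trial_row(prime_dur = 599.9),
    make_trial_row(probe_dur = 600),
    make_trial_row(probe_dur = 150))
  scr <- screen(trials, screening_preset("exp1"))
  expect_equal(nrow(scr$trials), 2)
  expect_false(any(scr$trials$prime_duration_ms >= 600))
  expect_false(any(scr$trials$probe_duration_ms >= 600))
})

test_that("the cascade equals the brute-force oracle on planted violations", {
  set.seed(404)
  base_rt <- rnorm(20, 320, 30)
  # one participant, two conditions -> cells of 10 (a 2.5 SD rule cannot
  # fire in smaller cells: max |z| in a cell of n is (n-1)/sqrt(n))
  rows <- lapply(seq_len(20), function(i)
    make_trial_row(participant_id = 1,
                   condition = c("congruent", "incongruent")[1 + i %% 2],
                   probe_rt = base_rt[i]))
  trials <- do.call(make_trials, rows)
  # plant one violation per rule
  trials$probe_rt_ms[1] <- 60                     # floor
  trials$probe_rt_ms[3] <- 900                    # mean + 2.5 sd ceiling
  trials$prime_duration_ms[5] <- 640              # prime cap
  trials$probe_duration_ms[7] <- 600              # probe cap (inclusive)
  trials$outcome[9] <- "miss"                     # ineligible
  for (mode in c("exp1", "exp2")) {
    got <- screen(trials, screening_preset(mode))$trials
    want <- oracle_screen(trials, mode)
    expect_equal(got$trial_index, want$trial_index, label = mode)
  }
  # exp2-specific plants
  trials2 <- trials
  trials2$probe_rt_ms[3] <- 3200                  # absolute ceiling
  got2 <- screen(trials2, screening_preset("exp2"))$trials
  expect_equal(got2$trial_index, oracle_screen(trials2, "exp2")$trial_index)
})

test_that("screening conserves counts and reports ordered rules", {
  trials <- simulate_experiment(design_preset("exp1"), population_spec(), 5,
                                seed = 31)
  scr <- screen(trials, screening_preset("exp1"))
  rep_ <- scr$report
  expect_equal(rep_$n_eligible, sum(trials$outcome == "ok"))
  expect_equal(rep_$n_eligible,
               rep_$n_surviving + sum(rep_$rule_log$n_rejected))
  expect_identical(rep_$rule_log$rule,
                   c("rt_floor", "rt_ceiling_mean_2.5sd",
                     "prime_duration_cap", "probe_duration_cap"))
  expect_true(all(rep_$rule_log$fraction >= 0 & rep_$rule_log$fraction <= 1))
  # excluded rows pass through untouched
  expect_equal(nrow(scr$excluded), sum(trials$outcome != "ok"))
})

test_that("deterministic rules are idempotent on their survivors", {
  set.seed(505)
  rows <- lapply(rnorm(15, 320, 10), function(rt)
    make_trial_row(probe_rt = rt))
  trials <- do.call(make_trials, rows)
  trials$probe_rt_ms[1] <- 60
  trials$prime_duration_ms[2] <- 700
  trials$probe_rt_ms[3] <- 3300
  rules <- screening_preset("exp2")
  first <- screen(trials, rules)
  second <- suppressWarnings(screen(first$trials, rules))
  # z-stage may legitimately re-fire; floor/absolute/caps must not
  log2 <- second$report$rule_log
  fixed <- log2$rule %in% c("rt_floor", "rt_ceiling_absolute_3000",
                            "prime_duration_cap", "probe_duration_cap")
  expect_true(all(log2$n_rejected[fixed] == 0))
})

test_that("stage order matters: cap-then-ceiling differs from ceiling-then-cap", {
  # the long-duration trial carries a huge RT; if the ceiling stage ran
  # after the duration cap, the remaining RTs would be tight and 450 ms
  # would be an outlier — in the documented order it survives
  set.seed(606)
  rows <- c(lapply(rnorm(10, 300, 5), function(rt) make_trial_row(probe_rt = rt)),
            list(make_trial_row(probe_rt = 450),
                 make_trial_row(probe_rt = 2000, prime_dur = 700)))
  trials <- do.call(make_trials, rows)
  scr <- screen(trials, screening_preset("exp1"))
  expect_true(450 %in% scr$trials$probe_rt_ms)    # survives documented order
  # oracle for the swapped order: duration cap first, then mean + 2.5 sd
  d <- trials[trials$prime_duration_ms < 600 & trials$probe_duration_ms < 600, ]
  mu <- mean(d$probe_rt_ms); s <- sd(d$probe_rt_ms)
  swapped_keep <- d$probe_rt_ms[d$probe_rt_ms <= mu + 2.5 * s]
  expect_false(450 %in% swapped_keep)             # swapped order rejects it
})

test_that("per-DV z rejection is cellwise, per variable, with n-1 SD", {
  set.seed(707)
  rows <- lapply(seq_len(12), function(i)
    make_trial_row(probe_rt = rnorm(1, 320, 10),
                   prime_peak = rnorm(1, 3, 0.2),
                   probe_peak = rnorm(1, 4, 0.2)))
  trials <- do.call(make_trials, rows)
  trials$prime_peak_N[4] <- 30   # extreme peak, normal duration
  out_peak <- screen_dv(trials, "peak")
  expect_false(4 %in% out_peak$trial_index)
  out_dur <- screen_dv(trials, "duration")   # unaffected analysis
  expect_true(4 %in% out_dur$trial_index)
  # oracle: longhand z with sample SD on the same cell
  z <- (trials$prime_peak_N - mean(trials$prime_peak_N)) /
    sd(trials$prime_peak_N)
  expect_identical(sort(out_peak$trial_index),
                   sort(trials$trial_index[abs(z) <= 2.5]))
})

test_that("a cell with fewer than 2 trials skips the z rule with a warning", {
  trials <- make_trials(make_trial_row(participant_id = 1),
                        make_trial_row(participant_id = 2),
                        make_trial_row(participant_id = 2))
  # one warning per screened column (prime and probe peak)
  expect_warning(expect_warning(screen_dv(trials, "peak"), "cell"), "cell")
})
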