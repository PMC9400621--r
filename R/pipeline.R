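# Orchestration: screened participant-level measures, the nine comparison
# families, the pooled analysis with the 2x2 mixed ANOVA, and the
# recovery/calibration experiments.

#' Participant-level measures after full screening
#'
#' Runs the rejection cascade, then — separately per dependent variable, as
#' the per-DV z rule requires — the z-screening and the prime-probe cell
#' summaries. Also extracts per-participant condition RT means and the
#' condition-pooled prime/probe means used by the prime-vs-probe comparison.
#'
#' @param trials Trial table with outcomes set.
#' @param rules A [screening_rules()].
#' @return A list: `summaries` (named by dv: [prime_probe_summary()] tables),
#'   `rt_cells`, `part_means`, `screening` (the report).
#' @export
participant_measures <- function(trials, rules = screening_rules()) {
  scr <- screen(trials, rules)
  dvs <- c("auc", "peak", "duration")
  summaries <- lapply(stats::setNames(dvs, dvs), function(dv)
    prime_probe_summary(screen_dv(scr$trials, dv, rules$dv_z_cutoff), dv))

  rt_trials <- screen_dv(scr$trials, "rt", rules$dv_z_cutoff)
  key <- interaction(rt_trials$participant_id, rt_trials$condition,
                     drop = TRUE)
  rt_cells <- do.call(rbind, lapply(split(rt_trials, key), function(d)
    data.frame(participant_id = d$participant_id[1],
               condition = d$condition[1],
               mean_rt_ms = mean(d$probe_rt_ms),
               stringsAsFactors = FALSE)))
  rownames(rt_cells) <- NULL

  part_means <- do.call(rbind, lapply(c("auc", "peak"), function(dv) {
    cols <- if (dv == "auc") c("prime_auc_Nms", "probe_auc_Nms") else
      c("prime_peak_N", "probe_peak_N")
    d <- screen_dv(scr$trials, dv, rules$dv_z_cutoff)
    agg <- do.call(rbind, lapply(split(d, d$participant_id), function(g)
      data.frame(participant_id = g$participant_id[1], dv = dv,
                 mean_prime = mean(g[[cols[1]]]),
                 mean_probe = mean(g[[cols[2]]]),
                 stringsAsFactors = FALSE)))
    agg
  }))
  rownames(part_means) <- NULL

  list(summaries = summaries, rt_cells = rt_cells, part_means = part_means,
       screening = scr$report)
}

# aligned congruent/incongruent participant vectors from a summary table
condition_pairs <- function(summary_df, col) {
  con <- summary_df[summary_df$condition == "congruent", ]
  inc <- summary_df[summary_df$condition == "incongruent", ]
  ids <- intersect(con$participant_id, inc$participant_id)
  list(congruent = con[[col]][match(ids, con$participant_id)],
       incongruent = inc[[col]][match(ids, inc$participant_id)])
}

tests_from_measures <- function(m) {
  tests <- list()
  for (dv in names(m$summaries)) {
    s <- m$summaries[[dv]]
    z <- condition_pairs(s, "z_r")
    tests[[paste0(dv, "_corr")]] <-
      paired_t(z$congruent, z$incongruent)
    d <- condition_pairs(s, "mean_abs_diff")
    tests[[paste0(dv, "_diff")]] <-
      paired_t(d$congruent, d$incongruent)
  }
  rt <- condition_pairs(m$rt_cells, "mean_rt_ms")
  tests$rt <- paired_t(rt$congruent, rt$incongruent)
  for (dv in c("auc", "peak")) {
    pm <- m$part_means[m$part_means$dv == dv, ]
    tests[[paste0("prime_vs_probe_", dv)]] <-
      paired_t(pm$mean_prime, pm$mean_probe)
  }
  tests
}

#' Run the full similarity analysis on one experiment
#'
#' Screens the trials and computes the nine comparison families: for each of
#' AUC, peak force and pinch duration, the Fisher-Z correlation congruency
#' test and the mean-absolute-difference congruency test; the probe RT
#' congruency test; and the prime-vs-probe comparison (condition-pooled) for
#' AUC and peak force. Correlation/difference/RT tests contrast congruent
#' against incongruent (positive t means congruent larger). Duration analyses
#' are exploratory and evaluated at the Bonferroni-adjusted level
#' `alpha_duration`.
#'
#' @param trials Trial table with outcomes set (from [generate_session()] /
#'   [simulate_experiment()], or measured via [features_to_trials()] and
#'   [classify_outcomes()]).
#' @param rules A [screening_rules()].
#' @param alpha Primary significance level.
#' @param alpha_duration Adjusted level for the two duration tests
#'   (default `bonferroni_alpha(0.05, 2)`).
#' @return An `analysis_report`: list with `tests` (named `test_result`s),
#'   `screening`, `alpha`, `alpha_duration`, `n_participants`.
#' @export
run_analysis <- function(trials, rules = screening_rules(),
                         alpha = 0.05,
                         alpha_duration = bonferroni_alpha(0.05, 2)) {
  m <- participant_measures(trials, rules)
  tests <- tests_from_measures(m)
  structure(
    list(tests = tests, screening = m$screening,
         alpha = alpha, alpha_duration = alpha_duration,
         n_participants = length(unique(trials$participant_id))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis report (%d participants):\n", x$n_participants))
  for (nm in names(x$tests)) {
    cat(sprintf("  %-20s ", nm)); print(x$tests[[nm]])
  }
  invisible(x)
}

#' Pooled analysis across two experiments
#'
#' Pools the participant-level measures of two experiments (as the combined
#' analysis of heterogeneous designs does — a heterogeneity warning is
#' issued), reruns the nine comparison families at the pooled sample size,
#' and adds the 2 (experiment, between) x 2 (part, within) mixed ANOVA on
#' the participant mean AUC and peak force.
#'
#' @param trials1,trials2 Trial tables of the two experiments.
#' @param rules1,rules2 Their [screening_rules()].
#' @inheritParams run_analysis
#' @return An `analysis_report` with an extra `anova` element (named list
#'   `auc`, `peak` of [mixed_anova_2x2()] tables).
#' @export
pooled_analysis <- function(trials1, trials2,
                            rules1 = screening_preset("exp1"),
                            rules2 = screening_preset("exp2"),
                            alpha = 0.05,
                            alpha_duration = bonferroni_alpha(0.05, 2)) {
  warning("pooling participant-level measures across experiments with ",
          "different designs", call. = FALSE)
  m1 <- participant_measures(trials1, rules1)
  m2 <- participant_measures(trials2, rules2)
  offset <- max(unlist(lapply(m1$summaries, function(s) s$participant_id)))
  shift <- function(d) { d$participant_id <- d$participant_id + offset; d }
  m <- list(
    summaries = stats::setNames(lapply(names(m1$summaries), function(dv)
      rbind(m1$summaries[[dv]], shift(m2$summaries[[dv]]))),
      names(m1$summaries)),
    rt_cells = rbind(m1$rt_cells, shift(m2$rt_cells)),
    part_means = rbind(m1$part_means, shift(m2$part_means)))
  tests <- tests_from_measures(m)

  anova <- lapply(stats::setNames(c("auc", "peak"), c("auc", "peak")),
                  function(dv) {
    pm1 <- m1$part_means[m1$part_means$dv == dv, ]
    pm2 <- m2$part_means[m2$part_means$dv == dv, ]
    long <- rbind(
      data.frame(subject = pm1$participant_id, group = "exp1",
                 part = rep(c("prime", "probe"), each = nrow(pm1)),
                 value = c(pm1$mean_prime, pm1$mean_probe)),
      data.frame(subject = pm2$participant_id + offset, group = "exp2",
                 part = rep(c("prime", "probe"), each = nrow(pm2)),
                 value = c(pm2$mean_prime, pm2$mean_probe)))
    mixed_anova_2x2(long)
  })

  structure(
    list(tests = tests, anova = anova,
         alpha = alpha, alpha_duration = alpha_duration,
         n_participants = length(unique(m$rt_cells$participant_id))),
    class = "analysis_report")
}

#' Parameter recovery / type-I-error calibration
#'
#' Simulates `reps` studies per (lambda_congruent, lambda_incongruent) grid
#' cell, runs the screening + similarity pipeline on each, and records the
#' rejection rate and mean dz of the chosen congruency test. The null row
#' (equal lambdas) calibrates the type-I error; increasing the lambda gap
#' traces the power curve of the binding effect.
#'
#' @param design A [design_spec()].
#' @param pop Base [population_spec()]; its lambdas are overridden per cell.
#' @param grid Data frame with columns `lambda_congruent`,
#'   `lambda_incongruent`; a null row is appended if none is present.
#' @param n_participants Participants per simulated study.
#' @param reps Simulated studies per cell.
#' @param seed Root seed; each rep derives its own stream.
#' @param dv Dependent variable of the congruency test (default
#'   `"duration"`).
#' @param statistic `"corr"` (Fisher-Z correlation test) or `"diff"`.
#' @param alpha Rejection level.
#' @return A data frame per cell: lambdas, `rejection_rate`, `mc_se`
#'   (binomial Monte-Carlo SE, NA when `reps` = 1), `mean_dz`, `reps`, `n`.
#' @export
recover <- function(design, pop, grid, n_participants = pop$n_participants,
                    reps = 200, seed = 1L,
                    dv = c("duration", "auc", "peak"),
                    statistic = c("corr", "diff"), alpha = 0.05) {
  dv <- match.arg(dv)
  statistic <- match.arg(statistic)
  if (nrow(grid) == 0) stop("grid must be non-empty", call. = FALSE)
  if (!any(grid$lambda_congruent == grid$lambda_incongruent))
    grid <- rbind(grid,
                  data.frame(lambda_congruent = pop$lambda_incongruent,
                             lambda_incongruent = pop$lambda_incongruent))
  col <- if (statistic == "corr") "z_r" else "mean_abs_diff"

  do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    pop_g <- pop
    pop_g$lambda_congruent <- grid$lambda_congruent[g]
    pop_g$lambda_incongruent <- grid$lambda_incongruent[g]
    res <- vapply(seq_len(reps), function(r) {
      rep_seed <- (as.numeric(seed) + 611953 * g + 7919 * r) %% 2147483647
      trials <- simulate_experiment(design, pop_g, n_participants,
                                    seed = rep_seed)
      scr <- screen(trials, screening_rules())
      s <- suppressWarnings(
        prime_probe_summary(screen_dv(scr$trials, dv), dv))
      v <- condition_pairs(s, col)
      tt <- paired_t(v$congruent, v$incongruent)
      c(reject = as.numeric(tt$p < alpha), dz = tt$dz)
    }, c(reject = 0, dz = 0))
    rate <- mean(res["reject", ])
    data.frame(lambda_congruent = grid$lambda_congruent[g],
               lambda_incongruent = grid$lambda_incongruent[g],
               rejection_rate = rate,
               mc_se = if (reps > 1) sqrt(rate * (1 - rate) / reps)
                       else NA_real_,
               mean_dz = mean(res["dz", ]),
               reps = reps, n = n_participants)
  }))
}

#' Effect-size table with noncentral-t confidence intervals
#'
#' Summarizes the tests of one or more analysis reports as signed dz point
#' estimates with 95% confidence intervals, one row per analysis.
#'
#' @param reports A named list of `analysis_report`s (names label the rows,
#'   e.g. `exp1`, `exp2`, `pooled`), or a single report.
#' @param conf Confidence level.
#' @return A data frame: `study`, `analysis`, `n`, `t`, `dz`, `ci_lower`,
#'   `ci_upper`.
#' @export
effect_size_table <- function(reports, conf = 0.95) {
  if (inherits(reports, "analysis_report")) reports <- list(study = reports)
  do.call(rbind, lapply(names(reports), function(nm) {
    rep_ <- reports[[nm]]
    do.call(rbind, lapply(names(rep_$tests), function(a) {
      tt <- rep_$tests[[a]]
      ci <- dz_ci(tt$t, tt$n, conf)
      data.frame(study = nm, analysis = a, n = tt$n, t = tt$t,
                 dz = ci$dz, ci_lower = ci$lower, ci_upper = ci$upper,
                 stringsAsFactors = FALSE)
    }))
  }))
}
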