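# Session simulator: hierarchical feature model + optional trace rendering.
#
# Ground-truth pinch features (peak force, duration, RT) are drawn per trial;
# traces are rendered from those features on demand as raised-sine-squared
# pulses plus sensor noise. This keeps Monte-Carlo loops (thousands of
# simulated studies) at feature level while the trace path stays fully
# exercisable.

participant_seed <- function(seed, participant_id) {
  # fixed per-participant offset so any session is reproducible on its own
  as.integer((as.numeric(seed) + 104729 * as.numeric(participant_id)) %%
               2147483647)
}

schedule_block <- function(design) {
  conds <- c(rep("congruent", design$n_congruent_per_block),
             rep("incongruent", design$n_incongruent_per_block),
             rep("catch", design$n_catch_per_block))
  n <- length(conds)
  if (n >= 2 && design$n_catch_per_block > n - 2L)
    stop("infeasible schedule: fewer than two non-catch trials per block ",
         "(the first two trials of a block cannot be catch trials)",
         call. = FALSE)
  repeat {
    ord <- sample.int(n)
    if (n < 2 || !any(conds[ord[seq_len(min(2L, n))]] == "catch"))
      return(conds[ord])
  }
}

#' Generate one simulated session
#'
#' Simulates a complete prime-probe session for one participant: a
#' pseudo-randomized trial schedule (the first two trials of each block are
#' never catch trials), ground-truth pinch features, reaction times, and
#' outcome flags.
#'
#' @details Pinch features follow a hierarchical retrieval model. The
#'   participant draws a mean peak force and mean duration from the
#'   population; the prime pinch scatters around those means with the
#'   within-participant SDs; the probe pinch reproduces a fraction
#'   `lambda` (per condition) of the prime's deviation from the participant
#'   mean, plus fresh within-participant noise and the systematic probe
#'   boosts. Probe RT is lognormal with a mean advantage on congruent trials.
#'   A trial can be preempted by a restart (pinching before the mandatory
#'   wait or go signal); the repeated attempt keeps the same condition.
#'   Force integral (AUC) is `peak * duration / 2`, the closed-form integral
#'   of the raised-sine-squared pulse shape used by [make_pulse()].
#'
#' @param design A [design_spec()].
#' @param pop A [population_spec()].
#' @param participant_id Integer id; also offsets the RNG stream.
#' @param seed Root RNG seed.
#' @return A data frame with one row per trial attempt: identifiers
#'   (`participant_id`, `block_index`, `trial_index`, `attempt`), `condition`,
#'   tones, stimulus onsets, ground-truth prime/probe features (`*_peak_N`,
#'   `*_duration_ms`, `*_auc_Nms`, `*_onset_ms`, `*_rt_ms`) and `outcome`
#'   (`ok`, `miss`, `false_alarm`, `restart`, `catch_correct`, `catch_error`).
#' @export
generate_session <- function(design, pop, participant_id = 1L, seed = 1L) {
  stopifnot(inherits(design, "design_spec"), inherits(pop, "population_spec"))
  set.seed(participant_seed(seed, participant_id))

  conds <- unlist(lapply(seq_len(design$n_blocks),
                         function(b) schedule_block(design)))
  n <- length(conds)
  block <- rep(seq_len(design$n_blocks), each = design$trials_per_block)
  trial <- rep(seq_len(design$trials_per_block), times = design$n_blocks)

  # participant-level means (truncated to sane positive values); the probe
  # boost also varies by participant on the same scale as overall
  # forcefulness (a constant boost would make the prime-vs-probe contrast
  # nearly noise-free at the participant level, which real samples are not)
  mu_peak <- max(0.6, rnorm(1, pop$mean_peak_N, pop$sd_peak_N))
  mu_dur  <- max(40, rnorm(1, pop$mean_duration_ms, pop$sd_duration_ms))
  boost_i <- if (pop$probe_boost_peak_N == 0) 0 else
    rnorm(1, pop$probe_boost_peak_N, pop$sd_peak_N)

  prime_tone <- sample(c("low", "high"), n, replace = TRUE)
  probe_tone <- ifelse(conds == "congruent", prime_tone,
                ifelse(conds == "incongruent",
                       ifelse(prime_tone == "low", "high", "low"), "none"))

  lambda <- ifelse(conds == "congruent", pop$lambda_congruent,
            ifelse(conds == "incongruent", pop$lambda_incongruent, 0))

  prime_peak <- pmax(0.5, mu_peak + rnorm(n, 0, pop$within_sd_peak_N))
  prime_dur  <- pmax(20, mu_dur + rnorm(n, 0, pop$within_sd_duration_ms))
  probe_peak <- pmax(0.5, mu_peak + lambda * (prime_peak - mu_peak) +
                       rnorm(n, 0, pop$within_sd_peak_N) +
                       boost_i) *
                (1 + pop$probe_boost_auc_frac)
  probe_dur  <- pmax(20, mu_dur + lambda * (prime_dur - mu_dur) +
                       rnorm(n, 0, pop$within_sd_duration_ms))

  # timing: trial clock starts at the go signal (exp2 style) or trial start
  if (design$go_signal) {
    prime_stim <- rep(0, n)
    prime_rt <- pmax(1, exp(rnorm(n, log(pop$rt_location_ms), pop$rt_scale)))
    prime_onset <- prime_stim + prime_rt
  } else {
    prime_stim <- rep(NA_real_, n)
    prime_rt <- rep(NA_real_, n)
    # self-initiated pinch after the mandatory 2 s wait
    prime_onset <- 2000 + exp(rnorm(n, log(400), 0.4))
  }
  probe_stim <- ifelse(conds == "catch", NA_real_, prime_onset + design$soa_ms)
  probe_rt <- pmax(1, exp(rnorm(n, log(pop$rt_location_ms), pop$rt_scale)) -
                     ifelse(conds == "congruent",
                            pop$rt_congruency_advantage_ms, 0))
  probe_onset <- probe_stim + probe_rt

  u <- runif(n)
  outcome <- ifelse(conds == "catch",
                    ifelse(u < pop$false_alarm_rate, "catch_error",
                           "catch_correct"),
                    ifelse(u < pop$false_alarm_rate, "false_alarm",
                    ifelse(u < pop$false_alarm_rate + pop$miss_rate, "miss",
                           "ok")))

  drop_probe <- outcome %in% c("miss", "false_alarm", "catch_correct",
                               "catch_error")
  probe_peak[drop_probe] <- NA_real_
  probe_dur[drop_probe] <- NA_real_
  probe_rt[drop_probe] <- NA_real_
  probe_onset[drop_probe] <- NA_real_

  out <- data.frame(
    participant_id = participant_id,
    block_index = block, trial_index = trial, attempt = 1L,
    condition = conds, prime_tone = prime_tone, probe_tone = probe_tone,
    prime_stim_onset_ms = prime_stim, probe_stim_onset_ms = probe_stim,
    prime_onset_ms = prime_onset, prime_rt_ms = prime_rt,
    prime_peak_N = prime_peak, prime_duration_ms = prime_dur,
    prime_auc_Nms = prime_peak * prime_dur / 2,
    probe_onset_ms = probe_onset, probe_rt_ms = probe_rt,
    probe_peak_N = probe_peak, probe_duration_ms = probe_dur,
    probe_auc_Nms = probe_peak * probe_dur / 2,
    outcome = outcome,
    stringsAsFactors = FALSE)

  # restarts: a too-early pinch aborts the attempt; the trial repeats with
  # the same condition
  restart <- runif(n) < pop$restart_rate
  if (any(restart)) {
    aborted <- out[restart, ]
    aborted$attempt <- 0L
    aborted$outcome <- "restart"
    aborted[, c("prime_stim_onset_ms", "probe_stim_onset_ms",
                "prime_onset_ms", "prime_rt_ms", "prime_peak_N",
                "prime_duration_ms", "prime_auc_Nms", "probe_onset_ms",
                "probe_rt_ms", "probe_peak_N", "probe_duration_ms",
                "probe_auc_Nms")] <- NA_real_
    out <- rbind(aborted, out)
    out <- out[order(out$block_index, out$trial_index, out$attempt), ]
    rownames(out) <- NULL
  }
  out
}

#' Simulate a complete multi-participant study
#'
#' Calls [generate_session()] once per participant with a fixed
#' per-participant RNG offset, so any single session can be regenerated
#' independently of the others.
#'
#' @inheritParams generate_session
#' @param n_participants Number of participants (defaults to the population
#'   spec).
#' @return Row-bound session data frames (see [generate_session()]).
#' @export
simulate_experiment <- function(design, pop,
                                n_participants = pop$n_participants,
                                seed = 1L) {
  do.call(rbind, lapply(seq_len(n_participants), function(p)
    generate_session(design, pop, participant_id = p, seed = seed)))
}

#' Render force traces for simulated trials
#'
#' Synthesizes per-part force traces from the ground-truth features of a
#' simulated trial table: each pinch becomes a raised-sine-squared pulse
#' ([make_pulse()]) at its onset time, with additive Gaussian sensor noise
#' (clipped at zero force). Trials whose part has no pinch (misses, catch
#' trials, restarts) yield a noise-only trace for that part.
#'
#' @param trials A trial table from [generate_session()].
#' @param pop The [population_spec()] (for the sensor noise SD).
#' @param sample_rate_hz Sampling rate of the rendered traces.
#' @param pad_ms Rest padding before and after each pulse (ms).
#' @param seed RNG seed for the sensor noise.
#' @return A list with one element per trial row, each a list of `prime` and
#'   `probe` [force_trace()] objects (absent parts are noise-only traces).
#' @export
render_traces <- function(trials, pop, sample_rate_hz = 1000,
                          pad_ms = 150, seed = 1L) {
  set.seed(participant_seed(seed, 999983))
  render_part <- function(onset, peak, dur, pid, tix, part) {
    if (is.na(onset) || is.na(peak)) {
      ns <- as.integer(2 * pad_ms * sample_rate_hz / 1000) + 1L
      tr <- force_trace(pmax(rnorm(ns, 0, pop$sensor_noise_sd_N), 0),
                        sample_rate_hz, t0_ms = 0, channel = "force_N",
                        participant_id = pid, trial_index = tix, part = part)
      return(tr)
    }
    tr <- make_pulse(peak, dur, sample_rate_hz, t0_ms = onset, pad_ms = pad_ms)
    tr$samples <- pmax(tr$samples +
                         rnorm(length(tr$samples), 0, pop$sensor_noise_sd_N),
                       0)
    tr$participant_id <- pid; tr$trial_index <- tix; tr$part <- part
    tr
  }
  lapply(seq_len(nrow(trials)), function(i) {
    r <- trials[i, ]
    list(prime = render_part(r$prime_onset_ms, r$prime_peak_N,
                             r$prime_duration_ms, r$participant_id,
                             r$trial_index, "prime"),
         probe = render_part(r$probe_onset_ms, r$probe_peak_N,
                             r$probe_duration_ms, r$participant_id,
                             r$trial_index, "probe"))
  })
}
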