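#' Experimental design specification
#'
#' Describes the block structure and timing of a prime-probe pinch session.
#' Each trial has a prime part (a pinch producing an effect tone) and a probe
#' part in which the tone either repeats (congruent), changes (incongruent)
#' or is absent (catch trial, responding is an error).
#'
#' @param n_blocks Number of experimental blocks.
#' @param trials_per_block Trials in each block.
#' @param n_congruent_per_block,n_incongruent_per_block,n_catch_per_block
#'   Per-block condition composition; must sum to `trials_per_block`.
#' @param soa_ms Stimulus-onset asynchrony: delay from the prime effect-tone
#'   onset to the probe stimulus (second tone) onset, in ms.
#' @param response_window_ms Time allowed for the probe pinch after the probe
#'   stimulus onset; a later (or absent) pinch is a miss.
#' @param tone_low_hz,tone_high_hz Frequencies of the two effect tones.
#' @param tone_duration_ms Tone duration.
#' @param go_signal Logical; if `TRUE` the prime pinch is itself a response to
#'   an auditory go signal (second-experiment style).
#' @param probe_effect_tone Logical; if `TRUE` the probe pinch also elicits a
#'   (randomly pitched) effect tone.
#' @param effect_delay_ms Constant hardware lag between detected action onset
#'   and tone presentation, carried as metadata only (it is excluded from RT,
#'   which is defined stimulus onset to pinch onset).
#'
#' @return An object of class `design_spec` (a named list).
#' @seealso [design_preset()] for the two canonical presets.
#' @export
design_spec <- function(n_blocks,
                        trials_per_block,
                        n_congruent_per_block,
                        n_incongruent_per_block,
                        n_catch_per_block,
                        soa_ms = 600,
                        response_window_ms = 1200,
                        tone_low_hz = 440,
                        tone_high_hz = 1175,
                        tone_duration_ms = 300,
                        go_signal = FALSE,
                        probe_effect_tone = FALSE,
                        effect_delay_ms = 6) {
  counts <- c(n_blocks, trials_per_block, n_congruent_per_block,
              n_incongruent_per_block, n_catch_per_block)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("block/trial counts must be non-negative integers", call. = FALSE)
  if (n_congruent_per_block + n_incongruent_per_block + n_catch_per_block !=
      trials_per_block)
    stop("condition counts must sum to trials_per_block", call. = FALSE)
  if (soa_ms <= 0 || response_window_ms <= 0)
    stop("soa_ms and response_window_ms must be positive", call. = FALSE)
  structure(
    list(n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         n_congruent_per_block = as.integer(n_congruent_per_block),
         n_incongruent_per_block = as.integer(n_incongruent_per_block),
         n_catch_per_block = as.integer(n_catch_per_block),
         soa_ms = soa_ms,
         response_window_ms = response_window_ms,
         tone_low_hz = tone_low_hz,
         tone_high_hz = tone_high_hz,
         tone_duration_ms = tone_duration_ms,
         go_signal = isTRUE(go_signal),
         probe_effect_tone = isTRUE(probe_effect_tone),
         effect_delay_ms = effect_delay_ms),
    class = "design_spec")
}

#' Canonical design presets
#'
#' `"exp1"`: 7 blocks of 30 trials (12 congruent / 12 incongruent / 6 catch,
#' i.e. 20% catch trials), 600 ms SOA, 1200 ms response window, 300 ms tones,
#' self-initiated prime. `"exp2"`: 9 blocks of 40 trials (10/10/20, 50% catch),
#' 150 ms tones, auditory go signal before the prime and an effect tone on the
#' probe.
#'
#' @param name `"exp1"` or `"exp2"`.
#' @return A [design_spec()].
#' @export
design_preset <- function(name = c("exp1", "exp2")) {
  name <- match.arg(name)
  switch(name,
    exp1 = design_spec(7, 30, 12, 12, 6,
                       soa_ms = 600, response_window_ms = 1200,
                       tone_duration_ms = 300,
                       go_signal = FALSE, probe_effect_tone = FALSE),
    exp2 = design_spec(9, 40, 10, 10, 20,
                       soa_ms = 600, response_window_ms = 1200,
                       tone_duration_ms = 150,
                       go_signal = TRUE, probe_effect_tone = TRUE))
}

#' Population specification for the session simulator
#'
#' Parameters of the simulated participant population. Pinch features are
#' drawn hierarchically: each participant gets a mean peak force and mean
#' pinch duration, trials scatter around those means, and the probe pinch
#' reproduces a fraction `lambda` of the prime pinch's deviation from the
#' participant mean ("retrieval strength"). A congruent/incongruent difference
#' in `lambda` is the planted binding effect; `lambda_congruent ==
#' lambda_incongruent` is the null (no-binding) regime.
#'
#' @param n_participants Default number of participants for a simulated study.
#' @param mean_peak_N,sd_peak_N Population mean and between-participant SD of
#'   the participant-level mean peak force (N).
#' @param mean_duration_ms,sd_duration_ms Same for pinch duration (ms).
#' @param within_sd_peak_N,within_sd_duration_ms Trial-level (within
#'   participant) SDs.
#' @param lambda_congruent,lambda_incongruent Retrieval strengths in \[0, 1\]:
#'   the fraction of the prime pinch's deviation from the participant mean
#'   carried into the probe pinch, per condition.
#' @param probe_boost_peak_N Additive probe > prime peak-force offset (N); the
#'   probe, being a speeded reaction, is systematically more forceful.
#' @param probe_boost_auc_frac Extra multiplicative scale on the probe pulse
#'   amplitude (fractional AUC increase beyond what the peak boost gives).
#' @param rt_location_ms,rt_scale Median (ms) and log-scale SD of the
#'   lognormal probe reaction-time distribution.
#' @param rt_congruency_advantage_ms Mean RT benefit on congruent trials (ms).
#' @param sensor_noise_sd_N SD of additive Gaussian sensor noise on rendered
#'   traces (N).
#' @param miss_rate,false_alarm_rate,restart_rate Trial-outcome error
#'   probabilities. Catch-trial errors use `false_alarm_rate`.
#'
#' @details Defaults follow the descriptive statistics of a typical pinch
#'   experiment: participant-mean peak forces around 3.6 N with a +1.2 N probe
#'   boost, pinch durations around 200 ms, probe RT median 310 ms with a 16 ms
#'   congruency advantage, ~2% misses, ~1% false alarms and ~8% trial
#'   restarts. Retrieval strengths default to the null regime
#'   (`lambda_congruent == lambda_incongruent == 0.5`); binding effects are
#'   planted explicitly by raising `lambda_congruent`.
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_participants = 19,
                            mean_peak_N = 3.6,
                            sd_peak_N = 1.2,
                            mean_duration_ms = 200,
                            sd_duration_ms = 45,
                            within_sd_peak_N = 1.0,
                            within_sd_duration_ms = 30,
                            lambda_congruent = 0.5,
                            lambda_incongruent = 0.5,
                            probe_boost_peak_N = 1.2,
                            probe_boost_auc_frac = 0,
                            rt_location_ms = 310,
                            rt_scale = 0.3,
                            rt_congruency_advantage_ms = 16,
                            sensor_noise_sd_N = 0.02,
                            miss_rate = 0.019,
                            false_alarm_rate = 0.008,
                            restart_rate = 0.08) {
  lam <- c(lambda_congruent, lambda_incongruent)
  if (any(!is.finite(lam)) || any(lam < 0) || any(lam > 1))
    stop("lambda_* must lie in [0, 1]", call. = FALSE)
  sds <- c(sd_peak_N, sd_duration_ms, within_sd_peak_N, within_sd_duration_ms,
           rt_scale, sensor_noise_sd_N)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  pr <- c(miss_rate, false_alarm_rate, restart_rate)
  if (any(pr < 0) || any(pr > 1))
    stop("rates must be probabilities in [0, 1]", call. = FALSE)
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  if (mean_peak_N <= 0 || mean_duration_ms <= 0 || rt_location_ms <= 0)
    stop("population means must be positive", call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants),
         mean_peak_N = mean_peak_N, sd_peak_N = sd_peak_N,
         mean_duration_ms = mean_duration_ms, sd_duration_ms = sd_duration_ms,
         within_sd_peak_N = within_sd_peak_N,
         within_sd_duration_ms = within_sd_duration_ms,
         lambda_congruent = lambda_congruent,
         lambda_incongruent = lambda_incongruent,
         probe_boost_peak_N = probe_boost_peak_N,
         probe_boost_auc_frac = probe_boost_auc_frac,
         rt_location_ms = rt_location_ms, rt_scale = rt_scale,
         rt_congruency_advantage_ms = rt_congruency_advantage_ms,
         sensor_noise_sd_N = sensor_noise_sd_N,
         miss_rate = miss_rate, false_alarm_rate = false_alarm_rate,
         restart_rate = restart_rate),
    class = "population_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("Prime-probe design: %d blocks x %d trials (%d congruent / %d incongruent / %d catch per block)\n",
              x$n_blocks, x$trials_per_block, x$n_congruent_per_block,
              x$n_incongruent_per_block, x$n_catch_per_block))
  cat(sprintf("  SOA %g ms, response window %g ms, tones %g/%g Hz (%g ms)\n",
              x$soa_ms, x$response_window_ms, x$tone_low_hz, x$tone_high_hz,
              x$tone_duration_ms))
  cat(sprintf("  go signal: %s, probe effect tone: %s\n",
              x$go_signal, x$probe_effect_tone))
  invisible(x)
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("Simulated population: %d participants\n", x$n_participants))
  cat(sprintf("  peak %g (+/- %g between, %g within) N, duration %g (+/- %g, %g) ms\n",
              x$mean_peak_N, x$sd_peak_N, x$within_sd_peak_N,
              x$mean_duration_ms, x$sd_duration_ms, x$within_sd_duration_ms))
  cat(sprintf("  retrieval lambda: congruent %g, incongruent %g\n",
              x$lambda_congruent, x$lambda_incongruent))
  invisible(x)
}
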