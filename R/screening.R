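# Trial outcome classification and the multi-stage rejection cascade.

#' Screening rules
#'
#' The trial-rejection cascade applied before any similarity analysis, in this
#' fixed order: RT floor, RT ceiling, prime-duration cap, probe-duration cap.
#' Per-dependent-variable z-score rejection is applied separately per analysis
#' by [screen_dv()], never globally. Mean/SD-based rules use a single pass
#' (statistics computed over the trials still eligible at that stage, within
#' participant x condition, sample SD with n-1 denominator).
#'
#' @param rt_floor_ms Reject probe (and, with a go signal, prime) RTs faster
#'   than this (ms).
#' @param rt_ceiling_mode `"mean_plus_2.5sd"`: reject RTs above the
#'   participant-x-condition mean + 2.5 SD. `"absolute_3000ms_then_z2.5"`:
#'   reject RTs above 3 s, then RTs with |z| > 2.5 within participant x
#'   condition.
#' @param duration_cap_ms Reject pinches with duration greater than or equal
#'   to this cap (inclusive), prime and probe separately.
#' @param dv_z_cutoff z-score cutoff for the per-DV rejection ([screen_dv()]).
#' @return An object of class `screening_rules`.
#' @export
screening_rules <- function(rt_floor_ms = 100,
                            rt_ceiling_mode = c("mean_plus_2.5sd",
                                                "absolute_3000ms_then_z2.5"),
                            duration_cap_ms = 600,
                            dv_z_cutoff = 2.5) {
  rt_ceiling_mode <- match.arg(rt_ceiling_mode)
  if (rt_floor_ms <= 0 || duration_cap_ms <= 0 || dv_z_cutoff <= 0)
    stop("all thresholds must be positive", call. = FALSE)
  structure(list(rt_floor_ms = rt_floor_ms,
                 rt_ceiling_mode = rt_ceiling_mode,
                 duration_cap_ms = duration_cap_ms,
                 dv_z_cutoff = dv_z_cutoff),
            class = "screening_rules")
}

#' Screening presets for the two experiment styles
#'
#' `"exp1"` uses the mean + 2.5 SD RT ceiling; `"exp2"` uses the absolute 3 s
#' ceiling followed by |z| > 2.5 rejection.
#'
#' @param name `"exp1"` or `"exp2"`.
#' @return A [screening_rules()].
#' @export
screening_preset <- function(name = c("exp1", "exp2")) {
  name <- match.arg(name)
  switch(name,
    exp1 = screening_rules(rt_ceiling_mode = "mean_plus_2.5sd"),
    exp2 = screening_rules(rt_ceiling_mode = "absolute_3000ms_then_z2.5"))
}

#' Classify trial outcomes from events and timing
#'
#' Assigns `outcome` from the recorded events: `catch_error` (pinch on a
#' catch trial) / `catch_correct`; `false_alarm` (probe pinch before the
#' probe stimulus onset, i.e. inside the SOA); `miss` (no probe pinch within
#' the response window — a later pinch still counts as a miss); `ok`
#' otherwise. Rows already flagged as restarts keep that outcome.
#'
#' @param trials Trial table with events populated (ground truth from
#'   [generate_session()] or measured via [features_to_trials()]).
#' @param design The [design_spec()] (for the response window).
#' @return The trial table with `outcome` set.
#' @export
classify_outcomes <- function(trials, design) {
  restart <- !is.null(trials$outcome) & trials$outcome == "restart"
  if (any(is.na(trials$prime_onset_ms) & !restart))
    stop("missing prime event on a non-restart trial", call. = FALSE)

  probe_present <- !is.na(trials$probe_onset_ms)
  rt <- trials$probe_rt_ms
  out <- ifelse(trials$condition == "catch",
                ifelse(probe_present, "catch_error", "catch_correct"),
         ifelse(probe_present &
                  trials$probe_onset_ms < trials$probe_stim_onset_ms,
                "false_alarm",
         ifelse(!probe_present | rt > design$response_window_ms,
                "miss", "ok")))
  out[restart] <- "restart"
  trials$outcome <- out
  trials
}

group_key <- function(trials) {
  paste(trials$participant_id, trials$condition, sep = ":")
}

# |z| within participant x condition; single pass, sample SD (n-1).
# Cells with < 2 trials yield NA (rule skipped there) with a warning.
group_abs_z <- function(x, key) {
  mu <- ave(x, key, FUN = function(v) mean(v, na.rm = TRUE))
  sd_ <- ave(x, key, FUN = function(v) stats::sd(v, na.rm = TRUE))
  n <- ave(!is.na(x), key, FUN = sum)
  if (any(n < 2)) {
    warning("participant x condition cell with < 2 trials: ",
            "z-based rule skipped there (SD undefined)", call. = FALSE)
  }
  z <- (x - mu) / sd_
  z[n < 2 | sd_ == 0] <- NA_real_
  abs(z)
}

#' Apply the rejection cascade
#'
#' Screens outcome-`ok` trials through the ordered cascade of
#' [screening_rules()]; catch and error trials are not eligible and pass
#' through untouched (returned separately for error-rate reporting). Each
#' stage's mean/SD statistics are computed over the trials still eligible at
#' that stage.
#'
#' @param trials Trial table with outcomes classified.
#' @param rules A [screening_rules()].
#' @return A list: `trials` (surviving ok trials), `excluded` (catch, error
#'   and restart rows, untouched), and `report` — a `screening_report` with
#'   the ordered rule log (`rule`, `n_rejected`, `fraction` of eligible),
#'   eligible/surviving totals, and per-condition remaining counts.
#' @export
screen <- function(trials, rules = screening_rules()) {
  stopifnot(inherits(rules, "screening_rules"))
  if (is.null(trials$outcome)) stop("classify outcomes first", call. = FALSE)
  eligible <- trials[trials$outcome == "ok", ]
  excluded <- trials[trials$outcome != "ok", ]
  n_eligible <- nrow(eligible)
  log <- list()
  reject <- function(d, bad, rule) {
    bad[is.na(bad)] <- FALSE
    log[[length(log) + 1L]] <<- data.frame(
      rule = rule, n_rejected = sum(bad),
      fraction = if (n_eligible > 0) sum(bad) / n_eligible else 0)
    d[!bad, ]
  }

  has_prime_rt <- any(!is.na(eligible$prime_rt_ms))

  # 1. RT floor
  bad <- eligible$probe_rt_ms < rules$rt_floor_ms
  if (has_prime_rt) bad <- bad | eligible$prime_rt_ms < rules$rt_floor_ms
  eligible <- reject(eligible, bad, "rt_floor")

  # 2. RT ceiling
  if (rules$rt_ceiling_mode == "mean_plus_2.5sd") {
    key <- group_key(eligible)
    mu <- ave(eligible$probe_rt_ms, key, FUN = mean)
    sd_ <- ave(eligible$probe_rt_ms, key,
               FUN = function(v) stats::sd(v))
    bad <- eligible$probe_rt_ms > mu + 2.5 * sd_
    eligible <- reject(eligible, bad, "rt_ceiling_mean_2.5sd")
  } else {
    bad <- eligible$probe_rt_ms > 3000
    if (has_prime_rt) bad <- bad | eligible$prime_rt_ms > 3000
    eligible <- reject(eligible, bad, "rt_ceiling_absolute_3000")
    z <- group_abs_z(eligible$probe_rt_ms, group_key(eligible))
    bad <- z > 2.5
    if (has_prime_rt) {
      zp <- group_abs_z(eligible$prime_rt_ms, group_key(eligible))
      bad <- bad | zp > 2.5
    }
    eligible <- reject(eligible, bad, "rt_z_2.5")
  }

  # 3./4. duration caps (inclusive: duration >= cap is rejected)
  eligible <- reject(eligible,
                     eligible$prime_duration_ms >= rules$duration_cap_ms,
                     "prime_duration_cap")
  eligible <- reject(eligible,
                     eligible$probe_duration_ms >= rules$duration_cap_ms,
                     "probe_duration_cap")

  log <- do.call(rbind, log)
  remaining <- as.data.frame(table(condition = eligible$condition),
                             stringsAsFactors = FALSE)
  names(remaining)[2] <- "n_remaining"
  report <- structure(
    list(rule_log = log, n_eligible = n_eligible,
         n_surviving = nrow(eligible), per_condition = remaining),
    class = "screening_report")
  list(trials = eligible, excluded = excluded, report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening: %d eligible -> %d surviving\n",
              x$n_eligible, x$n_surviving))
  print(x$rule_log, row.names = FALSE)
  invisible(x)
}

#' Per-dependent-variable z-score rejection
#'
#' Rejects trials whose prime or probe value of one dependent variable has
#' |z| above the cutoff within participant x condition. Applied separately
#' for each analysis: the force analyses and the duration analyses see
#' different survivor sets, so this runs on the cascade survivors at analysis
#' time rather than inside [screen()].
#'
#' @param trials Survivors from [screen()].
#' @param dv One of `"auc"`, `"peak"`, `"duration"`, `"rt"` (`"rt"` uses the
#'   probe RT only).
#' @param cutoff z cutoff (default 2.5).
#' @return The trials surviving the per-DV rejection.
#' @export
screen_dv <- function(trials, dv = c("auc", "peak", "duration", "rt"),
                      cutoff = 2.5) {
  dv <- match.arg(dv)
  key <- group_key(trials)
  cols <- switch(dv,
                 auc = c("prime_auc_Nms", "probe_auc_Nms"),
                 peak = c("prime_peak_N", "probe_peak_N"),
                 duration = c("prime_duration_ms", "probe_duration_ms"),
                 rt = "probe_rt_ms")
  bad <- rep(FALSE, nrow(trials))
  for (cl in cols) {
    z <- group_abs_z(trials[[cl]], key)
    bad <- bad | (!is.na(z) & z > cutoff)
  }
  trials[!bad, ]
}
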