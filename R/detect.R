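# Pinch detection: threshold + persistence rule on the force channel.

#' Detection parameters
#'
#' Threshold-plus-persistence rule for pinch onset/offset detection. Onset is
#' the first sample strictly above `threshold_N` preceded by at least
#' `persistence_ms` of consecutive samples at/below threshold (the trace start
#' counts as satisfied history); offset is the first subsequent sample
#' at/below threshold followed by at least `persistence_ms` at/below (trace
#' end counts as satisfied future).
#'
#' @param threshold_N Force threshold (N), default 0.32.
#' @param persistence_ms Persistence requirement (ms), default 10.
#' @param strict_above If `TRUE` (default) "exceeds" means strictly greater
#'   than the threshold and the sub-threshold state is `<=`; set `FALSE` to
#'   flip to `>=` / `<`.
#' @param transform_a,transform_b Calibration constants used when a voltage
#'   trace must first be converted with [voltage_to_force()].
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(threshold_N = 0.32, persistence_ms = 10,
                             strict_above = TRUE,
                             transform_a = 0.05, transform_b = 1.5) {
  if (threshold_N <= 0) stop("threshold_N must be positive", call. = FALSE)
  if (persistence_ms < 0) stop("persistence_ms must be >= 0", call. = FALSE)
  structure(list(threshold_N = threshold_N, persistence_ms = persistence_ms,
                 strict_above = isTRUE(strict_above),
                 transform_a = transform_a, transform_b = transform_b),
            class = "detection_params")
}

#' Detect the first pinch event in a force trace
#'
#' Applies the threshold-plus-persistence rule of [detection_params()] and
#' returns the first qualifying event, or `NULL` when no crossing qualifies
#' (absence is a valid result, e.g. on catch trials). A brief sub-threshold
#' dip shorter than the persistence requirement does not terminate an event,
#' so closely spaced pulses merge. Additional qualifying events later in the
#' trace are counted in `n_extra_events` as a quality flag.
#'
#' @param trace A [force_trace()] on the `force_N` channel.
#' @param params A [detection_params()].
#' @return A `pinch_event` (list with `onset_ms`, `offset_ms`, `duration_ms`,
#'   `peak_force_N`, `auc_Nms`, `rt_ms`, `n_extra_events`) or `NULL`. Feature
#'   fields are filled by [compute_features()].
#' @export
detect_pinch <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "force_trace"))
  if (trace$channel != "force_N")
    stop("detect_pinch() expects a force-channel trace; ",
         "convert with voltage_to_force()", call. = FALSE)
  x <- trace$samples
  above <- if (params$strict_above) x > params$threshold_N else
    x >= params$threshold_N
  k <- as.integer(round(params$persistence_ms * trace$sample_rate_hz / 1000))

  r <- rle(above)
  nr <- length(r$values)
  run_start <- cumsum(c(1L, r$lengths[-nr]))
  run_end <- cumsum(r$lengths)

  events <- list()
  i <- 1L
  while (i <= nr) {
    if (r$values[i]) {
      # onset candidate: preceded by >= k below samples, or trace start
      ok_hist <- (i == 1L) || (r$lengths[i - 1L] >= k)
      if (ok_hist) {
        onset_idx <- run_start[i]
        # walk forward to the first below-run long enough (or trace end)
        j <- i + 1L
        offset_idx <- NA_integer_
        while (j <= nr) {
          if (!r$values[j] && (r$lengths[j] >= k || j == nr)) {
            offset_idx <- run_start[j]
            break
          }
          j <- j + 1L
        }
        if (is.na(offset_idx)) {
          # event runs to the trace end with no sub-threshold return:
          # treat the final sample as the endpoint (trace end counts as
          # satisfied future)
          offset_idx <- length(x)
          j <- nr
        }
        events[[length(events) + 1L]] <- c(onset_idx, offset_idx)
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (length(events) == 0L) return(NULL)

  dt_ms <- 1000 / trace$sample_rate_hz
  ev <- events[[1L]]
  structure(
    list(onset_ms = trace$t0_ms + (ev[1L] - 1L) * dt_ms,
         offset_ms = trace$t0_ms + (ev[2L] - 1L) * dt_ms,
         duration_ms = (ev[2L] - ev[1L]) * dt_ms,
         peak_force_N = NA_real_, auc_Nms = NA_real_, rt_ms = NA_real_,
         n_extra_events = length(events) - 1L),
    class = "pinch_event")
}

#' Complete a pinch event with force features
#'
#' Fills in peak force, AUC (trapezoid integral of force between onset and
#' offset, in N*ms) and, when a stimulus onset is supplied, the reaction time
#' (onset minus stimulus onset). A negative RT (pinch before the stimulus) is
#' returned and flagged via `rt_flag = "negative"`, never silently dropped.
#'
#' @param trace The [force_trace()] the event was detected in.
#' @param event A `pinch_event` from [detect_pinch()].
#' @param stimulus_onset_ms Optional stimulus onset on the same clock (ms).
#' @return The completed `pinch_event`.
#' @export
compute_features <- function(trace, event, stimulus_onset_ms = NULL) {
  stopifnot(inherits(trace, "force_trace"), inherits(event, "pinch_event"))
  dt_ms <- 1000 / trace$sample_rate_hz
  i0 <- as.integer(round((event$onset_ms - trace$t0_ms) / dt_ms)) + 1L
  i1 <- as.integer(round((event$offset_ms - trace$t0_ms) / dt_ms)) + 1L
  if (i0 < 1L || i1 > length(trace$samples) || i0 >= i1)
    stop("event lies outside the trace extent", call. = FALSE)
  seg <- trace$samples[i0:i1]
  event$peak_force_N <- max(seg)
  event$auc_Nms <- sum((seg[-1L] + seg[-length(seg)]) / 2) * dt_ms
  if (!is.null(stimulus_onset_ms) && !is.na(stimulus_onset_ms)) {
    event$rt_ms <- event$onset_ms - stimulus_onset_ms
    if (event$rt_ms < 0) event$rt_flag <- "negative"
  }
  event
}

#' @export
print.pinch_event <- function(x, ...) {
  cat(sprintf("<pinch_event> onset %.1f ms, offset %.1f ms (duration %.1f ms)\n",
              x$onset_ms, x$offset_ms, x$duration_ms))
  cat(sprintf("  peak %.3g N, AUC %.4g N*ms, RT %s ms%s\n",
              x$peak_force_N, x$auc_Nms,
              ifelse(is.na(x$rt_ms), "-", sprintf("%.1f", x$rt_ms)),
              if (x$n_extra_events > 0)
                sprintf(" [%d extra event(s) in window]", x$n_extra_events)
              else ""))
  invisible(x)
}

#' Extract per-part features from rendered traces
#'
#' Runs [detect_pinch()] and [compute_features()] over the trace set produced
#' by [render_traces()], yielding one row per (participant, trial, part) —
#' the long `features` table consumed by the screening stage.
#'
#' @param traces Trace list from [render_traces()].
#' @param trials The matching trial table (for stimulus onsets and ids).
#' @param params A [detection_params()].
#' @return A data frame with columns `participant_id`, `block_index`,
#'   `trial_index`, `attempt`, `condition`, `part`, `onset_ms`, `offset_ms`,
#'   `duration_ms`, `peak_N`, `auc_Nms`, `rt_ms`, `n_extra_events` (rows with
#'   no detected event carry NAs).
#' @export
extract_features <- function(traces, trials, params = detection_params()) {
  stopifnot(length(traces) == nrow(trials))
  one <- function(i, part) {
    tr <- traces[[i]][[part]]
    stim <- trials[[paste0(part, "_stim_onset_ms")]][i]
    ev <- detect_pinch(tr, params)
    if (!is.null(ev)) ev <- compute_features(tr, ev, stim)
    data.frame(
      participant_id = trials$participant_id[i],
      block_index = trials$block_index[i],
      trial_index = trials$trial_index[i],
      attempt = trials$attempt[i],
      condition = trials$condition[i],
      part = part,
      onset_ms = if (is.null(ev)) NA_real_ else ev$onset_ms,
      offset_ms = if (is.null(ev)) NA_real_ else ev$offset_ms,
      duration_ms = if (is.null(ev)) NA_real_ else ev$duration_ms,
      peak_N = if (is.null(ev)) NA_real_ else ev$peak_force_N,
      auc_Nms = if (is.null(ev)) NA_real_ else ev$auc_Nms,
      rt_ms = if (is.null(ev)) NA_real_ else ev$rt_ms,
      n_extra_events = if (is.null(ev)) NA_integer_ else ev$n_extra_events,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_len(nrow(trials)), function(i)
    rbind(one(i, "prime"), one(i, "probe"))))
}

#' Pivot a long features table back to trial level
#'
#' Joins the measured prime/probe features of [extract_features()] into a
#' wide trial table with the same column layout as [generate_session()], so
#' the screening and statistics stages run identically on measured and
#' ground-truth features.
#'
#' @param features Long table from [extract_features()].
#' @param trials The originating trial table (for outcome flags and onsets).
#' @return A wide trial table with measured `prime_*` / `probe_*` features.
#' @export
features_to_trials <- function(features, trials) {
  key <- function(d) paste(d$participant_id, d$block_index, d$trial_index,
                           d$attempt)
  out <- trials
  for (part in c("prime", "probe")) {
    f <- features[features$part == part, ]
    idx <- match(key(out), key(f))
    out[[paste0(part, "_onset_ms")]] <- f$onset_ms[idx]
    out[[paste0(part, "_duration_ms")]] <- f$duration_ms[idx]
    out[[paste0(part, "_peak_N")]] <- f$peak_N[idx]
    out[[paste0(part, "_auc_Nms")]] <- f$auc_Nms[idx]
    out[[paste0(part, "_rt_ms")]] <- f$rt_ms[idx]
  }
  out
}
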