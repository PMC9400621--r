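# Plain-text I/O: the long-format trial table, per-trial trace files, and
# machine-readable results.

#' Write a simulated session bundle
#'
#' Writes `trials.csv` (one row per trial attempt, times in ms, forces in N),
#' `session_meta.json` (design + population + seed) and, optionally, per-part
#' trace files `traces/<participant>_<block>_<trial>_<attempt>_<part>.csv`
#' with columns `t_ms, value`.
#'
#' @param trials Trial table from [simulate_experiment()].
#' @param design,pop The specs that generated it.
#' @param dir Output directory (created if needed).
#' @param seed The root seed used.
#' @param traces Optional trace list from [render_traces()].
#' @return `dir`, invisibly.
#' @export
write_session <- function(trials, design, pop, dir, seed = NA,
                          traces = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(design = unclass(design), population = unclass(pop), seed = seed),
    file.path(dir, "session_meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(traces)) {
    tdir <- file.path(dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (i in seq_along(traces)) {
      for (part in c("prime", "probe")) {
        tr <- traces[[i]][[part]]
        utils::write.csv(
          data.frame(t_ms = trace_times_ms(tr), value = tr$samples),
          file.path(tdir, sprintf("%d_%d_%d_%d_%s.csv",
                                  trials$participant_id[i],
                                  trials$block_index[i],
                                  trials$trial_index[i],
                                  trials$attempt[i], part)),
          row.names = FALSE)
      }
    }
  }
  invisible(dir)
}

#' Read a trials table written by [write_session()]
#'
#' @param path Path to `trials.csv` or to the session directory.
#' @return The trial data frame.
#' @export
read_trials_csv <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "trials.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a two-column trace file as a force trace
#'
#' @param path CSV with columns `t_ms, value` at a uniform sampling rate.
#' @param channel Channel of the stored values.
#' @return A [force_trace()].
#' @export
read_trace_csv <- function(path, channel = "force_N") {
  d <- utils::read.csv(path)
  dt <- diff(d$t_ms)
  if (length(dt) == 0 || max(abs(dt - dt[1])) > 1e-9 * max(1, dt[1]))
    stop("trace file is not uniformly sampled", call. = FALSE)
  force_trace(d$value, sample_rate_hz = 1000 / dt[1], t0_ms = d$t_ms[1],
              channel = channel)
}

#' Write analysis results as JSON
#'
#' Serializes the test results (and ANOVA tables, if present) of an
#' `analysis_report` to a machine-readable `tests.json`.
#'
#' @param report An `analysis_report` from [run_analysis()] or
#'   [pooled_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tests_json <- function(report, path) {
  out <- list(
    n_participants = report$n_participants,
    alpha = report$alpha, alpha_duration = report$alpha_duration,
    tests = lapply(report$tests, unclass))
  if (!is.null(report$anova)) out$anova <- report$anova
  if (!is.null(report$screening))
    out$screening <- list(n_eligible = report$screening$n_eligible,
                          n_surviving = report$screening$n_surviving,
                          rule_log = report$screening$rule_log)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
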