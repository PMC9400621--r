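# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: plain loops and textbook formulas only.

# closed-form integral of P*sin^2(pi*t/D) over [t1, t2]
pulse_integral <- function(P, D, t1 = 0, t2 = D) {
  Fn <- function(t) P * (t / 2 - D / (4 * pi) * sin(2 * pi * t / D))
  Fn(t2) - Fn(t1)
}

# analytic threshold crossing of the sin^2 pulse: first t with F(t) = thr
pulse_crossing <- function(P, D, thr) (D / pi) * asin(sqrt(thr / P))

# brute-force detection scan: first event under the threshold + persistence
# rule, nested loops over samples
oracle_detect <- function(x, rate_hz, thr, persistence_ms) {
  k <- round(persistence_ms * rate_hz / 1000)
  n <- length(x)
  below <- x <= thr
  onset <- NA_integer_
  for (i in seq_len(n)) {
    if (!below[i]) {
      # trace start counts as satisfied history: need k below samples right
      # before i, or the run of below samples extends to the trace start
      run_start <- i
      while (run_start > 1 && below[run_start - 1]) run_start <- run_start - 1
      hist_ok <- (run_start == 1) || (i - run_start >= k)
      if (hist_ok) { onset <- i; break }
    }
  }
  if (is.na(onset)) return(NULL)
  offset <- NA_integer_
  j <- onset + 1
  while (j <= n) {
    if (below[j]) {
      run_end <- j
      while (run_end < n && below[run_end + 1]) run_end <- run_end + 1
      if (run_end - j + 1 >= k || run_end == n) { offset <- j; break }
      j <- run_end + 1
    } else j <- j + 1
  }
  if (is.na(offset)) offset <- n
  c(onset = onset, offset = offset)
}

# independent single-rule screening cascade (applied in the documented
# order, recomputing each rule from scratch on the current survivors)
oracle_screen <- function(df, mode = c("exp1", "exp2")) {
  mode <- match.arg(mode)
  grp <- function(d) paste(d$participant_id, d$condition)
  d <- df[df$outcome == "ok", ]
  has_prime_rt <- any(!is.na(d$prime_rt_ms))
  # floor
  bad <- d$probe_rt_ms < 100
  if (has_prime_rt) bad <- bad | d$prime_rt_ms < 100
  d <- d[!ifelse(is.na(bad), FALSE, bad), ]
  # ceiling
  if (mode == "exp1") {
    keep <- rep(TRUE, nrow(d))
    for (g in unique(grp(d))) {
      idx <- which(grp(d) == g)
      mu <- mean(d$probe_rt_ms[idx]); s <- sd(d$probe_rt_ms[idx])
      keep[idx] <- d$probe_rt_ms[idx] <= mu + 2.5 * s
    }
    d <- d[keep, ]
  } else {
    bad <- d$probe_rt_ms > 3000
    if (has_prime_rt) bad <- bad | d$prime_rt_ms > 3000
    d <- d[!ifelse(is.na(bad), FALSE, bad), ]
    keep <- rep(TRUE, nrow(d))
    for (g in unique(grp(d))) {
      idx <- which(grp(d) == g)
      for (col in c("probe_rt_ms", "prime_rt_ms")) {
        v <- d[[col]][idx]
        if (all(is.na(v)) || length(idx) < 2) next
        z <- (v - mean(v)) / sd(v)
        keep[idx] <- keep[idx] & (is.na(z) | abs(z) <= 2.5)
      }
    }
    d <- d[keep, ]
  }
  # duration caps, inclusive
  d <- d[d$prime_duration_ms < 600, ]
  d <- d[d$probe_duration_ms < 600, ]
  d
}

# textbook Pearson correlation, computed longhand
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# one-sample t on the differences, longhand
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# JZS BF10 by fixed-grid trapezoid quadrature on u = g / (1 + g)
oracle_jzs_bf10 <- function(t, n, r = sqrt(2) / 2, n_grid = 200000) {
  nu <- n - 1
  u <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  dens <- r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g))
  lik <- (1 + n * g)^(-0.5) * (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2)
  num <- sum((lik * dens * jac)[-1] + (lik * dens * jac)[-n_grid]) / 2 *
    (u[2] - u[1])
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# a small hand-designed trial table builder for screening tests
make_trial_row <- function(participant_id = 1, condition = "congruent",
                           prime_rt = NA, probe_rt = 300,
                           prime_dur = 150, probe_dur = 150,
                           prime_peak = 3, probe_peak = 4,
                           outcome = "ok",
                           probe_stim = 2600, probe_onset = NULL) {
  if (is.null(probe_onset))
    probe_onset <- if (is.na(probe_rt)) NA_real_ else probe_stim + probe_rt
  data.frame(participant_id = participant_id, block_index = 1,
             trial_index = 1, attempt = 1, condition = condition,
             prime_tone = "low",
             probe_tone = ifelse(condition == "catch", "none", "low"),
             prime_stim_onset_ms = NA_real_, probe_stim_onset_ms = probe_stim,
             prime_onset_ms = 2000, prime_rt_ms = prime_rt,
             prime_peak_N = prime_peak, prime_duration_ms = prime_dur,
             prime_auc_Nms = prime_peak * prime_dur / 2,
             probe_onset_ms = probe_onset, probe_rt_ms = probe_rt,
             probe_peak_N = probe_peak, probe_duration_ms = probe_dur,
             probe_auc_Nms = probe_peak * probe_dur / 2,
             outcome = outcome, stringsAsFactors = FALSE)
}

make_trials <- function(...) {
  rows <- list(...)
  d <- do.call(rbind, rows)
  d$trial_index <- seq_len(nrow(d))
  d
}
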