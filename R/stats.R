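# Similarity measures and inferential statistics: Fisher-Z prime-probe
# correlations, paired t with dz, the JZS Bayes factor, the noncentral-t
# power solver, and the 2x2 mixed ANOVA with generalized eta squared.

#' Fisher's Z transformation
#'
#' `z = atanh(r)`, the variance-stabilizing transform applied to Pearson
#' correlations before averaging or testing them.
#'
#' @param r Correlation(s) in (-1, 1).
#' @return The transformed value(s).
#' @export
fisher_z <- function(r) atanh(r)

#' Per-cell prime-probe similarity summary
#'
#' For every participant x condition cell, computes the Pearson correlation
#' between prime and probe values of one dependent variable across trials,
#' its Fisher-Z transform, the mean absolute prime-probe difference, and the
#' part means. Cells with fewer than 3 paired trials or zero variance in
#' either part yield `NA` correlations (excluded from z-based tests with a
#' warning); |r| = 1 gives an infinite `z_r`, likewise excluded from z-based
#' tests but retained for difference tests.
#'
#' @param trials Screened trial table.
#' @param dv `"auc"`, `"peak"`, `"duration"` or `"rt"`.
#' @return A data frame with one row per participant x condition:
#'   `participant_id`, `condition`, `dv`, `n_trials`, `r`, `z_r`,
#'   `mean_abs_diff`, `mean_prime`, `mean_probe`.
#' @export
prime_probe_summary <- function(trials,
                                dv = c("auc", "peak", "duration", "rt")) {
  dv <- match.arg(dv)
  cols <- switch(dv,
                 auc = c("prime_auc_Nms", "probe_auc_Nms"),
                 peak = c("prime_peak_N", "probe_peak_N"),
                 duration = c("prime_duration_ms", "probe_duration_ms"),
                 rt = c("prime_rt_ms", "probe_rt_ms"))
  key <- interaction(trials$participant_id, trials$condition, drop = TRUE)
  xs <- split(trials[[cols[1]]], key)
  ys <- split(trials[[cols[2]]], key)
  pid <- vapply(split(trials$participant_id, key), `[`, 0, 1L)
  cond <- vapply(split(trials$condition, key), `[`, "", 1L)
  stats_ <- vapply(seq_along(xs), function(i) {
    x <- xs[[i]]; y <- ys[[i]]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    r <- if (n >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0)
      stats::cor(x, y) else NA_real_
    c(n, r,
      if (n > 0) mean(abs(y - x)) else NA_real_,
      if (n > 0) mean(x) else NA_real_,
      if (n > 0) mean(y) else NA_real_)
  }, numeric(5))
  out <- data.frame(
    participant_id = pid, condition = cond, dv = dv,
    n_trials = as.integer(stats_[1, ]), r = stats_[2, ],
    z_r = fisher_z(stats_[2, ]), mean_abs_diff = stats_[3, ],
    mean_prime = stats_[4, ], mean_probe = stats_[5, ],
    stringsAsFactors = FALSE, row.names = NULL)
  if (any(is.na(out$r)))
    warning("cells with undefined correlation (n < 3 or zero variance) ",
            "excluded from z-based tests", call. = FALSE)
  if (any(is.infinite(out$z_r), na.rm = TRUE))
    warning("|r| = 1 in some cells: infinite Fisher-Z excluded from z-based ",
            "tests, retained for difference tests", call. = FALSE)
  out[order(out$participant_id, out$condition), ]
}

#' Paired t-test with effect size and Bayes factor
#'
#' Classical two-sided paired t-test, enriched with Cohen's
#' `dz = |t| / sqrt(n)` and the JZS Bayes factor ([jzs_bf10()]).
#' Participants with a non-finite value in either vector are dropped
#' pairwise.
#'
#' @param x,y Aligned participant-level vectors (e.g. congruent and
#'   incongruent Fisher-Z correlations).
#' @param cauchy_scale Prior scale for the Bayes factor.
#' @return An object of class `test_result`: `t`, `df`, `p`, `dz`, `bf10`,
#'   `n`, `mean_x`, `mean_y`.
#' @export
paired_t <- function(x, y, cauchy_scale = sqrt(2) / 2) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("zero variance of the paired differences: t undefined",
         call. = FALSE)
  tt <- stats::t.test(x, y, paired = TRUE)
  t <- unname(tt$statistic)
  structure(
    list(t = t, df = unname(tt$parameter), p = tt$p.value,
         dz = abs(t) / sqrt(n),
         bf10 = jzs_bf10(t, n, cauchy_scale = cauchy_scale),
         n = n, mean_x = mean(x), mean_y = mean(y)),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, dz = %.3f, BF10 = %.4g (n = %d)\n",
              x$df, x$t, x$p, x$dz, x$bf10, x$n))
  invisible(x)
}

#' JZS Bayes factor for a paired (one-sample) t-test
#'
#' Jeffreys-Zellner-Siow Bayes factor for the alternative over the null,
#' computed from the t statistic by numerical integration. The effect size
#' carries a zero-centered Cauchy prior with scale `cauchy_scale`, expressed
#' as the scale mixture `delta | g ~ N(0, g)`, `g ~ InverseGamma(1/2,
#' scale^2 / 2)`, and the marginal likelihood ratio is integrated over `g`
#' with adaptive quadrature (relative tolerance 1e-8).
#'
#' @param t Observed t statistic.
#' @param n Number of pairs (>= 2).
#' @param cauchy_scale Cauchy prior scale, default `sqrt(2)/2` (0.707).
#' @return The Bayes factor BF10 (alternative over null), a positive scalar.
#' @examples
#' jzs_bf10(2.67, 19)  # ~ 3.6
#' @export
jzs_bf10 <- function(t, n, cauchy_scale = sqrt(2) / 2) {
  if (n < 2 || n != round(n)) stop("n must be an integer >= 2", call. = FALSE)
  if (!is.finite(t)) stop("t must be finite", call. = FALSE)
  if (cauchy_scale <= 0) stop("cauchy_scale must be positive", call. = FALSE)
  nu <- n - 1
  r2 <- cauchy_scale^2
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  # integrand on the log scale for numerical stability at large |t|
  f <- function(g) {
    lg <- -0.5 * log1p(n * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) +
      0.5 * log(r2) - 0.5 * log(2 * pi) - 1.5 * log(g) - r2 / (2 * g) -
      log_null
    exp(lg)
  }
  q <- stats::integrate(f, 0, Inf, rel.tol = 1e-8, stop.on.error = FALSE)
  if (q$message != "OK" || !is.finite(q$value) || q$value <= 0)
    stop("JZS quadrature failed: ", q$message,
         " (t = ", t, ", n = ", n, ")", call. = FALSE)
  q$value
}

# exact power of the two-sided paired/one-sample t-test via the noncentral t;
# pt()'s benign tail-precision warnings are suppressed (we work far above
# its residual error)
paired_t_power <- function(n, d, alpha = 0.05) {
  nu <- n - 1
  tc <- stats::qt(1 - alpha / 2, nu)
  ncp <- d * sqrt(n)
  suppressWarnings(
    stats::pt(tc, nu, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tc, nu, ncp = ncp))
}

#' Solve the paired t-test power equation
#'
#' Power analysis for the two-sided paired t-test via the noncentral-t power
#' function. Exactly one of `n`, `d`, `power` must be `NULL`; it is solved
#' for. Sample-size solutions return the smallest integer `n` meeting the
#' target power; `d` and `power` are solved to 1e-6.
#'
#' @param n Number of pairs (>= 2), or `NULL`.
#' @param d Effect size dz (mean difference over SD of differences), or
#'   `NULL`.
#' @param power Target power in (0, 1), or `NULL`.
#' @param alpha Two-sided significance level.
#' @return A list with all of `n`, `d`, `power`, `alpha` filled in.
#' @examples
#' solve_power(n = 19, power = 0.80)$d        # ~ 0.68
#' solve_power(d = 0.5, power = 0.80)$n       # 34
#' solve_power(n = 53, d = 0.30)$power        # ~ 0.57
#' @export
solve_power <- function(n = NULL, d = NULL, power = NULL, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  missing_ <- c(n = is.null(n), d = is.null(d), power = is.null(power))
  if (sum(missing_) != 1L)
    stop("exactly one of n, d, power must be NULL", call. = FALSE)
  if (!is.null(power) && (power <= 0 || power >= 1))
    stop("power must be in (0, 1)", call. = FALSE)
  if (!is.null(n) && (n < 2 || n != round(n)))
    stop("n must be an integer >= 2", call. = FALSE)

  if (missing_["power"]) {
    power <- paired_t_power(n, d, alpha)
  } else if (missing_["d"]) {
    f <- function(d_) paired_t_power(n, d_, alpha) - power
    if (f(1e-8) > 0)
      stop("no solution: target power is below the type-I rate alpha",
           call. = FALSE)
    if (f(100) < 0) stop("target power unreachable at this n", call. = FALSE)
    d <- stats::uniroot(f, c(1e-8, 100), tol = 1e-9)$root
  } else {
    if (paired_t_power(2, d, alpha) >= power) {
      n <- 2L
    } else {
      hi <- 2L
      while (paired_t_power(hi, d, alpha) < power) {
        hi <- hi * 2L
        if (hi > 1e7) stop("required n exceeds 1e7", call. = FALSE)
      }
      lo <- hi %/% 2L
      while (hi - lo > 1L) {  # power is increasing in n: bisect
        mid <- (lo + hi) %/% 2L
        if (paired_t_power(mid, d, alpha) >= power) hi <- mid else lo <- mid
      }
      n <- hi
    }
  }
  list(n = n, d = d, power = power, alpha = alpha)
}

#' Bonferroni-adjusted alpha level
#'
#' @param alpha Family-wise alpha.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' 2x2 mixed ANOVA with generalized eta squared
#'
#' One between-subjects factor (two levels, e.g. experiment) crossed with one
#' within-subjects factor (two levels, e.g. trial part), subjects treated as
#' a random effect. Fit via `stats::aov` with an `Error(subject)` stratum;
#' generalized eta squared uses the additive sums-of-squares definition with
#' both factors manipulated: `ges = SS_effect / (SS_effect + SS_subjects +
#' SS_within_error)`.
#'
#' @param data Data frame with columns `subject`, `group` (between factor),
#'   `part` (within factor), `value`; one row per subject x part, complete.
#' @return A data frame with one row per effect (`group`, `part`,
#'   `group:part`): `F`, `df1`, `df2`, `p`, `ges`.
#' @export
mixed_anova_2x2 <- function(data) {
  need <- c("subject", "group", "part", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns subject, group, part, value", call. = FALSE)
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$part <- factor(data$part)
  if (!nlevels(data$group) %in% c(1L, 2L) || nlevels(data$part) != 2L)
    stop("part must have exactly 2 levels and group 2 (or 1 for the ",
         "degenerate repeated-measures case)", call. = FALSE)
  tab <- table(data$subject, data$part)
  if (any(tab != 1L))
    stop("unbalanced or missing cells: need exactly one value per ",
         "subject x part", call. = FALSE)

  if (nlevels(data$group) == 1L) {
    # degenerate single-group case: plain repeated-measures on part; its F
    # equals the squared paired t
    fit <- stats::aov(value ~ part + Error(subject), data = data)
    s <- summary(fit)
    between <- as.data.frame(s[["Error: subject"]][[1]])
    within <- as.data.frame(s[["Error: Within"]][[1]])
    rn_w <- trimws(rownames(within))
    ss_subj <- between[trimws(rownames(between)) == "Residuals", "Sum Sq"]
    i <- match("part", rn_w)
    ss_part <- within[i, "Sum Sq"]
    ss_err_w <- within[match("Residuals", rn_w), "Sum Sq"]
    return(data.frame(effect = "part",
                      F = within[i, "F value"], df1 = within[i, "Df"],
                      df2 = within[match("Residuals", rn_w), "Df"],
                      p = within[i, "Pr(>F)"],
                      ges = ss_part / (ss_part + ss_subj + ss_err_w),
                      stringsAsFactors = FALSE))
  }

  fit <- stats::aov(value ~ group * part + Error(subject), data = data)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between)); rn_w <- trimws(rownames(within))

  ss <- function(d, rn, eff) d[match(eff, rn), "Sum Sq"]
  ss_group <- ss(between, rn_b, "group")
  ss_subj <- ss(between, rn_b, "Residuals")
  ss_part <- ss(within, rn_w, "part")
  ss_int <- ss(within, rn_w, "group:part")
  ss_err_w <- ss(within, rn_w, "Residuals")
  denom_err <- ss_subj + ss_err_w

  row <- function(effect, d, rn, eff_name, ss_eff) {
    i <- match(eff_name, rn)
    data.frame(effect = effect,
               F = d[i, "F value"], df1 = d[i, "Df"],
               df2 = d[match("Residuals", rn), "Df"],
               p = d[i, "Pr(>F)"],
               ges = ss_eff / (ss_eff + denom_err),
               stringsAsFactors = FALSE)
  }
  out <- rbind(row("group", between, rn_b, "group", ss_group),
               row("part", within, rn_w, "part", ss_part),
               row("interaction", within, rn_w, "group:part", ss_int))
  rownames(out) <- NULL
  out
}

#' Effect size dz with a noncentral-t confidence interval
#'
#' Converts a paired t statistic to `dz = t / sqrt(n)` with a 95% (by
#' default) confidence interval obtained by inverting the noncentral-t
#' distribution for the noncentrality parameter.
#'
#' @param t Observed t statistic (signed).
#' @param n Number of pairs.
#' @param conf Confidence level.
#' @return A list: `dz` (signed), `lower`, `upper`.
#' @export
dz_ci <- function(t, n, conf = 0.95) {
  nu <- n - 1
  a <- (1 - conf) / 2
  bound <- function(prob) {
    # ncp such that pt(t, nu, ncp) = prob; pt is decreasing in ncp
    f <- function(ncp) suppressWarnings(stats::pt(t, nu, ncp = ncp)) - prob
    lim <- abs(t) + 20 + 10 * sqrt(n)
    if (f(-lim) < 0) return(-lim)
    if (f(lim) > 0) return(lim)
    stats::uniroot(f, c(-lim, lim), tol = 1e-8)$root
  }
  list(dz = t / sqrt(n),
       lower = bound(1 - a) / sqrt(n),
       upper = bound(a) / sqrt(n))
}
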