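---
title: "Methods: simulating and analysing pinch-force action-effect binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing pinch-force action-effect binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinchbind)
```

## The question and the design

In a prime–probe trial a participant pinches a force sensor and the pinch
produces a tone (the prime). After a fixed 600 ms stimulus-onset asynchrony a
second tone — the same pitch (congruent), the other pitch (incongruent), or
none (catch) — acts as the imperative stimulus for a second pinch (the
probe). If the metric, task-irrelevant parameters of the first pinch (peak
force, force integral, duration) are bound to the tone and retrieved when it
repeats, congruent prime–probe pairs should be more *similar* than
incongruent ones.

Similarity is quantified per participant and condition in two ways: the
Pearson correlation between prime and probe values across trials
(variance-stabilized with Fisher's Z, `atanh(r)`), and the mean absolute
prime–probe difference. Condition differences are tested with two-sided
paired t-tests, accompanied by Cohen's `dz = |t|/sqrt(n)`, a JZS Bayes factor,
and — for the exploratory duration analyses — a Bonferroni-adjusted
`alpha = .025`.

## The generative model of the simulator

The simulator exists so that every pipeline stage can be exercised, and its
error rates calibrated, without any raw data. Per participant `i` it draws a
mean peak force and mean duration

\[ \mu^{peak}_i \sim N(3.6, 1.2^2)\ \mathrm{N}, \qquad
   \mu^{dur}_i \sim N(200, 45^2)\ \mathrm{ms}, \]

and per trial a prime pinch scattered around them (within-participant SDs
1.0 N and 30 ms). The probe pinch reproduces a fraction λ of the prime's
deviation from the participant mean — the *retrieval strength*:

\[ \mathrm{probe} = \mu_i + \lambda_{cond}\,(\mathrm{prime} - \mu_i) +
   \varepsilon, \]

with fresh within-participant noise ε. The congruent–incongruent difference
in λ is the planted binding effect; `lambda_congruent = lambda_incongruent`
(default 0.5) is the null regime in which the two conditions are
exchangeable by construction. Under this linear-retrieval model the expected
prime–probe correlation increases monotonically in λ, which is what the
recovery grid verifies by simulation.

Probe pinches are additionally more forceful than primes (speeded reactions
vs self-initiated actions): each participant receives a probe peak-force
boost drawn once from `N(1.2, 1.2^2)` N. Drawing the boost per participant
rather than as a constant matters: a constant offset would cancel from the
participant-level SD and make the prime-vs-probe contrast essentially
noise-free (dz ≈ 10), unlike any real sample (dz ≈ 0.7–1.1 is typical).
Probe RTs are lognormal (median 310 ms, log-scale SD 0.3) with a 16 ms mean
advantage on congruent trials; misses (1.9%), premature pinches (0.8%) and
trial restarts (8%) occur at the quoted rates, and restarted trials repeat
with the same condition (an assumption — counterbalancing after restarts is
not specified anywhere).

Trial schedules honour the design presets exactly — `exp1`: 7 × 30 trials,
12/12/6 congruent/incongruent/catch, 300 ms tones, self-initiated prime;
`exp2`: 9 × 40, 10/10/20, 150 ms tones, auditory go signal, probe effect
tone — including the constraint that the first two trials of a block are
never catch trials. The 6 ms hardware tone delay is carried as metadata
only; RT is defined stimulus onset → pinch onset throughout.

### Traces vs features

The generator's ground truth is the feature triple (peak, duration, RT).
Traces are *rendered from* those features on demand as raised-sine-squared
pulses, `F(t) = P sin²(πt/D)`, plus Gaussian sensor noise (SD 0.02 N,
clipped at zero). This pulse shape was chosen because its peak, integral
(`PD/2`) and threshold-crossing times are closed-form, giving the detection
and feature stages analytic oracles. Monte-Carlo loops (2000 simulated
studies for calibration) run on the features directly; rendering megabytes
of 1000 Hz signal only to re-detect noiseless-by-construction pulses would
test nothing the dedicated trace-path tests do not already establish. What
the feature-level shortcut does *not* exercise per repetition is the
detector itself — its fidelity is covered separately by the analytic-oracle
and trace-recovery tests.

What the simulator deliberately does not emulate: drifting sensor baselines,
asymmetric or multi-peaked real pinches, online 200 Hz filtering (synthetic
pulses are band-limited by construction; a no-op hook exists for real data),
fatigue or learning trends across blocks, and tone-frequency-specific
effects. A calibrated pipeline on these data therefore shows the *method* is
sound, not that any particular empirical effect exists.

## Signal processing

The FSR voltage–force calibration is exponential, `F = a·exp(bV)`; the
constants are device-specific and unreported in typical setups, so the
defaults `a = 0.05` N, `b = 1.5` per volt are package configuration, stored
with every analysis, and the encoder is the exact inverse (round trip below
1e-9 N above the representable floor).

Pinch detection uses a threshold of 0.32 N with a 10 ms persistence
requirement on both sides: onset is the first sample strictly above
threshold preceded by ≥ 10 ms of consecutive at/below-threshold samples,
offset the first subsequent at/below sample followed by ≥ 10 ms at/below.
Two readings of the rule were fixed once and are config-overridable:
"exceeds" is strict (`>`), "stays under" is inclusive (`<=`); and trace
boundaries count as satisfied persistence (otherwise events at the edges of
a trial window could never be detected — trial windows begin at rest).
A sub-persistence dip does not terminate an event, so closely spaced pulses
merge; only the first qualifying event per window is used, later ones are
counted in a quality flag. AUC is the trapezoid integral of raw force
between the detected bounds, in N·ms (at 1000 Hz the discretization error on
the test pulses is well under 0.5%); integrating threshold-clipped force
would be the alternative reading, noted and not taken.

## Screening

Outcome classification precedes screening: premature probe pinches (inside
the SOA) are false alarms, absent-or-late probe pinches (beyond the 1200 ms
response window) are misses, any pinch on a catch trial is an error. Only
`ok` trials enter the cascade; catch and error trials pass through untouched
for error-rate reporting. One tension is resolved by the window-first
convention: an absolute 3 s RT ceiling coexisting with a 1200 ms miss window
can only ever apply to responses already classified by the window, so the
ceiling never resurrects a miss.

The cascade order is fixed (and a test locks it by exhibiting a fixture
where swapping two stages changes the outcome): RT floor (100 ms) → RT
ceiling → prime-duration cap → probe-duration cap, with the 600 ms caps
inclusive. The ceiling is mean + 2.5 SD within participant × condition
(exp1 preset) or an absolute 3 s followed by |z| > 2.5 (exp2 preset). All
mean/SD-based rules are single-pass — statistics are computed over the
trials still eligible at that stage and not re-iterated after removal, since
no iteration rule is specified anywhere — with the sample (n−1) SD, grouped
per participant × condition (the exp2-style z rule's grouping is ambiguous
in common usage; per-cell matches the explicit exp1 statement, and a
per-participant switch would be a one-line change). The per-DV |z| > 2.5
rejection runs separately for each analysis, so the force analyses and the
duration analyses see different survivor sets by design. Cells with fewer
than two trials skip z-rules with a warning (the SD is undefined).

## Inference

`paired_t()` wraps the classical two-sided paired t-test and enriches it
with `dz = |t|/sqrt(n)` and the JZS Bayes factor. The Bayes factor is
computed from `t` and `n` (computing it from raw data is the other
convention; from-t reproduces standard package output to within the rounding
of printed t values, so it is the implemented contract): the effect size has
a zero-centred Cauchy prior with scale 0.707, expressed as the normal
scale-mixture `delta|g ~ N(0, g)`, `g ~ InvGamma(1/2, r²/2)`, and the
marginal likelihood ratio is integrated over `g` by adaptive quadrature on
the log-scale integrand (relative tolerance 1e-8). Cells with |r| = 1 have
infinite Fisher-Z and are excluded from z-based tests rather than clamped
(a clamp would manufacture data; such cells are retained for difference
tests).

The power solver uses the exact noncentral-t power function of the two-sided
paired t-test (both rejection tails, which `stats::power.t.test` drops — the
difference is ~2e-5 at these parameters); sample-size solutions are the
smallest integer meeting the target (bisection on the integer power curve),
`d` and `power` solve to 1e-6. The 2×2 mixed ANOVA is fitted with
`stats::aov` and `Error(subject)` strata; generalized eta squared uses the
additive-SS definition with both factors manipulated,
`ges = SS_effect / (SS_effect + SS_subjects + SS_within-error)`. Effect-size
confidence intervals invert the noncentral-t distribution for the
noncentrality parameter and divide by `sqrt(n)`.

```{r}
solve_power(n = 19, power = 0.80)$d      # smallest detectable dz
solve_power(d = 0.5, power = 0.80)$n     # required sample size
jzs_bf10(2.67, 19)                        # duration-correlation BF
```

## Calibration and problem sizes

Because the null regime is exchangeable, the duration-correlation congruency
test must reject at the nominal rate. The acceptance suite verifies 5% ±
1.5 pp over 2000 simulated 19-participant studies (binomial MC SE at p=.05,
2000 reps is ~0.5 pp) and monotone power over the retrieval-strength grid
λ_congruent ∈ {0.3, 0.4, 0.5, 0.7} against λ_incongruent = 0.3 at 200
reps/point. These sizes put the Monte-Carlo error comfortably below the
tolerances while keeping the whole suite to a few minutes; the analysis
drivers under `analysis/` use 100–200 reps for the same reason. The pooled
analysis concatenates participant-level summaries across the two simulated
experiments (N = 53) despite their different designs, with a warning noting
the heterogeneity — mirroring how combined analyses of such pairs of
experiments are actually done.

## Known limitations

- The linear retrieval model is the simplest mechanism producing
  condition-dependent prime–probe correlations; it is a modelling choice,
  not an empirical claim, and real binding need not be linear in the prime
  deviation.
- Detected duration is the supra-threshold span, systematically shorter than
  the full pulse (by `2(D/π)asin(sqrt(thr/P))`); correlations with ground
  truth stay above 0.95, so similarity analyses are unaffected, but absolute
  duration means are not comparable across thresholds.
- The per-DV z-rejection convention (per analysis, per cell, single pass)
  is one of several defensible readings; all of them are config-reachable
  but only the default is calibrated here.
- RT screening applies the floor to prime and probe RT whenever a go signal
  provides a prime RT, and the ceiling rules to both; designs without a go
  signal have no prime RT at all.
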