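#!/usr/bin/env Rscript
# Apply the trial-rejection cascade to both simulated sessions and report
# the per-rule counts: RT floor (100 ms), RT ceiling (mean + 2.5 SD for the
# exp1 preset; absolute 3 s then |z| > 2.5 for exp2), and the inclusive
# 600 ms duration caps. Writes results/screening/<exp>_report.json and the
# surviving trials.

suppressPackageStartupMessages({library(pinchbind); library(jsonlite)})

dir.create("results/screening", recursive = TRUE, showWarnings = FALSE)

for (exp in c("exp1", "exp2")) {
  trials <- read_trials_csv(file.path("results/sim", exp))
  scr <- screen(trials, screening_preset(exp))
  cat("==", exp, "==\n")
  print(scr$report)
  per_ppt <- table(scr$trials$participant_id, scr$trials$condition)
  cat("mean remaining trials per participant:",
      round(mean(per_ppt[, "congruent"]), 1), "congruent,",
      round(mean(per_ppt[, "incongruent"]), 1), "incongruent\n\n")
  write.csv(scr$trials, sprintf("results/screening/%s_survivors.csv", exp),
            row.names = FALSE)
  # per-DV z-screened survivor sets (each analysis sees its own)
  for (dv in c("auc", "peak", "duration", "rt")) {
    dvs <- screen_dv(scr$trials, dv)
    cat(sprintf("  per-DV z (%s): %d -> %d trials\n",
                dv, nrow(scr$trials), nrow(dvs)))
    write.csv(dvs, sprintf("results/screening/%s_screened_%s.csv", exp, dv),
              row.names = FALSE)
  }
  write_json(list(rule_log = scr$report$rule_log,
                  n_eligible = scr$report$n_eligible,
                  n_surviving = scr$report$n_surviving,
                  per_condition = scr$report$per_condition),
             sprintf("results/screening/%s_report.json", exp),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
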