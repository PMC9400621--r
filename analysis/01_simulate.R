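#!/usr/bin/env Rscript
# Simulate the two study-style sessions: a 19-participant session with
# self-initiated primes (exp1 preset) and a 34-participant session with an
# auditory go signal and 50% catch trials (exp2 preset). Both use the null
# retrieval regime (lambda_congruent = lambda_incongruent = 0.5) so the
# downstream congruency tests should find nothing — the planted-effect runs
# live in 05_recover.R. Writes results/sim/<exp>/trials.csv + metadata, and
# rendered force traces for one demonstration participant.

suppressPackageStartupMessages(library(pinchbind))

seed <- 20260927
out <- "results/sim"

for (exp in c("exp1", "exp2")) {
  design <- design_preset(exp)
  pop <- population_spec(n_participants = if (exp == "exp1") 19 else 34)
  trials <- simulate_experiment(design, pop, seed = seed)
  dir <- file.path(out, exp)
  write_session(trials, design, pop, dir, seed = seed)
  cat(sprintf("%s: %d trial rows, %d participants -> %s\n",
              exp, nrow(trials), pop$n_participants, dir))
  print(table(trials$outcome))
}

# rendered 1000 Hz traces for participant 1 of exp1 (demonstration subset)
design <- design_preset("exp1")
pop <- population_spec(n_participants = 19)
p1 <- generate_session(design, pop, participant_id = 1, seed = seed)
p1 <- p1[p1$block_index == 1, ]
traces <- render_traces(p1, pop, seed = seed)
write_session(p1, design, pop, file.path(out, "exp1_p1_block1"),
              seed = seed, traces = traces)
cat("rendered", 2 * nrow(p1), "traces for participant 1, block 1\n")
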