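#!/usr/bin/env Rscript
# Simulate a complete exome-screen scenario: reference genome with gene
# models, mutant and background variant call sets, known-variant panels, a
# truth table and validation genotypes. Everything downstream (02-04) runs
# off the files this writes under results/scenario/.

library(enufunnel)

seed <- 20260922L
dir.create("results", showWarnings = FALSE)

sc <- simulate_scenario(scenario_config(seed = seed))
write_scenario(sc, "results/scenario")
write_cohort(generate_cohort(cohort_config(seed = seed)),
             "results/scenario/cohort.tsv", seed = seed)

cat("Scenario written to results/scenario (seed", seed, ")\n")
cat("  mutant calls:    ", nrow(sc$mutant), "\n")
cat("  background calls:", nrow(sc$background), "\n")
cat("  panels:          ", length(sc$panels), "(",
    paste(vapply(sc$panels, nrow, 1L), collapse = ", "), "entries )\n")
cat("  truth labels:\n")
print(table(sc$truth$label))
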