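#!/usr/bin/env Rscript
# Segregation and penetrance: cross tables, penetrance with Wilson CIs,
# homozygote-deficit and Mendelian-ratio tests -- on the published cohort
# counts and on the simulated cohort from 01.

library(enufunnel)

dir.create("results/segregation", showWarnings = FALSE, recursive = TRUE)
out <- function(df, f) utils::write.table(
  df, file.path("results/segregation", f), sep = "\t", quote = FALSE,
  row.names = FALSE)

co <- dearisch_cohort()
hh <- build_cross_table(co, "het_x_het")
hw <- build_cross_table(co, "het_x_wt")
cat("published cohort:\n"); print(hh); print(hw)

strict <- penetrance(co)
broad <- penetrance(co, affected_classes = c("affected", "intermediate"))
print(strict); print(broad)

p_hom <- homozygote_deficit_test(hh$n, sum(hh$counts["hom", ]))
p_mendel <- mendelian_ratio_test(unname(rowSums(hh$counts)), c(1, 2, 1))
p_outcross <- mendelian_ratio_test(unname(rowSums(hw$counts))[1:2], c(1, 1))
cat(sprintf("homozygote deficit (0 hom / %d): p = %.3g\n", hh$n, p_hom))
cat(sprintf("1:2:1 goodness of fit, intercross: p = %.3g\n", p_mendel))
cat(sprintf("1:1 wt:het split, outcross: p = %.3g\n", p_outcross))

out(data.frame(cross = c("het_x_het", "het_x_wt"),
               rbind(hh$row_totals, hw$row_totals),
               n = c(hh$n, hw$n)), "cross_totals.tsv")
out(data.frame(
  estimate = c("affected_only", "affected_or_intermediate"),
  numerator = c(strict$numerator, broad$numerator),
  denominator = c(strict$denominator, broad$denominator),
  proportion = c(strict$proportion, broad$proportion),
  ci_lower = c(strict$conf_int[1], broad$conf_int[1]),
  ci_upper = c(strict$conf_int[2], broad$conf_int[2])), "penetrance.tsv")
out(data.frame(test = c("homozygote_deficit", "mendelian_1_2_1",
                        "outcross_1_1"),
               p_value = c(p_hom, p_mendel, p_outcross)), "tests.tsv")

## simulated cohort (from 01): same analyses on generated data
sim <- read_cohort("results/scenario/cohort.tsv")
sim_hh <- build_cross_table(sim, "het_x_het")
cat("\nsimulated cohort (seed 20260922):\n"); print(sim_hh)
print(penetrance(sim))
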