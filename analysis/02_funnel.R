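#!/usr/bin/env Rscript
# Run the variant filtration funnel on the simulated scenario (01) and on the
# curated 23-candidate table from the dearisch study, writing survivor counts
# and adjudicated candidate tables under results/.

library(enufunnel)

dir.create("results/funnel", showWarnings = FALSE, recursive = TRUE)

## synthetic scenario, end to end from the files 01 wrote
models <- read_gene_models("results/scenario/genes.gff3",
                           "results/scenario/reference.fa")
rep <- run_funnel("results/scenario/mutant.vcf",
                  "results/scenario/background.vcf",
                  list("results/scenario/panel_1.vcf",
                       "results/scenario/panel_2.vcf"),
                  models,
                  validation = "results/scenario/validation.tsv")
print(rep)
write_funnel_report(rep, "results/funnel")

truth <- utils::read.delim("results/scenario/truth.tsv", comment.char = "#",
                           colClasses = c(chrom = "character"))
causal_key <- with(truth[truth$label == "causal", ],
                   paste(chrom, pos, alt, sep = ":"))
cat("\nplanted causal call:", causal_key, "\n")
cat("confirmed:", variant_key(rep$confirmed),
    if (identical(variant_key(rep$confirmed), causal_key))
      "(exactly the planted mutation)\n" else "(MISMATCH)\n")

## the published 23-candidate table with its capillary validation columns
adj <- confirm_with_validation(dearisch_candidates(), dearisch_validation())
utils::write.table(as.data.frame(adj), "results/funnel/dearisch_candidates.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\ndearisch candidates:", nrow(adj),
    "| heterozygous:", count_heterozygous(adj),
    "| confirmed:", sum(adj$confirmed),
    paste0("(", adj$gene[adj$confirmed], " ",
           variant_key(adj[adj$confirmed, ]), ")"), "\n")
cat("false-positive reasons:\n")
print(table(adj$reason[!adj$confirmed]))
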