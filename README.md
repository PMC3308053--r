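# enufunnel

Causal-variant prioritization and segregation analysis for ENU-mutagenized
mouse lines, in R.

ENU screens produce mutants whose phenotype may be too weakly penetrant for
backcross linkage mapping. The alternative is to exome-sequence one mutant and
one un-mutagenized background-strain animal and push the called variants
through a **filtration funnel**:

```
calls different from the reference genome
  → remove calls shared with the background strain
  → remove known polymorphisms (dbSNP-like panels, inbred-strain catalogues)
  → SNP quality ≥ 20
  → mapping quality > 45 and read depth > 10
  → remove intronic and intergenic calls
  → keep stop-gained/lost, nonsynonymous and essential-splice-site SNVs
  → confirm against validation (capillary) re-sequencing
```

`enufunnel` implements the funnel with per-step survivor accounting, plus
everything needed to interpret what comes out of it:

* **Codon-aware consequence annotation** against GFF3 gene models + FASTA
  (strand-aware codon extraction and translation; frameshift/in-frame/stop
  logic for indels; essential splice site = first or last two bases of an
  intron).
* **Indel-proximity flagging** of candidates — the dominant false-positive
  mode is SNVs miscalled around small indels.
* **Validation adjudication**: a candidate is confirmed iff the mutant's
  validation call carries the alternate allele and the background's does not;
  rejections get a reason code.
* **Linkage exclusion**: enumerate and classify every other private call on
  the candidate chromosome, inside and outside a ±10 Mb physical window.
* **Segregation statistics**: threshold-based hearing classification
  (affected ≥ 50 dB SPL, unaffected ≤ 30 dB SPL), genotype × class cross
  tables, penetrance with Wilson 95% intervals, the exact binomial
  homozygote-deficit test P(X ≤ k | n, ¼), and an exact multinomial
  Mendelian-ratio test.
* A **seeded simulator** that generates reference + gene models, variant
  scenarios with planted causal mutations and truth tables, validation
  genotypes, and genotype–phenotype cohorts with bimodal thresholds — so the
  whole pipeline is testable end to end without any sequencing data.

The package ships the curated end-of-funnel tables of the *dearisch* otitis
media mutant (`Isl1` Y71C, chromosome 13:117098488 T→C) as desk-scale real
data: the 23 candidate SNVs with their capillary validation calls, and the
colony's cross counts.

## Worked example

Simulate a scenario, run the funnel, and check the planted mutation is the
one call that survives:

```r
library(enufunnel)

sc  <- simulate_scenario(scenario_config(seed = 42))
rep <- run_funnel(sc$mutant, sc$background, sc$panels, sc$models,
                  validation = sc$validation)
rep
#> Variant filtration funnel
#>   different_from_reference          465
#>   not_shared_with_background        165
#>   not_in_known_panels               125
#>   snp_quality_filter                 99
#>   mapping_quality_and_depth          65
#>   remove_intronic_intergenic         25
#>   select_stop_nonsyn_splice           7
#>   confirmed_by_validation             1
#> 3 indel(s) in side channel; 6 candidate(s) flagged indel-proximal

rep$confirmed[, c("chrom", "pos", "ref", "alt", "genotype", "category", "detail")]
#>   chrom   pos ref alt genotype      category detail
#> 6  chr1 11729   T   C      het nonsynonymous    Y:C
```

465 simulated mutant calls funnel down to 7 candidates (the planted causal
call plus 6 indel-proximal artifacts, all flagged); validation rejects the
artifacts and confirms exactly the planted heterozygous Tyr→Cys missense
change.

The same machinery on the real 23-candidate table:

```r
adj <- confirm_with_validation(dearisch_candidates(), dearisch_validation())
sum(adj$confirmed)                                   #> 1
adj$gene[adj$confirmed]                              #> "Isl1"
count_heterozygous(adj)                              #> 14
count_candidates_on_chromosome(adj, "13")            #> 1

co <- dearisch_cohort()
penetrance(co)
#> Penetrance (affected): 28/121 = 23.1% (Wilson 95% CI 16.5-31.4%)
penetrance(co, affected_classes = c("affected", "intermediate"))
#> Penetrance (affected+intermediate): 62/121 = 51.2% (Wilson 95% CI 42.4-60.0%)
homozygote_deficit_test(111, 0)
#> [1] 1.354566e-14
```

So one of the 23 candidates is confirmed (the chromosome-13 `Isl1` het), the
phenotype is 23% penetrant in carriers (51% counting mildly affected
animals), and the complete absence of homozygotes among 111 intercross
offspring is incompatible with Mendelian homozygote viability.

## Analysis scripts

`analysis/01_simulate.R` … `04_segregation.R` are thin numbered drivers that
run the full story — simulate a scenario, funnel it, exclude linkage on a
replica chromosome, analyze segregation — and write their tables under
`results/`. Run them in order from the repository root with `Rscript`.

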