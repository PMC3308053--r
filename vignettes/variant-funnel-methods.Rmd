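---
title: "Prioritizing induced causal variants without linkage mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing induced causal variants without linkage mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enufunnel)
```

## The problem

Forward-genetics screens in the mouse expose males to the point mutagen ENU
and look for heritable phenotypes in their descendants. When a phenotype is
fully penetrant, the causal mutation is traditionally located by backcross
linkage mapping. With low penetrance that route collapses — too few affected
backcross animals — and one is left with exome sequencing of a single mutant
against its un-mutagenized background strain, followed by a *filtration
funnel* that whittles millions of called differences down to a handful of
candidates. `enufunnel` implements that funnel and the statistics that come
after it: consequence annotation, validation adjudication, physical linkage
exclusion, and segregation/penetrance analysis. The motivating use case is a
partially penetrant, dominant, middle-ear disease (otitis media) phenotype on
a C3HeB/FeJ background whose causal lesion is a heterozygous Tyr→Cys missense
change in *Isl1*; the package's curated tables (`dearisch_candidates()`,
`dearisch_cross_counts()`) carry that study's end-of-funnel data so the final
steps are reproducible on real numbers.

## The funnel

`run_funnel()` executes, in order, with survivor counts recorded after each
step:

1. **Load** the mutant and background call sets (VCF; `QUAL` = SNP quality,
   INFO `CQ`/`MQ`/`DP` = consensus quality, RMS mapping quality, read depth).
2. **Background subtraction** — drop every mutant call whose
   (chromosome, position, alternate allele) key occurs in the background
   strain. Shared calls are strain-vs-reference differences, not induced
   mutations. Matching is by position + allele; a position-only mode exists
   (`by_position = TRUE`) because the original analyses do not always state
   which convention they used.
3. **Known-variant subtraction** — drop calls found in any panel of known
   polymorphisms (dbSNP-like catalogues, inbred-strain resequencing).
4. **Quality stage A** — keep calls with SNP quality ≥ 20 (inclusive: the
   published rule is a "lower limit"). This stands in for the caller's
   composite quality filter; any further caller-internal heuristics of the
   original tooling are deliberately not reproduced, which is why full-scale
   survivor counts are not a reproduction target.
5. **Quality stage B** — keep calls with mapping quality > 45 **and** read
   depth > 10 (strict, following the published `>` operators). Consensus
   quality is never filtered on — in the motivating study it was kept for
   diagnosis only, because false positives were preferred to false
   negatives — but it is carried through for reporting.
6. **Annotation + noncoding removal** — classify every surviving call
   against the gene models and drop intronic and intergenic calls.
   Essential-splice-site calls survive despite intronic coordinates.
7. **Candidate selection** — keep SNVs that gain/lose a stop, change an
   amino acid, or hit an essential splice site. Indels are excluded here but
   preserved in a side channel: they feed linkage exclusion and
   indel-proximity flagging.
8. **Validation adjudication** (optional) — see below.

Unknown quality metrics fail their stage *closed* (treated as below
threshold); `quality_thresholds(fail_open = TRUE)` flips this. The
conservative default means a call with a missing depth field cannot sneak
through the depth filter.

### Consequence annotation

Annotation is codon-aware and transcript-oriented. For a coding SNV the codon
is located through the CDS coordinate map (exon-junction-spanning codons
included), read in transcript orientation (reverse-complemented on minus
strands), mutated, and translated under the standard nuclear code; the result
is `synonymous`, `nonsynonymous`, `stop_gained` or `stop_lost` with an
amino-acid detail such as `Y:C` and a 1-based residue index. Stop-retaining
changes at the stop codon count as synonymous. Coding indels are `frameshift`
when the allele-length difference is not a multiple of 3 (or when a deletion
removes a non-multiple-of-3 number of coding bases across a boundary);
in-frame indels are checked by rebuilding the mutant CDS — if a premature
in-frame stop appears the call is `stop_gained`, otherwise `inframe_indel`.
Translation is literal (`no.init.codon`): the first codon is not given
initiator-codon privileges.

An *essential splice site* is the first or last two bases of any intron, UTR
introns included, and outranks `intronic`. Exonic positions of noncoding
transcripts are `noncoding_transcript` — including noncoding biotypes that a
study might nonetheless have translated (e.g. pseudogene ORFs); where a
published table reports an amino-acid change for a pseudogene, this package
will disagree by design. Positions outside every transcript are `intergenic`.

When transcripts overlap, one consequence is reported per variant: the most
severe under a fixed total order (`severity_rank()`), ties broken by
lexicographic transcript id. The order — stop gain/loss and frameshift, then
essential splice, then nonsynonymous, in-frame indel, synonymous, UTRs,
noncoding, intronic, intergenic — is this package's own convention; the
source analyses only partition "selected" vs "not selected", so any total
order consistent with that partition would reproduce the same funnel. Fixing
one makes reports deterministic.

### Artifact flagging and validation

The dominant false-positive mode at the bottom of a funnel is misalignment
around small indels: the caller misreads SNVs on either side of the event.
`flag_indel_proximal()` flags any candidate within 20 bp (default) of an
indel call from either sample's raw calls. Flagging is advisory — candidates
are not removed, mirroring the original practice of resolving them by
re-sequencing rather than by filtering.

`confirm_with_validation()` adjudicates candidates against capillary-style
re-sequencing calls of both samples. A candidate is confirmed iff the mutant
trace contains the alternate allele, the background trace does not, and
neither trace is an indel or missing. Rejections carry a reason:
`indel_misalignment`, `missing_data`, `identical_to_background`,
`miscalled_zygosity` (checked in that order; an indel trace explains the
false call even when the other trace is missing or identical). Heterozygous
genotype strings are order-normalized (`C/T` ≡ `T/C`). Homozygous candidates
are retained all the way through selection even under a dominant model — the
het count (`count_heterozygous()`) informs reporting, never filtering.

## Linkage exclusion

A confirmed candidate could still be a linked marker rather than the lesion
itself. `build_linkage_report()` enumerates every other private call on the
candidate's chromosome, annotates it, and splits entries at an absolute
physical distance of 10 Mb (default) from the candidate — a full two-sided
closed interval, since linked lesions can sit on either side. Coding entries
(exonic stop/frameshift/nonsynonymous/in-frame changes) are flagged as the
only plausible alternative lesions; splice-site indels are reported with the
sub-label "Splice site (intronic)". Distance is physical (bp), not genetic
(cM) — at 10 Mb the difference does not change any in/out call in practice,
and the source analysis used physical distance.

## Segregation and penetrance

Hearing classification is threshold-based: *affected* at a click threshold of
50 dB SPL or over, *unaffected* at 30 dB SPL or below, *intermediate* in the
open interval between — the interval is open because both endpoints are
claimed by the neighboring classes, so the three classes partition the axis.
`build_cross_table()` tabulates a cross by genotype × class with exact
percentages (display rounds to one decimal, which is how the published
margins 64.9%, 57.6% arise from 72/111 and 49/85).

`penetrance()` is a binomial proportion over carriers with a Wilson score
95% interval. Wilson was chosen over Wald (poor small-sample behavior) and
Clopper–Pearson (overly conservative) because colony denominators are small
(~121) and the source reports no interval of its own. The pooled denominator
includes heterozygotes from both cross types — with the published counts,
28/121 = 23.1% strictly affected and 62/121 = 51.2% including mild cases,
matching both published figures, which is itself the evidence that the
original percentages were pooled.

`homozygote_deficit_test()` is the one-sided exact binomial tail
P(X ≤ observed homozygotes) under the Mendelian expectation (1/4 for an
intercross): with 0 of 111, p = 0.75^111 ≈ 1.4 × 10⁻¹⁴.
`mendelian_ratio_test()` is an exact multinomial test (total probability of
all outcomes no more probable than the observed one) for totals up to 200,
switching to the chi-square goodness-of-fit statistic above that; the
switch point keeps exact enumeration comfortably cheap at colony scales
while remaining exact wherever the counts are small enough for the
chi-square approximation to be questionable.

## The simulator

Because the raw sequencing data are not required (and their full-scale
reprocessing is out of scope), every pipeline stage is exercised on seeded
synthetic data with truth tables.

`generate_reference_and_genes()` builds random chromosomes carrying
non-overlapping multi-exon genes on both strands; every CDS is a clean ORF
(ATG, no internal stop, terminal stop, length a multiple of 3) and contains
at least one tyrosine codon so a Tyr→Cys lesion can always be planted.
`generate_variant_scenario()` plants, per the configured counts: a stratum of
calls shared with the background strain, known-panel hits, low-quality calls
(each failing exactly one of the three thresholds), good-quality noncoding
and synonymous calls, small deletions flanked by nonsynonymous artifact SNVs
within 10 bp (the misalignment mode), and one heterozygous causal missense
SNV whose metrics default to the profile of a genuine call that survives
every filter (consensus 199, SNP quality 228, mapping quality 60, depth 66).
The causal site is disjoint from the shared and panel strata *by
construction*: panel subtraction can never remove it, which is a property of
real ENU lesions (novel mutations are not catalogued polymorphisms), not an
artificial protection. Default stratum sizes (300 shared, 40 panel, 60
low-quality, 40 noncoding, 15 synonymous, 3 clusters) are desk-scale choices
that preserve the *shape* of a real funnel — each stage removes a visible
stratum — not its multi-million-call magnitudes.

`generate_cohort()` draws genotypes per cross among viable offspring
(1:2:1 intercross prior with homozygote survival probability 0 by default;
1:1 outcross) and genotype-dependent click thresholds: unaffected
~ Normal(22, 4) truncated to [0, 30] dB SPL, affected ~ Normal(65, 9)
truncated to [50, 97], intermediate ~ Uniform(31, 49), with het class
probabilities 23.1% affected / 28.1% intermediate and a 4% wild-type leak
into the intermediate band. Cross sizes (111, 85), class probabilities and
the leak reproduce the observed colony conditions; the distribution *shapes*
and their parameters are simulator choices constrained only by the observed
bimodality (normal hearing near 15–30 dB SPL, impaired 50–80 dB SPL) and are
config values, not code. Thresholds are rounded to whole dB.

All randomness flows from a single integer seed; generators are deterministic
per seed and every emitted file records its seed in a header line.

### What the simulator does not emulate

No read-level error model (no FASTQ/BAM), no genome-wide mutation-rate
model, no linkage disequilibrium between noise calls, no multi-sample VCF
semantics, and gene models are simpler than real annotation (no overlapping
genes, no alternative isoforms by default). Passing the planted-recovery
property therefore demonstrates the *logic* of the funnel — subtraction
soundness, threshold boundary semantics, annotation correctness,
adjudication — on data whose truth is known; it does not measure sensitivity
on real alignments, where artifact structure is richer.

## Numerical and design notes

* Coordinates are 1-based inclusive throughout; indels are VCF-anchored on
  the base before the event, and `variant_class` is derived from allele
  lengths. Same-length multi-base substitutions are rejected.
* Subtraction keys are `(chrom, pos, alt)`; genotype and qualities never
  enter a key. A het call whose listed alleles exclude the reference base
  yields one call per alternate allele, each keyed separately.
* Boundary semantics: SNP quality ≥ 20; mapping quality > 45; read depth
  > 10. The tests pin all six boundary cases (19/20, 45/46, 10/11).
* The exact multinomial test compares outcome probabilities with a relative
  tolerance of 10⁻⁷ so ties at the observed probability (including the
  exactly proportional outcome, p = 1) are not lost to floating-point noise.
* Degenerate inputs: empty call sets flow through every stage and yield
  all-zero reports; a cohort with zero carriers raises an explicit
  undefined-penetrance error rather than returning NaN.
* Problem sizes used by the test-suite properties and the acceptance script:
  100 seeded scenarios (three 300-kb chromosomes, 18 genes, ~465 mutant
  calls each) for planted recovery, ≥1000 random SNVs for oracle
  equivalence, 1000 simulated 121-carrier cohorts for CI coverage, and one
  11.3-Mb replica chromosome for linkage exclusion. These sizes give stable
  0/100%-type outcomes and tight Monte-Carlo error at desk scale.

## Known limitations

* Stage A is exactly the SNP-quality rule; composite caller heuristics are
  not reproduced, so full-scale intermediate counts from historical runs are
  not comparable at that step.
* Splice classification is positional (first/last two intron bases); there
  is no splice-strength scoring.
* Pseudogene/noncoding ORFs are never translated (see above).
* The simulator's homozygote thresholds (when `hom_viability > 0`) reuse the
  affected distribution; the motivating phenotype has no surviving
  homozygotes to calibrate against.
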