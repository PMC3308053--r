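test_that("genome generation is deterministic per seed and yields clean ORFs", {
  cfg <- scenario_config(seed = 21, n_genes = 6, n_noncoding_genes = 2)
  m1 <- generate_reference_and_genes(cfg)
  m2 <- generate_reference_and_genes(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_gene_models(m1, file.path(d1, "g.gff3"), file.path(d1, "r.fa"))
  write_gene_models(m2, file.path(d2, "g.gff3"), file.path(d2, "r.fa"))
  expect_identical(readLines(file.path(d1, "g.gff3")),
                   readLines(file.path(d2, "g.gff3")))
  expect_identical(readLines(file.path(d1, "r.fa")),
                   readLines(file.path(d2, "r.fa")))
  # a different seed changes the genome
  m3 <- generate_reference_and_genes(scenario_config(seed = 22, n_genes = 6,
                                                     n_noncoding_genes = 2))
  expect_false(identical(as.character(m1$reference[[1]]),
                         as.character(m3$reference[[1]])))
  # every coding transcript: starts ATG, single terminal stop, length %% 3 == 0
  for (tx in m1$transcripts) {
    if (tx$biotype != "protein_coding") next
    cds <- enufunnel:::cds_sequence(tx, m1$reference)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    prot <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds), no.init.codon = TRUE)), "")[[1]]
    expect_equal(which(prot == "*"), length(prot))
    expect_true("Y" %in% prot)       # guaranteed tyrosine for causal planting
  }
})

test_that("gene-free and infeasible configurations behave as specified", {
  cfg <- scenario_config(seed = 1, n_genes = 0, n_noncoding_genes = 0)
  m <- generate_reference_and_genes(cfg)
  expect_equal(length(m$transcripts), 0L)
  expect_equal(length(m$reference), cfg$n_chromosomes)
  too_many <- scenario_config(seed = 1, n_genes = 200,
                              chromosome_length = 50000L)
  expect_error(generate_reference_and_genes(too_many), "config error")
})

test_that("a noise-free scenario contains exactly the planted causal call", {
  cfg <- scenario_config(seed = 3, n_shared = 0, n_background_private = 0,
                         n_panel_hits = 0, n_panel_only = 0, n_low_quality = 0,
                         n_noncoding = 0, n_synonymous = 0, indel_clusters = 0)
  sc <- simulate_scenario(cfg)
  expect_equal(nrow(sc$mutant), 1L)
  expect_equal(sc$truth$label, "causal")
  expect_equal(sc$mutant$genotype, "het")
  expect_equal(sc$mutant$snp_quality, 228)
  expect_equal(sc$mutant$read_depth, 66)
  ann <- annotate_variants(sc$mutant, sc$models)
  expect_equal(ann$category, "nonsynonymous")
  expect_equal(ann$detail, "Y:C")
})

test_that("truth labels are sound under subtraction and the causal site is protected", {
  sc <- simulate_scenario(scenario_config(seed = 9))
  key <- function(df) paste(df$chrom, df$pos, df$alt, sep = ":")
  truth_key <- key(sc$truth)
  surv <- subtract_shared(sc$mutant, sc$background)
  lab_surv <- sc$truth$label[match(variant_key(surv), truth_key)]
  expect_false(any(lab_surv == "shared"))
  surv2 <- subtract_known(surv, sc$panels)
  lab2 <- sc$truth$label[match(variant_key(surv2), truth_key)]
  expect_false(any(lab2 %in% c("shared", "panel")))
  # non-shared, non-panel calls are never removed by those steps
  expect_equal(sum(!lab2 %in% c("shared", "panel")), nrow(surv2))
  causal_key <- truth_key[sc$truth$label == "causal"]
  expect_false(causal_key %in% unlist(lapply(sc$panels, variant_key)))
  expect_false(causal_key %in% variant_key(sc$background))
  expect_true(causal_key %in% variant_key(surv2))
})

test_that("validation patterns follow the truth taxonomy", {
  sc <- simulate_scenario(scenario_config(seed = 13))
  v <- sc$validation
  lab <- sc$truth$label
  causal <- which(lab == "causal")
  expect_equal(v$background_call[causal], sc$truth$ref[causal])
  expect_true(grepl(sc$truth$alt[causal], v$mutant_call[causal]))
  expect_false(v$mutant_call[causal] == v$background_call[causal])
  expect_true(all(v$background_call[lab == "indel_artifact"] == "Deletion"))
  expect_true(all(v$mutant_call[lab == "indel_artifact"] == "Deletion"))
  i <- lab == "low_quality"
  expect_true(all(v$mutant_call[i] == v$background_call[i]))
  i <- lab %in% c("shared", "panel")
  expect_true(all(v$mutant_call[i] == v$background_call[i]))
})

test_that("cohort generation honours viability, penetrance and determinism", {
  co <- generate_cohort(cohort_config(seed = 5))
  expect_equal(nrow(co), 111 + 85)
  expect_false(any(co$genotype == "hom"))
  expect_identical(generate_cohort(cohort_config(seed = 5)), co)
  expect_false(identical(generate_cohort(cohort_config(seed = 6)), co))
  # thresholds respect class boundaries: wt never >= 50, intermediates inside
  wt <- co$click_threshold[co$genotype == "wt"]
  expect_true(all(wt < 50))
  expect_true(all(co$click_threshold >= 0 & co$click_threshold <= 97))
  # partial homozygote viability produces some but few homs
  co2 <- generate_cohort(cohort_config(seed = 5, hom_viability = 0.5))
  n_hom <- sum(co2$genotype == "hom" & co2$cross_type == "het_x_het")
  expect_gt(n_hom, 0)
  expect_lt(n_hom / 111, 0.25)
  # a large cohort recovers the configured penetrance within 2 SE
  big <- generate_cohort(cohort_config(seed = 31, n_het_x_het = 12000,
                                       n_het_x_wt = 0))
  hets <- big[big$genotype == "het", ]
  p_hat <- mean(classify_hearing(hets$click_threshold) == "affected")
  se <- sqrt(0.231 * 0.769 / nrow(hets))
  expect_lt(abs(p_hat - 0.231), 2 * se)
})

test_that("simulated intercross litters are compatible with the published block", {
  # chi-square distance of simulated het-row class counts to the published
  # het x het row (32, 21, 19), non-significant at alpha = 0.01 in >= 95/100 seeds
  p_ref <- c(32, 21, 19) / 72
  ok <- 0L
  for (s in 1:100) {
    co <- generate_cohort(cohort_config(seed = 4000 + s))
    hets <- co[co$cross_type == "het_x_het" & co$genotype == "het", ]
    cnt <- table(classify_hearing(hets$click_threshold))
    p <- suppressWarnings(chisq.test(as.integer(cnt), p = p_ref)$p.value)
    ok <- ok + (p > 0.01)
  }
  expect_gte(ok, 95L)
})

test_that("scenario files round-trip and record their seed", {
  sc <- simulate_scenario(scenario_config(seed = 19))
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  expect_true(any(grepl("seed=19", readLines(file.path(dir, "mutant.vcf"),
                                             n = 5))))
  expect_true(any(grepl("seed=19", readLines(file.path(dir, "truth.tsv"),
                                             n = 1))))
  back <- read_variant_calls(file.path(dir, "mutant.vcf"))
  expect_equal(as.data.frame(back), as.data.frame(sc$mutant))
  models <- read_gene_models(file.path(dir, "genes.gff3"),
                             file.path(dir, "reference.fa"))
  expect_equal(length(models$transcripts), length(sc$models$transcripts))
  val <- read_validation_genotypes(file.path(dir, "validation.tsv"))
  expect_equal(val$mutant_call, sc$validation$mutant_call)
})
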