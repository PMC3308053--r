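rand_calls <- function(n, chrom = "1") {
  refs <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  variant_calls(chrom = rep_len(chrom, n), pos = sample.int(1e6, n), ref = refs,
                alt = vapply(refs, function(r)
                  sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1)),
                genotype = sample(c("het", "hom_alt"), n, replace = TRUE),
                consensus_quality = sample(0:200, n, TRUE),
                snp_quality = sample(0:250, n, TRUE),
                mapping_quality = sample(0:60, n, TRUE),
                read_depth = sample(0:120, n, TRUE))
}

test_that("background subtraction removes exactly the shared keys", {
  set.seed(1)
  mutant <- rand_calls(50)
  expect_equal(nrow(subtract_shared(mutant, mutant)), 0L)
  expect_equal(subtract_shared(mutant, mutant[0, ]), mutant)
  # planted: background = first 30 calls; survivors = the other 20, in order
  surv <- subtract_shared(mutant, mutant[1:30, ])
  expect_equal(variant_key(surv), setdiff(variant_key(mutant),
                                          variant_key(mutant[1:30, ])))
  expect_equal(length(intersect(variant_key(surv),
                                variant_key(mutant[1:30, ]))), 0L)
})

test_that("panel subtraction matches any panel, by key", {
  set.seed(2)
  calls <- rand_calls(40)
  expect_equal(subtract_known(calls, list()), calls)
  panels <- list(calls[3:7, ], calls[25:30, ])
  surv <- subtract_known(calls, panels)
  expect_equal(nrow(surv), 40L - 11L)
  expect_false(any(variant_key(surv) %in%
                     unlist(lapply(panels, variant_key))))
  # call present only in panel 2 of 2 is removed
  expect_false(variant_key(calls[26, ]) %in% variant_key(surv))
})

test_that("quality stages use the published boundary semantics", {
  mk <- function(sq, mq, dp) variant_calls("1", 100, "A", "G", "het",
                                           consensus_quality = 1,
                                           snp_quality = sq,
                                           mapping_quality = mq,
                                           read_depth = dp)
  keep_a <- function(c) nrow(apply_quality_filters(c)$stage_a) == 1
  keep_b <- function(c) nrow(apply_quality_filters(c)$stage_b) == 1
  expect_false(keep_a(mk(19, 60, 50)))    # SNP quality 19 fails, 20 passes
  expect_true(keep_a(mk(20, 60, 50)))
  expect_true(keep_b(mk(20, 60, 50)))
  expect_false(keep_b(mk(100, 45, 50)))   # mapping quality is strict (> 45)
  expect_true(keep_b(mk(100, 46, 50)))
  expect_false(keep_b(mk(100, 60, 10)))   # read depth is strict (> 10)
  expect_true(keep_b(mk(100, 60, 11)))
  # consensus quality is never filtered on
  expect_true(keep_b(mk(100, 60, 50)))
  # unknown metrics fail closed, pass with fail_open
  expect_false(keep_a(mk(NA, 60, 50)))
  expect_false(keep_b(mk(100, NA, 50)))
  open <- quality_thresholds(fail_open = TRUE)
  expect_equal(nrow(apply_quality_filters(mk(NA, NA, NA), open)$stage_b), 1L)
})

test_that("noncoding removal keeps splice sites; candidate selection keeps severe SNVs", {
  ann <- data.frame(
    chrom = "1", pos = 1:6, ref = "A", alt = "G", genotype = "het",
    variant_class = "snv",
    category = c("intergenic", "intronic", "essential_splice_site",
                 "nonsynonymous", "synonymous", "utr5"))
  kept <- remove_noncoding(ann)
  expect_equal(nrow(kept), 4L)
  expect_true("essential_splice_site" %in% kept$category)
  expect_false(any(c("intronic", "intergenic") %in% kept$category))
  sel <- select_candidates(kept)
  expect_equal(sort(sel$category), c("essential_splice_site", "nonsynonymous"))
  # synonymous and UTR excluded; indels excluded even when stop_gained
  indel <- data.frame(chrom = "1", pos = 9, ref = "A", alt = "ATAA",
                      genotype = "het", variant_class = "insertion",
                      category = "stop_gained")
  expect_equal(nrow(select_candidates(rbind(kept, indel))), 2L)
})

test_that("indel proximity flags respect the window boundary", {
  cand <- one_snv("1", 1000, "A", "G")
  del <- variant_calls("1", 1003, "AT", "A", "het")
  far <- variant_calls("1", 1021, "AT", "A", "het")
  expect_true(flag_indel_proximal(cand, del, window_bp = 20)$flagged)
  f <- flag_indel_proximal(cand, far, window_bp = 20)
  expect_false(f$flagged)
  expect_equal(f$distance_bp, 21)
  # SNV calls in the pool are ignored; no indels -> unflagged with Inf distance
  f2 <- flag_indel_proximal(cand, one_snv("1", 1001, "C", "T"))
  expect_false(f2$flagged)
  expect_equal(f2$distance_bp, Inf)
})

test_that("validation adjudication confirms mutant-specific alleles only", {
  cands <- variant_calls(chrom = rep("1", 5), pos = 1:5 * 100,
                         ref = c("C", "T", "A", "G", "T"),
                         alt = c("A", "C", "G", "A", "C"),
                         genotype = "het", snp_quality = 50,
                         mapping_quality = 50, read_depth = 50)
  validation <- data.frame(
    chrom = "1", pos = 1:5 * 100, ref = c("C", "T", "A", "G", "T"),
    alt = c("A", "C", "G", "A", "C"),
    background_call = c("C", "Deletion", "A", NA, "T"),
    mutant_call = c("C", "Deletion", "A/G", NA, "C/T"))
  adj <- confirm_with_validation(cands, validation)
  expect_equal(adj$confirmed, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(adj$reason[1], "identical_to_background")
  expect_equal(adj$reason[2], "indel_misalignment")
  expect_equal(adj$reason[4], "missing_data")
  # het allele order never matters: G/A vs A/G confirm identically
  validation$mutant_call[3] <- "G/A"
  expect_true(confirm_with_validation(cands, validation)$confirmed[3])
  # zygosity miscall: traces differ but carry no mutant-specific alt
  validation$background_call[5] <- "C/T"; validation$mutant_call[5] <- "T"
  adj <- confirm_with_validation(cands, validation)
  expect_false(adj$confirmed[5])
  expect_equal(adj$reason[5], "miscalled_zygosity")
  # every candidate must have a validation record
  expect_error(confirm_with_validation(cands, validation[-3, ]),
               "validation-completeness")
})

test_that("heterozygote counting ignores homozygous candidates", {
  expect_equal(count_heterozygous(rand_calls(0)), 0L)
  hom3 <- variant_calls("1", 1:3, "A", "G", "hom_alt")
  expect_equal(count_heterozygous(hom3), 0L)
  expect_equal(count_heterozygous(rbind(hom3, one_snv("1", 9, "A", "G"))), 1L)
})

test_that("an empty mutant call set yields an all-zero funnel", {
  models <- toy_plus_models()
  rep <- run_funnel(rand_calls(0), rand_calls(0), list(), models)
  expect_true(all(rep$steps$survivors == 0L))
  expect_equal(nrow(rep$candidates), 0L)
})

test_that("the funnel recovers a planted causal variant and is idempotent", {
  sc <- simulate_scenario(scenario_config(seed = 303))
  rep <- run_funnel(sc$mutant, sc$background, sc$panels, sc$models,
                    validation = sc$validation)
  causal_key <- variant_key(sc$truth[sc$truth$label == "causal", ])
  expect_true(causal_key %in% variant_key(rep$candidates))
  expect_equal(variant_key(rep$confirmed), causal_key)
  expect_equal(rep$confirmed$genotype, "het")
  expect_equal(rep$confirmed$category, "nonsynonymous")
  # monotone survivor counts
  expect_true(all(diff(rep$steps$survivors) <= 0))
  # artifact SNVs flagged indel-proximal, the causal call not
  adj <- rep$adjudicated
  expect_false(adj$indel_flagged[adj$confirmed])
  artifacts <- sc$truth$label == "indel_artifact" &
    variant_key(sc$truth) %in% variant_key(rep$candidates)
  expect_true(all(variant_key(sc$truth[artifacts, ]) %in%
                    rep$flags$candidate_key[rep$flags$flagged]))
  # byte-for-byte idempotence
  rep2 <- run_funnel(sc$mutant, sc$background, sc$panels, sc$models,
                     validation = sc$validation)
  expect_identical(serialize(rep, NULL), serialize(rep2, NULL))
})

test_that("funnel runs identically from VCF/TSV files on disk", {
  sc <- simulate_scenario(scenario_config(seed = 77))
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  rep_mem <- run_funnel(sc$mutant, sc$background, sc$panels, sc$models,
                        validation = sc$validation)
  rep_file <- run_funnel(
    file.path(dir, "mutant.vcf"), file.path(dir, "background.vcf"),
    list(file.path(dir, "panel_1.vcf"), file.path(dir, "panel_2.vcf")),
    sc$models, validation = file.path(dir, "validation.tsv"))
  expect_equal(rep_file$steps, rep_mem$steps)
  expect_equal(variant_key(rep_file$confirmed), variant_key(rep_mem$confirmed))
})

test_that("a planted variant at the depth boundary is lost at stage B", {
  cfg <- scenario_config(seed = 11)
  cfg$causal$read_depth <- 10            # '> 10' is strict
  sc <- simulate_scenario(cfg)
  rep <- run_funnel(sc$mutant, sc$background, sc$panels, sc$models)
  causal_key <- variant_key(sc$truth[sc$truth$label == "causal", ])
  qf <- apply_quality_filters(
    subtract_known(subtract_shared(sc$mutant, sc$background), sc$panels))
  expect_true(causal_key %in% variant_key(qf$stage_a))
  expect_false(causal_key %in% variant_key(qf$stage_b))
  expect_false(causal_key %in% variant_key(rep$candidates))
})
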