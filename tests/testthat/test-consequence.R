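test_that("coding SNVs translate codon-aware on the plus strand", {
  models <- toy_plus_models()
  # CDS base 5 (genomic 15) A>G: TAT -> TGT, Tyr -> Cys at residue 2
  ann <- annotate_snv(one_snv("chrT", 15, "A", "G"), models)
  expect_equal(ann$category, "nonsynonymous")
  expect_equal(ann$detail, "Y:C")
  expect_equal(ann$residue, 2L)
  expect_equal(ann$gene, "toygene")
  # CDS base 6 (genomic 16) T>A: TAT -> TAA, stop gained
  expect_equal(annotate_snv(one_snv("chrT", 16, "T", "A"), models)$category,
               "stop_gained")
  # CDS base 6 T>C: TAT -> TAC, synonymous Tyr
  syn <- annotate_snv(one_snv("chrT", 16, "T", "C"), models)
  expect_equal(syn$category, "synonymous")
  expect_equal(syn$detail, "Y:Y")
  # CDS base 9 (genomic 19) A>G: TGA -> TGG, stop lost
  expect_equal(annotate_snv(one_snv("chrT", 19, "A", "G"), models)$category,
               "stop_lost")
})

test_that("minus-strand codons are read in transcript orientation", {
  models <- toy_minus_models()
  # transcript codon 2 (TAT) middle base lies at genomic 15 (base T);
  # genomic T>C reads G in transcript sense: TAT -> TGT, Y:C
  ann <- annotate_snv(one_snv("chrM", 15, "T", "C"), models)
  expect_equal(ann$category, "nonsynonymous")
  expect_equal(ann$detail, "Y:C")
  expect_equal(ann$residue, 2L)
})

test_that("UTRs, splice sites, introns and intergenic regions classify by position", {
  models <- toy_intron_models()
  cat_at <- function(pos) {
    ref <- as.character(Biostrings::subseq(models$reference[["chrI"]], pos, pos))
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    annotate_snv(one_snv("chrI", pos, ref, alt), models)$category
  }
  expect_equal(cat_at(12), "utr5")          # exon 1 before CDS
  expect_equal(cat_at(50), "utr3")          # exon 2 after CDS
  expect_equal(cat_at(31), "essential_splice_site")  # intron base 1
  expect_equal(cat_at(32), "essential_splice_site")  # intron base 2
  expect_equal(cat_at(33), "intronic")               # intron base 3
  expect_equal(cat_at(39), "intronic")
  expect_equal(cat_at(40), "essential_splice_site")  # last two intron bases
  expect_equal(cat_at(41), "essential_splice_site")
  expect_equal(cat_at(5), "intergenic")
  expect_equal(cat_at(75), "intergenic")
})

test_that("every transcript position gets exactly one category, partitioning the span", {
  models <- toy_intron_models()
  tx <- models$transcripts[[1]]
  span <- min(tx$exons):max(tx$exons)
  cats <- vapply(span, function(pos) {
    ref <- as.character(Biostrings::subseq(models$reference[["chrI"]], pos, pos))
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    annotate_snv(one_snv("chrI", pos, ref, alt), models)$category
  }, character(1))
  expect_equal(length(cats), length(span))
  expect_equal(sum(cats == "essential_splice_site"), 4L)  # 2 per intron end
  expect_equal(sum(cats == "intronic"), 7L)               # 11-bp intron - 4
  expect_false(any(cats == "intergenic"))
  # coding positions yield only translation categories
  coding <- cats[span %in% c(17:30, 42:45)]
  expect_true(all(coding %in% c("synonymous", "nonsynonymous",
                                "stop_gained", "stop_lost")))
})

test_that("noncoding transcripts and out-of-range coordinates are handled", {
  models <- toy_plus_models()
  models$transcripts[[1]]$biotype <- "noncoding"
  models$transcripts[[1]]$cds <- matrix(integer(), ncol = 2)
  ann <- annotate_snv(one_snv("chrT", 15, "A", "G"), models)
  expect_equal(ann$category, "noncoding_transcript")
  expect_error(annotate_snv(one_snv("chrT", 9999, "A", "G"), models),
               "coordinate error")
})

test_that("severity order is fixed, total and repeatable", {
  expect_lt(severity_rank("stop_gained"), severity_rank("nonsynonymous"))
  expect_lt(severity_rank("frameshift"), severity_rank("essential_splice_site"))
  expect_lt(severity_rank("essential_splice_site"), severity_rank("nonsynonymous"))
  expect_lt(severity_rank("nonsynonymous"), severity_rank("inframe_indel"))
  expect_lt(severity_rank("inframe_indel"), severity_rank("synonymous"))
  expect_lt(severity_rank("synonymous"), severity_rank("utr5"))
  expect_lt(severity_rank("utr3"), severity_rank("noncoding_transcript"))
  expect_lt(severity_rank("noncoding_transcript"), severity_rank("intronic"))
  expect_lt(severity_rank("essential_splice_site"), severity_rank("intronic"))
  expect_equal(severity_rank("intergenic"),
               max(severity_rank(c("stop_gained", "stop_lost", "frameshift",
                                   "essential_splice_site", "nonsynonymous",
                                   "inframe_indel", "synonymous", "utr5",
                                   "utr3", "noncoding_transcript", "intronic",
                                   "intergenic"))))
  expect_identical(severity_rank("utr5"), severity_rank("utr5"))
  expect_error(severity_rank("exotic"), "unknown")
})

test_that("indels classify by frame, placement and introduced stops", {
  models <- toy_intron_models()
  seq_at <- function(s, e) as.character(
    Biostrings::subseq(models$reference[["chrI"]], s, e))
  # 1-bp insertion inside CDS -> frameshift
  ins1 <- variant_calls("chrI", 20, seq_at(20, 20),
                        paste0(seq_at(20, 20), "T"), "het")
  expect_equal(annotate_indel(ins1, models)$category, "frameshift")
  # 3-bp in-frame insertion of TAA right after codon 1 (CDS 17..19) -> stop
  insTAA <- variant_calls("chrI", 19, seq_at(19, 19),
                          paste0(seq_at(19, 19), "TAA"), "het")
  expect_equal(annotate_indel(insTAA, models)$category, "stop_gained")
  # 3-bp in-frame insertion of a sense codon -> inframe_indel
  insOK <- variant_calls("chrI", 19, seq_at(19, 19),
                         paste0(seq_at(19, 19), "GCA"), "het")
  expect_equal(annotate_indel(insOK, models)$category, "inframe_indel")
  # deletion wholly within the intron, > 2 bp from both ends -> intronic
  del <- variant_calls("chrI", 33, seq_at(33, 35), seq_at(33, 33), "het")
  expect_equal(annotate_indel(del, models)$category, "intronic")
  # deletion eating intron base 1 -> essential splice site
  del_sp <- variant_calls("chrI", 30, seq_at(30, 31), seq_at(30, 30), "het")
  expect_equal(annotate_indel(del_sp, models)$category, "essential_splice_site")
  # 2-bp coding deletion -> frameshift
  del_fs <- variant_calls("chrI", 19, seq_at(19, 21), seq_at(19, 19), "het")
  expect_equal(annotate_indel(del_fs, models)$category, "frameshift")
})

test_that("multi-transcript overlaps resolve to the most severe consequence", {
  models <- toy_plus_models()
  # add an overlapping transcript in which genomic 15 is intronic
  tx2 <- models$transcripts[[1]]
  tx2$transcript_id <- "toygene.2"
  tx2$exons <- matrix(c(5L, 20L, 10L, 25L), ncol = 2)
  tx2$cds <- matrix(c(8L, 20L, 10L, 25L), ncol = 2)
  models2 <- gene_model_set(c(models$transcripts, list(toygene.2 = tx2)),
                            models$reference)
  ann <- annotate_snv(one_snv("chrT", 15, "A", "G"), models2)
  expect_equal(ann$transcript_id, "toygene.1")   # nonsynonymous beats intronic
  expect_equal(ann$category, "nonsynonymous")
})

test_that("annotation agrees with a full-translation oracle over random SNVs", {
  set.seed(4242)
  n_checked <- 0L
  while (n_checked < 1000L) {
    fix <- random_single_exon_models()
    models <- fix$models
    for (r in seq_len(25L)) {
      pos <- sample(fix$cds_start:fix$cds_end, 1L)
      ref <- as.character(Biostrings::subseq(models$reference[["chrR"]],
                                             pos, pos))
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      got <- annotate_snv(one_snv("chrR", pos, ref, alt), models)
      want <- oracle_snv_consequence(models, "rnd.1", pos, alt)
      expect_equal(got$category, want$category,
                   info = sprintf("pos %d %s>%s", pos, ref, alt))
      expect_equal(got$residue, want$residue)
      if (got$category != "synonymous") expect_equal(got$detail, want$detail)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 1000L)
})

test_that("consequences are invariant under genome mirroring", {
  set.seed(99)
  fix <- random_single_exon_models()
  models <- fix$models
  L <- Biostrings::width(models$reference)[[1]]
  mirrored <- mirror_models(models)
  span <- min(models$transcripts[[1]]$exons):max(models$transcripts[[1]]$exons)
  for (pos in sample(span, 80L)) {
    ref <- as.character(Biostrings::subseq(models$reference[["chrR"]], pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    fwd <- annotate_snv(one_snv("chrR", pos, ref, alt), models)
    rev <- annotate_snv(one_snv("chrR", L - pos + 1L, comp1(ref), comp1(alt)),
                        mirrored)
    expect_equal(rev$category, fwd$category,
                 info = sprintf("pos %d %s>%s", pos, ref, alt))
    if (nzchar(fwd$detail)) expect_equal(rev$detail, fwd$detail)
  }
})
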