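#' Synthetic replica of a chromosome-wide linkage-exclusion setting
#'
#' Builds a single-chromosome scenario shaped like the candidate
#' chromosome of a completed funnel run: a candidate gene carrying a
#' heterozygous Tyr->Cys missense SNV, four noncoding indels inside the
#' +/- 10 Mb linkage window (a splice-site deletion, a 3' UTR deletion, a
#' 5' UTR deletion and a splice-site insertion -- none in coding sequence),
#' and, on the remainder of the chromosome (> 10 Mb away), coding indels that
#' would be flagged as alternative causal lesions: two exonic frameshift
#' insertions, one in-frame insertion that gains a stop codon, plus a 3' UTR
#' SNV and another splice-site deletion. Distances are physical, as in the
#' linkage report itself.
#'
#' @param seed integer seed.
#' @param chrom chromosome name used in the replica.
#' @return list with `models` (a [gene_model_set()]), `candidate` (one-row
#'   [variant_calls()]) and `calls` (a [variant_calls()] table of the other
#'   private calls, indels included).
#' @export
simulate_linkage_replica <- function(seed = 1L, chrom = "13") {
  set.seed(seed)
  chrom_len <- 11300000L
  env <- new.env()
  env$seq <- stats::setNames(list(random_dna(chrom_len)), chrom)

  mk <- function(start, strand, name, ...)
    make_transcript(env, chrom, start, strand, gene_name = name, ...)

  # rest of chromosome (> 10 Mb from the candidate at ~11.1 Mb)
  g_splice2 <- mk(400000L, "-", "rg01")
  g_fs1 <- mk(600000L, "+", "rg02")
  g_fs2 <- mk(800000L, "-", "rg03")
  g_stop <- mk(900000L, "+", "rg04")
  g_utr3snv <- mk(1000000L, "+", "rg05")
  # inside the 10 Mb window around the candidate
  g_splice_del <- mk(1700899L, "+", "wg01")
  g_utr3_del <- mk(1752127L, "-", "wg02")
  g_utr5_del <- mk(7523874L, "+", "wg03")
  g_splice_ins <- mk(7963370L, "-", "wg04")
  # the candidate gene itself
  g_cand <- mk(11098488L, "-", "cand", n_codons = 120L)

  txs <- list(g_splice2, g_fs1, g_fs2, g_stop, g_utr3snv, g_splice_del,
              g_utr3_del, g_utr5_del, g_splice_ins, g_cand)
  names(txs) <- vapply(txs, `[[`, "", "transcript_id")
  models <- gene_model_set(txs, Biostrings::DNAStringSet(unlist(env$seq)))

  seq_at <- function(s, e) as.character(Biostrings::subseq(
    models$reference[[chrom]], s, e))

  splice_del <- function(tx, genotype) {
    anchor <- tx$exons[1, 2]                 # deletes intron base 1
    data.frame(chrom = chrom, pos = anchor, ref = seq_at(anchor, anchor + 1L),
               alt = seq_at(anchor, anchor), genotype = genotype)
  }
  utr_del <- function(tx, side, genotype, dlen = 2L) {
    iv <- utr_intervals(tx)[[side]]
    iv <- iv[which.max(iv[, 2] - iv[, 1]), , drop = FALSE]
    anchor <- iv[1, 1] + 2L
    data.frame(chrom = chrom, pos = anchor,
               ref = seq_at(anchor, anchor + dlen),
               alt = seq_at(anchor, anchor), genotype = genotype)
  }
  splice_ins <- function(tx, genotype) {
    anchor <- tx$exons[nrow(tx$exons) - 1L, 2] + 1L  # intron base 1
    data.frame(chrom = chrom, pos = anchor, ref = seq_at(anchor, anchor),
               alt = paste0(seq_at(anchor, anchor), "T"), genotype = genotype)
  }
  exonic_ins <- function(tx, ins, genotype, at_codon_boundary = FALSE) {
    run <- tx$cds[which.max(tx$cds[, 2] - tx$cds[, 1]), , drop = FALSE]
    anchor <- if (at_codon_boundary) {
      cdspos <- cds_positions(tx)
      k <- 30L                                  # after codon 10
      sort(cdspos[c(k, k + 1L)])[1L]            # between two coding bases
    } else run[1, 1] + 15L
    data.frame(chrom = chrom, pos = anchor, ref = seq_at(anchor, anchor),
               alt = paste0(seq_at(anchor, anchor), ins), genotype = genotype)
  }

  cand <- plant_causal_snv(g_cand, models)
  cand$genotype <- "het"
  others <- rbind(
    splice_del(g_splice2, "het"),
    exonic_ins(g_fs1, "GG", "het"),
    exonic_ins(g_fs2, "G", "het"),
    exonic_ins(g_stop, "TAA", "hom_alt", at_codon_boundary = TRUE),
    {
      utr <- utr_intervals(g_utr3snv)$utr3
      p <- utr[1, 1] + 5L
      r <- seq_at(p, p)
      data.frame(chrom = chrom, pos = p, ref = r, alt = other_base(r),
                 genotype = "het")
    },
    splice_del(g_splice_del, "het"),
    utr_del(g_utr3_del, "utr3", "het", dlen = 1L),
    utr_del(g_utr5_del, "utr5", "hom_alt"),
    splice_ins(g_splice_ins, "het"))

  finish <- function(df) {
    m <- good_metrics(nrow(df))
    df <- cbind(df, m)
    df$variant_class <- variant_class(df$ref, df$alt)
    validate_variant_calls(df)
  }
  list(models = models, candidate = finish(cand), calls = finish(others))
}
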