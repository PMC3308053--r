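# Toy genomes built in code. Coordinates are 1-based inclusive throughout.

pad <- function(n, base = "A") paste(rep(base, n), collapse = "")

# single-exon plus-strand gene: exon 5..25, 5' UTR 5..10, CDS 11..19
# (ATGTATTGA: Met-Tyr-stop), 3' UTR 20..25
toy_plus_models <- function() {
  seq <- paste0("ACGT", "CCGGCC", "ATGTATTGA", "GGCCGG", "ACGTACGT")
  tx <- list(transcript_id = "toygene.1", gene_name = "toygene",
             chrom = "chrT", strand = "+",
             exons = matrix(c(5L, 25L), ncol = 2),
             cds = matrix(c(11L, 19L), ncol = 2), biotype = "protein_coding")
  gene_model_set(list(toygene.1 = tx),
                 Biostrings::DNAStringSet(c(chrT = seq)))
}

# same CDS on the minus strand: genomic 11..19 holds revcomp(ATGTATTGA) =
# TCAATACAT, so transcript codon 2 (TAT) sits at genomic 4..6 of the CDS
toy_minus_models <- function() {
  seq <- paste0("ACGT", "CCGGCC", "TCAATACAT", "GGCCGG", "ACGTACGT")
  tx <- list(transcript_id = "toyminus.1", gene_name = "toyminus",
             chrom = "chrM", strand = "-",
             exons = matrix(c(5L, 25L), ncol = 2),
             cds = matrix(c(11L, 19L), ncol = 2), biotype = "protein_coding")
  gene_model_set(list(toyminus.1 = tx),
                 Biostrings::DNAStringSet(c(chrM = seq)))
}

# two-exon plus-strand gene with an 11-bp intron:
# exon1 11..30 (5' UTR 11..16, CDS 17..30), intron 31..41, exon2 42..70
# (CDS 42..46, 3' UTR 47..70); CDS = ATG + 4 codons + TAA (18 bp)
toy_intron_models <- function() {
  cds1 <- "ATGTATAAACCCGG"                      # 14 bp in exon 1
  cds2 <- "GTAA"                                #  4 bp in exon 2
  seq <- paste0(pad(10, "G"), "CCGGCC", cds1, "GTGCGTGCGAG", cds2,
                paste(rep("CT", 12), collapse = ""), pad(10, "G"))
  tx <- list(transcript_id = "toyintron.1", gene_name = "toyintron",
             chrom = "chrI", strand = "+",
             exons = matrix(c(11L, 42L, 30L, 70L), ncol = 2),
             cds = matrix(c(17L, 42L, 30L, 45L), ncol = 2),
             biotype = "protein_coding")
  gene_model_set(list(toyintron.1 = tx),
                 Biostrings::DNAStringSet(c(chrI = seq)))
}

one_snv <- function(chrom, pos, ref, alt, genotype = "het",
                    cq = 100, sq = 100, mq = 60, dp = 50) {
  variant_calls(chrom = chrom, pos = pos, ref = ref, alt = alt,
                genotype = genotype, consensus_quality = cq, snp_quality = sq,
                mapping_quality = mq, read_depth = dp)
}

# random single-exon plus-strand gene set for the oracle-equivalence property
random_single_exon_models <- function(n_codons = 40, pad_len = 30) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- sample(setdiff(names(Biostrings::GENETIC_CODE), stops),
                   n_codons - 2L, replace = TRUE)
  cds <- paste(c("ATG", codons, sample(stops, 1)), collapse = "")
  left <- paste(sample(c("A", "C", "G", "T"), pad_len, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), pad_len, replace = TRUE),
                 collapse = "")
  cds_start <- pad_len + 6L
  cds_end <- cds_start + nchar(cds) - 1L
  seq <- paste0(left, "CGGCC", cds, "GGCCG", right)
  tx <- list(transcript_id = "rnd.1", gene_name = "rnd", chrom = "chrR",
             strand = "+",
             exons = matrix(c(pad_len + 1L, cds_end + 5L), ncol = 2),
             cds = matrix(c(cds_start, cds_end), ncol = 2),
             biotype = "protein_coding")
  list(models = gene_model_set(list(rnd.1 = tx),
                               Biostrings::DNAStringSet(c(chrR = seq))),
       cds_start = cds_start, cds_end = cds_end)
}
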