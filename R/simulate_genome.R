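DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
NONSTOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Configuration for a synthetic variant scenario
#'
#' Defines the conditions of a simulated exome experiment: a small genome
#' with ORF-bearing multi-exon genes on both strands, a large stratum of
#' variants shared by the mutant and its un-mutagenized background strain
#' (strain-vs-reference differences), known-panel polymorphisms, private
#' noise calls in the false-positive modes seen in real funnels (low-quality
#' calls, noncoding and synonymous changes, and SNV artifact clusters
#' flanking small deletions), and one planted heterozygous causal missense
#' SNV whose quality metrics default to the profile of a true call that
#' survives every filter (consensus 199, SNP quality 228, mapping quality 60,
#' depth 66).
#'
#' @param seed integer seed; all randomness of the scenario flows from it.
#' @param n_chromosomes,chromosome_length genome shape.
#' @param n_genes protein-coding gene count (spread over chromosomes).
#' @param n_noncoding_genes additional noncoding transcripts.
#' @param n_shared variants present in both mutant and background.
#' @param n_background_private variants private to the background sample.
#' @param n_panels,n_panel_hits,n_panel_only known-variant panels: `n_panel_hits`
#'   mutant calls also present in a panel, `n_panel_only` panel entries not in
#'   the mutant.
#' @param n_low_quality private calls failing one quality threshold each.
#' @param n_noncoding private good-quality calls in deep introns/intergenic.
#' @param n_synonymous private good-quality synonymous coding calls.
#' @param indel_clusters,artifacts_per_cluster,cluster_spacing_bp planted
#'   small deletions, each flanked by `artifacts_per_cluster` nonsynonymous
#'   artifact SNVs within `cluster_spacing_bp`.
#' @param causal list: `target` amino-acid change class (`"Y:C"`), `genotype`,
#'   and the four quality metrics of the planted call.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_chromosomes = 3L, chromosome_length = 300000L,
                            n_genes = 15L, n_noncoding_genes = 3L,
                            n_shared = 300L, n_background_private = 50L,
                            n_panels = 2L, n_panel_hits = 40L, n_panel_only = 30L,
                            n_low_quality = 60L, n_noncoding = 40L,
                            n_synonymous = 15L,
                            indel_clusters = 3L, artifacts_per_cluster = 2L,
                            cluster_spacing_bp = 10L,
                            causal = list(target = "Y:C", genotype = "het",
                                          consensus_quality = 199,
                                          snp_quality = 228,
                                          mapping_quality = 60,
                                          read_depth = 66)) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              chromosome_length = chromosome_length, n_genes = n_genes,
              n_noncoding_genes = n_noncoding_genes, n_shared = n_shared,
              n_background_private = n_background_private,
              n_panels = n_panels, n_panel_hits = n_panel_hits,
              n_panel_only = n_panel_only, n_low_quality = n_low_quality,
              n_noncoding = n_noncoding, n_synonymous = n_synonymous,
              indel_clusters = indel_clusters,
              artifacts_per_cluster = artifacts_per_cluster,
              cluster_spacing_bp = cluster_spacing_bp, causal = causal)
  counts <- unlist(cfg[grep("^n_|clusters|spacing", names(cfg))])
  if (any(counts < 0)) stop("scenario counts must be non-negative")
  class(cfg) <- "scenario_config"
  cfg
}

# Builds one transcript at `start` on chromosome `chrom` and patches its CDS
# sequence (clean ORF: ATG, non-stop codons incl. one forced TAT, stop) into
# the chromosome buffer held in `env$seq`. Returns the transcript model.
make_transcript <- function(env, chrom, start, strand, gene_name,
                            transcript_id = paste0(gene_name, ".1"),
                            n_exons = sample(2:4, 1),
                            utr5_len = sample(60:150, 1),
                            n_codons = sample(60:180, 1),
                            utr3_len = sample(80:200, 1),
                            intron_len = function() sample(120:600, 1),
                            biotype = "protein_coding") {
  exonic_total <- if (biotype == "protein_coding")
    utr5_len + 3L * n_codons + utr3_len else utr5_len + utr3_len + 300L
  cuts <- if (n_exons > 1L)
    sort(sample(seq_len(exonic_total - 1L), n_exons - 1L)) else integer()
  bounds <- c(0L, cuts, exonic_total)
  exon_lens <- diff(bounds)
  introns <- if (n_exons > 1L) vapply(seq_len(n_exons - 1L),
                                      function(i) intron_len(), numeric(1)) else numeric()
  exons <- matrix(0L, nrow = n_exons, ncol = 2L)
  at <- start
  for (j in seq_len(n_exons)) {
    exons[j, ] <- c(at, at + exon_lens[j] - 1L)
    at <- at + exon_lens[j] + if (j < n_exons) introns[j] else 0L
  }
  chrom_len <- nchar(env$seq[[chrom]])
  if (exons[n_exons, 2] > chrom_len)
    stop("config error: gene '", gene_name, "' does not fit on chromosome ",
         chrom, " (needs ", exons[n_exons, 2], " > ", chrom_len, " bp)")

  exonic_pos <- unlist(lapply(seq_len(n_exons), function(j) exons[j, 1]:exons[j, 2]))
  tx_order <- if (strand == "+") exonic_pos else rev(exonic_pos)
  cds <- matrix(integer(), ncol = 2L)
  if (biotype == "protein_coding") {
    codons <- sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE)
    codons[sample(seq_along(codons), 1L)] <- "TAT"   # guaranteed Tyr site
    cds_seq <- paste(c("ATG", codons, sample(STOP_CODONS, 1L)), collapse = "")
    cds_tx_idx <- (utr5_len + 1L):(utr5_len + 3L * n_codons)
    gpos <- sort(tx_order[cds_tx_idx])
    gchars <- if (strand == "+") cds_seq else revcomp(cds_seq)
    runs <- split(seq_along(gpos), cumsum(c(1L, diff(gpos) != 1L)))
    s <- env$seq[[chrom]]
    for (r in runs) {
      substr(s, gpos[r[1]], gpos[r[length(r)]]) <-
        substr(gchars, r[1], r[length(r)])
    }
    env$seq[[chrom]] <- s
    cds <- do.call(rbind, lapply(runs, function(r) c(gpos[r[1]], gpos[r[length(r)]])))
    dimnames(cds) <- NULL
  }
  list(transcript_id = transcript_id, gene_name = gene_name, chrom = chrom,
       strand = strand, exons = exons, cds = cds, biotype = biotype)
}

#' Generate a random reference genome with gene models
#'
#' Deterministic per seed: random chromosome sequences carrying non-overlapping
#' multi-exon genes on both strands, every protein-coding CDS a clean ORF
#' (ATG start, stop at the end, length a multiple of 3, no internal stop).
#'
#' @param config a [scenario_config()].
#' @return a validated [gene_model_set()].
#' @export
generate_reference_and_genes <- function(config) {
  set.seed(config$seed)
  env <- new.env()
  env$seq <- stats::setNames(
    lapply(seq_len(config$n_chromosomes),
           function(i) random_dna(config$chromosome_length)),
    paste0("chr", seq_len(config$n_chromosomes)))

  n_total <- config$n_genes + config$n_noncoding_genes
  transcripts <- list()
  if (n_total > 0L) {
    chrom_of <- rep(names(env$seq), length.out = n_total)
    per_chrom <- table(factor(chrom_of, levels = names(env$seq)))
    slot <- config$chromosome_length / (max(per_chrom) + 1L)
    if (slot < 8000)
      stop("config error: too many genes (", n_total,
           ") for chromosome length ", config$chromosome_length)
    idx_on_chrom <- stats::ave(seq_len(n_total), chrom_of, FUN = seq_along)
    biotypes <- c(rep("protein_coding", config$n_genes),
                  rep("noncoding", config$n_noncoding_genes))
    for (g in seq_len(n_total)) {
      start <- as.integer((idx_on_chrom[g] - 1L) * slot + slot / 4 +
                            sample.int(floor(slot / 8), 1L))
      transcripts[[g]] <- make_transcript(
        env, chrom_of[g], start, sample(c("+", "-"), 1L),
        gene_name = sprintf("g%03d", g), biotype = biotypes[g])
    }
    names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  }
  reference <- Biostrings::DNAStringSet(unlist(env$seq))
  gene_model_set(transcripts, reference)
}
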