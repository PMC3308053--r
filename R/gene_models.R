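#' Gene models plus reference sequence
#'
#' Container backing codon-aware consequence annotation: a set of transcript
#' models (exon and CDS intervals, 1-based inclusive, on either strand) and
#' the reference sequence they live on. Constructed by [read_gene_models()] or
#' by the simulator; [validate_gene_models()] enforces the structural
#' invariants (sorted non-overlapping exons inside the sequence, CDS nested in
#' exons, CDS length a positive multiple of 3 for protein-coding transcripts).
#'
#' @param transcripts named list of transcript models, each a list with fields
#'   `transcript_id`, `gene_name`, `chrom`, `strand` (`"+"`/`"-"`), `exons`
#'   (2-column start/end matrix), `cds` (2-column matrix, 0 rows if
#'   noncoding), `biotype` (`"protein_coding"` or `"noncoding"`).
#' @param reference a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @return object of class `gene_model_set`.
#' @export
gene_model_set <- function(transcripts, reference) {
  obj <- structure(list(transcripts = transcripts, reference = reference),
                   class = "gene_model_set")
  validate_gene_models(obj)
}

#' @rdname gene_model_set
#' @param x a `gene_model_set`.
#' @export
validate_gene_models <- function(x) {
  stopifnot(methods::is(x$reference, "DNAStringSet"))
  seqlen <- stats::setNames(Biostrings::width(x$reference), names(x$reference))
  for (tx in x$transcripts) {
    id <- tx$transcript_id
    if (!tx$chrom %in% names(seqlen))
      stop("transcript ", id, ": chromosome '", tx$chrom, "' not in reference")
    ex <- tx$exons
    if (!is.matrix(ex) || ncol(ex) != 2L || nrow(ex) == 0L)
      stop("transcript ", id, ": exons must be a non-empty 2-column matrix")
    if (any(ex[, 1] > ex[, 2]) || any(ex < 1L) || any(ex > seqlen[[tx$chrom]]))
      stop("transcript ", id, ": exon outside chromosome bounds")
    if (is.unsorted(ex[, 1], strictly = TRUE) ||
        (nrow(ex) > 1L && any(ex[-1L, 1] <= ex[-nrow(ex), 2])))
      stop("transcript ", id, ": exons must be sorted and non-overlapping")
    if (!tx$strand %in% c("+", "-")) stop("transcript ", id, ": bad strand")
    if (!tx$biotype %in% c("protein_coding", "noncoding"))
      stop("transcript ", id, ": bad biotype")
    cds <- tx$cds
    if (tx$biotype == "protein_coding") {
      if (!is.matrix(cds) || nrow(cds) == 0L)
        stop("transcript ", id, ": protein_coding transcript lacks CDS")
      for (j in seq_len(nrow(cds))) {
        inside <- any(cds[j, 1] >= ex[, 1] & cds[j, 2] <= ex[, 2])
        if (!inside) stop("transcript ", id, ": CDS interval not inside an exon")
      }
      len <- sum(cds[, 2] - cds[, 1] + 1L)
      if (len %% 3L != 0L || len == 0L)
        stop("transcript ", id, ": CDS length ", len, " is not a positive multiple of 3")
    }
  }
  x
}

#' Read gene models from GFF3 + FASTA
#'
#' Assembles a [gene_model_set()] from standard gene/mRNA/exon/CDS GFF3
#' features (UTR features are ignored; UTRs are derived from exon-minus-CDS
#' geometry) and a reference FASTA. Transcripts with a `biotype` attribute of
#' anything other than `protein_coding`, or with no CDS features, are treated
#' as noncoding.
#'
#' @param gff_path GFF3 file.
#' @param fasta_path FASTA file with every chromosome the GFF3 references.
#' @return a validated `gene_model_set`.
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  reference <- Biostrings::readDNAStringSet(fasta_path)
  names(reference) <- sub("\\s.*", "", names(reference))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  if (length(gr) == 0L) return(gene_model_set(list(), reference))
  md <- as.data.frame(gr)
  md$Parent <- vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                      character(1))
  genes <- md[md$type == "gene", , drop = FALSE]
  gene_name <- stats::setNames(
    ifelse(is.na(genes$Name), genes$ID, genes$Name), genes$ID)
  txs <- md[md$type %in% c("mRNA", "transcript"), , drop = FALSE]
  parts <- md[md$type %in% c("exon", "CDS"), , drop = FALSE]
  transcripts <- list()
  for (i in seq_len(nrow(txs))) {
    id <- txs$ID[i]
    p <- parts[parts$Parent == id, , drop = FALSE]
    ex <- p[p$type == "exon", c("start", "end"), drop = FALSE]
    cds <- p[p$type == "CDS", c("start", "end"), drop = FALSE]
    ex <- as.matrix(ex[order(ex$start), , drop = FALSE])
    cds <- as.matrix(cds[order(cds$start), , drop = FALSE])
    dimnames(ex) <- dimnames(cds) <- NULL
    biotype <- if (!is.null(txs$biotype)) txs$biotype[i] else NA_character_
    if (is.na(biotype)) biotype <- if (nrow(cds)) "protein_coding" else "noncoding"
    if (biotype != "protein_coding") biotype <- "noncoding"
    transcripts[[id]] <- list(
      transcript_id = id,
      gene_name = if (!is.na(txs$Parent[i]) && txs$Parent[i] %in% names(gene_name))
        unname(gene_name[[txs$Parent[i]]]) else id,
      chrom = as.character(txs$seqnames[i]),
      strand = as.character(txs$strand[i]),
      exons = ex,
      cds = if (biotype == "protein_coding") cds else matrix(integer(), ncol = 2),
      biotype = biotype
    )
  }
  gene_model_set(transcripts, reference)
}

#' Write gene models as GFF3 + FASTA
#'
#' Inverse of [read_gene_models()]; emits gene, mRNA/transcript, exon, CDS and
#' derived UTR features. Used by the simulator so every synthetic scenario
#' round-trips through the standard formats.
#'
#' @param models a `gene_model_set`.
#' @param gff_path,fasta_path output paths.
#' @return `gff_path`, invisibly.
#' @export
write_gene_models <- function(models, gff_path, fasta_path) {
  Biostrings::writeXStringSet(models$reference, fasta_path, width = 70L)
  ln <- c("##gff-version 3")
  feat <- function(chrom, src, type, start, end, strand, attrs)
    paste(chrom, src, type, start, end, ".", strand, ".", attrs, sep = "\t")
  for (tx in models$transcripts) {
    gid <- paste0("gene:", tx$gene_name)
    span <- c(min(tx$exons[, 1]), max(tx$exons[, 2]))
    ln <- c(ln,
      feat(tx$chrom, "enufunnel", "gene", span[1], span[2], tx$strand,
           paste0("ID=", gid, ";Name=", tx$gene_name)),
      feat(tx$chrom, "enufunnel", if (tx$biotype == "protein_coding") "mRNA" else "transcript",
           span[1], span[2], tx$strand,
           paste0("ID=", tx$transcript_id, ";Parent=", gid,
                  ";biotype=", tx$biotype)))
    for (j in seq_len(nrow(tx$exons)))
      ln <- c(ln, feat(tx$chrom, "enufunnel", "exon", tx$exons[j, 1],
                       tx$exons[j, 2], tx$strand,
                       paste0("Parent=", tx$transcript_id)))
    for (j in seq_len(nrow(tx$cds)))
      ln <- c(ln, feat(tx$chrom, "enufunnel", "CDS", tx$cds[j, 1],
                       tx$cds[j, 2], tx$strand,
                       paste0("ID=CDS:", tx$transcript_id, ";Parent=", tx$transcript_id)))
    if (nrow(tx$cds)) {
      utr <- utr_intervals(tx)
      for (side in names(utr)) for (j in seq_len(nrow(utr[[side]])))
        ln <- c(ln, feat(tx$chrom, "enufunnel",
                         if (side == "utr5") "five_prime_UTR" else "three_prime_UTR",
                         utr[[side]][j, 1], utr[[side]][j, 2], tx$strand,
                         paste0("Parent=", tx$transcript_id)))
    }
  }
  writeLines(ln, gff_path)
  invisible(gff_path)
}

# exonic-but-not-CDS intervals, split into 5' and 3' sides in transcript sense
utr_intervals <- function(tx) {
  cds_lo <- min(tx$cds[, 1]); cds_hi <- max(tx$cds[, 2])
  left <- list(); right <- list()
  for (j in seq_len(nrow(tx$exons))) {
    s <- tx$exons[j, 1]; e <- tx$exons[j, 2]
    if (s < cds_lo) left[[length(left) + 1L]] <- c(s, min(e, cds_lo - 1L))
    if (e > cds_hi) right[[length(right) + 1L]] <- c(max(s, cds_hi + 1L), e)
  }
  tomat <- function(l) if (length(l)) do.call(rbind, l) else matrix(integer(), ncol = 2)
  if (tx$strand == "+") list(utr5 = tomat(left), utr3 = tomat(right))
  else list(utr5 = tomat(right), utr3 = tomat(left))
}

# genomic positions of the CDS in transcript (5'->3') order
cds_positions <- function(tx) {
  pos <- unlist(lapply(seq_len(nrow(tx$cds)),
                       function(j) tx$cds[j, 1]:tx$cds[j, 2]))
  if (tx$strand == "-") rev(pos) else pos
}

ref_base <- function(reference, chrom, pos) {
  as.character(Biostrings::subseq(reference[[chrom]], pos, pos))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(b) unname(COMPLEMENT[toupper(b)])

revcomp <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
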