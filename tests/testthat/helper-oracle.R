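# Independent brute-force consequence oracle: rebuild the entire mutant CDS
# string, translate both full proteins with Biostrings, and diff them. Shares
# no code path with the codon-extraction logic under test.
oracle_snv_consequence <- function(models, tx_id, pos, alt) {
  tx <- models$transcripts[[tx_id]]
  stopifnot(tx$strand == "+", nrow(tx$cds) == 1L)   # oracle scope
  cds_start <- tx$cds[1, 1]; cds_end <- tx$cds[1, 2]
  if (pos < cds_start || pos > cds_end) stop("oracle: position not in CDS")
  ref_cds <- as.character(Biostrings::subseq(models$reference[[tx$chrom]],
                                             cds_start, cds_end))
  mut_cds <- ref_cds
  substr(mut_cds, pos - cds_start + 1L, pos - cds_start + 1L) <- alt
  tr <- function(s) strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(s), no.init.codon = TRUE)), "")[[1]]
  p_ref <- tr(ref_cds); p_mut <- tr(mut_cds)
  diff <- which(p_ref != p_mut)
  if (!length(diff))
    return(list(category = "synonymous", residue = ((pos - cds_start) %/% 3) + 1L))
  i <- diff[1]
  category <- if (p_mut[i] == "*") "stop_gained"
              else if (p_ref[i] == "*") "stop_lost"
              else "nonsynonymous"
  list(category = category, detail = paste0(p_ref[i], ":", p_mut[i]),
       residue = i)
}

# mirror a gene model set: reverse-complement every chromosome and flip all
# coordinates and strands; p -> L - p + 1
mirror_models <- function(models) {
  lens <- Biostrings::width(models$reference)
  names(lens) <- names(models$reference)
  mirrored <- lapply(models$transcripts, function(tx) {
    L <- lens[[tx$chrom]]
    flip <- function(m) {
      out <- cbind(L - m[, 2] + 1L, L - m[, 1] + 1L)
      out[order(out[, 1]), , drop = FALSE]
    }
    tx$exons <- flip(tx$exons)
    if (nrow(tx$cds)) tx$cds <- flip(tx$cds)
    tx$strand <- if (tx$strand == "+") "-" else "+"
    tx
  })
  gene_model_set(mirrored,
                 Biostrings::reverseComplement(models$reference))
}

comp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[toupper(b)]]
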