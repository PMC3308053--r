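CONSEQUENCE_CATEGORIES <- c(
  "stop_gained", "stop_lost", "frameshift", "essential_splice_site",
  "nonsynonymous", "inframe_indel", "synonymous", "utr5", "utr3",
  "noncoding_transcript", "intronic", "intergenic")

#' Severity rank of a consequence category
#'
#' Fixed total order used everywhere a single most-severe consequence must be
#' reported per variant: truncating changes (stop gain/loss, frameshift), then
#' essential splice site (first or last two bases of an intron), then
#' amino-acid changes, in-frame indels, synonymous changes, UTRs, noncoding
#' transcripts, intronic and finally intergenic. Lower rank = more severe.
#'
#' @param category character vector of consequence categories.
#' @return integer ranks (1 = most severe).
#' @export
severity_rank <- function(category) {
  r <- match(category, CONSEQUENCE_CATEGORIES)
  if (anyNA(r)) stop("unknown consequence category: ",
                     paste(unique(category[is.na(r)]), collapse = ", "))
  r
}

# point classification of a genomic position against one transcript;
# returns "cds" for coding positions (caller resolves the amino-acid change)
point_category <- function(tx, pos) {
  ex <- tx$exons
  if (pos < ex[1, 1] || pos > ex[nrow(ex), 2]) return("intergenic")
  hit <- which(pos >= ex[, 1] & pos <= ex[, 2])
  if (!length(hit)) {
    j <- max(which(ex[, 2] < pos))          # intron between exon j and j+1
    istart <- ex[j, 2] + 1L; iend <- ex[j + 1L, 1] - 1L
    if (pos <= istart + 1L || pos >= iend - 1L) return("essential_splice_site")
    return("intronic")
  }
  if (tx$biotype != "protein_coding") return("noncoding_transcript")
  in_cds <- any(pos >= tx$cds[, 1] & pos <= tx$cds[, 2])
  if (in_cds) return("cds")
  cds_lo <- min(tx$cds[, 1]); cds_hi <- max(tx$cds[, 2])
  upstream <- pos < cds_lo
  if (tx$strand == "+") if (upstream) "utr5" else "utr3"
  else if (upstream) "utr3" else "utr5"
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

cds_sequence <- function(tx, reference) {
  parts <- vapply(seq_len(nrow(tx$cds)), function(j)
    as.character(Biostrings::subseq(reference[[tx$chrom]], tx$cds[j, 1], tx$cds[j, 2])),
    character(1))
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

# consequence of a single-base substitution against one transcript
snv_consequence_tx <- function(tx, reference, pos, ref, alt) {
  cat <- point_category(tx, pos)
  if (cat != "cds")
    return(list(category = cat, detail = "", residue = NA_integer_))
  cdspos <- cds_positions(tx)
  idx <- match(pos, cdspos)
  codon_i <- (idx - 1L) %/% 3L + 1L
  off <- (idx - 1L) %% 3L + 1L
  codon_pos <- cdspos[(codon_i - 1L) * 3L + 1:3]
  bases <- vapply(codon_pos, function(p) ref_base(reference, tx$chrom, p), character(1))
  if (tx$strand == "-") bases <- vapply(bases, comp_base, character(1))
  genome_ref <- ref_base(reference, tx$chrom, pos)
  if (toupper(genome_ref) != toupper(ref))
    stop("reference mismatch at ", tx$chrom, ":", pos, " (reference has ",
         genome_ref, ", call says ", ref, ")")
  ref_codon <- paste(bases, collapse = "")
  alt_tx <- if (tx$strand == "-") comp_base(alt) else toupper(alt)
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt_tx
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  category <-
    if (identical(aa_ref, aa_alt)) "synonymous"
    else if (identical(aa_alt, "*")) "stop_gained"
    else if (identical(aa_ref, "*")) "stop_lost"
    else "nonsynonymous"
  list(category = category, detail = paste0(aa_ref, ":", aa_alt),
       residue = codon_i)
}

# consequence of a short indel against one transcript
indel_consequence_tx <- function(tx, reference, pos, ref, alt, variant_class) {
  chrom_len <- Biostrings::width(reference[names(reference) == tx$chrom])
  affected <- if (variant_class == "insertion")
    c(pos, min(pos + 1L, chrom_len)) else (pos + 1L):(pos + nchar(ref) - 1L)
  cats <- vapply(affected, function(p) point_category(tx, p), character(1))
  if (!any(cats == "cds")) {
    if (any(cats == "essential_splice_site"))
      return(list(category = "essential_splice_site", detail = "", residue = NA_integer_))
    best <- cats[which.min(severity_rank(cats))]
    return(list(category = best, detail = "", residue = NA_integer_))
  }
  net <- nchar(alt) - nchar(ref)
  cds_hit <- sum(cats == "cds")
  if (net %% 3L != 0L ||
      (variant_class == "deletion" && cds_hit %% 3L != 0L))
    return(list(category = "frameshift", detail = "", residue = NA_integer_))
  # in-frame: rebuild the mutant CDS and look for an introduced in-frame stop
  cdspos <- cds_positions(tx)
  ref_cds <- cds_sequence(tx, reference)
  chars <- strsplit(ref_cds, "")[[1]]
  if (variant_class == "deletion") {
    drop_idx <- stats::na.omit(match(affected, cdspos))
    mut_cds <- paste(chars[-drop_idx], collapse = "")
  } else {
    ins <- substring(alt, 2L)
    if (tx$strand == "+") {
      at <- match(pos, cdspos)                       # insert after this index
      if (is.na(at)) at <- match(pos + 1L, cdspos) - 1L
      ins_tx <- ins
    } else {
      at <- match(pos + 1L, cdspos)
      if (is.na(at)) at <- match(pos, cdspos) - 1L
      ins_tx <- revcomp(ins)
    }
    mut_cds <- paste0(substring(ref_cds, 1L, at), ins_tx,
                      substring(ref_cds, at + 1L))
  }
  prot <- function(s) strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(s), if.fuzzy.codon = "X",
                           no.init.codon = TRUE)), "")[[1]]
  first_internal_stop <- function(p) {
    hit <- which(p == "*")
    hit <- hit[hit < length(p)]
    if (length(hit)) hit[1] else Inf
  }
  ref_stop <- first_internal_stop(prot(ref_cds))
  mut_prot <- prot(mut_cds)
  mut_stop <- first_internal_stop(mut_prot)
  if (mut_stop < ref_stop) {
    ref_aa <- prot(ref_cds)
    before <- if (mut_stop <= length(ref_aa)) ref_aa[mut_stop] else "-"
    return(list(category = "stop_gained", detail = paste0(before, ":*"),
                residue = as.integer(mut_stop)))
  }
  list(category = "inframe_indel", detail = "", residue = NA_integer_)
}

#' Annotate variant calls with their most severe consequence
#'
#' Classifies every call against every overlapping transcript and reports the
#' single most severe consequence (ties broken by lexicographic transcript
#' id). SNVs in coding sequence are resolved codon-aware: the codon is
#' extracted in transcript orientation (reverse-complemented on the minus
#' strand), mutated and translated, yielding `synonymous`, `nonsynonymous`,
#' `stop_gained` or `stop_lost` with an amino-acid `detail` of the form
#' `"Y:C"` and a 1-based `residue` index. Coding indels are `frameshift` when
#' the length change is not a multiple of 3, otherwise `inframe_indel` unless
#' the rebuilt coding sequence gains a premature in-frame stop
#' (`stop_gained`). Variants in the first or last two bases of an intron are
#' `essential_splice_site` (this outranks `intronic` and applies to all
#' introns, UTR introns included); exonic positions of noncoding transcripts
#' are `noncoding_transcript`; positions outside every transcript are
#' `intergenic`.
#'
#' @param calls a [variant_calls()] table.
#' @param models a [gene_model_set()].
#' @return `calls` with columns `gene`, `transcript_id`, `category`, `detail`,
#'   `residue` appended (class `annotated_variants`).
#' @export
annotate_variants <- function(calls, models) {
  n <- nrow(calls)
  gene <- transcript <- detail <- character(n)
  category <- character(n)
  residue <- integer(n)
  seqlen <- stats::setNames(Biostrings::width(models$reference),
                            names(models$reference))
  for (i in seq_len(n)) {
    chrom <- calls$chrom[i]; pos <- calls$pos[i]
    if (!chrom %in% names(seqlen))
      stop("coordinate error: chromosome '", chrom, "' not in reference")
    last <- pos + max(0L, nchar(calls$ref[i]) - 1L)
    if (last > seqlen[[chrom]])
      stop("coordinate error: ", chrom, ":", pos, " beyond reference length ",
           seqlen[[chrom]])
    txs <- Filter(function(tx) tx$chrom == chrom, models$transcripts)
    hits <- list()
    for (tx in txs) {
      res <- if (calls$variant_class[i] == "snv")
        snv_consequence_tx(tx, models$reference, pos, calls$ref[i], calls$alt[i])
      else
        indel_consequence_tx(tx, models$reference, pos, calls$ref[i],
                             calls$alt[i], calls$variant_class[i])
      if (res$category != "intergenic")
        hits[[length(hits) + 1L]] <- c(res, list(tx = tx))
    }
    if (!length(hits)) {
      gene[i] <- ""; transcript[i] <- ""; category[i] <- "intergenic"
      detail[i] <- ""; residue[i] <- NA_integer_
    } else {
      ranks <- vapply(hits, function(h) severity_rank(h$category), integer(1))
      ids <- vapply(hits, function(h) h$tx$transcript_id, character(1))
      best <- hits[[order(ranks, ids)[1]]]
      gene[i] <- best$tx$gene_name; transcript[i] <- best$tx$transcript_id
      category[i] <- best$category; detail[i] <- best$detail
      residue[i] <- best$residue
    }
  }
  out <- cbind(as.data.frame(calls),
               data.frame(gene = gene, transcript_id = transcript,
                          category = category, detail = detail,
                          residue = residue, stringsAsFactors = FALSE))
  class(out) <- c("annotated_variants", "data.frame")
  out
}

#' @rdname annotate_variants
#' @details `annotate_snv()` and `annotate_indel()` are single-call
#'   conveniences over [annotate_variants()]; `annotate_snv()` requires an
#'   SNV, `annotate_indel()` an insertion or deletion.
#' @param v a one-row [variant_calls()] table.
#' @export
annotate_snv <- function(v, models) {
  stopifnot(nrow(v) == 1L, v$variant_class == "snv")
  annotate_variants(v, models)
}

#' @rdname annotate_variants
#' @export
annotate_indel <- function(v, models) {
  stopifnot(nrow(v) == 1L, v$variant_class %in% c("insertion", "deletion"))
  annotate_variants(v, models)
}

#' Write an annotation table as TSV
#'
#' Fixed column order: chrom, pos, ref, alt, gene, transcript, category,
#' detail.
#'
#' @param annotated an `annotated_variants` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotated, path) {
  out <- annotated[, c("chrom", "pos", "ref", "alt", "gene", "transcript_id",
                       "category", "detail")]
  names(out)[6] <- "transcript"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
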