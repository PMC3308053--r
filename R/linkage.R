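LOCATION_LABELS <- c(
  stop_gained = "Exonic", stop_lost = "Exonic", frameshift = "Exonic",
  nonsynonymous = "Exonic", inframe_indel = "Exonic", synonymous = "Exonic",
  essential_splice_site = "Splice site (intronic)",
  utr5 = "5' UTR", utr3 = "3' UTR", noncoding_transcript = "Noncoding",
  intronic = "Intronic", intergenic = "Intergenic")

CODING_CATEGORIES <- c("stop_gained", "stop_lost", "frameshift",
                       "nonsynonymous", "inframe_indel", "synonymous")

consequence_note <- function(category, detail) {
  switch(category,
    frameshift = "Frameshift leading to truncation of protein",
    stop_gained = if (nzchar(detail))
      paste0("Gain of stop codon (", detail, ")") else "Gain of stop codon",
    stop_lost = "Loss of stop codon",
    nonsynonymous = paste0("Nonsynonymous: ", detail),
    synonymous = paste0("Synonymous: ", detail),
    inframe_indel = "In-frame indel",
    "")
}

#' Linkage-exclusion report around a candidate
#'
#' A candidate variant can only be declared causal if no alternative
#' plausible mutation travels with it. This enumerates every other private
#' call (SNVs and indels) on the candidate's chromosome, annotates each via
#' the consequence module, and splits them into a window of `window_bp`
#' absolute distance around the candidate versus the remainder of the
#' chromosome. Coding entries (exonic stop / frameshift / nonsynonymous /
#' in-frame changes) are the ones that could constitute alternative causal
#' lesions and are flagged.
#'
#' @param candidate one-row [variant_calls()] table (or a list with `chrom`,
#'   `pos`, `alt`).
#' @param calls a [variant_calls()] table of post-subtraction private calls,
#'   indels included.
#' @param models a [gene_model_set()].
#' @param window_bp physical window, full closed interval of +/- `window_bp`
#'   around the candidate position (default 10 Mb).
#' @return object of class `linkage_report`: list with `candidate_key`,
#'   `window_bp` and an `entries` data.frame (gene, position, variant class,
#'   zygosity, location label, consequence category/note, `in_window`,
#'   `coding`).
#' @export
build_linkage_report <- function(candidate, calls, models, window_bp = 1e7) {
  ckey <- paste(candidate$chrom, candidate$pos, candidate$alt, sep = ":")
  same <- calls[calls$chrom == candidate$chrom &
                  variant_key(calls) != ckey, , drop = FALSE]
  if (nrow(same)) {
    ann <- annotate_variants(same, models)
    entries <- data.frame(
      gene = ann$gene, position = ann$pos, variant_class = ann$variant_class,
      zygosity = ifelse(ann$genotype == "het", "Het", "Hom"),
      location = unname(LOCATION_LABELS[ann$category]),
      category = ann$category,
      note = vapply(seq_len(nrow(ann)), function(i)
        consequence_note(ann$category[i], ann$detail[i]), character(1)),
      in_window = abs(ann$pos - candidate$pos) <= window_bp,
      coding = ann$category %in% CODING_CATEGORIES,
      stringsAsFactors = FALSE)
    entries <- entries[order(!entries$in_window, entries$position), , drop = FALSE]
    rownames(entries) <- NULL
  } else {
    entries <- data.frame(gene = character(), position = integer(),
                          variant_class = character(), zygosity = character(),
                          location = character(), category = character(),
                          note = character(), in_window = logical(),
                          coding = logical(), stringsAsFactors = FALSE)
  }
  structure(list(candidate_key = ckey, window_bp = window_bp,
                 entries = entries),
            class = "linkage_report")
}

#' @exportS3Method base::print
print.linkage_report <- function(x, ...) {
  cat("Linkage exclusion around", x$candidate_key,
      sprintf("(window +/- %.1f Mb)\n", x$window_bp / 1e6))
  cat(sprintf("  in window: %d entries, %d coding\n",
              sum(x$entries$in_window), sum(x$entries$in_window & x$entries$coding)))
  cat(sprintf("  rest of chromosome: %d entries, %d coding\n",
              sum(!x$entries$in_window),
              sum(!x$entries$in_window & x$entries$coding)))
  invisible(x)
}

#' Count coding entries inside the linkage window
#'
#' @param report a `linkage_report`.
#' @return integer count.
#' @export
count_coding_in_window <- function(report) {
  sum(report$entries$in_window & report$entries$coding)
}

#' Count final candidates on a chromosome
#'
#' @param candidates a [variant_calls()] table of final candidates.
#' @param chrom chromosome name.
#' @return integer count.
#' @export
count_candidates_on_chromosome <- function(candidates, chrom) {
  sum(candidates$chrom == as.character(chrom))
}

#' Write a linkage report as TSV
#'
#' @param report a `linkage_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_linkage_report <- function(report, path) {
  utils::write.table(report$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
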