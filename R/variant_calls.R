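#' Construct a variant-call table
#'
#' The atom of the filtration funnel: one called difference from the reference
#' genome (SNV or short indel), with its genotype and the per-call quality
#' metrics the funnel filters on. Calls are stored VCF-style: indels are
#' anchored on the base before the event, coordinates are 1-based, and an
#' allele pair is always a difference from the reference (`hom_ref` never
#' appears in a call list).
#'
#' @param chrom character chromosome names.
#' @param pos integer 1-based position of the first affected reference base.
#' @param ref,alt reference and alternate allele strings (non-empty,
#'   `ref != alt`).
#' @param genotype `"het"` or `"hom_alt"`.
#' @param consensus_quality,snp_quality,mapping_quality phred-scaled scores
#'   (`NA` = unknown; unknown values fail quality filters closed by default).
#' @param read_depth non-negative read depth (`NA` = unknown).
#' @return A `data.frame` of class `variant_calls` with one row per call and a
#'   derived `variant_class` column (`snv`, `insertion` or `deletion`).
#' @export
variant_calls <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          genotype = character(),
                          consensus_quality = NA_real_,
                          snp_quality = NA_real_,
                          mapping_quality = NA_real_,
                          read_depth = NA_real_) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    genotype = as.character(genotype),
    consensus_quality = rep_len(as.numeric(consensus_quality), n),
    snp_quality = rep_len(as.numeric(snp_quality), n),
    mapping_quality = rep_len(as.numeric(mapping_quality), n),
    read_depth = rep_len(as.numeric(read_depth), n),
    stringsAsFactors = FALSE
  )
  df$variant_class <- variant_class(df$ref, df$alt)
  validate_variant_calls(df)
}

variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

validate_variant_calls <- function(df) {
  if (nrow(df)) {
    stopifnot(all(df$pos >= 1L), all(nchar(df$ref) > 0L), all(nchar(df$alt) > 0L))
    if (any(df$ref == df$alt))
      stop("variant_calls: ref and alt must differ")
    if (!all(df$genotype %in% c("het", "hom_alt")))
      stop("variant_calls: genotype must be 'het' or 'hom_alt' (hom_ref is never stored)")
    qm <- c("consensus_quality", "snp_quality", "mapping_quality", "read_depth")
    for (m in qm)
      if (any(!is.na(df[[m]]) & df[[m]] < 0)) stop("variant_calls: negative ", m)
    same_len <- nchar(df$ref) == nchar(df$alt)
    if (any(same_len & nchar(df$ref) > 1L))
      stop("variant_calls: block substitutions are not supported")
  }
  class(df) <- c("variant_calls", "data.frame")
  df
}

#' Matching key for set-subtraction steps
#'
#' All subtraction operations in the funnel match on (chrom, pos, alt) only:
#' genotype and quality metrics never enter the key, so two calls that differ
#' only in zygosity or scores collide. With `by_position = TRUE` the key drops
#' the allele and matches on position alone.
#'
#' @param v a `variant_calls` table (or any data.frame with `chrom`, `pos`,
#'   `alt` columns).
#' @param by_position match on position only, ignoring the alternate allele.
#' @return character vector of keys, one per call.
#' @export
variant_key <- function(v, by_position = FALSE) {
  if (!nrow(v)) return(character())
  if (by_position) paste(v$chrom, v$pos, sep = ":")
  else paste(v$chrom, v$pos, v$alt, sep = ":")
}

norm_het_pair <- function(a, b) paste(sort(c(a, b)), collapse = "/")

#' Read variant calls from a single-sample VCF
#'
#' Parses a VCF 4.2 file into a [variant_calls()] table. Quality metrics are
#' taken from `QUAL` (SNP quality) and the INFO keys `CQ` (consensus quality),
#' `MQ` (RMS mapping quality) and `DP` (read depth); absent metrics become
#' `NA`. Each ALT allele of a multi-allelic record yields its own call, with
#' the genotype derived from the first sample's `GT` field; `0/0` records are
#' dropped, so the returned list contains only differences from the reference.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @return a [variant_calls()] table, in file order.
#' @export
read_variant_calls <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) return(variant_calls())
  gt_raw <- if (ncol(vcf@gt) >= 2L) vcf@gt[, 2L] else
    stop("VCF '", path, "' has no sample column")
  num <- function(x) suppressWarnings(as.numeric(x))
  cq <- num(vcfR::extract.info(vcf, "CQ"))
  mq <- num(vcfR::extract.info(vcf, "MQ"))
  dp <- num(vcfR::extract.info(vcf, "DP"))
  qual <- num(fix[, "QUAL"])

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gt <- strsplit(sub(":.*", "", gt_raw[i]), "[/|]")[[1]]
    if (length(gt) != 2L || anyNA(suppressWarnings(as.integer(gt))))
      stop("VCF '", path, "' line for ", fix[i, "CHROM"], ":", fix[i, "POS"],
           ": unsupported GT ploidy '", gt_raw[i], "'", call. = FALSE)
    gt <- as.integer(gt)
    if (all(gt == 0L)) next   # hom-ref: not a difference from reference
    rows <- lapply(seq_along(alts), function(a) {
      n_allele <- sum(gt == a)
      if (n_allele == 0L) return(NULL)
      data.frame(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                 ref = toupper(fix[i, "REF"]), alt = toupper(alts[a]),
                 genotype = if (n_allele == 2L) "hom_alt" else "het",
                 consensus_quality = cq[i], snp_quality = qual[i],
                 mapping_quality = mq[i], read_depth = dp[i],
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  df <- do.call(rbind, out)
  if (is.null(df)) return(variant_calls())
  df$variant_class <- variant_class(df$ref, df$alt)
  rownames(df) <- NULL
  validate_variant_calls(df)
}

#' Write variant calls as a single-sample VCF
#'
#' Inverse of [read_variant_calls()]: `QUAL` carries the SNP quality and INFO
#' keys `CQ`/`MQ`/`DP` the remaining metrics; genotypes are written as `0/1`
#' (het) or `1/1` (hom). Row order is preserved, so write-then-read round
#' trips the table.
#'
#' @param calls a [variant_calls()] table.
#' @param path output path.
#' @param sample_name sample column name.
#' @param header_extra optional character vector of extra `##` header lines
#'   (the simulator records its seed here).
#' @return `path`, invisibly.
#' @export
write_variant_calls <- function(calls, path, sample_name = "SAMPLE",
                                header_extra = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=enufunnel",
    header_extra,
    "##INFO=<ID=CQ,Number=1,Type=Float,Description=\"Consensus quality\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  fmt <- function(x) ifelse(is.na(x), NA, format(x, trim = TRUE, scientific = FALSE))
  info <- vapply(seq_len(nrow(calls)), function(i) {
    kv <- c(CQ = fmt(calls$consensus_quality[i]), MQ = fmt(calls$mapping_quality[i]),
            DP = fmt(calls$read_depth[i]))
    kv <- kv[!is.na(kv)]
    if (!length(kv)) "." else paste(names(kv), kv, sep = "=", collapse = ";")
  }, character(1))
  lines <- if (nrow(calls)) paste(
    calls$chrom, calls$pos, ".", calls$ref, calls$alt,
    ifelse(is.na(calls$snp_quality), ".", fmt(calls$snp_quality)), ".",
    info, "GT", ifelse(calls$genotype == "hom_alt", "1/1", "0/1"),
    sep = "\t") else character()
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a validation-genotype table
#'
#' Capillary-style re-sequencing results used to adjudicate funnel candidates:
#' for each variant key, the re-sequenced call in the background strain and in
#' the mutant. Calls are genotype strings (`"T"`, `"C/T"`) or the special
#' tokens `Deletion` / `Insertion` (the trace showed an indel, i.e. the SNV
#' call was a misalignment artifact) or `NA` (no readable trace).
#'
#' @param path TSV with columns `chrom, pos, ref, alt, background_call,
#'   mutant_call`.
#' @return data.frame of class `validation_genotypes`.
#' @export
read_validation_genotypes <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = c("NA", ""),
                          comment.char = "#")
  need <- c("chrom", "pos", "ref", "alt", "background_call", "mutant_call")
  if (!all(need %in% names(df)))
    stop("validation table must have columns: ", paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos)
  class(df) <- c("validation_genotypes", "data.frame")
  df
}

#' Read a cohort genotype/phenotype table
#'
#' One row per animal: the cross it came from, its genotype at the candidate
#' locus, sex, and its hearing threshold (the quietest click, in dB SPL, that
#' evoked an auditory brainstem response).
#'
#' @param path TSV with columns `animal_id, cross_type, genotype, sex,
#'   click_threshold`.
#' @param threshold_range plausible range for click thresholds; values outside
#'   it are rejected.
#' @return data.frame of class `cohort_records`.
#' @export
read_cohort <- function(path, threshold_range = c(0, 100)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_cohort(df, threshold_range)
}

validate_cohort <- function(df, threshold_range = c(0, 100)) {
  need <- c("animal_id", "cross_type", "genotype", "sex", "click_threshold")
  if (!all(need %in% names(df)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$cross_type %in% c("het_x_het", "het_x_wt")))
    stop("unknown cross_type value")
  if (!all(df$genotype %in% c("wt", "het", "hom")))
    stop("unknown genotype value in cohort table")
  if (!all(df$sex %in% c("m", "f", "unknown")))
    stop("unknown sex value")
  thr <- as.numeric(df$click_threshold)
  if (any(!is.finite(thr)) ||
      any(thr < threshold_range[1] | thr > threshold_range[2]))
    stop("click_threshold outside plausible range [",
         threshold_range[1], ", ", threshold_range[2], "] dB SPL")
  df$click_threshold <- thr
  class(df) <- c("cohort_records", "data.frame")
  df
}
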