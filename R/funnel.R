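#' Quality thresholds for the funnel
#'
#' Boundary semantics follow the published operators: SNP quality is an
#' inclusive lower limit (kept when `>= min_snp_quality`), while mapping
#' quality and read depth are strict (kept when `> min_mapping_quality` and
#' `> min_read_depth`). Consensus quality is deliberately never filtered on;
#' it is carried through for reporting only. Calls whose metric is unknown
#' (`NA`) fail the relevant stage unless `fail_open = TRUE`.
#'
#' @param min_snp_quality inclusive lower limit on SNP quality (default 20).
#' @param min_mapping_quality exclusive lower limit on RMS mapping quality
#'   (default 45).
#' @param min_read_depth exclusive lower limit on read depth (default 10).
#' @param fail_open if `TRUE`, calls with unknown metrics pass the filter.
#' @return object of class `quality_thresholds`.
#' @export
quality_thresholds <- function(min_snp_quality = 20, min_mapping_quality = 45,
                               min_read_depth = 10, fail_open = FALSE) {
  stopifnot(min_snp_quality >= 0, min_mapping_quality >= 0, min_read_depth >= 0)
  structure(list(min_snp_quality = min_snp_quality,
                 min_mapping_quality = min_mapping_quality,
                 min_read_depth = min_read_depth,
                 fail_open = isTRUE(fail_open)),
            class = "quality_thresholds")
}

#' Remove calls shared with the background strain
#'
#' Drops every mutant call whose (chrom, pos, alt) key also occurs in the
#' un-mutagenized background strain's call set: shared calls are strain-vs-
#' reference differences, not induced mutations. Order is preserved.
#'
#' @param mutant,background [variant_calls()] tables.
#' @param by_position match on position only instead of position + allele.
#' @return the private-to-mutant subset of `mutant`.
#' @export
subtract_shared <- function(mutant, background, by_position = FALSE) {
  keep <- !(variant_key(mutant, by_position) %in%
              variant_key(background, by_position))
  mutant[keep, , drop = FALSE]
}

#' Remove calls present in known-variant panels
#'
#' Drops calls whose key appears in any panel (e.g. dbSNP, inbred-strain
#' resequencing catalogues): such variants segregate in other strains and
#' cannot be the induced mutation.
#'
#' @param calls a [variant_calls()] table.
#' @param panels list of [variant_calls()] tables.
#' @inheritParams subtract_shared
#' @return the subset of `calls` absent from every panel.
#' @export
subtract_known <- function(calls, panels, by_position = FALSE) {
  panel_keys <- unlist(lapply(panels, variant_key, by_position = by_position))
  keep <- !(variant_key(calls, by_position) %in% panel_keys)
  calls[keep, , drop = FALSE]
}

#' Apply the two quality-filter stages
#'
#' Stage A keeps calls with `snp_quality >= min_snp_quality`; stage B further
#' keeps calls with `mapping_quality > min_mapping_quality` and
#' `read_depth > min_read_depth`. Unknown metrics fail closed unless the
#' thresholds were built with `fail_open = TRUE`.
#'
#' @param calls a [variant_calls()] table.
#' @param thresholds a [quality_thresholds()] object.
#' @return list with elements `stage_a` and `stage_b` (each a subset of
#'   `calls`, order preserved).
#' @export
apply_quality_filters <- function(calls, thresholds = quality_thresholds()) {
  cmp <- function(x, test) {
    ok <- test(x)
    ok[is.na(ok)] <- thresholds$fail_open
    ok
  }
  a_keep <- cmp(calls$snp_quality, function(x) x >= thresholds$min_snp_quality)
  stage_a <- calls[a_keep, , drop = FALSE]
  b_keep <- cmp(stage_a$mapping_quality,
                function(x) x > thresholds$min_mapping_quality) &
            cmp(stage_a$read_depth, function(x) x > thresholds$min_read_depth)
  list(stage_a = stage_a, stage_b = stage_a[b_keep, , drop = FALSE])
}

#' Remove intronic and intergenic variants
#'
#' Essential-splice-site calls are retained even though their coordinates are
#' intronic.
#'
#' @param annotated an `annotated_variants` table.
#' @return subset without `intronic` or `intergenic` calls.
#' @export
remove_noncoding <- function(annotated) {
  annotated[!annotated$category %in% c("intronic", "intergenic"), , drop = FALSE]
}

#' Select candidate causal SNVs
#'
#' Keeps SNVs predicted to gain or lose a stop codon, change an amino acid, or
#' hit an essential splice site. Indels and the remaining categories (UTR,
#' synonymous, noncoding transcript) are excluded here; callers keep indels in
#' a side channel for linkage exclusion.
#'
#' @param annotated an `annotated_variants` table.
#' @return the candidate subset.
#' @export
select_candidates <- function(annotated) {
  keep <- annotated$variant_class == "snv" &
    annotated$category %in% c("stop_gained", "stop_lost", "nonsynonymous",
                              "essential_splice_site")
  annotated[keep, , drop = FALSE]
}

#' Flag candidates close to indel calls
#'
#' The dominant false-positive mode of the funnel: small indels make the SNP
#' caller misread SNVs on either side of the event. Each candidate is flagged
#' when any indel call (typically pooled from both samples' raw calls) lies
#' within `window_bp` of it on the same chromosome, measured between anchored
#' positions.
#'
#' @param candidates a (possibly annotated) [variant_calls()] table.
#' @param indel_calls a [variant_calls()] table of insertion/deletion calls.
#' @param window_bp flagging distance in bp (default 20).
#' @return data.frame with one row per candidate: `candidate_key`,
#'   `nearest_indel_key`, `distance_bp`, `flagged`.
#' @export
flag_indel_proximal <- function(candidates, indel_calls, window_bp = 20) {
  indels <- indel_calls[indel_calls$variant_class %in%
                          c("insertion", "deletion"), , drop = FALSE]
  n <- nrow(candidates)
  nearest <- character(n); dist <- rep(Inf, n)
  for (i in seq_len(n)) {
    same <- indels[indels$chrom == candidates$chrom[i], , drop = FALSE]
    if (!nrow(same)) next
    d <- abs(same$pos - candidates$pos[i])
    j <- which.min(d)
    nearest[i] <- variant_key(same[j, , drop = FALSE])
    dist[i] <- d[j]
  }
  data.frame(candidate_key = variant_key(candidates),
             nearest_indel_key = nearest, distance_bp = dist,
             flagged = dist <= window_bp, stringsAsFactors = FALSE)
}

norm_validation_call <- function(x) {
  if (is.na(x) || !nzchar(x)) return(list(kind = "missing", alleles = character()))
  up <- toupper(trimws(x))
  if (up %in% c("DELETION", "INSERTION"))
    return(list(kind = tolower(up), alleles = character()))
  alleles <- toupper(strsplit(up, "/", fixed = TRUE)[[1]])
  if (length(alleles) == 1L) alleles <- rep(alleles, 2L)
  list(kind = "call", alleles = sort(alleles))
}

#' Adjudicate candidates against validation genotypes
#'
#' A candidate is confirmed iff the validation re-sequencing of the mutant
#' contains the alternate allele, the background strain's does not, and
#' neither trace showed an indel or failed. Everything else is labelled a
#' false positive with a reason: `indel_misalignment` (either trace was an
#' indel), `missing_data` (no readable trace), `identical_to_background`
#' (the two traces agree), or `miscalled_zygosity` (traces differ but do not
#' support a mutant-specific alternate allele).
#'
#' @param candidates a [variant_calls()] or `annotated_variants` table.
#' @param validation a `validation_genotypes` table (see
#'   [read_validation_genotypes()]); every candidate must have a record.
#' @return `candidates` with logical `confirmed` and character `reason`
#'   columns appended (`reason` is `NA` for confirmed calls).
#' @export
confirm_with_validation <- function(candidates, validation) {
  vkey <- paste(validation$chrom, validation$pos, validation$alt, sep = ":")
  ckey <- variant_key(candidates)
  idx <- match(ckey, vkey)
  if (anyNA(idx))
    stop("validation-completeness error: no validation record for ",
         paste(ckey[is.na(idx)], collapse = ", "))
  n <- nrow(candidates)
  confirmed <- logical(n); reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    bg <- norm_validation_call(validation$background_call[idx[i]])
    mu <- norm_validation_call(validation$mutant_call[idx[i]])
    alt <- toupper(candidates$alt[i])
    if (bg$kind %in% c("deletion", "insertion") ||
        mu$kind %in% c("deletion", "insertion")) {
      reason[i] <- "indel_misalignment"
    } else if (bg$kind == "missing" || mu$kind == "missing") {
      reason[i] <- "missing_data"
    } else if (identical(bg$alleles, mu$alleles)) {
      reason[i] <- "identical_to_background"
    } else if (alt %in% mu$alleles && !(alt %in% bg$alleles)) {
      confirmed[i] <- TRUE
    } else {
      reason[i] <- "miscalled_zygosity"
    }
  }
  out <- cbind(as.data.frame(candidates),
               data.frame(confirmed = confirmed, reason = reason,
                          stringsAsFactors = FALSE))
  class(out) <- class(candidates)
  out
}

#' Count heterozygous candidates
#'
#' Under a dominant model the induced mutation is expected as a heterozygote
#' in the sequenced mutant, so the het count among surviving candidates is a
#' consistency check (it informs reporting, not filtering: homozygous calls
#' are retained through selection).
#'
#' @param candidates a [variant_calls()] table.
#' @return integer count of `genotype == "het"` calls.
#' @export
count_heterozygous <- function(candidates) {
  sum(candidates$genotype == "het")
}

as_calls_input <- function(x) {
  if (is.character(x)) read_variant_calls(x) else x
}

#' Run the full candidate filtration funnel
#'
#' Executes the cascade in order: load both call sets, subtract calls shared
#' with the background strain, subtract known-variant panels, apply the SNP
#' quality stage then the mapping-quality/read-depth stage, annotate
#' consequences, remove intronic and intergenic calls, select stop /
#' nonsynonymous / essential-splice SNVs, and (optionally) adjudicate against
#' validation genotypes. Survivor counts are recorded after each step; indels
#' surviving the quality stages are diverted to a side channel (they are
#' excluded from candidate selection but preserved for linkage exclusion),
#' and every candidate is flagged for proximity to any raw indel call from
#' either sample.
#'
#' @param mutant,background [variant_calls()] tables or VCF paths.
#' @param panels list of [variant_calls()] tables or VCF paths.
#' @param models a [gene_model_set()].
#' @param thresholds a [quality_thresholds()] object.
#' @param validation optional `validation_genotypes` table or TSV path.
#' @param indel_window_bp indel-proximity flagging window (default 20).
#' @inheritParams subtract_shared
#' @return object of class `funnel_report`: list with `steps` (data.frame of
#'   `step`, `survivors`), `candidates` (annotated, with `indel_flagged`
#'   column), `indels` (annotated side channel), `flags`, and -- when
#'   validation is supplied -- `adjudicated` and `confirmed`.
#' @export
run_funnel <- function(mutant, background, panels = list(), models,
                       thresholds = quality_thresholds(), validation = NULL,
                       indel_window_bp = 20, by_position = FALSE) {
  mutant <- as_calls_input(mutant)
  background <- as_calls_input(background)
  panels <- lapply(panels, as_calls_input)
  if (is.character(validation)) validation <- read_validation_genotypes(validation)

  steps <- list()
  tally <- function(name, x) steps[[length(steps) + 1L]] <<-
    data.frame(step = name, survivors = nrow(x), stringsAsFactors = FALSE)

  tally("different_from_reference", mutant)
  private <- subtract_shared(mutant, background, by_position = by_position)
  tally("not_shared_with_background", private)
  private <- subtract_known(private, panels, by_position = by_position)
  tally("not_in_known_panels", private)
  qf <- apply_quality_filters(private, thresholds)
  tally("snp_quality_filter", qf$stage_a)
  tally("mapping_quality_and_depth", qf$stage_b)
  annotated <- annotate_variants(qf$stage_b, models)
  coding <- remove_noncoding(annotated)
  tally("remove_intronic_intergenic", coding)
  candidates <- select_candidates(coding)
  tally("select_stop_nonsyn_splice", candidates)

  indels <- annotated[annotated$variant_class %in% c("insertion", "deletion"), ,
                      drop = FALSE]
  raw_indels <- rbind(
    mutant[mutant$variant_class != "snv", , drop = FALSE],
    background[background$variant_class != "snv", , drop = FALSE])
  flags <- flag_indel_proximal(candidates, raw_indels, window_bp = indel_window_bp)
  candidates$indel_flagged <- flags$flagged

  report <- list(steps = do.call(rbind, steps), candidates = candidates,
                 indels = indels, flags = flags,
                 thresholds = thresholds)
  if (!is.null(validation)) {
    adjudicated <- confirm_with_validation(candidates, validation)
    report$adjudicated <- adjudicated
    report$confirmed <- adjudicated[adjudicated$confirmed, , drop = FALSE]
    report$steps <- rbind(report$steps,
                          data.frame(step = "confirmed_by_validation",
                                     survivors = nrow(report$confirmed),
                                     stringsAsFactors = FALSE))
  }
  class(report) <- "funnel_report"
  report
}

#' @exportS3Method base::print
print.funnel_report <- function(x, ...) {
  cat("Variant filtration funnel\n")
  for (i in seq_len(nrow(x$steps)))
    cat(sprintf("  %-28s %8d\n", x$steps$step[i], x$steps$survivors[i]))
  cat(nrow(x$indels), "indel(s) in side channel;",
      sum(x$candidates$indel_flagged), "candidate(s) flagged indel-proximal\n")
  invisible(x)
}

#' Write funnel outputs as TSV files
#'
#' Emits `funnel_report.tsv` (step, survivors), `candidates.tsv` and
#' `indels.tsv` into `dir`.
#'
#' @param report a `funnel_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_funnel_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  w(report$steps, "funnel_report.tsv")
  w(as.data.frame(if (!is.null(report$adjudicated)) report$adjudicated
                  else report$candidates), "candidates.tsv")
  w(as.data.frame(report$indels), "indels.tsv")
  invisible(dir)
}
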