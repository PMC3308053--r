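#' Published dearisch (Isl1) study tables
#'
#' Small curated tables from the dearisch mouse study -- an ENU-induced,
#' partially penetrant otitis media mutant on the C3HeB/FeJ background whose
#' causal lesion is the Isl1 Y71C missense change at 13:117098488 (T>C, het).
#' They are the desk-scale inputs for re-running the end of the published
#' analysis:
#'
#' * `dearisch_candidates()` -- the 23 candidate SNVs that survived the exome
#'   filtration funnel, with the mutant sample's genotype and quality metrics
#'   and the capillary re-sequencing calls for both strains
#'   (`background_call` = C3HeB/FeJ, `mutant_call` = dearisch).
#' * `dearisch_validation()` -- those capillary calls reshaped as a
#'   `validation_genotypes` table for [confirm_with_validation()].
#' * `dearisch_cross_counts()` -- offspring counts from the colony's
#'   intercross (het x het) and outcross (het x wt) matings, by genotype,
#'   hearing class and sex.
#' * `dearisch_cohort()` -- the same counts expanded to per-animal records via
#'   [cohort_from_counts()].
#'
#' @return see above; candidate rows carry the `variant_calls` columns plus
#'   `gene`, `category`, `detail` and the two validation columns.
#' @name dearisch_data
NULL

extdata <- function(f) system.file("extdata", f, package = "enufunnel",
                                   mustWork = TRUE)

#' @rdname dearisch_data
#' @export
dearisch_candidates <- function() {
  df <- utils::read.delim(extdata("dearisch_candidates.tsv"),
                          colClasses = c(chrom = "character", pos = "integer"),
                          na.strings = "NA", stringsAsFactors = FALSE)
  df$detail[is.na(df$detail)] <- ""
  df$variant_class <- variant_class(df$ref, df$alt)
  validate_variant_calls(df)
}

#' @rdname dearisch_data
#' @export
dearisch_validation <- function() {
  df <- dearisch_candidates()
  out <- df[, c("chrom", "pos", "ref", "alt", "background_call", "mutant_call")]
  class(out) <- c("validation_genotypes", "data.frame")
  out
}

#' @rdname dearisch_data
#' @export
dearisch_cross_counts <- function() {
  utils::read.delim(extdata("dearisch_cross_counts.tsv"),
                    stringsAsFactors = FALSE)
}

#' @rdname dearisch_data
#' @export
dearisch_cohort <- function() {
  cohort_from_counts(dearisch_cross_counts())
}
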