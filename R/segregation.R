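#' Classify hearing from a click threshold
#'
#' An animal is `affected` at a click threshold of 50 dB SPL or over and
#' `unaffected` at 30 dB SPL or below; the open interval between is
#' `intermediate` (mildly affected). The three classes partition the
#' threshold axis.
#'
#' @param threshold numeric click thresholds in dB SPL.
#' @param affected_min inclusive lower bound of the affected class (50).
#' @param unaffected_max inclusive upper bound of the unaffected class (30).
#' @return factor with levels `unaffected`, `intermediate`, `affected`.
#' @export
classify_hearing <- function(threshold, affected_min = 50, unaffected_max = 30) {
  stopifnot(all(is.finite(threshold)), unaffected_max < affected_min)
  cls <- ifelse(threshold >= affected_min, "affected",
                ifelse(threshold <= unaffected_max, "unaffected", "intermediate"))
  factor(cls, levels = c("unaffected", "intermediate", "affected"))
}

HEARING_LEVELS <- c("unaffected", "intermediate", "affected")
GENOTYPE_LEVELS <- c("wt", "het", "hom")

#' Genotype-by-hearing cross table
#'
#' Tabulates a cohort (one cross type at a time) by genotype and hearing
#' class, with row totals and row percentages of the cross total (percentages
#' are exact; use 1-decimal rounding for display).
#'
#' @param cohort a `cohort_records` table (see [read_cohort()]).
#' @param cross_type `"het_x_het"` or `"het_x_wt"`.
#' @inheritParams classify_hearing
#' @return object of class `cross_table`: list with `cross_type`, `counts`
#'   (genotype x class matrix), `row_totals`, `row_pct`, `col_totals`,
#'   `col_pct`, `n`.
#' @export
build_cross_table <- function(cohort, cross_type,
                              affected_min = 50, unaffected_max = 30) {
  cohort <- validate_cohort(as.data.frame(cohort))
  sub <- cohort[cohort$cross_type == cross_type, , drop = FALSE]
  cls <- classify_hearing(sub$click_threshold, affected_min, unaffected_max)
  geno <- factor(sub$genotype, levels = GENOTYPE_LEVELS)
  counts <- table(genotype = geno, hearing = cls)
  counts <- matrix(as.integer(counts), nrow = 3,
                   dimnames = list(GENOTYPE_LEVELS, HEARING_LEVELS))
  n <- sum(counts)
  row_totals <- rowSums(counts)
  col_totals <- colSums(counts)
  structure(list(cross_type = cross_type, counts = counts,
                 row_totals = row_totals,
                 row_pct = if (n > 0) 100 * row_totals / n else row_totals * NA,
                 col_totals = col_totals,
                 col_pct = if (n > 0) 100 * col_totals / n else col_totals * NA,
                 n = n),
            class = "cross_table")
}

#' @exportS3Method base::print
print.cross_table <- function(x, ...) {
  cat("Cross:", x$cross_type, " (n =", x$n, ")\n")
  m <- cbind(x$counts, total = x$row_totals,
             pct = round(x$row_pct, 1))
  print(m)
  cat("column totals:", paste(x$col_totals, collapse = " / "),
      " pct:", paste(round(x$col_pct, 1), collapse = " / "), "\n")
  invisible(x)
}

#' Penetrance of a genotype with a Wilson score interval
#'
#' Penetrance is the fraction of carriers of `genotype` whose hearing class
#' falls in `affected_classes` (by default the affected class only; add
#' `"intermediate"` to include mildly affected animals). The 95% confidence
#' interval is the Wilson score interval, which behaves well at the small
#' denominators typical of mouse colonies.
#'
#' @param cohort a `cohort_records` table (any mix of cross types; pool or
#'   pre-filter as desired).
#' @param genotype the carrier genotype (default `"het"`).
#' @param affected_classes hearing classes counted as penetrant.
#' @param conf_level confidence level (default 0.95).
#' @inheritParams classify_hearing
#' @return object of class `penetrance_estimate`: list with `numerator`,
#'   `denominator`, `proportion`, `conf_int` (lower, upper), and the classes
#'   used.
#' @export
penetrance <- function(cohort, genotype = "het",
                       affected_classes = "affected", conf_level = 0.95,
                       affected_min = 50, unaffected_max = 30) {
  stopifnot(all(affected_classes %in% HEARING_LEVELS))
  cohort <- validate_cohort(as.data.frame(cohort))
  carriers <- cohort[cohort$genotype == genotype, , drop = FALSE]
  n <- nrow(carriers)
  if (n == 0L) stop("undefined penetrance: no carriers of genotype '",
                    genotype, "'")
  cls <- classify_hearing(carriers$click_threshold, affected_min, unaffected_max)
  x <- sum(cls %in% affected_classes)
  ci <- suppressWarnings(
    stats::prop.test(x, n, conf.level = conf_level, correct = FALSE)$conf.int)
  structure(list(numerator = x, denominator = n, proportion = x / n,
                 conf_int = as.numeric(ci), conf_level = conf_level,
                 affected_classes = affected_classes),
            class = "penetrance_estimate")
}

#' @exportS3Method base::print
print.penetrance_estimate <- function(x, ...) {
  cat(sprintf("Penetrance (%s): %d/%d = %.1f%% (Wilson %.0f%% CI %.1f-%.1f%%)\n",
              paste(x$affected_classes, collapse = "+"),
              x$numerator, x$denominator, 100 * x$proportion,
              100 * x$conf_level, 100 * x$conf_int[1], 100 * x$conf_int[2]))
  invisible(x)
}

#' Exact test for a deficit of homozygotes
#'
#' One-sided exact binomial probability of observing `n_hom` or fewer
#' homozygous offspring out of `n_offspring` under the Mendelian expectation
#' (`expected_fraction`, 1/4 for a carrier intercross). A small p-value
#' indicates reduced homozygote viability.
#'
#' @param n_offspring total genotyped offspring.
#' @param n_hom homozygotes observed.
#' @param expected_fraction Mendelian homozygote fraction, in (0, 1).
#' @return the one-sided p-value `P(X <= n_hom)`.
#' @export
homozygote_deficit_test <- function(n_offspring, n_hom, expected_fraction = 0.25) {
  if (!(expected_fraction > 0 && expected_fraction < 1))
    stop("expected_fraction must lie strictly between 0 and 1")
  stopifnot(n_offspring >= 0, n_hom >= 0, n_hom <= n_offspring)
  stats::pbinom(n_hom, n_offspring, expected_fraction)
}

all_compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  do.call(rbind, lapply(0:n, function(i) cbind(i, all_compositions(n - i, k - 1L))))
}

#' Goodness-of-fit test of genotype counts to a Mendelian ratio
#'
#' Tests observed genotype counts against an expected ratio (e.g. 1:2:1 for
#' an intercross). Uses the exact multinomial test -- p = total probability of
#' all outcomes no more probable than the observed one -- when the total count
#' is at most `exact_max_n` (and the outcome space is small enough to
#' enumerate), otherwise a chi-square goodness-of-fit test.
#'
#' @param observed non-negative integer counts per genotype.
#' @param expected_ratio positive expected ratio of the same length.
#' @param exact_max_n largest total n for which the exact test is used.
#' @return the p-value.
#' @export
mendelian_ratio_test <- function(observed, expected_ratio = c(1, 2, 1),
                                 exact_max_n = 200) {
  stopifnot(length(observed) == length(expected_ratio), all(observed >= 0))
  if (any(expected_ratio <= 0))
    stop("expected_ratio must have strictly positive cells")
  n <- sum(observed)
  if (n == 0L) return(1)
  p <- expected_ratio / sum(expected_ratio)
  k <- length(observed)
  n_outcomes <- choose(n + k - 1, k - 1)
  if (n <= exact_max_n && n_outcomes <= 5e5) {
    p_obs <- stats::dmultinom(observed, prob = p)
    outcomes <- all_compositions(n, k)
    probs <- apply(outcomes, 1L, stats::dmultinom, prob = p)
    return(min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])))
  }
  suppressWarnings(stats::chisq.test(observed, p = p)$p.value)
}

#' Expand published cross counts into per-animal records
#'
#' Turns a counts table (cross type x genotype x hearing class, with optional
#' male/female splits) into a `cohort_records` table, assigning each class a
#' representative click threshold strictly inside its interval. This is how
#' printed segregation tables are fed back through [build_cross_table()] and
#' [penetrance()].
#'
#' @param counts data.frame with columns `cross_type`, `genotype`,
#'   `hearing_class`, `n` and optionally `n_male`, `n_female`.
#' @param class_thresholds representative thresholds (dB SPL) per class.
#' @return a `cohort_records` table.
#' @export
cohort_from_counts <- function(counts,
                               class_thresholds = c(unaffected = 20,
                                                    intermediate = 40,
                                                    affected = 65)) {
  rows <- list()
  idn <- 0L
  for (i in seq_len(nrow(counts))) {
    n <- counts$n[i]
    if (n == 0L) next
    sexes <- if (all(c("n_male", "n_female") %in% names(counts)) &&
                 counts$n_male[i] + counts$n_female[i] == n)
      rep(c("m", "f"), c(counts$n_male[i], counts$n_female[i]))
    else rep("unknown", n)
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = sprintf("a%04d", idn + seq_len(n)),
      cross_type = counts$cross_type[i], genotype = counts$genotype[i],
      sex = sexes,
      click_threshold = unname(class_thresholds[[counts$hearing_class[i]]]),
      stringsAsFactors = FALSE)
    idn <- idn + n
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal_id = character(), cross_type = character(),
               genotype = character(), sex = character(),
               click_threshold = numeric(), stringsAsFactors = FALSE)
  validate_cohort(df)
}
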