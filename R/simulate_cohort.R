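#' Configuration for a simulated genotype-phenotype cohort
#'
#' Emulates a partially penetrant dominant hearing phenotype: offspring of
#' carrier intercrosses (het x het, Mendelian 1:2:1 prior with homozygote
#' survival probability `hom_viability`) and carrier outcrosses (het x wt,
#' 1:1), with click thresholds drawn from a genotype-dependent bimodal
#' mixture. Heterozygotes are fully affected (threshold >= 50 dB SPL) with
#' probability `p_affected`, mildly affected (threshold strictly between 30
#' and 50) with probability `p_intermediate`, and otherwise hear normally;
#' wild types hear normally apart from a small leak into the intermediate
#' band (`wt_intermediate_leak`). Defaults reproduce the dearisch colony's
#' observed conditions: cross sizes 111 and 85, het penetrance 23.1%
#' (strictly affected) and 28.1% (intermediate), no surviving homozygotes,
#' and a wild-type leak of 3/75. Threshold-distribution parameters are
#' simulator choices constrained only by the observed bimodality.
#'
#' @param seed integer seed.
#' @param n_het_x_het,n_het_x_wt viable genotyped offspring per cross.
#' @param p_affected,p_intermediate het class probabilities (sum <= 1).
#' @param hom_viability survival probability of homozygotes (default 0).
#' @param wt_intermediate_leak probability a wild type lands in the
#'   intermediate band.
#' @param unaffected_mean,unaffected_sd Normal(22, 4) dB SPL, truncated to
#'   `[0, 30]`.
#' @param affected_mean,affected_sd,affected_range Normal(65, 9) truncated to
#'   `[50, 97]`.
#' @param intermediate_range Uniform(31, 49).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L, n_het_x_het = 111L, n_het_x_wt = 85L,
                          p_affected = 0.231, p_intermediate = 0.281,
                          hom_viability = 0, wt_intermediate_leak = 0.04,
                          unaffected_mean = 22, unaffected_sd = 4,
                          affected_mean = 65, affected_sd = 9,
                          affected_range = c(50, 97),
                          intermediate_range = c(31, 49)) {
  if (p_affected + p_intermediate > 1)
    stop("p_affected + p_intermediate must not exceed 1")
  stopifnot(hom_viability >= 0, hom_viability <= 1,
            wt_intermediate_leak >= 0, wt_intermediate_leak <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate a genotype-phenotype cohort
#'
#' Deterministic per seed. Genotypes are drawn per cross among viable
#' offspring (conditioning the Mendelian prior on `hom_viability`), then a
#' click threshold is drawn per animal from its genotype's mixture; surviving
#' homozygotes (if any) draw from the affected distribution. Thresholds are
#' rounded to whole dB SPL.
#'
#' @param config a [cohort_config()].
#' @return a `cohort_records` table.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  draw_threshold <- function(class) {
    n <- length(class)
    thr <- numeric(n)
    i <- class == "unaffected"
    thr[i] <- rtrunc_norm(sum(i), config$unaffected_mean, config$unaffected_sd,
                          0, 30)
    i <- class == "intermediate"
    thr[i] <- stats::runif(sum(i), config$intermediate_range[1],
                           config$intermediate_range[2])
    i <- class == "affected"
    thr[i] <- rtrunc_norm(sum(i), config$affected_mean, config$affected_sd,
                          config$affected_range[1], config$affected_range[2])
    round(thr)
  }
  one_cross <- function(cross, n) {
    if (n == 0L)
      return(data.frame(animal_id = character(), cross_type = character(),
                        genotype = character(), sex = character(),
                        click_threshold = numeric(), stringsAsFactors = FALSE))
    w <- if (cross == "het_x_het") c(wt = 1, het = 2, hom = config$hom_viability)
         else c(wt = 1, het = 1, hom = 0)
    geno <- sample(names(w), n, replace = TRUE, prob = w / sum(w))
    class <- character(n)
    for (g in unique(geno)) {
      i <- which(geno == g)
      class[i] <- switch(g,
        wt = sample(c("intermediate", "unaffected"), length(i), replace = TRUE,
                    prob = c(config$wt_intermediate_leak,
                             1 - config$wt_intermediate_leak)),
        het = sample(c("affected", "intermediate", "unaffected"), length(i),
                     replace = TRUE,
                     prob = c(config$p_affected, config$p_intermediate,
                              1 - config$p_affected - config$p_intermediate)),
        hom = rep("affected", length(i)))
    }
    data.frame(animal_id = sprintf("%s_%04d", cross, seq_len(n)),
               cross_type = cross, genotype = geno,
               sex = sample(c("m", "f"), n, replace = TRUE),
               click_threshold = draw_threshold(class),
               stringsAsFactors = FALSE)
  }
  df <- rbind(one_cross("het_x_het", config$n_het_x_het),
              one_cross("het_x_wt", config$n_het_x_wt))
  validate_cohort(df)
}

#' Write a cohort table as TSV
#'
#' @param cohort a `cohort_records` table.
#' @param path output path.
#' @param seed optional seed recorded in a comment line.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  con <- file(path, "w")
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  utils::write.table(as.data.frame(cohort), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}
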