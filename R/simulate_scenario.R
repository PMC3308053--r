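# position bookkeeping: one logical vector per chromosome, TRUE = taken
new_used <- function(models) {
  lapply(stats::setNames(nm = names(models$reference)),
         function(ch) logical(Biostrings::width(
           models$reference[names(models$reference) == ch])))
}

take <- function(used, chrom, pos) {
  used[[chrom]][pos] <- TRUE
  used
}

good_metrics <- function(n) data.frame(
  consensus_quality = sample(30:150, n, replace = TRUE),
  snp_quality = sample(30:250, n, replace = TRUE),
  mapping_quality = sample(46:60, n, replace = TRUE),
  read_depth = sample(11:120, n, replace = TRUE))

low_metrics <- function(n) {
  m <- good_metrics(n)
  mode <- sample(1:3, n, replace = TRUE)
  m$snp_quality[mode == 1] <- sample(0:19, sum(mode == 1), replace = TRUE)
  m$mapping_quality[mode == 2] <- sample(0:45, sum(mode == 2), replace = TRUE)
  m$read_depth[mode == 3] <- sample(0:10, sum(mode == 3), replace = TRUE)
  m
}

other_base <- function(b) sample(setdiff(DNA_BASES, toupper(b)), 1L)

gene_span_mask <- function(models) {
  mask <- lapply(stats::setNames(nm = names(models$reference)),
                 function(ch) logical(Biostrings::width(
                   models$reference[names(models$reference) == ch])))
  for (tx in models$transcripts) {
    lo <- max(1L, min(tx$exons) - 50L)
    hi <- max(tx$exons) + 50L
    mask[[tx$chrom]][lo:min(hi, length(mask[[tx$chrom]]))] <- TRUE
  }
  mask
}

# n free positions anywhere (optionally restricted by a candidate pool)
sample_positions <- function(models, used, n, pool = NULL) {
  out <- data.frame(chrom = character(), pos = integer())
  guard <- 0L
  while (nrow(out) < n) {
    guard <- guard + 1L
    if (guard > 1000L) stop("config error: cannot place ", n, " variants")
    if (is.null(pool)) {
      chrom <- sample(names(models$reference), 1L)
      pos <- sample.int(length(used[[chrom]]), 1L)
    } else {
      j <- sample.int(nrow(pool), 1L)
      chrom <- pool$chrom[j]; pos <- pool$pos[j]
    }
    if (used[[chrom]][pos]) next
    used[[chrom]][pos] <- TRUE
    out <- rbind(out, data.frame(chrom = chrom, pos = pos))
    guard <- 0L
  }
  list(positions = out, used = used)
}

# deep-intronic (> 2 bp from both intron ends) and intergenic position pool
noncoding_pool <- function(models, n_intergenic = 2000L) {
  rows <- list()
  for (tx in models$transcripts) {
    ex <- tx$exons
    if (nrow(ex) < 2L) next
    for (j in seq_len(nrow(ex) - 1L)) {
      s <- ex[j, 2] + 3L; e <- ex[j + 1L, 1] - 3L
      if (e > s + 1L)
        rows[[length(rows) + 1L]] <- data.frame(chrom = tx$chrom, pos = s:e)
    }
  }
  mask <- gene_span_mask(models)
  for (ch in names(mask)) {
    free <- which(!mask[[ch]])
    if (length(free))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos = sample(free, min(n_intergenic, length(free))))
  }
  do.call(rbind, rows)
}

# forced-consequence SNV at a given coding genomic position (or near it);
# returns NULL if no alt at that position yields the wanted class
snv_with_class_at <- function(tx, models, gpos, want) {
  cdspos <- cds_positions(tx)
  idx <- match(gpos, cdspos)
  if (is.na(idx)) return(NULL)
  ref_g <- ref_base(models$reference, tx$chrom, gpos)
  for (alt_tx in sample(setdiff(DNA_BASES,
                                if (tx$strand == "+") ref_g else comp_base(ref_g)))) {
    alt_g <- if (tx$strand == "+") alt_tx else comp_base(alt_tx)
    res <- snv_consequence_tx(tx, models$reference, gpos, ref_g, alt_g)
    if (res$category == want)
      return(data.frame(chrom = tx$chrom, pos = gpos, ref = ref_g, alt = alt_g))
  }
  NULL
}

# random coding SNV of a wanted class somewhere in a transcript
random_cds_snv <- function(tx, models, want, used) {
  cdspos <- cds_positions(tx)
  for (try in seq_len(200L)) {
    gpos <- sample(cdspos, 1L)
    if (used[[tx$chrom]][gpos]) next
    hit <- snv_with_class_at(tx, models, gpos, want)
    if (!is.null(hit)) return(hit)
  }
  stop("could not place a ", want, " SNV in ", tx$transcript_id)
}

# the planted causal lesion: a TAT (Tyr) codon mutated at its middle base to
# TGT (Cys) -- on a minus-strand gene this is a genomic T>C, mirroring a
# classic ENU transition
plant_causal_snv <- function(tx, models) {
  cds_seq <- cds_sequence(tx, models$reference)
  codons <- substring(cds_seq, seq(1L, nchar(cds_seq) - 2L, 3L),
                      seq(3L, nchar(cds_seq), 3L))
  ci <- which(codons == "TAT")
  if (!length(ci)) stop("gene ", tx$gene_name, " has no TAT codon for the causal placement")
  ci <- ci[1L]
  idx <- 3L * (ci - 1L) + 2L
  gpos <- cds_positions(tx)[idx]
  ref_g <- if (tx$strand == "+") "A" else "T"
  alt_g <- if (tx$strand == "+") "G" else "C"
  data.frame(chrom = tx$chrom, pos = gpos, ref = ref_g, alt = alt_g)
}

#' Generate a synthetic variant scenario with a truth table
#'
#' Builds the mutant and background call sets, known-variant panels, and a
#' truth table labelling every mutant call as one of `shared`, `panel`,
#' `low_quality`, `noncoding`, `synonymous`, `indel_artifact` or `causal`.
#' The planted causal call is a heterozygous nonsynonymous SNV (Tyr->Cys by
#' default) with quality metrics exceeding every threshold, and is disjoint
#' from the shared and panel strata by construction, so panel subtraction can
#' never remove it. Artifact SNVs are placed within `cluster_spacing_bp` of
#' planted deletions and get `Deletion`/`Deletion` validation calls.
#'
#' @param config a [scenario_config()].
#' @param models the [gene_model_set()] from [generate_reference_and_genes()]
#'   under the same config.
#' @return list with `mutant`, `background` ([variant_calls()]), `panels`
#'   (list of [variant_calls()]), and `truth` (chrom, pos, ref, alt, genotype,
#'   label).
#' @export
generate_variant_scenario <- function(config, models) {
  set.seed(config$seed + 17L)
  used <- new_used(models)
  coding_txs <- Filter(function(tx) tx$biotype == "protein_coding",
                       models$transcripts)
  if (!length(coding_txs)) stop("config error: scenario needs at least one coding gene")

  strata <- list()
  add <- function(positions, label, metrics, genotype = NULL,
                  ref = NULL, alt = NULL) {
    n <- nrow(positions)
    if (n == 0L) return(invisible())
    if (is.null(ref)) {
      ref <- vapply(seq_len(n), function(i)
        ref_base(models$reference, positions$chrom[i], positions$pos[i]),
        character(1))
      alt <- vapply(ref, other_base, character(1))
    }
    if (is.null(genotype)) genotype <- sample(c("het", "hom_alt"), n,
                                              replace = TRUE, prob = c(0.6, 0.4))
    strata[[length(strata) + 1L]] <<- cbind(
      data.frame(chrom = positions$chrom, pos = positions$pos, ref = ref,
                 alt = alt, genotype = genotype, stringsAsFactors = FALSE),
      metrics, data.frame(label = label, stringsAsFactors = FALSE))
  }

  # causal first so nothing can steal its position
  causal_tx <- coding_txs[[1L]]
  causal <- plant_causal_snv(causal_tx, models)
  used <- take(used, causal$chrom, causal$pos)
  cq <- config$causal
  add(causal, "causal",
      data.frame(consensus_quality = cq$consensus_quality,
                 snp_quality = cq$snp_quality,
                 mapping_quality = cq$mapping_quality,
                 read_depth = cq$read_depth),
      genotype = cq$genotype, ref = causal$ref, alt = causal$alt)

  s <- sample_positions(models, used, config$n_shared)
  used <- s$used
  add(s$positions, "shared", good_metrics(nrow(s$positions)))

  s <- sample_positions(models, used, config$n_panel_hits)
  used <- s$used
  add(s$positions, "panel", good_metrics(nrow(s$positions)))

  s <- sample_positions(models, used, config$n_low_quality)
  used <- s$used
  add(s$positions, "low_quality", low_metrics(nrow(s$positions)))

  pool <- noncoding_pool(models)
  s <- sample_positions(models, used, config$n_noncoding, pool = pool)
  used <- s$used
  add(s$positions, "noncoding", good_metrics(nrow(s$positions)))

  syn_txs <- if (length(coding_txs) > 1L) coding_txs[-1L] else coding_txs
  if (config$n_synonymous > 0L) {
    syn <- do.call(rbind, lapply(seq_len(config$n_synonymous), function(i) {
      tx <- syn_txs[[sample.int(length(syn_txs), 1L)]]
      hit <- random_cds_snv(tx, models, "synonymous", used)
      used <<- take(used, hit$chrom, hit$pos)
      hit
    }))
    add(syn[, c("chrom", "pos")], "synonymous", good_metrics(nrow(syn)),
        ref = syn$ref, alt = syn$alt)
  }

  # deletion clusters with flanking nonsynonymous artifact SNVs
  if (config$indel_clusters > 0L) {
    for (k in seq_len(config$indel_clusters)) {
      tx <- syn_txs[[sample.int(length(syn_txs), 1L)]]
      runs <- tx$cds[tx$cds[, 2] - tx$cds[, 1] + 1L >= 60L, , drop = FALSE]
      if (!nrow(runs)) next
      run <- runs[sample.int(nrow(runs), 1L), ]
      anchor <- sample((run[1] + 20L):(run[2] - 30L), 1L)
      dlen <- sample(1:3, 1L)
      ref_del <- as.character(Biostrings::subseq(
        models$reference[[tx$chrom]], anchor, anchor + dlen))
      used[[tx$chrom]][anchor:(anchor + dlen)] <- TRUE
      add(data.frame(chrom = tx$chrom, pos = anchor), "indel_artifact",
          good_metrics(1L), genotype = "het",
          ref = ref_del, alt = substr(ref_del, 1L, 1L))
      flank <- setdiff(
        max(run[1], anchor - config$cluster_spacing_bp):
          min(run[2], anchor + dlen + config$cluster_spacing_bp),
        anchor:(anchor + dlen))
      placed <- 0L
      for (gpos in sample(flank)) {
        if (placed >= config$artifacts_per_cluster) break
        if (used[[tx$chrom]][gpos]) next
        hit <- snv_with_class_at(tx, models, gpos, "nonsynonymous")
        if (is.null(hit)) next
        used <- take(used, tx$chrom, gpos)
        add(hit[, c("chrom", "pos")], "indel_artifact", good_metrics(1L),
            ref = hit$ref, alt = hit$alt)
        placed <- placed + 1L
      }
    }
  }

  truth <- do.call(rbind, strata)
  o <- order(truth$chrom, truth$pos)
  truth <- truth[o, , drop = FALSE]
  rownames(truth) <- NULL

  core <- c("chrom", "pos", "ref", "alt", "genotype", "consensus_quality",
            "snp_quality", "mapping_quality", "read_depth")
  mutant <- truth[, core]
  mutant$variant_class <- variant_class(mutant$ref, mutant$alt)
  mutant <- validate_variant_calls(mutant)

  # background: the shared stratum (its own metrics) + private background noise
  shared <- truth[truth$label == "shared", core]
  if (nrow(shared)) {
    m <- good_metrics(nrow(shared))
    shared[, names(m)] <- m
  }
  s <- sample_positions(models, used, config$n_background_private)
  used <- s$used
  bg_priv <- data.frame()
  if (nrow(s$positions)) {
    ref <- vapply(seq_len(nrow(s$positions)), function(i)
      ref_base(models$reference, s$positions$chrom[i], s$positions$pos[i]),
      character(1))
    bg_priv <- cbind(s$positions,
                     data.frame(ref = ref,
                                alt = vapply(ref, other_base, character(1)),
                                genotype = sample(c("het", "hom_alt"),
                                                  nrow(s$positions), replace = TRUE)),
                     good_metrics(nrow(s$positions)))[, core]
  }
  background <- rbind(shared, bg_priv)
  if (nrow(background)) {
    background <- background[order(background$chrom, background$pos), ]
    rownames(background) <- NULL
  }
  background$variant_class <- variant_class(background$ref, background$alt)
  background <- validate_variant_calls(background)

  # panels: every 'panel' mutant call lands in one panel, plus panel-only noise
  panels <- list()
  if (config$n_panels > 0L) {
    hits <- truth[truth$label == "panel", core]
    assign_to <- if (nrow(hits)) sample.int(config$n_panels, nrow(hits),
                                            replace = TRUE) else integer()
    for (p in seq_len(config$n_panels)) {
      pp <- hits[assign_to == p, , drop = FALSE]
      s <- sample_positions(models, used,
                            ceiling(config$n_panel_only / config$n_panels))
      used <- s$used
      if (nrow(s$positions)) {
        ref <- vapply(seq_len(nrow(s$positions)), function(i)
          ref_base(models$reference, s$positions$chrom[i], s$positions$pos[i]),
          character(1))
        extra <- cbind(s$positions,
                       data.frame(ref = ref,
                                  alt = vapply(ref, other_base, character(1)),
                                  genotype = sample(c("het", "hom_alt"),
                                                    nrow(s$positions), replace = TRUE)),
                       good_metrics(nrow(s$positions)))[, core]
        pp <- rbind(pp, extra)
      }
      if (nrow(pp)) {
        pp <- pp[order(pp$chrom, pp$pos), ]
        rownames(pp) <- NULL
      }
      pp$variant_class <- variant_class(pp$ref, pp$alt)
      panels[[p]] <- validate_variant_calls(pp)
    }
  }

  list(mutant = mutant, background = background, panels = panels,
       truth = truth[, c("chrom", "pos", "ref", "alt", "genotype", "label")])
}

#' Derive validation genotypes from a scenario truth table
#'
#' Emulates capillary re-sequencing of every mutant call: the causal call
#' validates as background homozygous-reference and mutant heterozygous for
#' the alternate allele; indel-artifact calls validate as `Deletion` in both
#' samples; low-quality miscalls validate identical to the background; shared
#' and panel calls validate identically in both samples; other true private
#' calls (noncoding, synonymous) validate as genuine mutant-specific changes.
#' Deterministic given the truth table.
#'
#' @param truth the truth table from [generate_variant_scenario()].
#' @return a `validation_genotypes` table.
#' @export
generate_validation_genotypes <- function(truth) {
  n <- nrow(truth)
  bg <- mu <- character(n)
  for (i in seq_len(n)) {
    ref1 <- substr(truth$ref[i], 1L, 1L)
    pair <- if (truth$genotype[i] == "hom_alt") truth$alt[i]
            else norm_het_pair(ref1, truth$alt[i])
    switch(truth$label[i],
      causal = { bg[i] <- ref1; mu[i] <- pair },
      indel_artifact = { bg[i] <- "Deletion"; mu[i] <- "Deletion" },
      low_quality = { bg[i] <- ref1; mu[i] <- ref1 },
      shared = , panel = { bg[i] <- pair; mu[i] <- pair },
      { bg[i] <- ref1; mu[i] <- pair })
  }
  out <- data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
                    alt = truth$alt, background_call = bg, mutant_call = mu,
                    stringsAsFactors = FALSE)
  class(out) <- c("validation_genotypes", "data.frame")
  out
}

#' Simulate a complete scenario
#'
#' Convenience wrapper: genome + gene models, variant call sets, truth table
#' and validation genotypes, all from one seed.
#'
#' @param config a [scenario_config()].
#' @return list of class `variant_scenario` with `models`, `mutant`,
#'   `background`, `panels`, `truth`, `validation`, `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  models <- generate_reference_and_genes(config)
  sc <- generate_variant_scenario(config, models)
  sc$validation <- generate_validation_genotypes(sc$truth)
  sc$models <- models
  sc$config <- config
  class(sc) <- "variant_scenario"
  sc
}

#' Write a scenario to disk in standard formats
#'
#' Emits `reference.fa`, `genes.gff3`, `mutant.vcf`, `background.vcf`,
#' `panel_<i>.vcf`, `truth.tsv` and `validation.tsv` under `dir`; every file
#' records the generating seed in a header/comment line.
#'
#' @param scenario a `variant_scenario` from [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_line <- paste0("##seed=", scenario$config$seed)
  write_gene_models(scenario$models, file.path(dir, "genes.gff3"),
                    file.path(dir, "reference.fa"))
  write_variant_calls(scenario$mutant, file.path(dir, "mutant.vcf"),
                      sample_name = "mutant", header_extra = seed_line)
  write_variant_calls(scenario$background, file.path(dir, "background.vcf"),
                      sample_name = "background", header_extra = seed_line)
  for (p in seq_along(scenario$panels))
    write_variant_calls(scenario$panels[[p]],
                        file.path(dir, sprintf("panel_%d.vcf", p)),
                        sample_name = sprintf("panel_%d", p),
                        header_extra = seed_line)
  wt <- function(df, f) {
    con <- file(file.path(dir, f), "w")
    writeLines(paste0("# seed=", scenario$config$seed), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wt(scenario$truth, "truth.tsv")
  wt(as.data.frame(scenario$validation), "validation.tsv")
  invisible(dir)
}
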