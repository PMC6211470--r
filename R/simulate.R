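## Seeded generators for every fixture the pipeline needs. All randomness
## goes through withr::with_seed so a fixed seed gives byte-identical output
## without touching the caller's RNG state.

#' Generate a truth annotation
#'
#' Non-overlapping multi-exon genes laid out left to right on one
#' chromosome, strands alternating at random. Deterministic for a fixed
#' seed.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes. Default 200.
#' @param chrom_length Chromosome length in bp. Default 1e6 — genes that do
#'   not fit raise an error.
#' @param exon_count_range,exon_length_range,intron_length_range,gap_range
#'   Integer ranges (inclusive) for exons per gene, exon length, intron
#'   length and intergenic gap.
#' @param chrom Chromosome name.
#' @return A gene model tibble.
#' @export
generate_truth <- function(seed, n_genes = 200, chrom_length = 1e6,
                           exon_count_range = c(2, 6),
                           exon_length_range = c(150, 400),
                           intron_length_range = c(200, 1200),
                           gap_range = c(500, 2000), chrom = "chr1") {
  withr::with_seed(seed, {
    rows <- vector("list", n_genes)
    pos <- sample(gap_range[1]:gap_range[2], 1)
    for (i in seq_len(n_genes)) {
      n_ex <- sample(exon_count_range[1]:exon_count_range[2], 1)
      ex_len <- sample(exon_length_range[1]:exon_length_range[2], n_ex,
                       replace = TRUE)
      in_len <- if (n_ex > 1) {
        sample(intron_length_range[1]:intron_length_range[2], n_ex - 1,
               replace = TRUE)
      } else integer()
      starts <- pos + cumsum(c(0L, ex_len[-n_ex] + in_len))
      ends <- starts + ex_len
      strand <- sample(c("+", "-"), 1)
      id <- sprintf("g%04d", i)
      rows[[i]] <- tibble(transcript_id = id, gene_id = id, chrom = chrom,
                          start = as.integer(starts), end = as.integer(ends),
                          strand = strand, source = "truth")
      pos <- max(ends) + sample(gap_range[1]:gap_range[2], 1)
    }
    if (pos > chrom_length) {
      stop("genes do not fit on a chromosome of length ", chrom_length)
    }
    gene_models(bind_rows(rows))
  })
}

#' Noise settings for evidence simulation
#'
#' Class-specific noise applied by [corrupt_evidence()]. Setting
#' `zero = TRUE` returns the noiseless configuration under which every
#' evidence class reproduces the truth exactly (the fixed point of the
#' whole pipeline).
#'
#' @param zero All noise off?
#' @param cdna_jitter_sd Terminal-end jitter SD (bp) for cDNA alignments.
#' @param est_jitter_sd Terminal jitter SD for ESTs.
#' @param est_fragmentation Probability that an EST is a fragment (a random
#'   consecutive exon sub-chain) rather than full length.
#' @param est_p_missing_exon Probability of dropping each internal exon from
#'   an EST; 1 collapses ESTs to single-exon fragments.
#' @param rnaseq_jitter_sd Terminal jitter SD for assembled RNA-seq
#'   transcripts.
#' @param rnaseq_p_retained_intron Per-intron probability that an RNA-seq
#'   transcript retains the intron as exonic sequence.
#' @param rnaseq_p_false_exon Per-intron probability of a spurious exon.
#' @param rnaseq_tissue_prob Per-tissue emission probability of each truth
#'   transcript (1 = seen in every tissue).
#' @param refseq_p_missing,ncbi_p_missing Probability that a truth gene is
#'   absent from the RefSeq / independent annotation track.
#' @param refseq_truncation Bases removed from one terminal exon of each
#'   RefSeq model (0 = off).
#' @param refseq_truncation_end Which genomic end to truncate: `"left"`,
#'   `"right"` or `"random"`.
#' @return A named list of noise settings.
#' @export
evidence_noise <- function(zero = FALSE, cdna_jitter_sd = 3,
                           est_jitter_sd = 10, est_fragmentation = 0.7,
                           est_p_missing_exon = 0, rnaseq_jitter_sd = 15,
                           rnaseq_p_retained_intron = 0.03,
                           rnaseq_p_false_exon = 0.02,
                           rnaseq_tissue_prob = 0.7,
                           refseq_p_missing = 0.05, ncbi_p_missing = 0.1,
                           refseq_truncation = 0,
                           refseq_truncation_end = "random") {
  if (zero) {
    return(list(cdna_jitter_sd = 0, est_jitter_sd = 0, est_fragmentation = 0,
                est_p_missing_exon = 0, rnaseq_jitter_sd = 0,
                rnaseq_p_retained_intron = 0, rnaseq_p_false_exon = 0,
                rnaseq_tissue_prob = 1, refseq_p_missing = 0,
                ncbi_p_missing = 0, refseq_truncation = 0,
                refseq_truncation_end = "random"))
  }
  list(cdna_jitter_sd = cdna_jitter_sd, est_jitter_sd = est_jitter_sd,
       est_fragmentation = est_fragmentation,
       est_p_missing_exon = est_p_missing_exon,
       rnaseq_jitter_sd = rnaseq_jitter_sd,
       rnaseq_p_retained_intron = rnaseq_p_retained_intron,
       rnaseq_p_false_exon = rnaseq_p_false_exon,
       rnaseq_tissue_prob = rnaseq_tissue_prob,
       refseq_p_missing = refseq_p_missing, ncbi_p_missing = ncbi_p_missing,
       refseq_truncation = refseq_truncation,
       refseq_truncation_end = refseq_truncation_end)
}

## internal: jitter both terminal ends of a single-transcript table,
## keeping exons valid (length >= 20, start >= 0)
jitter_ends <- function(tx, sd) {
  if (sd <= 0) return(tx)
  tx <- arrange(tx, .data$start)
  n <- nrow(tx)
  d1 <- round(stats::rnorm(1, 0, sd))
  d2 <- round(stats::rnorm(1, 0, sd))
  tx$start[1] <- max(0L, min(tx$start[1] + d1, tx$end[1] - 20L))
  tx$end[n] <- max(tx$start[n] + 20L, tx$end[n] + d2)
  tx
}

#' Derive noisy evidence tracks from a truth annotation
#'
#' Emulates the statistical character of each evidence class: cDNAs are
#' full-length with low terminal jitter; ESTs are fragmentary sub-chains;
#' RNA-seq transcripts are emitted per tissue with moderate jitter,
#' occasional retained introns and false exons; RefSeq/NCBI tracks are the
#' truth with planted truncations and missing genes. Every alignment
#' records its truth transcript in an `origin` column so downstream scoring
#' never relies on coordinates alone.
#'
#' @param truth Truth annotation from [generate_truth()].
#' @param seed Integer seed.
#' @param tissues Tissue labels for RNA-seq emission.
#' @param noise An [evidence_noise()] list.
#' @return A list with `evidence` (cDNA/EST/RNAseq rows, with
#'   `evidence_class`, `tissue`, `origin`), `refseq` and `ncbi` annotation
#'   tibbles.
#' @export
corrupt_evidence <- function(truth, seed,
                             tissues = c("liver", "lung", "cortex",
                                         "muscle", "spleen"),
                             noise = evidence_noise()) {
  withr::with_seed(seed, {
    ev <- list()
    k <- 1L
    for (tx in split_models(truth)) {
      id <- tx$transcript_id[1]
      n <- nrow(tx)

      cd <- jitter_ends(tx, noise$cdna_jitter_sd)
      cd$transcript_id <- paste0("cdna_", id)
      cd$evidence_class <- "cDNA"
      cd$tissue <- NA_character_
      cd$origin <- id
      ev[[k]] <- cd; k <- k + 1L

      es <- tx
      if (noise$est_p_missing_exon >= 1 && n > 1) {
        keep <- sample(seq_len(n), 1)
        es <- tx[keep, ]
      } else if (stats::runif(1) < noise$est_fragmentation && n > 1) {
        a <- sample(seq_len(n), 1)
        b <- sample(a:n, 1)
        es <- tx[a:b, ]
        if (noise$est_p_missing_exon > 0 && nrow(es) > 2) {
          internal <- 2:(nrow(es) - 1)
          drop <- internal[stats::runif(length(internal)) <
                             noise$est_p_missing_exon]
          if (length(drop) > 0) es <- es[-drop, ]
        }
      }
      es <- jitter_ends(es, noise$est_jitter_sd)
      es$transcript_id <- paste0("est_", id)
      es$evidence_class <- "EST"
      es$tissue <- NA_character_
      es$origin <- id
      ev[[k]] <- es; k <- k + 1L

      in_tissue <- stats::runif(length(tissues)) < noise$rnaseq_tissue_prob
      for (t in tissues[in_tissue]) {
        rn <- arrange(tx, .data$start)
        if (nrow(rn) > 1 && noise$rnaseq_p_retained_intron > 0) {
          kk <- 1L
          while (kk < nrow(rn)) {
            if (stats::runif(1) < noise$rnaseq_p_retained_intron) {
              rn$end[kk] <- rn$end[kk + 1]
              rn <- rn[-(kk + 1), ]
            } else kk <- kk + 1L
          }
        }
        if (nrow(rn) > 1 && noise$rnaseq_p_false_exon > 0) {
          add_s <- integer(); add_e <- integer()
          for (kk in seq_len(nrow(rn) - 1)) {
            gap <- rn$start[kk + 1] - rn$end[kk]
            if (gap > 120 && stats::runif(1) < noise$rnaseq_p_false_exon) {
              fs <- rn$end[kk] + sample(10:(gap - 110), 1)
              add_s <- c(add_s, fs); add_e <- c(add_e, fs + 80L)
            }
          }
          if (length(add_s) > 0) {
            rn <- rebuild_model(rn, c(rn$start, add_s), c(rn$end, add_e))
          }
        }
        rn <- jitter_ends(rn, noise$rnaseq_jitter_sd)
        rn$transcript_id <- paste0("rna_", t, "_", id)
        rn$evidence_class <- "RNAseq"
        rn$tissue <- t
        rn$origin <- id
        ev[[k]] <- rn; k <- k + 1L
      }
    }
    evidence <- gene_models(bind_rows(ev))

    refseq <- corrupt_annotation(truth, seed = sample.int(2^31 - 1, 1),
                                 p_missing = noise$refseq_p_missing,
                                 end_truncation = noise$refseq_truncation,
                                 truncate_end = noise$refseq_truncation_end,
                                 id_prefix = "rs_")
    ncbi <- corrupt_annotation(truth, seed = sample.int(2^31 - 1, 1),
                               p_missing = noise$ncbi_p_missing,
                               end_truncation = 0, id_prefix = "nc_")
    list(evidence = evidence, refseq = refseq, ncbi = ncbi)
  })
}

#' Corrupt a truth annotation into a degraded candidate
#'
#' Used both for RefSeq-like tracks (missing genes, truncated terminal
#' exons) and for candidate annotations whose repair the curation engine is
#' tested on (truncations plus spurious exons).
#'
#' @param truth Truth annotation.
#' @param seed Integer seed.
#' @param p_missing Probability of dropping each gene.
#' @param end_truncation Bases removed from one terminal exon of each model
#'   (capped so at least 50 bp of the exon remain).
#' @param truncate_end `"left"`, `"right"` or `"random"` genomic end.
#' @param p_spurious_exon Per-intron probability of inserting an
#'   unsupported 80 bp exon.
#' @param id_prefix Prefix for the derived transcript ids (`""` keeps truth
#'   ids, useful for candidate annotations).
#' @return A gene model tibble with an `origin` column.
#' @export
corrupt_annotation <- function(truth, seed, p_missing = 0,
                               end_truncation = 0,
                               truncate_end = "random",
                               p_spurious_exon = 0, id_prefix = "") {
  withr::with_seed(seed, {
    out <- list()
    k <- 1L
    for (tx in split_models(truth)) {
      if (stats::runif(1) < p_missing) next
      tx <- arrange(tx, .data$start)
      n <- nrow(tx)
      if (end_truncation > 0) {
        side <- if (truncate_end == "random") {
          sample(c("left", "right"), 1)
        } else truncate_end
        if (side == "left") {
          cut <- min(end_truncation, tx$end[1] - tx$start[1] - 50L)
          tx$start[1] <- tx$start[1] + max(0L, cut)
        } else {
          cut <- min(end_truncation, tx$end[n] - tx$start[n] - 50L)
          tx$end[n] <- tx$end[n] - max(0L, cut)
        }
      }
      if (p_spurious_exon > 0 && n > 1) {
        add_s <- integer(); add_e <- integer()
        for (kk in seq_len(nrow(tx) - 1)) {
          gap <- tx$start[kk + 1] - tx$end[kk]
          if (gap > 120 && stats::runif(1) < p_spurious_exon) {
            fs <- tx$end[kk] + sample(10:(gap - 110), 1)
            add_s <- c(add_s, fs); add_e <- c(add_e, fs + 80L)
          }
        }
        if (length(add_s) > 0) {
          tx <- rebuild_model(tx, c(tx$start, add_s), c(tx$end, add_e))
        }
      }
      tx$origin <- tx$transcript_id[1]
      tx$transcript_id <- paste0(id_prefix, tx$transcript_id)
      tx$gene_id <- paste0(id_prefix, tx$gene_id)
      out[[k]] <- tx; k <- k + 1L
    }
    if (length(out) == 0) return(empty_models())
    gene_models(bind_rows(out))
  })
}

#' Generate an assembly-stringency sweep with a planted crossing
#'
#' Builds one assembled exon set per stringency value such that exon
#' detection sensitivity strictly decreases and precision strictly
#' increases with `c`, and `|precision - sensitivity|` is minimized exactly
#' at `crossing_c`. Detection decays by dropping reference exons from the
#' right end of the (chrom, start)-sorted list; imprecision is planted by
#' extending assembled exons 25% of their length into downstream non-exonic
#' sequence.
#'
#' @param truth Truth annotation supplying the reference exons.
#' @param c_values Ordered stringency grid. Default `seq(2.5, 15.5, 1)`.
#' @param crossing_c The value where the curves must cross. Must lie in
#'   `c_values` but above the default (smallest) value: sensitivity is
#'   pinned at 1 there, so a strictly increasing precision can only cross
#'   it degenerately.
#' @param sens_drop Total sensitivity drop across the grid (square-root
#'   decay, steep at permissive values). Default 0.6.
#' @return A named list (one gene model tibble per `c`), ready for
#'   [run_sweep()] with `default_c = min(c_values)`.
#' @export
generate_sweep <- function(truth, c_values = seq(2.5, 15.5, by = 1),
                           crossing_c, sens_drop = 0.6) {
  if (!crossing_c %in% c_values) stop("crossing_c must be one of c_values")
  ex <- refseq_exon_table(truth) |> arrange(.data$chrom, .data$start)
  n <- nrow(ex)
  ks <- seq_along(c_values)
  K <- length(ks)
  kstar <- which(c_values == crossing_c)
  if (kstar == 1) {
    stop("crossing_c cannot be the default stringency: sensitivity is 1 ",
         "there by definition, so a strictly increasing precision cannot ",
         "cross it")
  }
  tt <- (ks - 1) / (K - 1)
  r <- 1 - sens_drop * sqrt(tt)
  slope <- min(0.45,
               if (tt[kstar] < 1) (0.98 - r[kstar]) / (1 - tt[kstar]) else Inf,
               (r[kstar] - 0.02) / tt[kstar])
  q <- r[kstar] + slope * (tt - tt[kstar])
  d_all <- pmax(1L, round(n * r))
  p_all <- pmin(d_all, pmax(0L, round(d_all * q)))
  sens <- d_all / d_all[1]
  prec <- p_all / d_all
  feasible <- all(diff(sens) < 0) && all(diff(prec) > 0) &&
    which.min(abs(sens - prec)) == kstar
  if (!feasible) {
    stop("too few reference exons to plant strictly monotone curves with ",
         "a crossing at ", crossing_c)
  }
  out <- list()
  for (k in ks) {
    d <- d_all[k]
    p <- p_all[k]
    det <- ex[seq_len(d), ]
    imprecise <- rep(FALSE, d)
    if (d > p) imprecise[(p + 1):d] <- TRUE
    rows <- det
    ext <- ifelse(imprecise,
                  pmax(ceiling((det$end - det$start) / 4),
                       ceiling((det$end - det$start) / 9) + 1L), 0L)
    rows$end <- rows$end + as.integer(ext)
    rows$transcript_id <- sprintf("asm_c%s_%05d", c_values[k], seq_len(d))
    rows <- tibble(transcript_id = rows$transcript_id, gene_id =
                     rows$transcript_id, chrom = rows$chrom,
                   start = rows$start, end = rows$end, strand = rows$strand,
                   source = "assembly")
    out[[as.character(c_values[k])]] <- gene_models(rows)
  }
  out
}

#' Generate a two-species multi-tissue expression data set
#'
#' Orthologous-gene expression with planted structure: each tissue has a
#' Zipf-weighted dominance profile over a tissue-specific gene ranking
#' (large exponents give liver-like low-complexity transcriptomes),
#' conserved tissues share that profile across species, divergent tissues
#' reshuffle the profile of a fraction `divergence_effect` of genes
#' independently per species, each species adds a species-wide lognormal
#' gene effect, and replicates add iid lognormal noise.
#'
#' @param seed Integer seed.
#' @param n_genes Number of orthologous genes. Default 2000.
#' @param tissues Tissue names.
#' @param zipf_exponents Named per-tissue Zipf exponent (0 = uniform).
#' @param divergent Tissues whose regulatory program diverges between the
#'   species; the rest are conserved.
#' @param divergence_effect Fraction of genes reshuffled in divergent
#'   tissues. Default 0.8.
#' @param n_reps Replicates per (species, tissue). Default 3.
#' @param species Two species labels.
#' @param species_sd,noise_sd Log-scale SD of the species-wide gene effect
#'   and of replicate noise. Defaults 0.4 and 0.25.
#' @param mean_level Target mean expression level (RPKM-like). Default 50.
#' @return A list with `expression` (wide tibble, both species' samples),
#'   `meta` (sample, tissue, species) and `ortholog_map`.
#' @export
generate_expression <- function(seed, n_genes = 2000,
                                tissues = c("liver", "muscle", "cortex",
                                            "testis", "spleen"),
                                zipf_exponents = c(liver = 1.1, muscle = 0.9,
                                                   cortex = 0.45,
                                                   testis = 0.6,
                                                   spleen = 0.6),
                                divergent = c("testis", "spleen"),
                                divergence_effect = 0.8, n_reps = 3,
                                species = c("speciesA", "speciesB"),
                                species_sd = 0.4, noise_sd = 0.25,
                                mean_level = 50) {
  stopifnot(length(species) == 2, all(tissues %in% names(zipf_exponents)),
            all(divergent %in% tissues))
  withr::with_seed(seed, {
    genes <- sprintf("og%05d", seq_len(n_genes))
    ## per-tissue base log-profiles (shared across species)
    base_log <- sapply(tissues, function(t) {
      a <- zipf_exponents[[t]]
      w <- sample(seq_len(n_genes))^(-a)
      log(w / mean(w) * mean_level)
    })
    species_eff <- sapply(species, function(s) {
      stats::rnorm(n_genes, 0, species_sd)
    })
    n_eff <- round(divergence_effect * n_genes)

    cols <- list()
    meta_rows <- list()
    for (s in seq_along(species)) {
      for (t in tissues) {
        profile <- base_log[, t]
        if (t %in% divergent && n_eff > 1) {
          eff <- sample(seq_len(n_genes), n_eff)
          profile[eff] <- profile[sample(eff)]
        }
        profile <- profile + species_eff[, s]
        for (rep in seq_len(n_reps)) {
          nm <- paste(species[s], t, rep, sep = "_")
          cols[[nm]] <- exp(profile + stats::rnorm(n_genes, 0, noise_sd))
          meta_rows[[nm]] <- tibble(sample = nm, tissue = t,
                                    species = species[s])
        }
      }
    }
    expression <- tibble(gene = genes, !!!cols)
    list(expression = expression, meta = bind_rows(meta_rows),
         ortholog_map = tibble(gene = genes,
                               species_a_gene = paste0(species[1], "_", genes),
                               species_b_gene = paste0(species[2], "_", genes)))
  })
}
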