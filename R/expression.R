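## Expression tables are wide tibbles: a `gene` column plus one numeric
## column per sample; `meta` maps sample -> (tissue, species).

validate_expression <- function(mat, meta = NULL) {
  if (!"gene" %in% names(mat)) stop("expression table needs a gene column")
  samples <- setdiff(names(mat), "gene")
  if (anyDuplicated(mat$gene)) stop("duplicate gene ids")
  vals <- as.matrix(mat[samples])
  if (any(vals < 0, na.rm = TRUE)) stop("negative expression values")
  if (!is.null(meta)) {
    need <- c("sample", "tissue", "species")
    if (!all(need %in% names(meta))) {
      stop("metadata needs columns: ", paste(need, collapse = ", "))
    }
    miss <- setdiff(samples, meta$sample)
    if (length(miss) > 0) {
      stop("samples missing from metadata: ", paste(miss, collapse = ", "))
    }
  }
  invisible(samples)
}

#' RPKM from raw counts
#'
#' Reads per kilobase of gene model per million mapped reads:
#' `count * 1e9 / (gene_length * library_size)`.
#'
#' @param counts Wide tibble: `gene` column plus one integer column per
#'   sample.
#' @param gene_lengths Named numeric vector (bp per gene) or a tibble with
#'   `gene` and `length` columns.
#' @param library_sizes Named numeric vector of mapped reads per sample.
#' @return A tibble of the same shape holding RPKM values.
#' @examples
#' counts <- tibble::tibble(gene = "g1", s1 = 100L)
#' compute_rpkm(counts, c(g1 = 1000), c(s1 = 1e6)) # 100 RPKM
#' @export
compute_rpkm <- function(counts, gene_lengths, library_sizes) {
  samples <- validate_expression(counts)
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- setNames(gene_lengths$length, gene_lengths$gene)
  }
  len <- gene_lengths[counts$gene]
  if (any(is.na(len)) || any(len <= 0)) {
    stop("every gene needs a positive length")
  }
  lib <- library_sizes[samples]
  if (any(is.na(lib)) || any(lib <= 0)) {
    stop("every sample needs a positive library size")
  }
  out <- counts
  for (s in samples) {
    out[[s]] <- unname(counts[[s]] * 1e9 / (unname(len) * lib[[s]]))
  }
  out
}

#' Quantile-normalize an expression table
#'
#' Forces every sample's value distribution onto the common reference
#' distribution (the per-rank mean of the sorted columns) while preserving
#' within-sample rank order; tied values receive the mean of the reference
#' values they span. Idempotent.
#'
#' @param mat Wide expression tibble (`gene` + sample columns; at least 2
#'   samples).
#' @return The normalized tibble.
#' @export
quantile_normalize <- function(mat) {
  samples <- validate_expression(mat)
  if (length(samples) < 2) stop("quantile normalization needs >= 2 samples")
  m <- as.matrix(mat[samples])
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  out <- mat
  out[samples] <- as_tibble(as.data.frame(norm))
  out
}

#' Transcriptome complexity curves
#'
#' Per tissue: average each gene's expression across that tissue's samples,
#' sort in decreasing order, divide by the total, and cumulate. The curve
#' answers "how many top genes account for a given fraction of the tissue's
#' transcription" — low-complexity tissues (liver-like) saturate within a
#' few dominant genes, high-complexity ones (cortex-like) need many.
#'
#' @param mat Wide expression tibble.
#' @param meta Sample metadata (`sample`, `tissue`, `species`). When both
#'   species are present, curves are computed per (species, tissue) pair if
#'   `by_species = TRUE`.
#' @param by_species Split curves by species? Default `FALSE` (all samples
#'   of a tissue pooled).
#' @return A tibble with `tissue` (and `species` when split), `rank`,
#'   `increment` and cumulative `fraction`.
#' @export
complexity_curves <- function(mat, meta, by_species = FALSE) {
  validate_expression(mat, meta)
  samples <- setdiff(names(mat), "gene")
  meta <- filter(meta, .data$sample %in% samples)
  groups <- if (by_species) split(meta, paste(meta$species, meta$tissue))
  else split(meta, meta$tissue)
  rows <- lapply(groups, function(g) {
    avg <- rowMeans(as.matrix(mat[g$sample]))
    tot <- sum(avg)
    if (tot <= 0) {
      stop("tissue ", g$tissue[1], " has all-zero expression")
    }
    inc <- sort(avg, decreasing = TRUE) / tot
    tibble(tissue = g$tissue[1],
           species = if (by_species) g$species[1] else NA_character_,
           rank = seq_along(inc), increment = inc, fraction = cumsum(inc))
  })
  out <- bind_rows(rows)
  if (!by_species) out$species <- NULL
  out
}

#' Genes needed to reach a fraction of total transcription
#'
#' @param curves Output of [complexity_curves()].
#' @param target Transcription fraction to reach. Default 0.5.
#' @return A tibble with one row per curve and `genes_to_target`.
#' @export
complexity_summary <- function(curves, target = 0.5) {
  groups <- intersect(c("species", "tissue"), names(curves))
  curves |>
    group_by(across(dplyr::all_of(groups))) |>
    summarise(genes_to_target = min(.data$rank[.data$fraction >= target]),
              .groups = "drop")
}

#' Plot transcriptome complexity curves
#' @param curves Output of [complexity_curves()].
#' @return A ggplot object.
#' @export
plot_complexity_curves <- function(curves) {
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$rank, .data$fraction,
                                            colour = .data$tissue)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "genes (decreasing expression)",
                  y = "cumulative fraction of transcription") +
    ggplot2::theme_minimal()
  if ("species" %in% names(curves)) {
    p <- p + ggplot2::facet_wrap(~species)
  }
  p
}

#' All-versus-all Pearson correlation of expression profiles
#'
#' Profiles are correlated on `log2(value + 1)` by default (the standard
#' transform for RPKM-scale data; `log_transform = FALSE` uses raw values).
#' At `level = "tissue"` samples are first averaged within each
#' (species, tissue) pair, then transformed. Zero-variance profiles yield
#' `NA` correlations.
#'
#' @param mat Wide expression tibble.
#' @param meta Sample metadata.
#' @param level `"tissue"` (default) or `"sample"`.
#' @param log_transform Correlate on `log2(x + 1)`? Default `TRUE`.
#' @return A `correlation_tbl`: long tibble with `profile_a`, `profile_b`,
#'   `species_a`, `tissue_a`, `species_b`, `tissue_b`, `r`; the square
#'   matrix is in `attr(, "matrix")` and profile metadata in
#'   `attr(, "profiles")`.
#' @export
correlation_matrix <- function(mat, meta, level = c("tissue", "sample"),
                               log_transform = TRUE) {
  level <- match.arg(level)
  validate_expression(mat, meta)
  samples <- setdiff(names(mat), "gene")
  meta <- filter(meta, .data$sample %in% samples)
  if (nrow(mat) < 2) stop("need >= 2 genes to correlate profiles")
  if (level == "sample") {
    prof <- as.matrix(mat[meta$sample])
    colnames(prof) <- meta$sample
    pmeta <- tibble(profile = meta$sample, species = meta$species,
                    tissue = meta$tissue)
  } else {
    groups <- split(meta, paste(meta$species, meta$tissue, sep = "|"))
    prof <- vapply(groups, function(g) rowMeans(as.matrix(mat[g$sample])),
                   numeric(nrow(mat)))
    pmeta <- tibble(profile = names(groups),
                    species = vapply(groups, function(g) g$species[1],
                                     character(1)),
                    tissue = vapply(groups, function(g) g$tissue[1],
                                    character(1)))
  }
  if (log_transform) prof <- log2(prof + 1)
  r <- suppressWarnings(cor(prof, method = "pearson"))
  long <- as_tibble(as.data.frame(as.table(r), stringsAsFactors = FALSE))
  names(long) <- c("profile_a", "profile_b", "r")
  long <- long |>
    left_join(setNames(pmeta, c("profile_a", "species_a", "tissue_a")),
              by = "profile_a") |>
    left_join(setNames(pmeta, c("profile_b", "species_b", "tissue_b")),
              by = "profile_b") |>
    select("profile_a", "profile_b", "species_a", "tissue_a", "species_b",
           "tissue_b", "r")
  attr(long, "matrix") <- r
  attr(long, "profiles") <- pmeta
  class(long) <- c("correlation_tbl", class(long))
  long
}

#' Average-linkage dendrogram of expression profiles
#'
#' Clusters profiles with average linkage on distance `1 - r`.
#'
#' @param corr A [correlation_matrix()] result.
#' @return An [ape::as.phylo()] tree (writable as newick).
#' @export
correlation_dendrogram <- function(corr) {
  r <- attr(corr, "matrix")
  if (is.null(r)) stop("corr must come from correlation_matrix()")
  ape::as.phylo(hclust(as.dist(1 - r), method = "average"))
}

#' Tissue- versus species-dominated clustering
#'
#' A tissue shows tissue-dominated clustering when, in both species, the
#' nearest neighbour (highest Pearson r) of that species' tissue profile is
#' the same tissue in the other species — the signature of a conserved
#' regulatory program. Otherwise the tissue clusters by species. Tissues
#' present in only one species are excluded with a warning.
#'
#' @param corr A tissue-level [correlation_matrix()] result covering two
#'   species.
#' @return A tibble with `tissue`, `pattern` (`"tissue_dominated"` or
#'   `"species_dominated"`) and the nearest-neighbour profile of each
#'   species' copy; the profile dendrogram is in `attr(, "dendrogram")`.
#' @export
classify_clustering_pattern <- function(corr) {
  pmeta <- attr(corr, "profiles")
  r <- attr(corr, "matrix")
  if (is.null(pmeta) || is.null(r)) {
    stop("corr must come from correlation_matrix()")
  }
  species <- sort(unique(pmeta$species))
  if (length(species) != 2) stop("need profiles from exactly two species")
  shared <- names(which(table(unique(pmeta[c("species", "tissue")])$tissue)
                        == 2))
  dropped <- setdiff(unique(pmeta$tissue), shared)
  if (length(dropped) > 0) {
    warning("tissues present in one species only were excluded: ",
            paste(dropped, collapse = ", "))
  }
  nn <- function(profile) {
    row <- r[profile, ]
    row <- row[setdiff(names(row), profile)]
    names(which.max(row))
  }
  rows <- lapply(sort(shared), function(t) {
    p1 <- pmeta$profile[pmeta$species == species[1] & pmeta$tissue == t]
    p2 <- pmeta$profile[pmeta$species == species[2] & pmeta$tissue == t]
    nn1 <- nn(p1)
    nn2 <- nn(p2)
    tied <- nn1 == p2 && nn2 == p1
    tibble(tissue = t,
           pattern = if (tied) "tissue_dominated" else "species_dominated",
           nn_species_a = nn1, nn_species_b = nn2)
  })
  out <- bind_rows(rows)
  attr(out, "dendrogram") <- correlation_dendrogram(corr)
  out
}

## internal: two-sided Wilcoxon rank-sum p-value. Exact enumeration of all
## group labelings when both groups have <= max_exact observations (valid
## with ties); otherwise the tie-corrected normal approximation.
wilcoxon_p <- function(a, b, max_exact = 8L) {
  na <- length(a)
  nb <- length(b)
  if (na <= max_exact && nb <= max_exact) {
    pooled <- c(a, b)
    rk <- rank(pooled)
    w_obs <- sum(rk[seq_len(na)])
    combs <- combn(na + nb, na)
    w_all <- colSums(matrix(rk[combs], nrow = na))
    eps <- 1e-9
    p_low <- mean(w_all <= w_obs + eps)
    p_high <- mean(w_all >= w_obs - eps)
    min(1, 2 * min(p_low, p_high))
  } else {
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                        correct = TRUE)$p.value)
  }
}

#' Differential genes by Wilcoxon rank-sum test and fold change
#'
#' A gene is called higher in group A when the two-sided Wilcoxon rank-sum
#' p-value is below `alpha` and the ratio of group means exceeds `min_fc`
#' (a pseudocount guards against zero means); symmetrically for group B.
#' P-values are computed by exact enumeration of all group labelings when
#' both groups have at most `max_exact` samples (correct in the presence of
#' ties), and by the tie-corrected normal approximation otherwise.
#'
#' @param mat Wide expression tibble.
#' @param group_a,group_b Character vectors of sample column names (each
#'   non-empty, >= 2 samples recommended).
#' @param alpha Significance threshold (strict `<`). Default 0.05.
#' @param min_fc Mean fold-change threshold (strict `>`). Default 2.
#' @param pseudocount Added to both means before the ratio. Default 0.01.
#' @param max_exact Largest group size for exact enumeration. Default 8.
#' @return A tibble with `gene`, `mean_a`, `mean_b`, `fold_change`
#'   (direction-aware ratio), `p_value` and `direction` (`"A_high"`,
#'   `"B_high"` or `NA`).
#' @export
differential_genes <- function(mat, group_a, group_b, alpha = 0.05,
                               min_fc = 2, pseudocount = 0.01,
                               max_exact = 8L) {
  validate_expression(mat)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups need at least one sample")
  }
  miss <- setdiff(c(group_a, group_b), names(mat))
  if (length(miss) > 0) stop("unknown samples: ", paste(miss, collapse = ", "))
  ma <- as.matrix(mat[group_a])
  mb <- as.matrix(mat[group_b])
  mean_a <- rowMeans(ma)
  mean_b <- rowMeans(mb)
  p <- vapply(seq_len(nrow(mat)), function(i) {
    if (all(ma[i, 1] == c(ma[i, ], mb[i, ]))) return(1)  # constant gene
    wilcoxon_p(ma[i, ], mb[i, ], max_exact)
  }, numeric(1))
  fc_a <- (mean_a + pseudocount) / (mean_b + pseudocount)
  direction <- dplyr::case_when(
    p < alpha & fc_a > min_fc ~ "A_high",
    p < alpha & 1 / fc_a > min_fc ~ "B_high",
    TRUE ~ NA_character_)
  tibble(gene = mat$gene, mean_a = mean_a, mean_b = mean_b,
         fold_change = ifelse(fc_a >= 1, fc_a, 1 / fc_a),
         p_value = p, direction = direction)
}
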