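EVIDENCE_CLASSES <- c("cDNA", "EST", "RNAseq", "RNAseq_high_confidence",
                      "protein", "RefSeq", "NCBI", "other_species_refseq")

## transcript/expression evidence classes that count as "independent pieces
## of evidence" for confidence-level assignment (annotation classes — RefSeq,
## NCBI, other-species RefSeq — never count; protein optionally does)
independent_classes <- function(count_protein = FALSE) {
  c("cDNA", "EST", "RNAseq_high_confidence", if (count_protein) "protein")
}

## evidence-priority order used for tie-breaking during curation
EVIDENCE_PRIORITY <- c(cDNA = 1, EST = 2, RNAseq_high_confidence = 3,
                       NCBI = 3, RefSeq = 3, RNAseq = 3.5,
                       protein = 4, other_species_refseq = 4)

validate_evidence <- function(evidence) {
  validate_gene_models(evidence)
  if (nrow(evidence) == 0) return(invisible(evidence))
  if (!"evidence_class" %in% names(evidence)) {
    stop("evidence table needs an evidence_class column")
  }
  bad <- !evidence$evidence_class %in% EVIDENCE_CLASSES
  if (any(bad)) {
    stop("unknown evidence class: ",
         paste(unique(evidence$evidence_class[bad]), collapse = ", "))
  }
  is_rna <- evidence$evidence_class %in% c("RNAseq", "RNAseq_high_confidence")
  if (any(is_rna)) {
    if (!"tissue" %in% names(evidence) ||
        any(is.na(evidence$tissue[is_rna]) | !nzchar(evidence$tissue[is_rna]))) {
      stop("RNA-seq evidence alignments require a non-empty tissue label")
    }
  }
  invisible(evidence)
}

#' Keep RNA-seq alignments whose structure recurs in at least two tissues
#'
#' Assembled RNA-seq transcripts are only trusted when the same structure is
#' observed in two or more distinct tissues or cell types (replicates of one
#' tissue do not count). Recurrence means an identical intron chain for
#' multi-exon transcripts, or at least `min_reciprocal` reciprocal exonic
#' overlap for single-exon transcripts. Surviving alignments are relabelled
#' `RNAseq_high_confidence`; the filter is idempotent.
#'
#' @param evidence An evidence tibble whose rows have `evidence_class` equal
#'   to `"RNAseq"` (or `"RNAseq_high_confidence"`) and a `tissue` column.
#' @param min_reciprocal Reciprocal-overlap threshold for single-exon
#'   recurrence (default 0.9).
#' @param stranded Strand-aware single-exon matching? Default `TRUE`.
#' @return The retained alignments, with `evidence_class` set to
#'   `"RNAseq_high_confidence"`.
#' @export
filter_high_confidence_rnaseq <- function(evidence, min_reciprocal = 0.9,
                                          stranded = TRUE) {
  if (nrow(evidence) == 0) return(evidence)
  if (!all(evidence$evidence_class %in%
           c("RNAseq", "RNAseq_high_confidence"))) {
    stop("filter_high_confidence_rnaseq expects RNAseq alignments only")
  }
  validate_evidence(evidence)

  chains <- intron_chain(evidence)
  meta <- model_spans(evidence) |>
    left_join(distinct(evidence, .data$transcript_id, .data$tissue),
              by = "transcript_id") |>
    left_join(select(chains, "transcript_id", "intron_chain"),
              by = "transcript_id")

  multi <- filter(meta, .data$n_exons > 1)
  keep_multi <- multi |>
    group_by(.data$intron_chain) |>
    mutate(n_tissues = dplyr::n_distinct(.data$tissue)) |>
    ungroup() |>
    filter(.data$n_tissues >= 2)

  single <- filter(meta, .data$n_exons == 1)
  keep_single_ids <- character()
  if (nrow(single) > 0) {
    gr <- GenomicRanges::GRanges(
      single$chrom, IRanges::IRanges(single$span_start + 1L, single$span_end),
      strand = ifelse(single$strand == ".", "*", single$strand))
    hits <- GenomicRanges::findOverlaps(gr, gr,
                                        ignore.strand = !stranded)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    len <- single$span_end - single$span_start
    ov <- pmin(single$span_end[qh], single$span_end[sh]) -
      pmax(single$span_start[qh], single$span_start[sh])
    recip <- pmin(ov / len[qh], ov / len[sh])
    ok <- qh != sh & recip >= min_reciprocal &
      single$tissue[qh] != single$tissue[sh]
    keep_single_ids <- unique(single$transcript_id[qh[ok]])
  }

  keep_ids <- c(keep_multi$transcript_id, keep_single_ids)
  out <- filter(evidence, .data$transcript_id %in% keep_ids)
  out$evidence_class <- "RNAseq_high_confidence"
  out
}

#' Per-model evidence coverage and supporting classes
#'
#' For every gene model, the fraction of its exonic bases covered by the
#' union of each evidence class's alignments (fragments of one class are
#' unioned, never summed). A class supports the model when its coverage
#' reaches `support_threshold` (default 0.7, the fraction of model length
#' that a reference annotation must cover for highest-confidence status —
#' applied uniformly to every class). The number of independent pieces of
#' evidence counts supporting transcript classes only (cDNA, EST,
#' high-confidence RNA-seq; protein when `count_protein = TRUE`).
#'
#' @param models A gene model tibble (one or many models).
#' @param evidence An evidence tibble (gene model columns plus
#'   `evidence_class`, and `tissue` for RNA-seq).
#' @param support_threshold Coverage fraction at which a class supports a
#'   model. Default 0.7.
#' @param count_protein Count protein alignments as independent evidence?
#'   Default `FALSE`.
#' @param stranded Strand-aware coverage? Default `TRUE` (`"."` matches
#'   either strand).
#' @return A tibble with one row per model: `model_id`, `exonic_length`, one
#'   coverage column per evidence class (named `cov_<class>`),
#'   `refseq_coverage`, `supporting` (list of supporting class names) and
#'   `n_independent`.
#' @export
compute_support <- function(models, evidence, support_threshold = 0.7,
                            count_protein = FALSE, stranded = TRUE) {
  validate_gene_models(models)
  validate_evidence(evidence)
  classes <- EVIDENCE_CLASSES
  ev_by_class <- lapply(setNames(classes, classes), function(cl) {
    evidence[evidence$evidence_class == cl, ]
  })

  rows <- lapply(split_models(models), function(tx) {
    len <- sum(tx$end - tx$start)
    cov <- vapply(classes, function(cl) {
      ev <- ev_by_class[[cl]]
      if (nrow(ev) == 0) return(0)
      keep <- ev$chrom == tx$chrom[1] & ev$start < max(tx$end) &
        ev$end > min(tx$start)
      if (stranded) keep <- keep & strand_compatible(ev$strand, tx$strand[1])
      ev <- ev[keep, ]
      covered_bases(tx, ev) / len
    }, numeric(1))
    c(list(model_id = tx$transcript_id[1], exonic_length = len),
      as.list(setNames(cov, paste0("cov_", classes))))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$refseq_coverage <- out$cov_RefSeq
  cov_mat <- as.matrix(out[paste0("cov_", classes)])
  out$supporting <- lapply(seq_len(nrow(out)), function(i) {
    classes[cov_mat[i, ] >= support_threshold]
  })
  ind <- independent_classes(count_protein)
  out$n_independent <- vapply(out$supporting,
                              function(s) length(intersect(s, ind)),
                              integer(1))
  out
}

#' Assign four-tier confidence levels from support profiles
#'
#' Levels follow reference-annotation concordance and the number of
#' independent evidence classes:
#'
#' * level 1 — over 70% of the model covered by the reference (RefSeq)
#'   annotation and at least two independent pieces of evidence;
#' * level 2 — supported by the reference annotation but lacking the two
#'   independent evidences required for level 1 (the "reference only" tier;
#'   a reference-backed model with a single independent evidence also lands
#'   here, the tiers not covering that case explicitly);
#' * level 3 — at least two independent pieces of evidence but absent from
#'   the reference annotation;
#' * level 4 — exactly one piece of evidence and no reference support.
#'
#' Models supported by nothing at all fall outside the published tiers and
#' are flagged `unsupported` (level `NA`) rather than forced into level 4.
#'
#' @param profiles Output of [compute_support()].
#' @param support_threshold Same threshold used to compute the profiles.
#' @return `profiles` with `level` (integer or `NA`) and `unsupported`
#'   (logical) columns added.
#' @export
assign_confidence_level <- function(profiles, support_threshold = 0.7) {
  stopifnot(all(c("refseq_coverage", "supporting", "n_independent") %in%
                  names(profiles)))
  n_ind <- profiles$n_independent
  refseq_cov <- profiles$refseq_coverage
  refseq_supports <- refseq_cov >= support_threshold
  any_support <- lengths(profiles$supporting) > 0
  level <- rep(NA_integer_, nrow(profiles))
  level[any_support] <- 4L
  level[!refseq_supports & n_ind >= 2] <- 3L
  level[refseq_supports] <- 2L
  level[refseq_cov > 0.7 & n_ind >= 2] <- 1L
  profiles$level <- level
  profiles$unsupported <- !any_support
  profiles
}
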