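#' Base-level sensitivity, specificity and congruency of a model pair
#'
#' For an annotation unit `i` and an evidence alignment `j`, sensitivity is
#' `|i n j| / |j|`, specificity is `|i n j| / |i|`, and congruency is their
#' average, where `|.|` counts exonic bases and `|i n j|` counts bases shared
#' by both exonic sets. RNA-derived evidence cannot cover introns, so base
#' sets are exonic by default; `span = TRUE` switches `|i|` and `|j|` to full
#' genomic spans for a literal full-gene-length reading.
#'
#' @param i Annotation gene model (single-transcript tibble).
#' @param j Evidence gene model (single-transcript tibble).
#' @param stranded Strand-aware intersection? Default `TRUE`.
#' @param span Use genomic spans instead of exonic base sets? Default
#'   `FALSE`.
#' @return A one-row tibble with `sn`, `sp`, `c`.
#' @examples
#' i <- gene_models(data.frame(transcript_id = "i", chrom = "c",
#'                             start = 100, end = 200, strand = "+"))
#' j <- gene_models(data.frame(transcript_id = "j", chrom = "c",
#'                             start = 150, end = 250, strand = "+"))
#' congruency_pair(i, j) # sn = sp = c = 0.5
#' @export
congruency_pair <- function(i, j, stranded = TRUE, span = FALSE) {
  if (span) {
    si <- model_spans(i); sj <- model_spans(j)
    ii <- tibble(transcript_id = si$transcript_id, chrom = si$chrom,
                 start = si$span_start, end = si$span_end,
                 strand = si$strand)
    jj <- tibble(transcript_id = sj$transcript_id, chrom = sj$chrom,
                 start = sj$span_start, end = sj$span_end,
                 strand = sj$strand)
    i <- ii; j <- jj
  }
  inter <- exonic_overlap(i, j, stranded = stranded)
  li <- sum(i$end - i$start)
  lj <- sum(j$end - j$start)
  sn <- inter / lj
  sp <- inter / li
  tibble(sn = sn, sp = sp, c = (sn + sp) / 2)
}

#' Score an annotation against evidence at gene or exon level
#'
#' Gene level: every gene model is paired with its best-matching overlapping
#' alignment of each evidence class (the one maximizing congruency); models
#' with no overlapping alignment of a class contribute a (0, 0, 0) record —
#' dropping them would inflate the curves. Exon level: every annotated exon
#' `i` is scored against `j` = the union of that class's evidence exons
#' overlapping it.
#'
#' @param annotation A gene model tibble.
#' @param evidence An evidence tibble.
#' @param unit `"gene"` or `"exon"`.
#' @param label Annotation version label carried into the report.
#' @param stranded Strand-aware? Default `TRUE`.
#' @return A `congruency_report` tibble: `unit_id`, `evidence_class`, `sn`,
#'   `sp`, `c`, `label`, with attributes `unit` and `label`.
#' @export
evaluate_annotation <- function(annotation, evidence,
                                unit = c("gene", "exon"),
                                label = "annotation", stranded = TRUE) {
  unit <- match.arg(unit)
  validate_gene_models(annotation)
  validate_evidence(evidence)
  classes <- sort(unique(evidence$evidence_class))
  out <- if (unit == "gene") {
    eval_gene_level(annotation, evidence, classes, stranded)
  } else {
    eval_exon_level(annotation, evidence, classes, stranded)
  }
  out$label <- label
  attr(out, "unit") <- unit
  attr(out, "label") <- label
  class(out) <- c("congruency_report", class(out))
  out
}

eval_gene_level <- function(annotation, evidence, classes, stranded) {
  ev_split <- lapply(setNames(classes, classes), function(cl) {
    split_models(filter(evidence, .data$evidence_class == cl))
  })
  rows <- lapply(split_models(annotation), function(tx) {
    span <- c(min(tx$start), max(tx$end))
    per_class <- lapply(classes, function(cl) {
      best <- tibble(sn = 0, sp = 0, c = 0)
      for (al in ev_split[[cl]]) {
        if (al$chrom[1] != tx$chrom[1]) next
        if (max(al$end) <= span[1] || min(al$start) >= span[2]) next
        cur <- congruency_pair(tx, al, stranded = stranded)
        if (cur$c > best$c) best <- cur
      }
      best$evidence_class <- cl
      best
    })
    res <- bind_rows(per_class)
    res$unit_id <- tx$transcript_id[1]
    res
  })
  select(bind_rows(rows), "unit_id", "evidence_class", "sn", "sp", "c")
}

eval_exon_level <- function(annotation, evidence, classes, stranded) {
  rows <- list()
  k <- 1L
  for (tx in split_models(annotation)) {
    tx <- arrange(tx, .data$start)
    for (e in seq_len(nrow(tx))) {
      ex <- tx[e, ]
      exon_id <- paste0(ex$transcript_id, ".exon", e)
      for (cl in classes) {
        sel <- evidence$evidence_class == cl & evidence$chrom == ex$chrom &
          evidence$start < ex$end & evidence$end > ex$start
        if (stranded) {
          sel <- sel & strand_compatible(evidence$strand, ex$strand)
        }
        ev <- evidence[sel, ]
        if (nrow(ev) == 0) {
          rows[[k]] <- tibble(unit_id = exon_id, evidence_class = cl,
                              sn = 0, sp = 0, c = 0)
        } else {
          ir <- union_intervals(ev$start, ev$end)
          lj <- sum(ir$end - ir$start)
          inter <- intersect_length(ir, list(start = ex$start, end = ex$end))
          sn <- inter / lj
          sp <- inter / (ex$end - ex$start)
          rows[[k]] <- tibble(unit_id = exon_id, evidence_class = cl,
                              sn = sn, sp = sp, c = (sn + sp) / 2)
        }
        k <- k + 1L
      }
    }
  }
  bind_rows(rows)
}

#' Cumulative congruence curve of a report
#'
#' For a grid of thresholds t in \[0, 1\] (step 0.01), the fraction of units
#' whose congruency is at least t — a monotone non-increasing survival curve
#' suitable for overlaying several annotation versions.
#'
#' @param report One [evaluate_annotation()] report, or several row-bound
#'   together (distinguished by `label`).
#' @param by_class Keep one curve per evidence class (default `TRUE`)?
#' @return A tibble with `label`, `evidence_class` (when `by_class`),
#'   `threshold`, `fraction`.
#' @export
cumulative_congruence <- function(report, by_class = TRUE) {
  if (nrow(report) == 0) stop("empty congruency report")
  grid <- seq(0, 1, by = 0.01)
  groups <- if (by_class) c("label", "evidence_class") else "label"
  report |>
    group_by(across(dplyr::all_of(groups))) |>
    dplyr::reframe(threshold = grid,
                   fraction = vapply(grid, function(t) mean(.data$c >= t),
                                     numeric(1)))
}

#' Plot cumulative congruence curves
#'
#' @param curves Output of [cumulative_congruence()].
#' @return A ggplot object (one panel per evidence class when present).
#' @export
plot_cumulative_congruence <- function(curves) {
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$threshold, .data$fraction,
                                            colour = .data$label)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "congruency threshold",
                  y = "fraction of units ≥ threshold",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if ("evidence_class" %in% names(curves)) {
    p <- p + ggplot2::facet_wrap(~evidence_class)
  }
  p
}
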