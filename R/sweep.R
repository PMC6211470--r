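#' Reference exons detected by an assembly
#'
#' A reference exon counts as detected when strictly more than
#' `min_overlap` (default 0.9) of its bases are covered by the union of
#' assembled exons. Exons are identified as `<transcript_id>.exon<k>` in
#' genomic order.
#'
#' @param assembled Assembled-transcript gene model tibble (one assembly).
#' @param refseq Reference annotation tibble.
#' @param min_overlap Strict lower bound on the covered fraction. Default
#'   0.9.
#' @param stranded Strand-aware coverage? Default `TRUE`.
#' @return Character vector of detected reference exon ids.
#' @export
detected_exons <- function(assembled, refseq, min_overlap = 0.9,
                           stranded = TRUE) {
  ex <- refseq_exon_table(refseq)
  if (nrow(ex) == 0 || nrow(assembled) == 0) return(character())
  out <- character()
  for (k in seq_len(nrow(ex))) {
    keep <- assembled$chrom == ex$chrom[k] & assembled$start < ex$end[k] &
      assembled$end > ex$start[k]
    if (stranded) {
      keep <- keep & strand_compatible(assembled$strand, ex$strand[k])
    }
    cover <- assembled[keep, ]
    frac <- covered_bases(ex[k, ], cover) / (ex$end[k] - ex$start[k])
    if (frac > min_overlap) out <- c(out, ex$exon_id[k])
  }
  out
}

refseq_exon_table <- function(refseq) {
  if (nrow(refseq) == 0) {
    return(tibble(exon_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  refseq |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(exon_id = paste0(.data$transcript_id, ".exon", row_number())) |>
    ungroup() |>
    select("exon_id", "chrom", "start", "end", "strand")
}

#' Detected exons whose assembly is free of intron pollution
#'
#' A detected reference exon is precise when the assembled exons overlapping
#' it keep strictly less than `max_pollution` (default 0.1) of their bases
#' in reference non-exonic space (introns and intergenic regions). With
#' `denominator = "refseq_exon"` the polluted bases are instead divided by
#' the reference exon's length — an alternative reading of the same
#' intron-pollution idea.
#'
#' @param detected Character vector from [detected_exons()].
#' @param assembled Assembled gene model tibble.
#' @param refseq Reference annotation tibble.
#' @param max_pollution Strict upper bound on the polluted fraction. Default
#'   0.1.
#' @param denominator `"assembled"` (default) or `"refseq_exon"`.
#' @param stranded Strand-aware matching? Default `TRUE`.
#' @return The subset of `detected` that is precise.
#' @export
precise_detected_exons <- function(detected, assembled, refseq,
                                   max_pollution = 0.1,
                                   denominator = c("assembled", "refseq_exon"),
                                   stranded = TRUE) {
  denominator <- match.arg(denominator)
  ex <- refseq_exon_table(refseq)
  stopifnot(all(detected %in% ex$exon_id))
  if (length(detected) == 0) return(character())
  ## reference exonic space per chromosome (strand-blind: non-exon region
  ## means intronic/intergenic sequence regardless of strand)
  exonic_by_chrom <- lapply(split(ex, ex$chrom), function(d) {
    union_intervals(d$start, d$end)
  })
  keep <- character()
  for (eid in detected) {
    r <- ex[ex$exon_id == eid, ]
    sel <- assembled$chrom == r$chrom & assembled$start < r$end &
      assembled$end > r$start
    if (stranded) sel <- sel & strand_compatible(assembled$strand, r$strand)
    cover <- assembled[sel, ]
    if (nrow(cover) == 0) next
    ic <- union_intervals(cover$start, cover$end)
    inside <- intersect_length(ic, exonic_by_chrom[[r$chrom]])
    total <- sum(ic$end - ic$start)
    polluted <- total - inside
    denom <- if (denominator == "assembled") total else r$end - r$start
    if (polluted / denom < max_pollution) keep <- c(keep, eid)
  }
  keep
}

#' Exon detection sensitivity/precision across a stringency sweep
#'
#' For each assembly-stringency value `c`, counts the detected reference
#' exons (DE) and the precisely detected ones (PDE), and reports sensitivity
#' `DE / MDE` (MDE = DE at the default, most permissive `c`) and precision
#' `PDE / DE`. Precision is `NA` when an assembly detects nothing.
#'
#' @param assemblies Named list of gene model tibbles; names are the numeric
#'   `c` values.
#' @param refseq Reference annotation tibble.
#' @param default_c The `c` value whose detected-exon count defines MDE.
#' @param min_overlap,max_pollution,denominator,stranded Passed to
#'   [detected_exons()] and [precise_detected_exons()].
#' @return A `sweep_result` tibble: `c`, `DE`, `PDE`, `sensitivity`,
#'   `precision`, with attribute `MDE`.
#' @export
run_sweep <- function(assemblies, refseq, default_c, min_overlap = 0.9,
                      max_pollution = 0.1,
                      denominator = c("assembled", "refseq_exon"),
                      stranded = TRUE) {
  denominator <- match.arg(denominator)
  cs <- as.numeric(names(assemblies))
  if (any(is.na(cs))) stop("assembly list names must be numeric c values")
  if (!any(cs == default_c)) stop("default_c not present among assemblies")
  rows <- lapply(seq_along(assemblies), function(k) {
    de <- detected_exons(assemblies[[k]], refseq, min_overlap = min_overlap,
                         stranded = stranded)
    pde <- precise_detected_exons(de, assemblies[[k]], refseq,
                                  max_pollution = max_pollution,
                                  denominator = denominator,
                                  stranded = stranded)
    tibble(c = cs[k], DE = length(de), PDE = length(pde))
  })
  out <- arrange(bind_rows(rows), .data$c)
  mde <- out$DE[out$c == default_c][1]
  if (mde == 0) stop("no exons detected at the default c; MDE undefined")
  out$sensitivity <- out$DE / mde
  out$precision <- ifelse(out$DE > 0, out$PDE / out$DE, NA_real_)
  attr(out, "MDE") <- mde
  class(out) <- c("sweep_result", class(out))
  out
}

#' Pick the stringency where precision is closest to sensitivity
#'
#' Returns the `c` minimizing `|precision - sensitivity|`; ties break toward
#' the smaller (more permissive) `c`. Values with undefined precision are
#' skipped.
#'
#' @param sweep A [run_sweep()] result (or any tibble with `c`,
#'   `sensitivity`, `precision`).
#' @return The selected `c` value.
#' @export
select_optimal_c <- function(sweep) {
  ok <- !is.na(sweep$precision)
  if (!any(ok)) stop("precision undefined at every c")
  s <- sweep[ok, ]
  s <- arrange(s, .data$c)
  s$c[which.min(abs(s$precision - s$sensitivity))]
}

#' Plot a stringency sweep
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot of sensitivity and precision against `c`, with the
#'   selected crossing marked.
#' @export
autoplot.sweep_result <- function(object, ...) {
  best <- select_optimal_c(object)
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("sensitivity", "precision"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$c, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, linetype = 2) +
    ggplot2::labs(x = "assembly stringency (-c)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
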