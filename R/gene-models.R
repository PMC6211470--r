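#' Gene model tables
#'
#' Throughout the package an annotation is a plain tibble with one row per
#' exon. Coordinates are 0-based half-open (`start` inclusive, `end`
#' exclusive), the single internal convention; format readers and writers
#' convert from/to the 1-based closed convention of GFF3/GTF. Required
#' columns:
#'
#' * `transcript_id` — unique id of the gene model (the unit being curated)
#' * `gene_id`       — grouping id; equals `transcript_id` when no grouping
#'                     attribute is present in the input
#' * `chrom`, `start`, `end`, `strand` — exon coordinates; strand is one of
#'   `"+"`, `"-"`, `"."` (unstranded, matches either)
#' * `source`        — free-text provenance
#'
#' Additional columns (e.g. `evidence_class`, `tissue`, `best_refseq`,
#' `origin`) travel along untouched. `gene_models()` coerces and validates;
#' all invariants (non-empty models, sorted pairwise-disjoint exons sharing
#' one chrom/strand, `0 <= start < end`) are enforced.
#'
#' @param x A data frame with at least `transcript_id`, `chrom`, `start`,
#'   `end`, `strand` columns.
#' @return A validated tibble of exons, sorted by (chrom, start,
#'   transcript_id).
#' @examples
#' gene_models(data.frame(
#'   transcript_id = "t1", chrom = "chr1",
#'   start = c(0, 200), end = c(100, 300), strand = "+"
#' ))
#' @export
gene_models <- function(x) {
  x <- as_tibble(x)
  if (!"gene_id" %in% names(x)) x$gene_id <- x$transcript_id
  if (!"source" %in% names(x)) x$source <- "annocurate"
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x <- dplyr::relocate(x, "transcript_id", "gene_id", "chrom", "start", "end",
                       "strand", "source")
  x <- arrange(x, .data$chrom, .data$start, .data$transcript_id)
  validate_gene_models(x)
  x
}

#' Validate a gene model table
#'
#' Checks the exon-table invariants and fails with an informative message on
#' the first violation.
#'
#' @param x A gene model tibble (see [gene_models()]).
#' @return `x`, invisibly.
#' @export
validate_gene_models <- function(x) {
  req <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    stop("gene model table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) stop("empty chromosome name")
  if (!all(x$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  bad <- x$start < 0 | x$start >= x$end
  if (any(bad)) {
    stop("invalid exon interval (need 0 <= start < end) for transcript ",
         x$transcript_id[which(bad)[1]])
  }
  per <- split(x, x$transcript_id)
  for (tx in per) {
    id <- tx$transcript_id[1]
    if (length(unique(tx$chrom)) > 1 || length(unique(tx$strand)) > 1) {
      stop("exons of transcript ", id, " span multiple chrom/strand values")
    }
    s <- sort(tx$start)
    e <- tx$end[order(tx$start)]
    if (any(s[-1] < e[-length(e)])) {
      stop("overlapping exons in transcript ", id)
    }
  }
  invisible(x)
}

empty_models <- function() {
  tibble(transcript_id = character(), gene_id = character(),
         chrom = character(), start = integer(), end = integer(),
         strand = character(), source = character())
}

## internal: exon tibble -> GRanges ("." mapped to "*")
models_to_gr <- function(x) {
  if (nrow(x) == 0) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand == ".", "*", x$strand)
  )
  S4Vectors::mcols(gr)$transcript_id <- x$transcript_id
  gr
}

#' Per-model summary: span and exonic length
#'
#' One row per transcript, with the genomic span (`[span_start, span_end)`),
#' exon count and total exonic length in bases.
#'
#' @param models A gene model tibble.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `span_start`, `span_end`, `n_exons`, `exonic_length`.
#' @export
model_spans <- function(models) {
  if (nrow(models) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  chrom = character(), strand = character(),
                  span_start = integer(), span_end = integer(),
                  n_exons = integer(), exonic_length = integer()))
  }
  f <- factor(models$transcript_id)
  idx <- unname(vapply(split(seq_len(nrow(models)), f), `[`, integer(1), 1))
  tibble(
    transcript_id = levels(f),
    gene_id = models$gene_id[idx],
    chrom = models$chrom[idx],
    strand = models$strand[idx],
    span_start = as.integer(unname(vapply(split(models$start, f), min,
                                          numeric(1)))),
    span_end = as.integer(unname(vapply(split(models$end, f), max,
                                        numeric(1)))),
    n_exons = as.integer(tabulate(f)),
    exonic_length = as.integer(unname(vapply(split(models$end - models$start,
                                                   f), sum, numeric(1))))
  )
}

strand_compatible <- function(a, b) a == "." | b == "." | a == b

#' Exonic overlap between two gene models
#'
#' The number of bases in the intersection of the two models' exonic base
#' sets — the `|i .. j|` primitive of the congruency formulas. Zero when the
#' models sit on different chromosomes or (with `stranded = TRUE`, the
#' default) on incompatible strands; `"."` matches either strand.
#'
#' @param a,b Gene model tibbles each containing a single transcript.
#' @param stranded Require strand compatibility? Default `TRUE`.
#' @return Integer number of shared exonic bases.
#' @examples
#' a <- gene_models(data.frame(transcript_id = "a", chrom = "c",
#'                             start = 100, end = 200, strand = "+"))
#' b <- gene_models(data.frame(transcript_id = "b", chrom = "c",
#'                             start = 150, end = 250, strand = "+"))
#' exonic_overlap(a, b) # 50
#' @export
exonic_overlap <- function(a, b, stranded = TRUE) {
  stopifnot(length(unique(a$transcript_id)) == 1,
            length(unique(b$transcript_id)) == 1)
  if (a$chrom[1] != b$chrom[1]) return(0L)
  if (stranded && !strand_compatible(a$strand[1], b$strand[1])) return(0L)
  intersect_length(union_intervals(a$start, a$end),
                   union_intervals(b$start, b$end))
}

## internal: union of 0-based half-open intervals -> list(start, end)
union_intervals <- function(start, end) {
  o <- order(start)
  s <- start[o]; e <- end[o]
  us <- s[1]; ue <- e[1]
  k <- 1L
  for (i in seq_along(s)[-1]) {
    if (s[i] <= ue[k]) {
      if (e[i] > ue[k]) ue[k] <- e[i]
    } else {
      k <- k + 1L
      us[k] <- s[i]; ue[k] <- e[i]
    }
  }
  list(start = us, end = ue)
}

## internal: total length of the intersection of two interval unions
intersect_length <- function(a, b) {
  total <- 0L
  i <- 1L; j <- 1L
  na <- length(a$start); nb <- length(b$start)
  while (i <= na && j <= nb) {
    lo <- max(a$start[i], b$start[j])
    hi <- min(a$end[i], b$end[j])
    if (hi > lo) total <- total + (hi - lo)
    if (a$end[i] < b$end[j]) i <- i + 1L else j <- j + 1L
  }
  as.integer(total)
}

## internal: exonic bases of `x` covered by the union of `cover` rows;
## both on one chrom already.
covered_bases <- function(x, cover) {
  if (nrow(cover) == 0 || nrow(x) == 0) return(0L)
  intersect_length(union_intervals(x$start, x$end),
                   union_intervals(cover$start, cover$end))
}

#' Query an annotation by genomic interval
#'
#' Returns the models whose genomic span intersects the query interval
#' (0-based half-open), honouring strand compatibility.
#'
#' @param models A gene model tibble.
#' @param chrom Chromosome name.
#' @param start,end Query interval, 0-based half-open.
#' @param strand Query strand; `"."` (default) matches any.
#' @param stranded Require strand compatibility? Default `TRUE`.
#' @return The subset of `models` (all exon rows of matching transcripts).
#' @export
query_overlaps <- function(models, chrom, start, end, strand = ".",
                           stranded = TRUE) {
  if (nrow(models) == 0) return(models)
  sp <- model_spans(models)
  hit <- sp$chrom == chrom & sp$span_start < end & sp$span_end > start
  if (stranded) hit <- hit & strand_compatible(sp$strand, strand)
  filter(models, .data$transcript_id %in% sp$transcript_id[hit])
}

#' Intron chain of each model
#'
#' A canonical string key for a model's internal structure: the ordered
#' intron coordinates on its chromosome/strand, or `""` for single-exon
#' models. Two multi-exon models share a structure iff their keys are equal.
#'
#' @param models A gene model tibble.
#' @return A tibble with `transcript_id`, `chrom`, `strand`, `n_exons`,
#'   `intron_chain`.
#' @export
intron_chain <- function(models) {
  if (nrow(models) == 0) {
    return(tibble(transcript_id = character(), chrom = character(),
                  strand = character(), n_exons = integer(),
                  intron_chain = character()))
  }
  per <- unname(split_models(models))
  tibble(
    transcript_id = vapply(per, function(tx) tx$transcript_id[1],
                           character(1)),
    chrom = vapply(per, function(tx) tx$chrom[1], character(1)),
    strand = vapply(per, function(tx) tx$strand[1], character(1)),
    n_exons = vapply(per, nrow, integer(1)),
    intron_chain = vapply(per, chain_of, character(1))
  )
}

## internal: fast intron-chain key of ONE single-transcript table
chain_of <- function(tx) {
  n <- nrow(tx)
  if (n < 2) return("")
  o <- order(tx$start)
  paste(tx$chrom[1], tx$strand[1],
        paste(tx$end[o][-n], tx$start[o][-1], sep = "-", collapse = ","),
        sep = ":")
}

## internal: do two single-transcript tables share identical structure
## (intron chain AND terminal boundaries within `end_slack` bases)?
same_structure <- function(a, b, end_slack = 0L) {
  if (nrow(a) != nrow(b)) return(FALSE)
  if (a$chrom[1] != b$chrom[1]) return(FALSE)
  if (chain_of(a) != chain_of(b)) return(FALSE)
  abs(min(a$start) - min(b$start)) <= end_slack &&
    abs(max(a$end) - max(b$end)) <= end_slack
}

## internal: reciprocal exonic overlap fraction between two single-exon-ish
## models: min(ov/len_a, ov/len_b)
reciprocal_overlap <- function(a, b, stranded = TRUE) {
  ov <- exonic_overlap(a, b, stranded = stranded)
  la <- sum(a$end - a$start)
  lb <- sum(b$end - b$start)
  min(ov / la, ov / lb)
}

## internal: split a model table into a named list of single-transcript
## tables, in deterministic (chrom, span_start, transcript_id) order.
split_models <- function(models) {
  if (nrow(models) == 0) return(list())
  out <- split(models, factor(models$transcript_id))
  chroms <- vapply(out, function(tx) tx$chrom[1], character(1))
  starts <- vapply(out, function(tx) min(tx$start), numeric(1))
  out[order(chroms, starts, names(out))]
}
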