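## Attribute columns that round-trip through GFF3 when present.
EXTRA_COLS <- c("evidence_class", "tissue", "best_refseq", "origin")

## internal: cheap structural scan so malformed lines are reported with a
## line number before handing the file to the importer.
check_line_shapes <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  want <- switch(format, gff3 = 9L, gtf = 9L, bed12 = 12L)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf != want) {
      stop("malformed ", format, " line ", i, ": expected ", want,
           " tab-separated fields, found ", nf)
    }
  }
  invisible(NULL)
}

#' Read an annotation file into a gene model table
#'
#' Transcript structures in GFF3, GTF or BED12 become one gene model each.
#' Coordinates are converted to the internal 0-based half-open convention
#' (GFF3/GTF are 1-based closed on disk; BED is already 0-based half-open).
#' For GFF3, exon features are attached to their `Parent` transcript and the
#' transcript feature's `gene_id` attribute (or its own `Parent`) provides
#' gene grouping; a transcript without any grouping attribute becomes a
#' single-transcript gene. Attribute keys `evidence_class`, `tissue`,
#' `best_refseq` and `origin` are recovered when present.
#'
#' @param path File to read.
#' @param format One of `"gff3"`, `"gtf"`, `"bed12"`.
#' @param stranded Unused here; kept for interface symmetry.
#' @return A validated gene model tibble (possibly empty).
#' @seealso [write_annotation()]
#' @export
read_annotation <- function(path, format = c("gff3", "gtf", "bed12"),
                            stranded = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  check_line_shapes(path, format)
  switch(format,
         gff3 = read_gff3(path),
         gtf = read_gtf(path),
         bed12 = read_bed12(path))
}

gr_strand <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  ifelse(s == "*", ".", s)
}

first_chr <- function(x) {
  ## CharacterList / list column -> first element or NA
  vapply(as.list(x), function(v) {
    if (length(v) == 0 || all(is.na(v))) NA_character_ else as.character(v[[1]])
  }, character(1))
}

read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(empty_models())
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  is_exon <- type == "exon"
  if (!any(is_exon)) return(empty_models())

  get_col <- function(obj, nm) {
    if (nm %in% names(obj)) obj[[nm]] else rep(NA_character_, nrow(obj))
  }
  parent <- if ("Parent" %in% names(mc)) first_chr(mc$Parent) else
    rep(NA_character_, length(gr))
  id <- as.character(get_col(mc, "ID"))

  ## transcript-level features carry gene grouping and extra attributes
  is_tx <- type %in% c("mRNA", "transcript")
  tx_meta <- NULL
  if (any(is_tx)) {
    tx_meta <- tibble(
      transcript_id = id[is_tx],
      tx_gene = dplyr::coalesce(as.character(get_col(mc, "gene_id"))[is_tx],
                                parent[is_tx]),
      tx_start = GenomicRanges::start(gr)[is_tx] - 1L,
      tx_end = GenomicRanges::end(gr)[is_tx]
    )
    for (col in EXTRA_COLS) {
      if (col %in% names(mc)) tx_meta[[col]] <- as.character(mc[[col]])[is_tx]
    }
  }

  ex <- tibble(
    transcript_id = dplyr::coalesce(parent[is_exon],
                                    as.character(get_col(mc, "transcript_id"))[is_exon],
                                    id[is_exon]),
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon],
    strand = gr_strand(gr)[is_exon],
    source = as.character(mc$source)[is_exon]
  )
  if (any(is.na(ex$transcript_id))) {
    stop("exon feature without Parent/ID attribute in ", path)
  }
  if (!is.null(tx_meta)) {
    ex <- left_join(ex, tx_meta, by = "transcript_id")
    bad <- !is.na(ex$tx_start) & (ex$start < ex$tx_start | ex$end > ex$tx_end)
    if (any(bad)) {
      stop("exon outside declared parent span for transcript ",
           ex$transcript_id[which(bad)[1]])
    }
    ex$gene_id <- dplyr::coalesce(ex$tx_gene, ex$transcript_id)
    ex$tx_gene <- ex$tx_start <- ex$tx_end <- NULL
  } else {
    ex$gene_id <- ex$transcript_id
  }
  if ("best_refseq" %in% names(ex)) {
    ex$best_refseq <- ex$best_refseq %in% c("true", "TRUE", "1", "yes")
  }
  gene_models(ex)
}

read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0) return(empty_models())
  mc <- S4Vectors::mcols(gr)
  keep <- as.character(mc$type) == "exon"
  if (!any(keep)) return(empty_models())
  ex <- tibble(
    transcript_id = as.character(mc$transcript_id)[keep],
    gene_id = as.character(mc$gene_id)[keep],
    chrom = as.character(GenomicRanges::seqnames(gr))[keep],
    start = GenomicRanges::start(gr)[keep] - 1L,
    end = GenomicRanges::end(gr)[keep],
    strand = gr_strand(gr)[keep],
    source = as.character(mc$source)[keep]
  )
  gene_models(ex)
}

read_bed12 <- function(path) {
  if (length(readLines(path, warn = FALSE)) == 0) return(empty_models())
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) return(empty_models())
  mc <- S4Vectors::mcols(gr)
  rows <- lapply(seq_along(gr), function(i) {
    chrom_start <- GenomicRanges::start(gr)[i] - 1L
    blocks <- mc$blocks[[i]]  # 1-based, relative to chromStart
    if (is.null(blocks) || length(blocks) == 0) {
      bs <- chrom_start
      be <- GenomicRanges::end(gr)[i]
    } else {
      bs <- chrom_start + IRanges::start(blocks) - 1L
      be <- chrom_start + IRanges::end(blocks)
    }
    tibble(
      transcript_id = as.character(mc$name[i]),
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      start = as.integer(bs), end = as.integer(be),
      strand = gr_strand(gr)[i], source = "bed12"
    )
  })
  gene_models(bind_rows(rows))
}

#' Write a gene model table to GFF3 or BED12
#'
#' The inverse of [read_annotation()]: coordinates convert back to the
#' on-disk convention, and `read_annotation(write_annotation(x))` reproduces
#' ids, coordinates and strands exactly. GFF3 output contains one `mRNA`
#' feature per transcript (holding `gene_id` and any extra attribute columns)
#' and one `exon` feature per exon.
#'
#' @param models A gene model tibble.
#' @param path Output file.
#' @param format `"gff3"` or `"bed12"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  validate_gene_models(models)
  if (format == "gff3") write_gff3(models, path) else write_bed12(models, path)
  invisible(path)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

write_gff3 <- function(models, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(models) == 0) return(invisible(path))
  extras <- intersect(EXTRA_COLS, names(models))
  for (tx in split_models(models)) {
    tx <- arrange(tx, .data$start)
    id <- tx$transcript_id[1]
    attrs <- paste0("ID=", gff3_escape(id), ";gene_id=",
                    gff3_escape(tx$gene_id[1]))
    for (col in extras) {
      v <- tx[[col]][1]
      if (!is.na(v)) {
        v <- if (is.logical(v)) tolower(as.character(v)) else as.character(v)
        attrs <- paste0(attrs, ";", col, "=", gff3_escape(v))
      }
    }
    writeLines(paste(tx$chrom[1], tx$source[1], "mRNA", min(tx$start) + 1L,
                     max(tx$end), ".", tx$strand[1], ".", attrs,
                     sep = "\t"), con)
    for (k in seq_len(nrow(tx))) {
      writeLines(paste(tx$chrom[k], tx$source[k], "exon", tx$start[k] + 1L,
                       tx$end[k], ".", tx$strand[k], ".",
                       paste0("ID=", gff3_escape(id), ".exon", k,
                              ";Parent=", gff3_escape(id)),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

write_bed12 <- function(models, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tx in split_models(models)) {
    tx <- arrange(tx, .data$start)
    cs <- min(tx$start)
    ce <- max(tx$end)
    writeLines(paste(tx$chrom[1], cs, ce, tx$transcript_id[1], 0L,
                     tx$strand[1], cs, ce, "0", nrow(tx),
                     paste0(paste(tx$end - tx$start, collapse = ","), ","),
                     paste0(paste(tx$start - cs, collapse = ","), ","),
                     sep = "\t"), con)
  }
  invisible(path)
}
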