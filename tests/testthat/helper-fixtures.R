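## compact constructors and independent per-base oracles used across tests

mk_model <- function(id, starts, ends, strand = "+", chrom = "chr1",
                     gene_id = id, ...) {
  gene_models(tibble::tibble(transcript_id = id, gene_id = gene_id,
                             chrom = chrom, start = starts, end = ends,
                             strand = strand, ...))
}

mk_evidence <- function(id, starts, ends, class, strand = "+",
                        chrom = "chr1", tissue = NA_character_) {
  m <- mk_model(id, starts, ends, strand, chrom)
  m$evidence_class <- class
  m$tissue <- tissue
  m
}

## a random valid model: sorted disjoint exons on a random strand
rand_model <- function(id, chrom = "chr1", max_exons = 5) {
  n <- sample(1:max_exons, 1)
  lens <- sample(30:200, n, replace = TRUE)
  gaps <- sample(50:400, n, replace = TRUE)
  starts <- sample(0:5000, 1) + cumsum(gaps) + cumsum(c(0, lens[-n]))
  mk_model(id, starts, starts + lens, strand = sample(c("+", "-", "."), 1),
           chrom = chrom)
}

## --- independent brute-force oracles (explicit per-base sets) ------------

bases_of <- function(tx) {
  unlist(lapply(seq_len(nrow(tx)), function(k) tx$start[k]:(tx$end[k] - 1L)))
}

oracle_overlap <- function(a, b, stranded = TRUE) {
  if (a$chrom[1] != b$chrom[1]) return(0L)
  if (stranded) {
    sa <- a$strand[1]; sb <- b$strand[1]
    if (sa != "." && sb != "." && sa != sb) return(0L)
  }
  length(intersect(bases_of(a), bases_of(b)))
}

oracle_congruency <- function(i, j, stranded = TRUE) {
  ov <- oracle_overlap(i, j, stranded)
  c(sn = ov / length(bases_of(j)), sp = ov / length(bases_of(i)))
}

## coverage of a model's exonic bases by a set of evidence rows
oracle_coverage <- function(tx, ev_rows, stranded = TRUE) {
  mb <- bases_of(tx)
  if (nrow(ev_rows) == 0) return(0)
  keep <- ev_rows$chrom == tx$chrom[1]
  if (stranded) {
    keep <- keep & (ev_rows$strand == "." | tx$strand[1] == "." |
                      ev_rows$strand == tx$strand[1])
  }
  ev_rows <- ev_rows[keep, ]
  if (nrow(ev_rows) == 0) return(0)
  eb <- unique(unlist(lapply(seq_len(nrow(ev_rows)), function(k) {
    ev_rows$start[k]:(ev_rows$end[k] - 1L)
  })))
  length(intersect(mb, eb)) / length(mb)
}

## two-sided rank-sum p-value by full enumeration of labelings
oracle_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  rk <- rank(pooled)
  na <- length(a)
  w_obs <- sum(rk[seq_len(na)])
  combs <- utils::combn(length(pooled), na)
  w_all <- apply(combs, 2, function(idx) sum(rk[idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps)))
}
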