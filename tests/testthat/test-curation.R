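test_that("terminal ends extend to the longest compatible candidate", {
  model <- mk_model("m", c(1000, 1500), c(1200, 2000))
  cdna <- mk_evidence("c", c(900, 1500), c(1200, 2100), "cDNA")
  adj <- adjust_terminal_ends(model, cdna)
  expect_identical(min(adj$start), 900L)
  expect_identical(max(adj$end), 2100L)
  expect_identical(adj$end[1], 1200L)  # internal boundary untouched

  expect_identical(
    as.data.frame(adjust_terminal_ends(model, cdna[0, ])),
    as.data.frame(model))

  ## incompatible intron chain: no extension
  other <- mk_evidence("x", c(900, 1600), c(1200, 2100), "cDNA")
  expect_identical(as.data.frame(adjust_terminal_ends(model, other)),
                   as.data.frame(model))
})

test_that("minus-strand end adjustment mirrors the plus-strand case", {
  plus <- mk_model("p", c(1000, 1500), c(1200, 2000), strand = "+")
  minus <- mk_model("q", c(1000, 1500), c(1200, 2000), strand = "-")
  don_p <- mk_evidence("dp", c(900, 1500), c(1200, 2100), "cDNA", "+")
  don_m <- mk_evidence("dm", c(900, 1500), c(1200, 2100), "cDNA", "-")
  ap <- adjust_terminal_ends(plus, don_p)
  am <- adjust_terminal_ends(minus, don_m)
  expect_identical(ap[c("start", "end")], am[c("start", "end")])
})

test_that("level-1 rules keep, adjust or arbitrate structures", {
  cfg <- curation_config()
  model <- mk_model("m", c(100, 500, 900), c(200, 600, 1000))
  refseq <- mk_model("rs1", c(100, 500, 900), c(200, 600, 1000),
                     gene_id = "G")
  ev <- mk_evidence("c1", c(100, 500, 900), c(200, 600, 1000), "cDNA")

  oc <- curate_level1(model, refseq, ev, cfg)
  expect_identical(oc$action, "kept_identical")
  expect_true("1.1" %in% oc$rules)

  ## same introns, shorter ends -> extended via rule 1.2
  short <- mk_model("m", c(150, 500, 900), c(200, 600, 950))
  oc2 <- curate_level1(short, refseq, ev, cfg)
  expect_identical(oc2$action, "end_adjusted")
  expect_identical(min(oc2$result$start), 100L)
  expect_identical(max(oc2$result$end), 1000L)

  ## internal structural difference: most-evidenced structure wins (1.3)
  alt <- mk_model("m", c(100, 450, 900), c(200, 650, 1000))
  ev_alt <- dplyr::bind_rows(
    mk_evidence("c1", c(100, 450, 900), c(200, 650, 1000), "cDNA"),
    mk_evidence("c2", c(100, 450, 900), c(200, 650, 1000), "cDNA"),
    mk_evidence("c3", c(100, 450, 900), c(200, 650, 1000), "cDNA"),
    mk_evidence("e1", c(100, 500, 900), c(200, 600, 1000), "EST"))
  oc3 <- curate_level1(alt, refseq, ev_alt, cfg)
  expect_identical(oc3$action, "kept_identical")
  expect_identical(oc3$result$start, alt$start)

  ## reversed support: reference structure replaces the model
  ev_ref <- dplyr::bind_rows(
    mk_evidence("e1", c(100, 500, 900), c(200, 600, 1000), "EST"),
    mk_evidence("e2", c(100, 500, 900), c(200, 600, 1000), "EST"))
  oc4 <- curate_level1(alt, refseq, ev_ref, cfg)
  expect_identical(oc4$action, "structure_replaced")
  expect_identical(oc4$result$start, refseq$start)
})

test_that("overlapping reference transcripts of one gene merge (rule 1.4)", {
  model <- mk_model("m", c(100, 500), c(200, 600))
  refseq <- dplyr::bind_rows(
    mk_model("rs1", c(100, 500), c(200, 600), gene_id = "G"),
    mk_model("rs2", c(100, 450), c(200, 620), gene_id = "G"))
  oc <- curate_level1(model, refseq, mk_evidence("c", 100, 200, "cDNA")[0, ],
                      curation_config())
  expect_true("1.4" %in% oc$rules)
  ## merged reference = exon union [100,200) + [450,620)
  expect_identical(oc$result$start, c(100L, 450L))
  expect_identical(oc$result$end, c(200L, 620L))
})

test_that("level-2 rules delete unsupported single-exon reference models", {
  cfg <- curation_config()
  single <- mk_model("s", 100, 400)
  no_ev <- mk_evidence("z", 1, 2, "EST")[0, ]
  oc <- curate_level2(single, single[0, ], no_ev, cfg = cfg)
  expect_identical(oc$action, "deleted")
  expect_true("2.2" %in% oc$rules)

  est <- mk_evidence("e", 100, 400, "EST")
  oc2 <- curate_level2(single, single[0, ], est, cfg = cfg)
  expect_identical(oc2$action, "kept_identical")

  ## duplicate gene ids collapse onto the best-RefSeq flag
  a <- mk_model("a", 100, 400, gene_id = "G")
  a$best_refseq <- TRUE
  b <- mk_model("b", 120, 380, gene_id = "G")
  b$best_refseq <- FALSE
  sibs <- dplyr::bind_rows(a, b)
  expect_identical(curate_level2(b, sibs, est, cfg = cfg)$action, "deleted")
  expect_identical(curate_level2(a, sibs, est, cfg = cfg)$action,
                   "kept_identical")
})

test_that("level-3 rules add supported exons and delete unsupported ones", {
  cfg <- curation_config()
  model <- mk_model("m", c(100, 900), c(200, 1000))
  ## novel exon [500,600) backed by an EST and a high-confidence RNA-seq
  ev <- dplyr::bind_rows(
    mk_evidence("e1", c(100, 500, 900), c(200, 600, 1000), "EST"),
    mk_evidence("r1", c(100, 500, 900), c(200, 600, 1000),
                "RNAseq_high_confidence", tissue = "liver"))
  oc <- curate_level3(model, ev, cfg = cfg)
  expect_true("3.2" %in% oc$rules)
  expect_identical(oc$result$start, c(100L, 500L, 900L))

  ## a single backer is not enough under the conjunctive rule...
  oc_one <- curate_level3(model, ev[ev$transcript_id == "e1", ], cfg = cfg)
  expect_false("3.2" %in% oc_one$rules)
  ## ...but is accepted under the literal any-criterion reading
  oc_any <- curate_level3(model, ev[ev$transcript_id == "e1", ],
                          cfg = curation_config(addition_rule = "any"))
  expect_true("3.2" %in% oc_any$rules)

  ## unsupported internal exon is deleted (3.3)
  spurious <- mk_model("m", c(100, 500, 900), c(200, 560, 1000))
  support <- dplyr::bind_rows(
    mk_evidence("e1", c(100, 900), c(200, 1000), "EST"),
    mk_evidence("r2", c(100, 900), c(200, 1000),
                "RNAseq_high_confidence", tissue = "lung"))
  oc2 <- curate_level3(spurious, support, cfg = cfg)
  expect_true("3.3" %in% oc2$rules)
  expect_identical(oc2$result$start, c(100L, 900L))
})

test_that("conflicting structures are replaced by the backed cDNA (3.4)", {
  model <- mk_model("m", c(100, 400), c(200, 500))
  cdna <- mk_evidence("c1", c(100, 450), c(220, 560), "cDNA")
  est <- mk_evidence("e1", c(100, 450), c(220, 560), "EST")
  oc <- curate_level3(model, dplyr::bind_rows(cdna, est),
                      cfg = curation_config())
  expect_true("3.4" %in% oc$rules)
  expect_identical(oc$result$start, c(100L, 450L))
  expect_identical(oc$result$end, c(220L, 560L))
})

test_that("co-located models merge as isoforms above 70% span overlap", {
  run_pair <- function(b_starts, b_ends) {
    a <- mk_model("a", c(0, 600), c(200, 1000), gene_id = "a")
    b <- mk_model("b", b_starts, b_ends, gene_id = "b")
    ann <- gene_models(dplyr::bind_rows(a, b))
    ev <- dplyr::bind_rows(
      mk_evidence("ca", c(0, 600), c(200, 1000), "cDNA"),
      mk_evidence("ea", c(0, 600), c(200, 1000), "EST"),
      mk_evidence("cb", b_starts, b_ends, "cDNA"),
      mk_evidence("eb", b_starts, b_ends, "EST"))
    run_curation(ann, refseq = a[0, ], evidence = ev)
  }
  ## spans [0,1000) and [0,750): overlap 750/750 = 100% -> merged
  merged <- run_pair(c(0, 600), c(200, 750))
  expect_identical(dplyr::n_distinct(merged$curated$transcript_id), 1L)
  expect_true(all(merged$audit$action == "isoforms_merged"))
  ## spans [0,1000) and [650,1650): overlap 350/1000 = 35% -> kept separate
  apart <- run_pair(c(650, 1300), c(800, 1650))
  expect_identical(dplyr::n_distinct(apart$curated$transcript_id), 2L)
})

test_that("noiseless curation is a fixed point of the pipeline", {
  truth <- generate_truth(seed = 61, n_genes = 20)
  z <- corrupt_evidence(truth, seed = 62, noise = evidence_noise(zero = TRUE))
  cur <- run_curation(truth, z$refseq, z$evidence, z$ncbi)
  expect_true(all(cur$audit$action == "kept_identical"))
  cols <- c("chrom", "start", "end", "strand")
  expect_identical(
    as.data.frame(dplyr::arrange(cur$curated[cols], chrom, start, end)),
    as.data.frame(dplyr::arrange(truth[cols], chrom, start, end)))
})

test_that("one model per level yields a full audit and drops level 4", {
  ## four disjoint loci engineered to land on levels 1-4
  l1 <- mk_model("L1", c(1000, 2000), c(1400, 2400))
  l2 <- mk_model("L2", c(10000, 11000), c(10400, 11400))
  l3 <- mk_model("L3", c(20000, 21000), c(20400, 21400))
  l4 <- mk_model("L4", c(30000, 31000), c(30400, 31400))
  ann <- gene_models(dplyr::bind_rows(l1, l2, l3, l4))
  refseq <- gene_models(dplyr::bind_rows(
    mk_model("rs1", c(1000, 2000), c(1400, 2400)),
    mk_model("rs2", c(10000, 11000), c(10400, 11400))))
  ev <- dplyr::bind_rows(
    mk_evidence("c1", c(1000, 2000), c(1400, 2400), "cDNA"),
    mk_evidence("e1", c(1000, 2000), c(1400, 2400), "EST"),
    mk_evidence("c3", c(20000, 21000), c(20400, 21400), "cDNA"),
    mk_evidence("e3", c(20000, 21000), c(20400, 21400), "EST"),
    mk_evidence("e4", c(30000, 31000), c(30400, 31400), "EST"))
  cur <- run_curation(ann, refseq, ev)
  expect_identical(nrow(cur$audit), 4L)
  expect_identical(sort(cur$profiles$level), 1:4)
  expect_identical(dplyr::n_distinct(cur$curated$transcript_id), 3L)
  expect_false("L4" %in% cur$curated$transcript_id)

  keep <- run_curation(ann, refseq, ev,
                       cfg = curation_config(keep_level4 = TRUE))
  expect_true("L4" %in% keep$curated$transcript_id)
})

test_that("no curated exon lacks overlapping evidence or reference support", {
  truth <- generate_truth(seed = 71, n_genes = 20)
  z <- corrupt_evidence(truth, seed = 72)
  ann <- corrupt_annotation(truth, seed = 73, end_truncation = 100,
                            p_spurious_exon = 0.2)
  cur <- run_curation(ann, z$refseq, z$evidence, z$ncbi)
  pool <- dplyr::bind_rows(z$evidence, z$refseq, z$ncbi)
  for (k in seq_len(nrow(cur$curated))) {
    exon <- cur$curated[k, ]
    hits <- pool$chrom == exon$chrom & pool$start < exon$end &
      pool$end > exon$start
    expect_true(any(hits))
  }
})
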