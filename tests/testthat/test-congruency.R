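test_that("congruency of a pair follows the base-level formulas", {
  i <- mk_model("i", 100, 200)
  j <- mk_model("j", 150, 250)
  expect_equal(as.numeric(congruency_pair(i, j)), c(0.5, 0.5, 0.5))
  expect_equal(as.numeric(congruency_pair(i, i)), c(1, 1, 1))
  far <- mk_model("f", 5000, 5100)
  expect_equal(as.numeric(congruency_pair(i, far)), c(0, 0, 0))
})

test_that("congruency matches the per-base oracle on random pairs", {
  set.seed(81)
  for (k in 1:200) {
    i <- rand_model("i")
    j <- rand_model("j")
    got <- congruency_pair(i, j)
    want <- oracle_congruency(i, j)
    expect_equal(got$sn, unname(want["sn"]), tolerance = 1e-15)
    expect_equal(got$sp, unname(want["sp"]), tolerance = 1e-15)
    expect_equal(got$c, mean(want), tolerance = 1e-15)
    ## duality: SN(i, j) == SP(j, i)
    expect_equal(got$sn, congruency_pair(j, i)$sp, tolerance = 1e-15)
  }
})

test_that("spurious exons and over-extension cannot help the scores", {
  set.seed(82)
  for (k in 1:50) {
    i <- rand_model("i", max_exons = 3)
    j <- rand_model("j", max_exons = 3)
    base <- congruency_pair(i, j)
    ## spurious exon appended to i far away: SP cannot increase
    ext <- max(i$end, j$end) + 1000L
    i2 <- gene_models(dplyr::bind_rows(
      i, tibble::tibble(transcript_id = i$transcript_id[1],
                        gene_id = i$gene_id[1], chrom = i$chrom[1],
                        start = ext, end = ext + 100L,
                        strand = i$strand[1], source = "x")))
    expect_lte(congruency_pair(i2, j)$sp, base$sp + 1e-12)
    ## extending j beyond i (a distant extra exon): SN cannot increase
    j2 <- gene_models(dplyr::bind_rows(
      j, tibble::tibble(transcript_id = j$transcript_id[1],
                        gene_id = j$gene_id[1], chrom = j$chrom[1],
                        start = ext + 2000L, end = ext + 2300L,
                        strand = j$strand[1], source = "x")))
    expect_lte(congruency_pair(i, j2)$sn, base$sn + 1e-12)
  }
})

test_that("gene-level reports keep the best-matching alignment per class", {
  gene <- mk_model("g", c(0, 500), c(100, 700))
  good <- mk_evidence("good", c(0, 500), c(100, 700), "cDNA")
  poor <- mk_evidence("poor", 0, 60, "cDNA")
  rep <- evaluate_annotation(gene, dplyr::bind_rows(poor, good),
                             unit = "gene")
  expect_identical(nrow(rep), 1L)
  expect_equal(rep$c, 1)

  ## no overlapping evidence: (0,0,0) record retained, not dropped
  lonely <- mk_model("far", 90000, 90100)
  rep2 <- evaluate_annotation(gene_models(dplyr::bind_rows(gene, lonely)),
                              good, unit = "gene")
  expect_identical(nrow(rep2), 2L)
  expect_equal(rep2$c[rep2$unit_id == "far"], 0)
})

test_that("exon-level records score each exon against the class union", {
  gene <- mk_model("g", c(0, 500), c(100, 700))
  ev <- dplyr::bind_rows(
    mk_evidence("a", c(0, 500), c(100, 700), "cDNA"),
    mk_evidence("b", 550, 650, "cDNA"))
  rep <- evaluate_annotation(gene, ev, unit = "exon")
  expect_identical(nrow(rep), 2L)
  first <- rep[rep$unit_id == "g.exon1", ]
  expect_equal(first$sp, 1)   # exon fully covered
  expect_equal(first$sn, 1)   # union overlapping exon1 is exactly [0,100)
  second <- rep[rep$unit_id == "g.exon2", ]
  expect_equal(second$sp, 1)  # [500,700) covered by the union
  expect_equal(second$sn, 1)  # union of overlapped exons == [500,700)

  ## identical annotation and evidence: all records perfect
  same <- evaluate_annotation(gene, mk_evidence("c", c(0, 500),
                                                c(100, 700), "cDNA"),
                              unit = "exon")
  expect_true(all(same$c == 1))
})

test_that("cumulative congruence curves are survival curves", {
  rep <- tibble::tibble(unit_id = c("a", "b", "c"),
                        evidence_class = "cDNA",
                        sn = 1, sp = 1, c = c(0.2, 0.6, 1.0),
                        label = "x")
  cc <- cumulative_congruence(rep)
  expect_equal(cc$fraction[cc$threshold == 0.5], 2 / 3)
  expect_equal(cc$fraction[cc$threshold == 0], 1)
  expect_true(all(diff(cc$fraction) <= 1e-12))

  perfect <- dplyr::mutate(rep, c = 1)
  cc2 <- cumulative_congruence(perfect)
  expect_true(all(cc2$fraction == 1))

  expect_error(cumulative_congruence(rep[0, ]), "empty")
})

test_that("a uniformly better annotation dominates pointwise", {
  good <- tibble::tibble(unit_id = paste0("u", 1:10), evidence_class = "cDNA",
                         sn = 1, sp = 1, c = seq(0.5, 0.95, by = 0.05),
                         label = "good")
  bad <- dplyr::mutate(good, c = c - 0.3, label = "bad")
  cc <- cumulative_congruence(dplyr::bind_rows(good, bad))
  wide <- tidyr::pivot_wider(cc, names_from = "label",
                             values_from = "fraction")
  expect_true(all(wide$good >= wide$bad))
  expect_true(any(wide$good > wide$bad))
})
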