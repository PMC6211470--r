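test_that("RPKM follows the reads-per-kilobase-per-million formula", {
  counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(100L, 0L))
  r <- compute_rpkm(counts, c(g1 = 1000, g2 = 500), c(s1 = 1e6))
  expect_equal(r$s1, c(100, 0))
  ## doubling the library size halves every value
  r2 <- compute_rpkm(counts, c(g1 = 1000, g2 = 500), c(s1 = 2e6))
  expect_equal(r2$s1, r$s1 / 2)
  expect_error(compute_rpkm(counts, c(g1 = 0, g2 = 500), c(s1 = 1e6)),
               "length")
  expect_error(compute_rpkm(counts, c(g1 = 1000, g2 = 500), c(s1 = 0)),
               "library")
})

test_that("quantile normalization equalizes distributions exactly", {
  m <- tibble::tibble(gene = c("g1", "g2"), s1 = c(1, 2), s2 = c(3, 4))
  qn <- quantile_normalize(m)
  expect_equal(qn$s1, c(2, 3))
  expect_equal(qn$s2, c(2, 3))

  set.seed(101)
  big <- tibble::tibble(gene = paste0("g", 1:200),
                        a = rlnorm(200), b = rlnorm(200, 1),
                        c = rlnorm(200, 2))
  qb <- quantile_normalize(big)
  expect_identical(sort(qb$a), sort(qb$b))
  expect_identical(sort(qb$b), sort(qb$c))
  ## idempotence
  expect_equal(quantile_normalize(qb), qb, tolerance = 1e-12)

  ## a column of ties collapses to the mean of the reference distribution
  tied <- tibble::tibble(gene = paste0("g", 1:4),
                         a = c(5, 5, 5, 5), b = c(1, 2, 3, 4))
  qt <- quantile_normalize(tied)
  expect_true(all(qt$a == mean(qt$b)))
})

test_that("complexity curves cumulate sorted expression fractions", {
  m <- tibble::tibble(gene = c("g1", "g2", "g3"), s1 = c(6, 3, 1))
  meta <- tibble::tibble(sample = "s1", tissue = "liver",
                         species = "speciesA")
  cc <- complexity_curves(m, meta)
  expect_equal(cc$fraction, c(0.6, 0.9, 1.0))
  expect_equal(complexity_summary(cc)$genes_to_target, 1L)

  ## uniform expression: cumulative k/G, ceiling(G/2) genes to half
  G <- 11
  u <- tibble::tibble(gene = paste0("g", 1:G), s1 = rep(2, G))
  cu <- complexity_curves(u, meta)
  expect_equal(cu$fraction, (1:G) / G)
  expect_equal(complexity_summary(cu)$genes_to_target, ceiling(G / 2))

  z <- tibble::tibble(gene = "g1", s1 = 0)
  expect_error(complexity_curves(z, meta), "all-zero")
})

test_that("complexity curve invariants hold on generated tissues", {
  ex <- generate_expression(seed = 111, n_genes = 400)
  cc <- complexity_curves(ex$expression, ex$meta)
  for (t in unique(cc$tissue)) {
    f <- cc$fraction[cc$tissue == t]
    inc <- cc$increment[cc$tissue == t]
    expect_true(all(diff(f) >= -1e-12))          # non-decreasing
    expect_lt(abs(f[length(f)] - 1), 1e-9)       # ends at 1
    expect_true(all(inc >= -1e-12))              # non-negative increments
    expect_true(all(diff(inc) <= 1e-12))         # concave (sorted dec.)
  }
  s <- complexity_summary(cc)
  expect_lt(s$genes_to_target[s$tissue == "liver"],
            s$genes_to_target[s$tissue == "cortex"])
})

test_that("Pearson correlations match the textbook formula", {
  m <- tibble::tibble(gene = paste0("g", 1:4),
                      s1 = c(1, 4, 2, 7), s2 = c(2, 8, 3, 13),
                      s3 = c(10, 2, 9, 1))
  meta <- tibble::tibble(sample = c("s1", "s2", "s3"),
                         tissue = c("a", "b", "c"), species = "sp")
  corr <- correlation_matrix(m, meta, level = "sample",
                             log_transform = FALSE)
  r <- attr(corr, "matrix")
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(r["s1", "s2"], pearson(m$s1, m$s2), tolerance = 1e-12)
  expect_equal(r["s1", "s3"], pearson(m$s1, m$s3), tolerance = 1e-12)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 3))

  ## duplicate samples correlate at exactly 1
  dup <- tibble::tibble(gene = m$gene, s1 = m$s1, s2 = m$s1)
  meta2 <- tibble::tibble(sample = c("s1", "s2"), tissue = c("a", "b"),
                          species = "sp")
  r2 <- attr(correlation_matrix(dup, meta2, level = "sample",
                                log_transform = FALSE), "matrix")
  expect_equal(r2["s1", "s2"], 1)

  ## a profile against its centered negation correlates at -1
  neg <- tibble::tibble(gene = m$gene, s1 = m$s1,
                        s2 = max(m$s1) + min(m$s1) - m$s1)
  r3 <- attr(correlation_matrix(neg, meta2, level = "sample",
                                log_transform = FALSE), "matrix")
  expect_equal(r3["s1", "s2"], -1)
})

test_that("planted conserved and divergent tissues are classified", {
  ex <- generate_expression(seed = 121, n_genes = 600)
  corr <- correlation_matrix(ex$expression, ex$meta, level = "tissue")
  cls <- classify_clustering_pattern(corr)
  expect_setequal(cls$tissue[cls$pattern == "species_dominated"],
                  c("testis", "spleen"))
  expect_setequal(cls$tissue[cls$pattern == "tissue_dominated"],
                  c("liver", "muscle", "cortex"))
  dend <- attr(cls, "dendrogram")
  expect_s3_class(dend, "phylo")

  ## no divergence: everything clusters by tissue
  ex0 <- generate_expression(seed = 122, n_genes = 400,
                             divergence_effect = 0)
  cls0 <- classify_clustering_pattern(
    correlation_matrix(ex0$expression, ex0$meta, level = "tissue"))
  expect_true(all(cls0$pattern == "tissue_dominated"))

  ## a single tissue present in both species is trivially tissue-dominated
  one <- ex$meta$sample[ex$meta$tissue == "liver"]
  m1 <- ex$expression[c("gene", one)]
  cls1 <- classify_clustering_pattern(
    correlation_matrix(m1, ex$meta, level = "tissue"))
  expect_identical(cls1$pattern, "tissue_dominated")
})

test_that("differential calls need both a small p and a large fold change", {
  set.seed(131)
  m <- tibble::tibble(gene = c("up", "flat"),
                      a1 = c(10, 5), a2 = c(12, 6), a3 = c(11, 5.5),
                      a4 = c(13, 5.2),
                      b1 = c(1, 5.1), b2 = c(2, 6.1), b3 = c(1, 5.4),
                      b4 = c(2, 5.9))
  de <- differential_genes(m, paste0("a", 1:4), paste0("b", 1:4))
  expect_identical(de$direction[de$gene == "up"], "A_high")
  expect_true(is.na(de$direction[de$gene == "flat"]))
  expect_equal(de$p_value[de$gene == "up"],
               oracle_wilcoxon(c(10, 12, 11, 13), c(1, 2, 1, 2)))

  ## identical groups: nothing is called
  ident <- tibble::tibble(gene = paste0("g", 1:5),
                          a1 = 1:5, a2 = 2:6, b1 = 1:5, b2 = 2:6)
  de2 <- differential_genes(ident, c("a1", "a2"), c("b1", "b2"))
  expect_true(all(is.na(de2$direction)))

  ## fold change 1.5 with a tiny p-value stays uncalled
  fc <- tibble::tibble(gene = "g",
                       a1 = 30, a2 = 30.2, a3 = 29.8, a4 = 30.1,
                       b1 = 20, b2 = 20.2, b3 = 19.8, b4 = 20.1)
  de3 <- differential_genes(fc, paste0("a", 1:4), paste0("b", 1:4))
  expect_lt(de3$p_value, 0.05)
  expect_true(is.na(de3$direction))

  expect_error(differential_genes(m, character(), "b1"), "at least one")
})

test_that("exact Wilcoxon p-values match full enumeration, ties included", {
  set.seed(141)
  for (k in 1:30) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    a <- sample(c(0, 1, 2, 5, 10), na, replace = TRUE)
    b <- sample(c(0, 1, 2, 5, 10), nb, replace = TRUE)
    m <- tibble::tibble(gene = "g", !!!setNames(as.list(c(a, b)),
                                                paste0("s", seq_len(na + nb))))
    de <- differential_genes(m, paste0("s", seq_len(na)),
                             paste0("s", na + seq_len(nb)))
    expect_equal(de$p_value, oracle_wilcoxon(a, b), tolerance = 1e-12)
  }
  ## without ties the enumeration agrees with the exact distribution
  for (k in 1:10) {
    a <- runif(5)
    b <- runif(5)
    m <- tibble::tibble(gene = "g", !!!setNames(as.list(c(a, b)),
                                                paste0("s", 1:10)))
    de <- differential_genes(m, paste0("s", 1:5), paste0("s", 6:10))
    expect_equal(de$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})
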