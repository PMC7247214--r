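test_that("per-region CAG percentage pools glutamine codons over member rows", {
  a <- aln(r1 = "QQQQ", r2 = "QQQQ")
  cat_r <- categorize_alignment(a)
  p_all_cag <- pair_cds_with_protein(a, list(r1 = rep("CAG", 4), r2 = rep("CAG", 4)))
  u <- region_codon_usage(cat_r, a, p_all_cag)
  expect_equal(u$pct_cag, 100)
  expect_equal(u$n_cag, 8L)

  # 3:1 CAG:CAA, the mammalian background ratio, gives 75%
  p_31 <- pair_cds_with_protein(a, list(r1 = c("CAG", "CAG", "CAG", "CAA"),
                                        r2 = c("CAG", "CAG", "CAG", "CAA")))
  expect_equal(region_codon_usage(cat_r, a, p_31)$pct_cag, 75)

  p_caa <- pair_cds_with_protein(a, list(r1 = rep("CAA", 4), r2 = rep("CAA", 4)))
  expect_equal(region_codon_usage(cat_r, a, p_caa)$pct_cag, 0)
})

test_that("glutamines outside a row's own polyQ still contribute at region columns", {
  # r2 has a lone Q aligned inside r1's tract: included in the pool
  a <- aln(r1 = "QQQQQ", r2 = "AAQAA")
  cat_r <- categorize_alignment(a)
  p <- pair_cds_with_protein(a, list(r1 = rep("CAG", 5),
                                     r2 = c("GCT", "GCT", "CAA", "GCT", "GCT")))
  u <- region_codon_usage(cat_r, a, p)
  expect_equal(u$n_cag, 5L)
  expect_equal(u$n_caa, 1L)
})

test_that("rows without a valid CDS are skipped and empty pools are non-reportable", {
  a <- aln(r1 = "QQQQ", r2 = "QQQQ", r3 = "QQQQ")
  suppressMessages({
    p <- pair_cds_with_protein(a, list(r1 = rep("CAG", 4), r3 = rep("CAG", 3)))
  })
  cat_r <- categorize_alignment(a)
  u <- region_codon_usage(cat_r, a, p)
  expect_equal(u$n_rows_used, 1L)
  expect_equal(u$n_cag, 4L)
  # no valid pairings covering the region -> region excluded, with a message
  suppressMessages(p2 <- pair_cds_with_protein(a, list(r1 = rep("CAA", 3))))
  expect_message(u2 <- region_codon_usage(cat_r, a, p2), "non-reportable")
  expect_equal(nrow(u2), 0L)
})

test_that("pooled percentages are invariant to row order and corpus duplication", {
  a <- aln(r1 = "LQQQQL", r2 = "LQ-QQL", r3 = "LQQQQL")
  cds <- list(r1 = c("CTT", "CAG", "CAA", "CAG", "CAG", "CTT"),
              r2 = c("CTT", "CAG", "CAA", "CAG", "CTT"),
              r3 = c("CTT", "CAA", "CAA", "CAG", "CAG", "CTT"))
  u1 <- region_codon_usage(categorize_alignment(a), a, pair_cds_with_protein(a, cds))
  perm <- c("r3", "r1", "r2")
  b <- ortholog_alignment(a$seqs[perm], "t2")
  u2 <- region_codon_usage(categorize_alignment(b), b, pair_cds_with_protein(b, cds))
  expect_equal(u2$pct_cag, u1$pct_cag)
  # duplicating every row leaves the pooled proportion unchanged
  dup_rows <- c(a$seqs, setNames(a$seqs, paste0(names(a$seqs), "_d")))
  dup_cds <- c(cds, setNames(cds, paste0(names(cds), "_d")))
  d <- ortholog_alignment(dup_rows, "t3")
  u3 <- region_codon_usage(categorize_alignment(d), d, pair_cds_with_protein(d, dup_cds))
  expect_equal(u3$pct_cag, u1$pct_cag)
  expect_equal(u3$n_cag, 2L * u1$n_cag)
})

test_that("background CAG fraction pools every glutamine of the corpus", {
  a <- aln(r1 = "QAQ", r2 = "AAA")
  p <- pair_cds_with_protein(a, list(r1 = c("CAG", "GCT", "CAA"),
                                     r2 = c("GCT", "GCT", "GCT")))
  bg <- background_cag_fraction(p)
  expect_equal(bg$pct_cag, 50)
  expect_equal(bg$n_cag + bg$n_caa, 2L)
  b <- aln(r1 = "QQ", r2 = "QQ")
  pb <- pair_cds_with_protein(b, list(r1 = c("CAG", "CAG"), r2 = c("CAG", "CAG")))
  expect_equal(background_cag_fraction(pb)$pct_cag, 100)
  c_ <- aln(r1 = "AAA", r2 = "LLL")
  pc <- pair_cds_with_protein(c_, list(r1 = rep("GCT", 3), r2 = rep("CTT", 3)))
  expect_error(background_cag_fraction(pc), "no glutamine")
})

test_that("a planted background CAG probability is recovered within the binomial CI", {
  set.seed(31)
  n_q <- 10000L
  p <- 0.5
  codons <- ifelse(runif(n_q) < p, "CAG", "CAA")
  a <- ortholog_alignment(c(x = strrep("Q", n_q), y = strrep("A", n_q)), "bin")
  pr <- pair_cds_with_protein(a, list(x = codons, y = rep("GCT", n_q)))
  got <- background_cag_fraction(pr)$pct_cag / 100 * n_q
  ci <- qbinom(c(0.005, 0.995), n_q, p)
  expect_gte(got, ci[1])
  expect_lte(got, ci[2])
})

test_that("Mann-Whitney comparisons report U, p and the caption star bins", {
  x <- 1:100
  cmp_same <- compare_category_distributions(c(x, x), rep(c("stable", "mutated"), each = 100))
  expect_equal(cmp_same$significance, "ns")
  expect_gt(cmp_same$p_value, 0.05)

  cmp_shift <- compare_category_distributions(c(1:50, 1001:1050),
                                              rep(c("stable", "mutated"), each = 50))
  expect_lte(cmp_shift$p_value, 1e-4)
  expect_equal(cmp_shift$significance, "****")
  # complete separation with the first group lower gives U = 0
  expect_equal(unname(cmp_shift$statistic), 0)

  # star bins agree with the printed thresholds on the computed p-values
  set.seed(32)
  vals <- c(rnorm(40), rnorm(40, 0.6), rnorm(40, 3))
  labs <- rep(c("stable", "inserted", "mutated"), each = 40)
  cmp <- compare_category_distributions(vals, labs)
  bins <- ifelse(cmp$p_value <= 1e-4, "****",
                 ifelse(cmp$p_value <= 1e-3, "***",
                        ifelse(cmp$p_value <= 0.01, "**",
                               ifelse(cmp$p_value <= 0.05, "*", "ns"))))
  expect_equal(cmp$significance, bins)
  expect_equal(nrow(cmp), 3L)

  expect_message(
    cmp_small <- compare_category_distributions(c(1, 2, 3), c("a", "a", "b")),
    "skipping")
  expect_equal(nrow(cmp_small), 0L)
})
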