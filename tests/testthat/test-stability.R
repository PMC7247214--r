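test_that("column classification applies the printed thresholds exactly", {
  # 8 Q + 2 A in 10 rows: 0.8 meets the >= 80% rule
  c1 <- classify_column(c(rep("Q", 8), rep("A", 2)))
  expect_equal(c1$value, "conserved")
  expect_equal(c1$subvalue, "none")
  # 4 Q + 5 gaps + 1 L: unstable, gaps outnumber non-Q -> inserted
  c2 <- classify_column(c(rep("Q", 4), rep("-", 5), "L"))
  expect_equal(c(c2$value, c2$subvalue), c("unstable", "inserted"))
  # 4 Q + 3 gaps + 3 L: tie -> undefined
  c3 <- classify_column(c(rep("Q", 4), rep("-", 3), rep("L", 3)))
  expect_equal(c(c3$value, c3$subvalue), c("unstable", "undefined"))
  # 1 Q + 9 A: 0.1 < 20%
  c4 <- classify_column(c("Q", rep("A", 9)))
  expect_equal(c4$value, "uncategorized")
  expect_error(classify_column(character(0)), "empty")
})

test_that("column classification agrees with the integer-arithmetic rule oracle
           for every composition up to 15 rows", {
  for (n in 2:15) {
    for (n_q in 0:n) {
      for (n_gap in 0:(n - n_q)) {
        n_other <- n - n_q - n_gap
        col <- c(rep("Q", n_q), rep("-", n_gap), rep("L", n_other))
        got <- classify_column(col)
        want <- oracle_column_class(n_q, n_gap, n_other)
        expect_equal(c(got$value, got$subvalue), unname(want),
                     label = sprintf("n=%d q=%d gap=%d", n, n_q, n_gap))
        expect_equal(got$n_q + got$n_gap + got$n_other, n)
      }
    }
  }
})

test_that("region categorization follows the strict-majority rules", {
  cc <- function(values, subvalues) {
    data.frame(value = values, subvalue = subvalues, stringsAsFactors = FALSE)
  }
  expect_equal(categorize_region(cc(c("conserved", "conserved", "unstable"),
                                    c("none", "none", "inserted")))$category, 1L)
  expect_equal(categorize_region(cc(c("conserved", rep("unstable", 3)),
                                    c("none", "inserted", "inserted", "mutated")))$category, 2L)
  expect_equal(categorize_region(cc(rep("unstable", 2),
                                    c("inserted", "mutated")))$category, 4L)
  expect_equal(categorize_region(cc(c("conserved", "unstable"),
                                    c("none", "inserted")))$category, 5L)
  # uncategorized columns count toward neither side
  expect_equal(categorize_region(cc(c("uncategorized", "uncategorized", "conserved"),
                                    rep("none", 3)))$category, 1L)
})

test_that("region categorization equals the rule oracle over all small count vectors", {
  for (C in 0:4) for (U in 0:4) {
    if (U == 0L && C == 0L) next
    parts <- expand.grid(I = 0:U, M = 0:U, D = 0:U)
    parts <- parts[rowSums(parts) == U, , drop = FALSE]
    for (k in seq_len(nrow(parts))) {
      I <- parts$I[k]; M <- parts$M[k]; D <- parts$D[k]
      cc <- data.frame(
        value = c(rep("conserved", C), rep("unstable", U)),
        subvalue = c(rep("none", C), rep("inserted", I), rep("mutated", M),
                     rep("undefined", D)), stringsAsFactors = FALSE)
      expect_equal(categorize_region(cc)$category, oracle_category(C, U, I, M, D),
                   label = sprintf("C=%d U=%d I=%d M=%d D=%d", C, U, I, M, D))
    }
  }
})

test_that("alignment-level categorization composes detection and classification", {
  # five identical rows: all region columns conserved -> stable
  a1 <- ortholog_alignment(setNames(rep("AAQQQQAA", 5), paste0("s", 1:5)), "a1")
  r1 <- categorize_alignment(a1)$regions
  expect_equal(r1$label, "stable")
  expect_equal(c(r1$col_start, r1$col_end), c(3L, 6L))

  # 8 tract rows + 2 gap rows: each Q column exactly 0.8 -> conserved -> stable
  a2 <- ortholog_alignment(setNames(c(rep("AQQQQA", 8), rep("A----A", 2)),
                                    paste0("s", 1:10)), "a2")
  expect_equal(categorize_alignment(a2)$regions$label, "stable")

  # 5 tract rows + 5 gap rows: 0.5 Q, 5 gaps > 0 non-Q -> inserted
  a3 <- ortholog_alignment(setNames(c(rep("AQQQQA", 5), rep("A----A", 5)),
                                    paste0("s", 1:10)), "a3")
  r3 <- categorize_alignment(a3)$regions
  expect_equal(r3$label, "inserted")
  expect_equal(r3$n_unstable, 4L)
  expect_equal(r3$n_inserted, 4L)
})

test_that("every region receives exactly one category and counts partition", {
  set.seed(21)
  sp <- synthetic_spec()
  labels <- character(0)
  for (i in 1:25) {
    lab <- sample(stability_levels(), 1)
    g <- generate_ortholog_set(sp, lab, seed = 3000 + i)
    out <- categorize_alignment(g$alignment)
    expect_equal(nrow(out$regions), 1L)
    expect_true(out$regions$category %in% 1:5)
    expect_equal(out$regions$label, stability_levels()[out$regions$category])
    labels <- c(labels, out$regions$label)
  }
  tab <- table(factor(labels, levels = stability_levels()))
  expect_equal(sum(tab), length(labels))
})

test_that("categorization is invariant under row permutation", {
  set.seed(22)
  sp <- synthetic_spec()
  for (lab in stability_levels()) {
    g <- generate_ortholog_set(sp, lab, seed = 4000 + match(lab, stability_levels()))
    a <- g$alignment
    perm <- sample(length(a$ids))
    b <- ortholog_alignment(a$seqs[perm], set_id = a$set_id,
                            species = a$species[perm])
    ra <- categorize_alignment(a)$regions
    rb <- categorize_alignment(b)$regions
    expect_equal(rb$label, ra$label)
    expect_equal(rb[, c("col_start", "col_end", "n_conserved", "n_unstable")],
                 ra[, c("col_start", "col_end", "n_conserved", "n_unstable")])
  }
})

test_that("raising a column's Q count never moves it toward uncategorized", {
  rank_of <- c(uncategorized = 1L, unstable = 2L, conserved = 3L)
  set.seed(23)
  for (i in 1:200) {
    n <- sample(2:15, 1)
    n_q <- sample(0:(n - 1), 1)
    rest <- n - n_q
    n_gap <- sample(0:rest, 1)
    col <- c(rep("Q", n_q), rep("-", n_gap), rep("A", rest - n_gap))
    before <- classify_column(col)$value
    j <- which(col != "Q")[1]
    col[j] <- "Q"
    after <- classify_column(col)$value
    expect_gte(rank_of[[after]], rank_of[[before]])
  }
})

test_that("higher ortholog conservation yields a larger stable fraction", {
  # the generator's stable plants double as a conservation gradient: sets
  # planted stable are more self-similar than inserted/mutated plants, and
  # the categorizer must recover that direction
  sp <- synthetic_spec()
  idents <- list(stable = c(), inserted = c())
  for (i in 1:30) {
    gs <- generate_ortholog_set(sp, "stable", seed = 5000 + i)
    gi <- generate_ortholog_set(sp, "inserted", seed = 5100 + i)
    idents$stable <- c(idents$stable, average_identity(gs$alignment))
    idents$inserted <- c(idents$inserted, average_identity(gi$alignment))
  }
  expect_gt(mean(idents$stable), mean(idents$inserted))
})
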