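test_that("representative selection is uniform over members and seed-stable", {
  a1 <- aln(r1 = "AQQQQA", r2 = "A----A", r3 = "AQQQQA", r4 = "AQQQQA", r5 = "A----A")
  cat1 <- categorize_alignment(a1)
  # only rows that themselves carry the repeat are candidates
  r <- select_representatives(cat1, a1, seed = 7)
  expect_equal(nrow(r), 1L)
  expect_true(r$row_id %in% c("r1", "r3", "r4"))
  expect_identical(select_representatives(cat1, a1, seed = 7), r)

  # single-member region: that member, any seed
  a2 <- aln(r1 = "AQQQQA", r2 = "AAAAAA", r3 = "A----A", r4 = "AAAAAA", r5 = "AAAAAA")
  cat2 <- categorize_alignment(a2)
  expect_equal(select_representatives(cat2, a2, seed = 1)$row_id, "r1")
  expect_equal(select_representatives(cat2, a2, seed = 99)$row_id, "r1")

  # two members: both drawn close to 50% over many seeded draws
  a3 <- aln(r1 = "AQQQQA", r2 = "AQQQQA", r3 = "AAAAAA", r4 = "AAAAAA", r5 = "AAAAAA")
  cat3 <- categorize_alignment(a3)
  set.seed(41)
  picks <- vapply(1:10000, function(i) select_representatives(cat3, a3)$row_id,
                  character(1))
  expect_true(all(picks %in% c("r1", "r2")))
  expect_lt(abs(mean(picks == "r1") - 0.5), 0.02)
})

test_that("context profiles count residues at exact offsets in ungapped space", {
  reps <- data.frame(set_id = "s", region_id = "s_r1", category = 1L,
                     label = "stable", row_id = "r1",
                     start_res = 2L, end_res = 5L, protein = "LQQQQP",
                     stringsAsFactors = FALSE)
  pl <- residue_context_profile(reps, "L", flank = 10)
  expect_equal(pl$freq[pl$position == -1], 1.0)
  pp <- residue_context_profile(reps, "P", flank = 10)
  expect_equal(pp$freq[pp$position == 1], 1.0)
  # region at the sequence start: all negative offsets unsampled
  reps2 <- within(reps, { start_res <- 1L; end_res <- 4L; protein <- "QQQQPA" })
  p2 <- residue_context_profile(reps2, "L", flank = 10)
  expect_true(all(p2$n[p2$position < 0] == 0L))
  expect_true(all(is.na(p2$freq[p2$position < 0])))
  # interior positions are never sampled: offsets are relative to boundaries
  expect_equal(sort(unique(pl$position)), c(-10:-1, 1:10))
})

test_that("profiles are invariant to representative order", {
  set.seed(42)
  reps <- do.call(rbind, lapply(1:50, function(i) {
    prot <- random_protein(40, 0)
    prot <- paste0(substr(prot, 1, 10), "QQQQQ", substr(prot, 16, 40))
    data.frame(set_id = "s", region_id = paste0("r", i), category = 1L,
               label = "stable", row_id = "x", start_res = 11L, end_res = 15L,
               protein = prot, stringsAsFactors = FALSE)
  }))
  p1 <- residue_context_profile(reps, "L")
  p2 <- residue_context_profile(reps[sample(nrow(reps)), ], "L")
  expect_equal(p2, p1)
})

test_that("background frequency counts residues over the gap-free corpus", {
  expect_equal(background_frequency("LLLL", "L"), 1.0)
  expect_equal(background_frequency("LP", "L"), 0.5)
  expect_equal(background_frequency(c("L-P-", "LL--"), "L"), 0.75)
  set.seed(43)
  corpus <- vapply(1:100, function(i) random_protein(1000, 1 / 20), character(1))
  expect_lt(abs(background_frequency(corpus, "Q") - 0.05), 0.002)
})

test_that("structure windows cover the repeat plus flanks, truncated at termini", {
  base <- data.frame(set_id = "s", region_id = "s_r1", category = 1L,
                     label = "stable", row_id = "x", stringsAsFactors = FALSE)
  prot100 <- strrep("A", 24) %+% "QQQQQQ" %+% strrep("A", 70)
  w1 <- extract_structure_windows(cbind(base, start_res = 25L, end_res = 30L,
                                        protein = prot100))
  expect_equal(c(w1$win_start, w1$win_end), c(5L, 50L))
  expect_equal(c(w1$region_start_in_window, w1$region_end_in_window), c(21L, 26L))

  w2 <- extract_structure_windows(cbind(base, start_res = 3L, end_res = 8L,
                                        protein = strrep("A", 2) %+% "QQQQQQ" %+% strrep("A", 40)))
  expect_equal(c(w2$win_start, w2$win_end), c(1L, 28L))

  sym <- strrep("A", 41) %+% "QQQQQQ" %+% strrep("A", 41)
  w3 <- extract_structure_windows(cbind(base, start_res = 42L, end_res = 47L,
                                        protein = sym), flank = 20)
  expect_equal(c(w3$win_start, w3$win_end), c(22L, 67L))
  # symmetric flanks: 20 residues on each side of the repeat
  expect_equal(w3$region_start_in_window - 1L, nchar(w3$sequence) - w3$region_end_in_window)
  expect_equal(nchar(w3$sequence), 46L)
})

test_that("structure aggregation maps H/E/other and conserves mass", {
  base <- data.frame(set_id = "s", category = 1L, label = "stable",
                     row_id = "x", stringsAsFactors = FALSE)
  reps <- do.call(rbind, lapply(1:20, function(i) {
    cbind(base, region_id = paste0("r", i), start_res = 21L, end_res = 26L,
          protein = strrep("A", 20) %+% "QQQQQQ" %+% strrep("A", 20))
  }))
  w <- extract_structure_windows(reps, flank = 20)
  ss_all_h <- setNames(rep(strrep("H", 46), 20), w$window_id)
  agg <- aggregate_structure(w, ss_all_h, flank = 10)
  expect_true(all(agg$helical == 1))
  expect_true(all(agg$extended == 0))

  # half helical, half extended at every position
  ss_half <- setNames(c(rep(strrep("H", 46), 10), rep(strrep("E", 46), 10)),
                      w$window_id)
  agg2 <- aggregate_structure(w, ss_half, flank = 10)
  expect_true(all(agg2$helical == 0.5 & agg2$extended == 0.5 & agg2$other == 0))

  # random states: proportions sum to one wherever observed
  set.seed(44)
  ss_rand <- setNames(vapply(1:20, function(i) {
    paste(sample(c("H", "E", "C", "-"), 46, replace = TRUE), collapse = "")
  }, character(1)), w$window_id)
  agg3 <- aggregate_structure(w, ss_rand, flank = 10)
  expect_equal(agg3$helical + agg3$extended + agg3$other, rep(1, nrow(agg3)))

  # length-mismatched structure strings are skipped with a message
  ss_bad <- ss_all_h
  ss_bad[1] <- strrep("H", 10)
  expect_message(agg4 <- aggregate_structure(w, ss_bad, flank = 10), "skipped")
  expect_true(all(agg4$n == 19L))
})
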