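# Independent oracles: deliberately naive implementations used to check the
# package's vectorized code paths.

# Brute-force polyQ scanner: enumerate every window, mark covered positions,
# take maximal covered runs, trim each run to its terminal glutamines.
oracle_scan_polyq <- function(s, min_q = 4, window = 6) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  w <- min(window, L)
  covered <- rep(FALSE, L)
  if (L >= 1L && w >= min_q) {
    for (st in seq_len(max(0L, L - w + 1L))) {
      win <- chars[st:(st + w - 1L)]
      if (sum(win == "Q") >= min_q) covered[st:(st + w - 1L)] <- TRUE
    }
  }
  starts <- integer(0L); ends <- integer(0L)
  i <- 1L
  while (i <= L) {
    if (!covered[i]) { i <- i + 1L; next }
    j <- i
    while (j < L && covered[j + 1L]) j <- j + 1L
    a <- i
    while (a <= j && chars[a] != "Q") a <- a + 1L
    b <- j
    while (b >= a && chars[b] != "Q") b <- b - 1L
    if (a <= b) { starts <- c(starts, a); ends <- c(ends, b) }
    i <- j + 1L
  }
  if (!length(starts)) {
    return(data.frame(start_res = integer(0L), end_res = integer(0L),
                      sequence = character(0L), n_q = integer(0L),
                      stringsAsFactors = FALSE))
  }
  data.frame(start_res = starts, end_res = ends,
             sequence = substring(toupper(s), starts, ends),
             n_q = vapply(seq_along(starts),
                          function(k) sum(chars[starts[k]:ends[k]] == "Q"), integer(1L)),
             stringsAsFactors = FALSE)
}

# Direct transcription of the column-classification rules using exact
# integer arithmetic at the printed 80% / 20% thresholds.
oracle_column_class <- function(n_q, n_gap, n_other) {
  n <- n_q + n_gap + n_other
  if (5L * n_q >= 4L * n) return(c(value = "conserved", subvalue = "none"))
  if (5L * n_q < n) return(c(value = "uncategorized", subvalue = "none"))
  sub <- if (n_gap > n_other) "inserted" else if (n_other > n_gap) "mutated" else "undefined"
  c(value = "unstable", subvalue = sub)
}

# Direct transcription of the five category rules from counts.
oracle_category <- function(C, U, I, M, D) {
  if (C > U) return(1L)
  if (U > C) {
    if (I > M && I > D) return(2L)
    if (M > I && M > D) return(3L)
    return(4L)
  }
  5L
}

# Pairwise identity computed pair by pair, column by column.
oracle_average_identity <- function(seq_vec) {
  rows <- strsplit(seq_vec, "", fixed = TRUE)
  n <- length(rows)
  acc <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    denom <- 0L; ident <- 0L
    for (k in seq_along(rows[[i]])) {
      a <- rows[[i]][k]; b <- rows[[j]][k]
      if (a == "-" && b == "-") next
      denom <- denom + 1L
      if (a == b) ident <- ident + 1L
    }
    if (denom > 0L) acc <- c(acc, ident / denom)
  }
  100 * mean(acc)
}

# Random test-sequence factories.
.NON_Q <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","R","S","T","V","W","Y")

random_protein <- function(len, q_freq) {
  paste(sample(c("Q", .NON_Q), len, replace = TRUE,
               prob = c(q_freq, rep((1 - q_freq) / 19, 19))), collapse = "")
}

random_gapped <- function(len, gap_freq = 0.3) {
  paste(sample(c("-", "A", "Q", "L"), len, replace = TRUE,
               prob = c(gap_freq, rep((1 - gap_freq) / 3, 3))), collapse = "")
}

`%+%` <- function(a, b) paste0(a, b)

# Small alignment builder for literal rows.
aln <- function(..., set_id = "t") {
  rows <- c(...)
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    names(rows) <- sprintf("s%d", seq_along(rows))
  }
  ortholog_alignment(rows, set_id = set_id)
}

# Build a paired-CDS object directly from proteins + codon lists.
paired_from <- function(alignment, codons) {
  pair_cds_with_protein(alignment, codons)
}
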