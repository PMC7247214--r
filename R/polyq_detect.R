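#' Scan a protein sequence for polyglutamine regions
#'
#' Applies the 4-in-6 density rule: every window of `window` consecutive
#' residues containing at least `min_q` glutamines marks a hit. Positions
#' covered by overlapping or adjacent hit windows are merged into maximal
#' runs, and each run is trimmed so it begins and ends with a glutamine.
#' Sequences shorter than `window` are treated as a single truncated window,
#' so a bare `"QQQQ"` tract qualifies. All coordinates are 1-based inclusive
#' positions in the ungapped sequence.
#'
#' @param residues Ungapped amino-acid string. Any non-Q letter (including
#'   `X`) is equivalent for detection.
#' @param min_q Minimum number of glutamines per window (default 4).
#' @param window Window length in residues (default 6).
#' @return Data frame with one row per region: `start_res`, `end_res`,
#'   `sequence`, `n_q`. Zero rows when no region qualifies.
#' @examples
#' scan_polyq("QQEQDQ")            # one impure region, 1..6
#' scan_polyq("QQQQAAAAAAQQQQ")    # two pure tracts
#' @export
scan_polyq <- function(residues, min_q = 4L, window = 6L) {
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  min_q <- as.integer(min_q); window <- as.integer(window)
  if (min_q > window) {
    stop("configuration error: min_q (", min_q, ") exceeds window (", window, ")",
         call. = FALSE)
  }
  if (min_q < 1L) stop("configuration error: min_q must be >= 1", call. = FALSE)
  empty <- data.frame(start_res = integer(0L), end_res = integer(0L),
                      sequence = character(0L), n_q = integer(0L),
                      stringsAsFactors = FALSE)
  residues <- toupper(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L == 0L) return(empty)
  isq <- chars == "Q"
  w <- min(window, L)
  if (w < min_q || sum(isq) < min_q) return(empty)
  # Q count per window via cumulative sums.
  cs <- c(0L, cumsum(isq))
  n_win <- L - w + 1L
  qc <- cs[(w + 1L):(L + 1L)] - cs[seq_len(n_win)]
  hits <- which(qc >= min_q)
  if (!length(hits)) return(empty)
  # Coverage union of [h, h + w - 1] via a difference array.
  d <- integer(L + 1L)
  d[hits] <- d[hits] + 1L
  d[hits + w] <- d[hits + w] - 1L
  covered <- cumsum(d[seq_len(L)]) > 0L
  r <- rle(covered)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    s <- run_start[k]; e <- run_end[k]
    qs <- which(isq[s:e]) + s - 1L
    c(qs[1L], qs[length(qs)])
  })
  starts <- vapply(out, `[`, integer(1L), 1L)
  ends <- vapply(out, `[`, integer(1L), 2L)
  data.frame(start_res = starts, end_res = ends,
             sequence = substring(residues, starts, ends),
             n_q = cs[ends + 1L] - cs[starts],
             stringsAsFactors = FALSE)
}

#' Extract orthologous polyQ regions from an alignment
#'
#' Runs [scan_polyq()] on each ungapped row, lifts every per-row region to
#' its alignment-column span, and merges column spans that overlap across
#' rows (transitive closure) into orthologous regions. Spans that merely
#' touch without sharing a column are kept separate, so no two orthologous
#' regions in an alignment ever share a column.
#'
#' @param alignment An [ortholog_alignment()].
#' @param column_map Optional precomputed [build_column_map()] result.
#' @inheritParams scan_polyq
#' @return List with two data frames: `regions` (`set_id`, `region_id`,
#'   `col_start`, `col_end`, `n_members`) ordered by `col_start`, and
#'   `members` (`region_id`, `row_id`, `start_res`, `end_res`, `start_col`,
#'   `end_col`, `sequence`, `n_q`), one row per per-sequence polyQ.
#' @export
extract_orthologous_regions <- function(alignment, column_map = NULL,
                                        min_q = 4L, window = 6L) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  if (is.null(column_map)) column_map <- build_column_map(alignment)
  mem <- list()
  for (id in alignment$ids) {
    ungapped <- gsub("-", "", alignment$seqs[[id]], fixed = TRUE)
    reg <- scan_polyq(ungapped, min_q = min_q, window = window)
    if (!nrow(reg)) next
    r2c <- column_map[[id]]$res_to_col
    reg$row_id <- id
    reg$start_col <- r2c[reg$start_res]
    reg$end_col <- r2c[reg$end_res]
    mem[[id]] <- reg
  }
  empty_regions <- data.frame(set_id = character(0L), region_id = character(0L),
                              col_start = integer(0L), col_end = integer(0L),
                              n_members = integer(0L), stringsAsFactors = FALSE)
  empty_members <- data.frame(region_id = character(0L), row_id = character(0L),
                              start_res = integer(0L), end_res = integer(0L),
                              start_col = integer(0L), end_col = integer(0L),
                              sequence = character(0L), n_q = integer(0L),
                              stringsAsFactors = FALSE)
  if (!length(mem)) return(list(regions = empty_regions, members = empty_members))
  members <- do.call(rbind, mem)
  rownames(members) <- NULL
  # Transitive overlap closure on column intervals: sort by start, then a
  # new component begins whenever the next start lies beyond the running
  # maximum end (touching spans, start == end + 1, are NOT merged).
  ord <- order(members$start_col, members$end_col)
  members <- members[ord, ]
  comp <- integer(nrow(members))
  cur <- 0L
  cur_end <- -1L
  for (i in seq_len(nrow(members))) {
    if (members$start_col[i] > cur_end) cur <- cur + 1L
    comp[i] <- cur
    cur_end <- max(cur_end, members$end_col[i])
  }
  members$region_id <- sprintf("%s_r%d", alignment$set_id, comp)
  regions <- do.call(rbind, lapply(split(members, comp), function(d) {
    data.frame(set_id = alignment$set_id, region_id = d$region_id[1L],
               col_start = min(d$start_col), col_end = max(d$end_col),
               n_members = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(regions) <- NULL
  members <- members[, c("region_id", "row_id", "start_res", "end_res",
                         "start_col", "end_col", "sequence", "n_q")]
  list(regions = regions[order(regions$col_start), ], members = members)
}

#' Filter ortholog sets by minimum species count
#'
#' Sets with fewer than `min_rows` sequences are dropped (the retention
#' boundary is inclusive: a set with exactly `min_rows` rows is kept). The
#' number of dropped sets is reported via `message()`.
#'
#' @param alignments List of [ortholog_alignment()] objects.
#' @param min_rows Minimum number of sequences per retained set (default 5).
#' @return The retained alignments, in input order.
#' @export
filter_sets <- function(alignments, min_rows = 5L) {
  stopifnot(is.list(alignments))
  keep <- vapply(alignments, function(a) length(a$ids) >= min_rows, logical(1L))
  if (any(!keep)) {
    message(sum(!keep), " ortholog set(s) dropped (< ", min_rows, " sequences)")
  }
  alignments[keep]
}
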