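#' Pick one representative sequence per orthologous polyQ region
#'
#' For every region, chooses uniformly at random one member row — a row that
#' itself carries a polyQ inside the region span — and records that member's
#' repeat boundaries in its own ungapped sequence. Deterministic for a fixed
#' seed.
#'
#' @param categorized Result of [categorize_alignment()].
#' @param alignment The matching [ortholog_alignment()].
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return Data frame, one row per region: `set_id`, `region_id`,
#'   `category`, `label`, `row_id`, `start_res`, `end_res`, `protein` (the
#'   representative's full ungapped sequence).
#' @export
select_representatives <- function(categorized, alignment, seed = NULL) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  local_seed(seed)
  regions <- categorized$regions
  members <- categorized$members
  ungapped <- gsub("-", "", alignment$seqs, fixed = TRUE)
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    cand <- members[members$region_id == regions$region_id[i], , drop = FALSE]
    pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
    out[[i]] <- data.frame(
      set_id = regions$set_id[i], region_id = regions$region_id[i],
      category = regions$category[i], label = regions$label[i],
      row_id = pick$row_id, start_res = pick$start_res, end_res = pick$end_res,
      protein = unname(ungapped[[pick$row_id]]), stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(set_id = character(0L), region_id = character(0L),
               category = integer(0L), label = character(0L),
               row_id = character(0L), start_res = integer(0L),
               end_res = integer(0L), protein = character(0L),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Residue frequency profile around polyQ regions
#'
#' For each relative position -flank..-1 (before the repeat) and +1..+flank
#' (after it), counts the representatives whose residue at that offset in
#' their ungapped sequence equals `residue`, divided by the representatives
#' that have any residue there. Positions beyond a sequence terminus are
#' skipped for that representative (no padding), so per-position
#' denominators shrink near termini. Region-interior positions are never
#' sampled. Profiles are computed per category when a `label` column is
#' present.
#'
#' @param representatives Data frame from [select_representatives()] (rows
#'   from several alignments may be concatenated).
#' @param residue Single amino-acid letter, e.g. `"L"` or `"P"`.
#' @param flank Number of positions profiled on each side (default 10).
#' @return Data frame: `label`, `residue`, `position` (negative before,
#'   positive after the repeat), `n` (denominator), `n_match`, `freq`.
#' @export
residue_context_profile <- function(representatives, residue, flank = 10L) {
  stopifnot(is.data.frame(representatives), nchar(residue) == 1L)
  if (!nrow(representatives)) stop("empty representative set", call. = FALSE)
  labs <- if ("label" %in% names(representatives)) representatives$label
          else rep("all", nrow(representatives))
  chars <- strsplit(representatives$protein, "", fixed = TRUE)
  len <- nchar(representatives$protein)
  positions <- c(seq.int(-flank, -1L), seq_len(flank))
  out <- list()
  for (lab in unique(labs)) {
    idx <- which(labs == lab)
    for (pos in positions) {
      at <- if (pos < 0L) representatives$start_res[idx] + pos
            else representatives$end_res[idx] + pos
      ok <- at >= 1L & at <= len[idx]
      n <- sum(ok)
      n_match <- if (n) sum(vapply(which(ok), function(k) {
        chars[[idx[k]]][at[k]] == residue
      }, logical(1L))) else 0L
      out[[length(out) + 1L]] <- data.frame(
        label = lab, residue = residue, position = pos,
        n = n, n_match = n_match,
        freq = if (n) n_match / n else NA_real_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Background frequency of a residue in a sequence corpus
#'
#' @param corpus Character vector of protein sequences (gaps are ignored).
#' @param residue Single amino-acid letter.
#' @return Fraction of residues equal to `residue` among all (non-gap)
#'   residues of the corpus.
#' @export
background_frequency <- function(corpus, residue) {
  stopifnot(length(corpus) >= 1L, nchar(residue) == 1L)
  all_chars <- strsplit(paste(gsub("-", "", corpus, fixed = TRUE), collapse = ""),
                        "", fixed = TRUE)[[1L]]
  if (!length(all_chars)) stop("empty corpus", call. = FALSE)
  mean(all_chars == residue)
}

#' Extract sequence windows around polyQ regions
#'
#' For every representative, extracts the repeat plus `flank` residues on
#' each side from its ungapped sequence, truncating at the sequence termini.
#' The resulting windows are the input handed to an external secondary
#' structure predictor; [write_windows_fasta()] serializes them.
#'
#' @inheritParams residue_context_profile
#' @param flank Residues on each side of the repeat (default 20).
#' @return Data frame: `window_id`, `set_id`, `region_id`, `label`,
#'   `row_id`, `win_start`, `win_end` (in the ungapped sequence),
#'   `region_start_in_window`, `region_end_in_window`, `sequence`.
#' @export
extract_structure_windows <- function(representatives, flank = 20L) {
  stopifnot(is.data.frame(representatives))
  if (!nrow(representatives)) stop("empty representative set", call. = FALSE)
  len <- nchar(representatives$protein)
  win_start <- pmax(1L, representatives$start_res - flank)
  win_end <- pmin(len, representatives$end_res + flank)
  data.frame(
    window_id = paste(representatives$region_id, representatives$row_id, sep = "|"),
    set_id = representatives$set_id, region_id = representatives$region_id,
    label = if ("label" %in% names(representatives)) representatives$label else "all",
    row_id = representatives$row_id,
    win_start = win_start, win_end = win_end,
    region_start_in_window = representatives$start_res - win_start + 1L,
    region_end_in_window = representatives$end_res - win_start + 1L,
    sequence = substring(representatives$protein, win_start, win_end),
    stringsAsFactors = FALSE)
}

#' Write structure windows as FASTA
#'
#' @param windows Data frame from [extract_structure_windows()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  x <- Biostrings::BStringSet(stats::setNames(windows$sequence, windows$window_id))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read per-window secondary-structure strings
#'
#' Expects a FASTA-formatted file whose record ids match `window_id`s and
#' whose sequences carry one structure character per window residue
#' (`H` helical, `E` extended, anything else other).
#'
#' @param path Path to the structure-string FASTA.
#' @return Named character vector of structure strings.
#' @export
read_ss_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1L), 1L)
  stats::setNames(toupper(as.character(x)), ids)
}

#' Aggregate secondary-structure states around polyQ regions
#'
#' Maps each structure character to Helical (`H`), Extended (`E`) or Other,
#' and computes, per category and relative position -flank..-1 / +1..+flank
#' (region interior excluded), the proportion of windows in each state.
#' Windows whose structure string length does not match the window length
#' are skipped with a message. The three proportions sum to 1 at every
#' position with at least one observation.
#'
#' @param windows Data frame from [extract_structure_windows()].
#' @param ss Named character vector of structure strings (names are
#'   `window_id`s), e.g. from [read_ss_fasta()].
#' @param flank Positions reported on each side (default 10; the windows are
#'   typically extracted with a wider flank so that border effects in the
#'   prediction fall outside the reported range).
#' @return Data frame: `label`, `position`, `n`, `helical`, `extended`,
#'   `other`.
#' @export
aggregate_structure <- function(windows, ss, flank = 10L) {
  stopifnot(is.data.frame(windows))
  have <- windows$window_id %in% names(ss)
  windows <- windows[have, , drop = FALSE]
  if (!nrow(windows)) stop("no window has a matching structure string", call. = FALSE)
  wlen <- nchar(windows$sequence)
  slen <- nchar(ss[windows$window_id])
  ok <- wlen == slen
  if (any(!ok)) {
    message(sum(!ok), " window(s) skipped: structure string length mismatch")
    windows <- windows[ok, , drop = FALSE]
  }
  if (!nrow(windows)) stop("no window with a usable structure string", call. = FALSE)
  sschars <- strsplit(unname(ss[windows$window_id]), "", fixed = TRUE)
  positions <- c(seq.int(-flank, -1L), seq_len(flank))
  wlen <- nchar(windows$sequence)
  out <- list()
  for (lab in unique(windows$label)) {
    idx <- which(windows$label == lab)
    for (pos in positions) {
      at <- if (pos < 0L) windows$region_start_in_window[idx] + pos
            else windows$region_end_in_window[idx] + pos
      ok <- at >= 1L & at <= wlen[idx]
      states <- vapply(which(ok), function(k) sschars[[idx[k]]][at[k]], character(1L))
      n <- length(states)
      out[[length(out) + 1L]] <- data.frame(
        label = lab, position = pos, n = n,
        helical = if (n) mean(states == "H") else NA_real_,
        extended = if (n) mean(states == "E") else NA_real_,
        other = if (n) mean(!states %in% c("H", "E")) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
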