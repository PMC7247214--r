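#' Count high-confidence interactors from a STRING-style links table
#'
#' Reads a whitespace/tab-separated table of `protein1 protein2
#' combined_score` rows (a header line is detected and skipped), keeps only
#' edges with score strictly above `threshold`, deduplicates undirected
#' pairs, and counts distinct partners per protein. Scores may be given on
#' `[0, 1]` or on STRING's integer 0-1000 file scale: when any score
#' exceeds 1 the whole table is divided by 1000 before thresholding, so
#' "score > 0.7" and "score > 700" are the same filter.
#'
#' @param path Path to the links table.
#' @param threshold High-confidence cutoff, strict inequality (default 0.7).
#' @return Data frame `protein_id`, `n_interactors` (proteins with at least
#'   one retained partner; proteins never seen above threshold are absent,
#'   not zero-filled). Attribute `"n_edges"` holds the retained undirected
#'   edge count.
#' @export
parse_links <- function(path, threshold = 0.7) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty links file: ", path, call. = FALSE)
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  score_chr <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA_character_,
                      character(1L))
  score <- suppressWarnings(as.numeric(score_chr))
  malformed <- nf < 3L | is.na(score)
  # A leading header row is expected in STRING files; only warn about
  # malformed rows beyond it.
  if (malformed[1L]) malformed[1L] <- NA
  n_bad <- sum(malformed, na.rm = TRUE)
  if (n_bad > 0L) warning(n_bad, " malformed link row(s) skipped", call. = FALSE)
  keep <- !is.na(malformed) & !malformed
  keep[1L] <- isFALSE(malformed[1L])
  p1 <- vapply(parts[keep], `[`, character(1L), 1L)
  p2 <- vapply(parts[keep], `[`, character(1L), 2L)
  sc <- score[keep]
  if (!length(sc)) stop("links file has no parseable rows: ", path, call. = FALSE)
  if (any(sc > 1)) sc <- sc / 1000
  hi <- sc > threshold
  p1 <- p1[hi]; p2 <- p2[hi]
  a <- pmin(p1, p2); b <- pmax(p1, p2)
  dup <- duplicated(paste(a, b, sep = "\r"))
  a <- a[dup == FALSE]; b <- b[dup == FALSE]
  self <- a == b
  a <- a[!self]; b <- b[!self]
  counts <- table(c(a, b))
  out <- data.frame(protein_id = names(counts),
                    n_interactors = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_edges") <- length(a)
  out
}

#' Attach polyQ stability categories to interactor counts
#'
#' Every protein belonging to a categorized ortholog set inherits that
#' set's region category — independently of whether the protein itself
#' carries the polyQ. Proteins with no entry in the links table are dropped
#' (absence from STRING cannot be distinguished from having no
#' interactors). A protein associated with several regions yields one row
#' per region, which is reported via `message()`.
#'
#' @param counts Data frame from [parse_links()].
#' @param regions Data frame with at least `set_id`, `region_id`,
#'   `category`, `label` (e.g. the `regions` element of
#'   [categorize_alignment()] results, possibly concatenated).
#' @param proteins Data frame `set_id`, `protein_id`, `protein_length`
#'   listing every protein of every set with its ungapped length.
#' @return Data frame: `protein_id`, `set_id`, `region_id`, `category`,
#'   `label`, `n_interactors`, `protein_length`.
#' @export
attach_categories <- function(counts, regions, proteins) {
  stopifnot(all(c("protein_id", "n_interactors") %in% names(counts)),
            all(c("set_id", "region_id", "category", "label") %in% names(regions)),
            all(c("set_id", "protein_id", "protein_length") %in% names(proteins)))
  lab <- merge(proteins, regions[, c("set_id", "region_id", "category", "label")],
               by = "set_id")
  out <- merge(lab, counts, by = "protein_id")
  multi <- unique(out$protein_id[duplicated(out$protein_id)])
  if (length(multi)) {
    message(length(multi), " protein(s) carry multiple region labels; one row kept per region")
  }
  out <- out[, c("protein_id", "set_id", "region_id", "category", "label",
                 "n_interactors", "protein_length")]
  out <- out[order(out$set_id, out$region_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare interactor counts and protein lengths across categories
#'
#' Pairwise Mann-Whitney U tests (as in
#' [compare_category_distributions()]) run separately on the
#' `n_interactors` and `protein_length` columns. The length comparison is
#' the control: a count difference accompanied by a length difference could
#' merely reflect that longer proteins have more interactions.
#'
#' @param table Data frame from [attach_categories()].
#' @return List of two comparison data frames, `interactors` and `lengths`.
#' @export
compare_counts_and_lengths <- function(table) {
  stopifnot(all(c("n_interactors", "protein_length", "label") %in% names(table)))
  list(interactors = compare_category_distributions(table$n_interactors, table$label),
       lengths = compare_category_distributions(table$protein_length, table$label))
}
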