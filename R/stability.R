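#' @title Stability category labels
#' @description The five evolutionary stability categories, in their
#'   canonical numeric order: stable (1), inserted (2), mutated (3),
#'   undefined (4), uncategorized (5). Only categories 1-3 carry a clear
#'   interpretation of how (in)stability is achieved; 4 and 5 are labelled
#'   and, by default, excluded from downstream feature analyses.
#' @return Character vector of the five labels.
#' @export
stability_levels <- function() {
  c("stable", "inserted", "mutated", "undefined", "uncategorized")
}

# Exact-threshold comparison with a small epsilon so that fractions such as
# 12/15 compare equal to 0.8 despite binary floating point.
.THRESH_EPS <- 1e-9

#' Classify alignment columns by glutamine conservation
#'
#' For each requested column, counts glutamines, gaps and other residues
#' over all rows and assigns the column value:
#' * `conserved` when the glutamine fraction is >= `conserved` (default 0.8),
#' * `uncategorized` when it is < `uncat` (default 0.2),
#' * `unstable` otherwise, with a sub-value describing the remainder:
#'   `inserted` when gaps outnumber non-glutamine residues, `mutated` when
#'   non-glutamine residues outnumber gaps, and `undefined` on a tie.
#'
#' The denominator is always the full row count: a gapped row is a row "not
#' having a glutamine".
#'
#' @param alignment An [ortholog_alignment()].
#' @param cols Integer vector of column indices (default: all columns).
#' @param conserved,uncat Fraction thresholds; `conserved` must exceed `uncat`.
#' @return Data frame: `col`, `n_rows`, `n_q`, `n_gap`, `n_other`, `value`,
#'   `subvalue` (`"none"` unless `value == "unstable"`).
#' @export
classify_columns <- function(alignment, cols = NULL, conserved = 0.8, uncat = 0.2) {
  m <- alignment_matrix(alignment)
  if (is.null(cols)) cols <- seq_len(ncol(m))
  classify_column_matrix(m[, cols, drop = FALSE], cols, conserved, uncat)
}

#' Classify a single alignment column
#'
#' @param column_residues Character vector of the column's characters, one
#'   per row (amino-acid letters or `-`).
#' @inheritParams classify_columns
#' @return One-row data frame as in [classify_columns()].
#' @export
classify_column <- function(column_residues, conserved = 0.8, uncat = 0.2) {
  if (length(column_residues) < 1L) stop("empty column", call. = FALSE)
  classify_column_matrix(matrix(column_residues, ncol = 1L), 1L, conserved, uncat)
}

# Shared worker: m is a character matrix (rows = sequences), cols its
# original column indices.
classify_column_matrix <- function(m, cols, conserved, uncat) {
  stopifnot(conserved > uncat)
  n <- nrow(m)
  if (n < 1L) stop("empty column", call. = FALSE)
  n_q <- colSums(m == "Q")
  n_gap <- colSums(m == "-")
  n_other <- n - n_q - n_gap
  frac <- n_q / n
  value <- ifelse(frac >= conserved - .THRESH_EPS, "conserved",
                  ifelse(frac < uncat - .THRESH_EPS, "uncategorized", "unstable"))
  subvalue <- rep("none", length(cols))
  uns <- value == "unstable"
  subvalue[uns & n_gap > n_other] <- "inserted"
  subvalue[uns & n_other > n_gap] <- "mutated"
  subvalue[uns & n_other == n_gap] <- "undefined"
  data.frame(col = as.integer(cols), n_rows = n, n_q = as.integer(n_q),
             n_gap = as.integer(n_gap), n_other = as.integer(n_other),
             value = value, subvalue = subvalue, stringsAsFactors = FALSE)
}

#' Assign a stability category from a region's column classes
#'
#' Counts conserved (C) and unstable (U) columns over the region span
#' (uncategorized columns contribute to neither), plus the unstable
#' sub-value counts I (inserted), M (mutated), D (undefined), and applies
#' the strict-majority rules:
#' * stable when C > U;
#' * inserted when U > C and I > M and I > D;
#' * mutated when U > C and M > I and M > D;
#' * undefined when U > C but neither of the above;
#' * uncategorized otherwise (including every C = U tie).
#'
#' @param column_classes Data frame from [classify_columns()] restricted to
#'   the region's column span (>= 1 row).
#' @return List with `category` (integer 1-5), `label`, and the counts
#'   `n_conserved`, `n_unstable`, `n_inserted`, `n_mutated`, `n_undefined`.
#' @export
categorize_region <- function(column_classes) {
  stopifnot(is.data.frame(column_classes), nrow(column_classes) >= 1L)
  C <- sum(column_classes$value == "conserved")
  U <- sum(column_classes$value == "unstable")
  I <- sum(column_classes$subvalue == "inserted")
  M <- sum(column_classes$subvalue == "mutated")
  D <- sum(column_classes$subvalue == "undefined")
  cat_i <- if (C > U) {
    1L
  } else if (U > C) {
    if (I > M && I > D) 2L else if (M > I && M > D) 3L else 4L
  } else {
    5L
  }
  list(category = cat_i, label = stability_levels()[cat_i],
       n_conserved = C, n_unstable = U,
       n_inserted = I, n_mutated = M, n_undefined = D)
}

#' Categorize every orthologous polyQ region of an alignment
#'
#' Composes [extract_orthologous_regions()], [classify_columns()] over each
#' region's merged column span (the union across members), and
#' [categorize_region()]. Regions in categories 4 (undefined) and 5
#' (uncategorized) are labelled like any other; downstream analyses exclude
#' them by default.
#'
#' @param alignment An [ortholog_alignment()], typically one that passed
#'   [filter_sets()].
#' @inheritParams classify_columns
#' @inheritParams scan_polyq
#' @return List with data frames `regions` (region table plus `n_conserved`,
#'   `n_unstable`, `n_inserted`, `n_mutated`, `n_undefined`, `category`,
#'   `label`), `members`, and `columns` (per-region column classes, keyed by
#'   `region_id`).
#' @export
categorize_alignment <- function(alignment, min_q = 4L, window = 6L,
                                 conserved = 0.8, uncat = 0.2) {
  ext <- extract_orthologous_regions(alignment, min_q = min_q, window = window)
  regions <- ext$regions
  if (!nrow(regions)) {
    regions[c("n_conserved", "n_unstable", "n_inserted", "n_mutated",
              "n_undefined")] <- integer(0L)
    regions$category <- integer(0L)
    regions$label <- character(0L)
    cols <- classify_columns(alignment, cols = integer(0L),
                             conserved = conserved, uncat = uncat)
    cols$region_id <- character(0L)
    return(list(regions = regions, members = ext$members, columns = cols))
  }
  m <- alignment_matrix(alignment)
  col_list <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    span <- regions$col_start[i]:regions$col_end[i]
    cc <- classify_column_matrix(m[, span, drop = FALSE], span, conserved, uncat)
    cat_r <- categorize_region(cc)
    regions$n_conserved[i] <- cat_r$n_conserved
    regions$n_unstable[i] <- cat_r$n_unstable
    regions$n_inserted[i] <- cat_r$n_inserted
    regions$n_mutated[i] <- cat_r$n_mutated
    regions$n_undefined[i] <- cat_r$n_undefined
    regions$category[i] <- cat_r$category
    regions$label[i] <- cat_r$label
    cc$region_id <- regions$region_id[i]
    col_list[[i]] <- cc
  }
  columns <- do.call(rbind, col_list)
  rownames(columns) <- NULL
  list(regions = regions, members = ext$members, columns = columns)
}
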