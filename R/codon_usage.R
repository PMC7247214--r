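#' Glutamine codon usage per orthologous polyQ region
#'
#' Pools, over every alignment row with a valid CDS pairing, the codon of
#' every glutamine residue whose alignment column falls inside a region's
#' merged column span. Glutamines in rows that themselves lack a polyQ are
#' included: they sit in a column where at least one ortholog has the
#' repeat. By the pairing contract every such codon is CAG or CAA. Regions
#' with zero contributing glutamine codons are marked non-reportable and
#' excluded (with a message).
#'
#' @param categorized Result of [categorize_alignment()] for `alignment`.
#' @param alignment The [ortholog_alignment()] the regions came from.
#' @param paired Result of [pair_cds_with_protein()] for the same alignment.
#' @param column_map Optional precomputed [build_column_map()].
#' @param per_row When `TRUE`, additionally return per-row counts in
#'   attribute `"per_row"` (one row per contributing sequence and region).
#' @return Data frame: `set_id`, `region_id`, `col_start`, `col_end`,
#'   `category`, `label`, `n_cag`, `n_caa`, `pct_cag`
#'   (`100 * n_cag / (n_cag + n_caa)`), `n_rows_used`.
#' @export
region_codon_usage <- function(categorized, alignment, paired,
                               column_map = NULL, per_row = FALSE) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  if (is.null(column_map)) column_map <- build_column_map(alignment)
  regions <- categorized$regions
  out <- regions[, c("set_id", "region_id", "col_start", "col_end",
                     "category", "label")]
  out$n_cag <- 0L; out$n_caa <- 0L; out$n_rows_used <- 0L
  rowtab <- list()
  for (id in names(paired$codons)) {
    prot_chars <- strsplit(paired$residues[[id]], "", fixed = TRUE)[[1L]]
    qpos <- which(prot_chars == "Q")
    if (!length(qpos)) next
    qcols <- column_map[[id]]$res_to_col[qpos]
    qcod <- paired$codons[[id]][qpos]
    for (i in seq_len(nrow(out))) {
      in_span <- qcols >= out$col_start[i] & qcols <= out$col_end[i]
      if (!any(in_span)) next
      cag <- sum(qcod[in_span] == "CAG")
      caa <- sum(qcod[in_span] == "CAA")
      out$n_cag[i] <- out$n_cag[i] + cag
      out$n_caa[i] <- out$n_caa[i] + caa
      out$n_rows_used[i] <- out$n_rows_used[i] + 1L
      if (per_row) {
        rowtab[[length(rowtab) + 1L]] <-
          data.frame(region_id = out$region_id[i], row_id = id,
                     n_cag = cag, n_caa = caa, stringsAsFactors = FALSE)
      }
    }
  }
  tot <- out$n_cag + out$n_caa
  if (any(tot == 0L)) {
    message(sum(tot == 0L), " region(s) non-reportable (no glutamine codons) in set '",
            alignment$set_id, "'")
  }
  out$pct_cag <- ifelse(tot > 0L, 100 * out$n_cag / tot, NA_real_)
  out <- out[tot > 0L, , drop = FALSE]
  rownames(out) <- NULL
  if (per_row) {
    attr(out, "per_row") <- if (length(rowtab)) do.call(rbind, rowtab) else NULL
  }
  out
}

#' Background glutamine codon usage of a CDS corpus
#'
#' Pools every glutamine codon of every validly paired protein, inside or
#' outside polyQ regions, and reports the CAG percentage among glutamine
#' codons. This is the horizontal reference line the per-category region
#' distributions are compared against.
#'
#' @param pairings One [pair_cds_with_protein()] result or a list of them.
#' @param scope Label for the corpus (e.g. a taxon or batch name).
#' @return List with `scope`, `n_cag`, `n_caa`, `pct_cag`.
#' @export
background_cag_fraction <- function(pairings, scope = "corpus") {
  if (!is.null(pairings$codons)) pairings <- list(pairings)
  n_cag <- 0L; n_caa <- 0L
  for (p in pairings) {
    for (id in names(p$codons)) {
      chars <- strsplit(p$residues[[id]], "", fixed = TRUE)[[1L]]
      qcod <- p$codons[[id]][chars == "Q"]
      n_cag <- n_cag + sum(qcod == "CAG")
      n_caa <- n_caa + sum(qcod == "CAA")
    }
  }
  if (n_cag + n_caa == 0L) {
    stop("no glutamine codons in the supplied CDS corpus", call. = FALSE)
  }
  list(scope = scope, n_cag = n_cag, n_caa = n_caa,
       pct_cag = 100 * n_cag / (n_cag + n_caa))
}

# Significance stars, matching the figure-caption convention.
p_stars <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

#' Pairwise Mann-Whitney U comparisons across categories
#'
#' Runs a two-sided Mann-Whitney U (Wilcoxon rank-sum) test for every pair
#' of categories, using the normal approximation (`exact = FALSE`) so that
#' heavily tied percentage distributions are handled deterministically.
#' P-values are annotated with the conventional star bins:
#' `****` <= 1e-4, `***` <= 1e-3, `**` <= 0.01, `*` <= 0.05, else `ns`.
#' Pairs where either group has fewer than 2 values are skipped with a
#' message.
#'
#' @param values Numeric vector of per-region (or per-protein) values.
#' @param categories Category label per value.
#' @return Data frame: `group1`, `group2`, `n1`, `n2`, `statistic` (the U
#'   statistic for `group1` vs `group2`), `p_value`, `significance`.
#' @export
compare_category_distributions <- function(values, categories) {
  stopifnot(length(values) == length(categories))
  keep <- !is.na(values) & !is.na(categories)
  values <- values[keep]; categories <- as.character(categories[keep])
  lev <- intersect(stability_levels(), unique(categories))
  lev <- c(lev, setdiff(unique(categories), lev))
  res <- list()
  if (length(lev) >= 2L) {
    for (i in seq_len(length(lev) - 1L)) {
      for (j in seq.int(i + 1L, length(lev))) {
        x <- values[categories == lev[i]]
        y <- values[categories == lev[j]]
        if (length(x) < 2L || length(y) < 2L) {
          message("skipping ", lev[i], " vs ", lev[j], ": group with < 2 values")
          next
        }
        wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                                 exact = FALSE, correct = TRUE)
        res[[length(res) + 1L]] <- data.frame(
          group1 = lev[i], group2 = lev[j],
          n1 = length(x), n2 = length(y),
          statistic = unname(wt$statistic), p_value = wt$p.value,
          significance = p_stars(wt$p.value), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(group1 = character(0L), group2 = character(0L),
                      n1 = integer(0L), n2 = integer(0L),
                      statistic = numeric(0L), p_value = numeric(0L),
                      significance = character(0L), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
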