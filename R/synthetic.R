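# Cache for the inverted genetic code (amino acid -> codon choices).
.codon_env <- new.env(parent = emptyenv())

codon_choices <- function(aa) {
  if (is.null(.codon_env$table)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$table <- split(names(gc), unname(gc))
  }
  if (aa == "X") return("NNN")
  ch <- .codon_env$table[[aa]]
  if (is.null(ch)) stop("no codon for residue '", aa, "'", call. = FALSE)
  ch
}

# Draw one codon per residue; glutamines use CAG with probability cag_prob
# (else CAA), other residues a uniform synonymous codon.
sample_codons <- function(res_chars, cag_prob) {
  out <- character(length(res_chars))
  qi <- res_chars == "Q"
  nq <- sum(qi)
  if (nq) out[qi] <- ifelse(stats::runif(nq) < cag_prob, "CAG", "CAA")
  for (aa in unique(res_chars[!qi])) {
    idx <- which(!qi & res_chars == aa)
    ch <- codon_choices(aa)
    out[idx] <- ch[sample.int(length(ch), length(idx), replace = TRUE)]
  }
  out
}

# Column class under the thresholds, from raw counts.
col_class_of <- function(n_q, n_gap, n_other, n, conserved, uncat) {
  frac <- n_q / n
  if (frac >= conserved - .THRESH_EPS) return(c("conserved", "none"))
  if (frac < uncat - .THRESH_EPS) return(c("uncategorized", "none"))
  if (n_gap > n_other) c("unstable", "inserted")
  else if (n_other > n_gap) c("unstable", "mutated")
  else c("unstable", "undefined")
}

#' Specification for the synthetic ortholog-set generator
#'
#' Bundles every knob of the generator: alignment shape, the per-category
#' glutamine-codon probabilities, flanking-context enrichments, and
#' interactor-count distributions. The defaults define the simulated study
#' conditions: 15 species per set (one taxon's worth of orthologs), repeats
#' of 6-12 columns, 20-residue flanks, CAG probabilities of 0.75/0.85/0.70
#' for stable/inserted/mutated regions (the 3:1 mammalian background with
#' the slippage-driven elevation in length-variable repeats), a leucine
#' enrichment at position -1 of stable regions (P = 0.3) and a proline
#' enrichment across +1..+10 of inserted regions (P = 0.25), and mean
#' interactor counts of 25 for stable-region proteins versus 15 for
#' unstable ones.
#'
#' @param n_sets Sets generated per category by [generate_dataset()].
#' @param n_species Rows per alignment (>= 2).
#' @param region_length Length-2 integer range of planted repeat columns.
#' @param flank_length Flank residues on each side of the repeat.
#' @param conserved,uncat Column-classification thresholds the plants are
#'   built against.
#' @param cag_prob Named per-category probability that a glutamine codon is
#'   CAG.
#' @param context_enrich Per-category list of residue enrichments, each a
#'   list with `positions` (relative offsets, negative before / positive
#'   after the repeat, within `flank_length`) and `prob`. `prob` is the
#'   exact per-sequence probability of the residue at that offset: cells
#'   that miss the draw are filled from the background with the enriched
#'   residue excluded.
#' @param interactor_lambda Named per-category Poisson mean for planted
#'   interactor counts (counts are `1 + rpois(lambda)`).
#' @param background_residues Residues the flanks are drawn from; glutamine
#'   is excluded by default so no unplanned polyQ can arise.
#' @param impurity_prob Per-member probability of one class-preserving
#'   non-glutamine impurity inside the repeat.
#' @param noise Per-column probability that one non-anchor cell of the
#'   repeat is resampled uniformly among glutamine, gap and a random
#'   background residue (0 = unambiguous plants).
#' @param n_hubs Size of the synthetic interaction-hub pool.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sets = 100L,
                           n_species = 15L,
                           region_length = c(6L, 12L),
                           flank_length = 20L,
                           conserved = 0.8,
                           uncat = 0.2,
                           cag_prob = c(stable = 0.75, inserted = 0.85,
                                        mutated = 0.70, undefined = 0.75,
                                        uncategorized = 0.75),
                           context_enrich = list(
                             stable = list(L = list(positions = -1L, prob = 0.3)),
                             inserted = list(P = list(positions = 1:10, prob = 0.25))),
                           interactor_lambda = c(stable = 25, inserted = 15,
                                                 mutated = 15, undefined = 15,
                                                 uncategorized = 15),
                           background_residues = setdiff(.AA20, "Q"),
                           impurity_prob = 0.1,
                           noise = 0,
                           n_hubs = 5000L) {
  stopifnot(n_species >= 2L, length(region_length) == 2L,
            region_length[1L] >= 4L, region_length[2L] >= region_length[1L],
            flank_length >= 0L, conserved > uncat,
            all(cag_prob >= 0 & cag_prob <= 1),
            all(stability_levels() %in% names(cag_prob)),
            all(stability_levels() %in% names(interactor_lambda)),
            impurity_prob >= 0, impurity_prob <= 1, noise >= 0, noise <= 1,
            length(background_residues) >= 1L)
  for (cat_en in context_enrich) {
    for (en in cat_en) {
      stopifnot(en$prob >= 0, en$prob <= 1,
                all(abs(en$positions) >= 1L),
                all(abs(en$positions) <= flank_length))
    }
  }
  structure(list(n_sets = as.integer(n_sets), n_species = as.integer(n_species),
                 region_length = as.integer(region_length),
                 flank_length = as.integer(flank_length),
                 conserved = conserved, uncat = uncat,
                 cag_prob = cag_prob, context_enrich = context_enrich,
                 interactor_lambda = interactor_lambda,
                 background_residues = background_residues,
                 impurity_prob = impurity_prob, noise = noise,
                 n_hubs = as.integer(n_hubs)),
            class = "synthetic_spec")
}

# Integer band limits for a given row count: smallest conserved Q count and
# largest uncategorized Q count.
q_bands <- function(n, conserved, uncat) {
  q_min_cons <- as.integer(ceiling(conserved * n - .THRESH_EPS))
  q_max_uncat <- as.integer(ceiling(uncat * n - .THRESH_EPS)) - 1L
  list(q_min_cons = q_min_cons, q_max_uncat = q_max_uncat,
       band = seq.int(q_max_uncat + 1L, q_min_cons - 1L))
}

# Sample an (n_q, n_gap, n_other) composition for one unstable sub-value.
sample_unstable_comp <- function(n, bands, subvalue) {
  band <- bands$band
  if (subvalue == "undefined") band <- band[(n - band) %% 2L == 0L & (n - band) >= 2L]
  if (!length(band)) {
    stop("unsatisfiable plant: no valid glutamine count for sub-value '",
         subvalue, "' at ", n, " rows", call. = FALSE)
  }
  n_q <- sample1(band)
  m <- n - n_q
  if (subvalue == "inserted") {
    lo <- m %/% 2L + 1L
    n_gap <- if (lo == m) m else sample1(seq.int(lo, m))
  } else if (subvalue == "mutated") {
    hi <- (m - 1L) %/% 2L
    n_gap <- if (hi == 0L) 0L else sample1(seq.int(0L, hi))
  } else {
    n_gap <- m %/% 2L
  }
  c(n_q = n_q, n_gap = n_gap, n_other = m - n_gap)
}

#' Generate one synthetic ortholog set with a planted category
#'
#' The plant is constructed directly in alignment space, row-wise: after an
#' anchor row that is glutamine across the whole repeat (guaranteeing
#' detection and the full column span), each remaining row is, over the
#' repeat columns, a glutamine row, an all-gap row or an all-substitution
#' row, with row-type counts drawn so that every repeat column satisfies
#' the planted category's composition band. Glutamine rows may receive one
#' interior non-glutamine impurity when that provably preserves both the
#' row's repeat span and the column's class. Flanks carry no glutamine, so
#' no unplanned polyQ can arise, and context enrichments written into the
#' flanks sit at exact offsets from every member's realized repeat
#' boundaries. Uncategorized plants alternate between a conserved/unstable
#' tie and an all-low-glutamine span.
#'
#' @param spec A [synthetic_spec()].
#' @param category One of [stability_levels()].
#' @param set_id Identifier stem for the set.
#' @param seed Optional integer seed (deterministic output when fixed).
#' @return List with `alignment` (an [ortholog_alignment()]), `cds` (named
#'   list of codon vectors, as from [read_cds_fasta()]) and `truth` (the
#'   planted ground-truth record).
#' @export
generate_ortholog_set <- function(spec, category, set_id = "set1", seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), category %in% stability_levels())
  local_seed(seed)
  n <- spec$n_species
  fl <- spec$flank_length
  bands <- q_bands(n, spec$conserved, spec$uncat)
  R <- sample1(seq.int(spec$region_length[1L], spec$region_length[2L]))
  mode <- NA_character_
  bg <- spec$background_residues
  bg_non_q <- setdiff(bg, "Q")
  if (!length(bg_non_q)) bg_non_q <- "A"

  # Region cell matrix (n x R), filled block-wise.
  fill_block <- function(comp, k) {
    block <- matrix("", nrow = n, ncol = k)
    q_rows <- seq_len(comp[["n_q"]])           # nested: anchor row first
    rest <- setdiff(seq_len(n), q_rows)
    rest <- rest[sample.int(length(rest))]
    gap_rows <- rest[seq_len(comp[["n_gap"]])]
    oth_rows <- setdiff(rest, gap_rows)
    block[q_rows, ] <- "Q"
    block[gap_rows, ] <- "-"
    if (length(oth_rows)) {
      block[oth_rows, ] <- sample(bg_non_q, length(oth_rows) * k, replace = TRUE)
    }
    block
  }

  if (category == "stable") {
    n_q <- sample1(seq.int(bands$q_min_cons, n))
    m <- n - n_q
    n_gap <- if (m == 0L) 0L else sample1(seq.int(0L, m))
    comp <- c(n_q = n_q, n_gap = n_gap, n_other = m - n_gap)
    region <- fill_block(comp, R)
  } else if (category %in% c("inserted", "mutated", "undefined")) {
    comp <- sample_unstable_comp(n, bands, category)
    region <- fill_block(comp, R)
  } else {
    # uncategorized: tie between conserved and unstable columns, or an
    # all-low glutamine span.
    mode <- if (bands$q_max_uncat >= 1L) sample(c("tie", "low"), 1L) else "tie"
    if (mode == "low") {
      n_q <- sample.int(bands$q_max_uncat, 1L)
      m <- n - n_q
      n_gap <- sample1(seq.int(0L, m))
      comp <- c(n_q = n_q, n_gap = n_gap, n_other = m - n_gap)
      region <- fill_block(comp, R)
    } else {
      if (R %% 2L == 1L) R <- R + 1L
      k <- R %/% 2L
      n_q1 <- sample1(seq.int(bands$q_min_cons, n))
      m1 <- n - n_q1
      comp1 <- c(n_q = n_q1, n_gap = if (m1 == 0L) 0L else sample1(seq.int(0L, m1)),
                 n_other = 0L)
      comp1[["n_other"]] <- m1 - comp1[["n_gap"]]
      comp2 <- sample_unstable_comp(n, bands, "inserted")
      region <- cbind(fill_block(comp1, k), fill_block(comp2, k))
    }
  }

  # Interior impurities: at most one per glutamine row (never the anchor),
  # only when the column keeps its exact class.
  if (spec$impurity_prob > 0 && R >= 6L && is.na(mode)) {
    base_q <- colSums(region == "Q")
    base_gap <- colSums(region == "-")
    for (r in seq.int(2L, n)) {
      if (!all(region[r, ] == "Q")) next
      if (stats::runif(1L) >= spec$impurity_prob) next
      cc <- sample1(seq.int(2L, R - 1L))
      n_q <- sum(region[, cc] == "Q")
      n_gap <- sum(region[, cc] == "-")
      before <- col_class_of(n_q, n_gap, n - n_q - n_gap, n, spec$conserved, spec$uncat)
      after <- col_class_of(n_q - 1L, n_gap, n - n_q - n_gap + 1L, n,
                            spec$conserved, spec$uncat)
      if (identical(before, after)) {
        region[r, cc] <- sample(bg_non_q, 1L)
      }
    }
  }

  # Per-column noise: resample one non-anchor cell.
  if (spec$noise > 0) {
    for (cc in seq_len(R)) {
      if (stats::runif(1L) >= spec$noise) next
      r <- sample1(seq.int(2L, n))
      region[r, cc] <- switch(sample.int(3L, 1L),
                              "Q", "-", sample(bg_non_q, 1L))
    }
  }

  left <- matrix(sample(bg, n * fl, replace = TRUE), nrow = n)
  right <- matrix(sample(bg, n * fl, replace = TRUE), nrow = n)
  m_all <- cbind(left, region, right)

  # Flanking-context enrichment at exact offsets from the repeat span.
  enrich <- spec$context_enrich[[category]]
  if (!is.null(enrich)) {
    for (res in names(enrich)) {
      en <- enrich[[res]]
      bg_minus <- setdiff(bg, res)
      if (!length(bg_minus)) bg_minus <- "A"
      for (k in en$positions) {
        colk <- if (k < 0L) fl + 1L + k else fl + R + k
        # the planted probability is exact: non-hit cells are redrawn from
        # the background without the enriched residue
        hit <- stats::runif(n) < en$prob
        m_all[hit, colk] <- res
        if (any(!hit)) {
          m_all[!hit, colk] <- sample(bg_minus, sum(!hit), replace = TRUE)
        }
      }
    }
  }

  ids <- sprintf("%s_sp%02d", set_id, seq_len(n))
  seqs <- stats::setNames(apply(m_all, 1L, paste, collapse = ""), ids)
  alignment <- ortholog_alignment(seqs, set_id = set_id,
                                  species = sprintf("species_%02d", seq_len(n)))
  p_cag <- spec$cag_prob[[category]]
  cds <- lapply(seqs, function(s) {
    sample_codons(strsplit(gsub("-", "", s, fixed = TRUE), "", fixed = TRUE)[[1L]],
                  p_cag)
  })
  names(cds) <- ids

  # Guard against unplanned repeats when the flank alphabet contains Q.
  if ("Q" %in% bg) {
    ext <- extract_orthologous_regions(alignment)
    ok <- nrow(ext$regions) == 1L &&
      ext$regions$col_start == fl + 1L && ext$regions$col_end == fl + R
    if (!ok) {
      return(generate_ortholog_set(spec, category, set_id,
                                   seed = derive_seed(if (is.null(seed)) 0L else seed,
                                                      sample.int(1e6, 1L))))
    }
  }

  truth <- list(set_id = set_id, category = category, mode = mode,
                region_col_start = fl + 1L, region_col_end = fl + R,
                region_length = R, n_species = n, cag_prob = p_cag)
  list(alignment = alignment, cds = cds, truth = truth)
}

#' Generate a STRING-style links table with planted interactor counts
#'
#' Each protein receives `1 + rpois(lambda[label])` distinct high-confidence
#' hub partners (scores drawn above 0.7) plus two sub-threshold decoy edges
#' that any correct parser must discard.
#'
#' @param proteins Data frame with `protein_id` and `label` columns.
#' @param spec A [synthetic_spec()] (supplies `interactor_lambda`, `n_hubs`).
#' @param seed Optional integer seed.
#' @return List with `links` (data frame `protein1`, `protein2`,
#'   `combined_score`) and `planted` (data frame `protein_id`, `label`,
#'   `n_planted`).
#' @export
generate_links_table <- function(proteins, spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"),
            all(c("protein_id", "label") %in% names(proteins)))
  local_seed(seed)
  hubs <- sprintf("HUB%05d", seq_len(spec$n_hubs))
  lam <- spec$interactor_lambda[proteins$label]
  k <- 1L + stats::rpois(nrow(proteins), lam)
  rows <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    partners <- hubs[sample.int(length(hubs), k[i] + 2L)]
    score <- c(round(stats::runif(k[i], 0.701, 0.999), 3L),
               round(stats::runif(2L, 0.150, 0.700), 3L))
    rows[[i]] <- data.frame(protein1 = proteins$protein_id[i],
                            protein2 = partners, combined_score = score,
                            stringsAsFactors = FALSE)
  }
  list(links = do.call(rbind, rows),
       planted = data.frame(protein_id = proteins$protein_id,
                            label = proteins$label, n_planted = k,
                            stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes `n_sets` alignments per category (aligned FASTA under
#' `alignments/`, matching CDS FASTA under `cds/`), a links table
#' (`links.tsv`), a machine-readable manifest (`manifest.tsv`) and the full
#' ground truth (`ground_truth.json`). Identical spec and seed produce
#' byte-identical files.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory.
#' @param seed Integer seed driving every random choice.
#' @param overwrite Allow writing into a non-empty existing directory.
#' @param categories Categories to plant (default all five).
#' @return Invisibly, a list with the `manifest` data frame and the planted
#'   links `planted` counts.
#' @export
generate_dataset <- function(spec, out_dir, seed = 1L, overwrite = FALSE,
                             categories = stability_levels()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    stop("output directory exists and is not empty: ", out_dir,
         " (use overwrite = TRUE)", call. = FALSE)
  }
  dir.create(file.path(out_dir, "alignments"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "cds"), recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  proteins <- list()
  truths <- list()
  idx <- 0L
  for (category in categories) {
    for (i in seq_len(spec$n_sets)) {
      idx <- idx + 1L
      set_id <- sprintf("set%04d", idx)
      g <- generate_ortholog_set(spec, category, set_id = set_id,
                                 seed = derive_seed(seed, idx))
      write_alignment_fasta(g$alignment, file.path(out_dir, "alignments",
                                                   paste0(set_id, ".fasta")))
      cds_str <- vapply(g$cds, paste, character(1L), collapse = "")
      Biostrings::writeXStringSet(Biostrings::BStringSet(cds_str),
                                  file.path(out_dir, "cds", paste0(set_id, ".fasta")))
      manifest[[idx]] <- data.frame(
        set_id = set_id, category = category,
        region_col_start = g$truth$region_col_start,
        region_col_end = g$truth$region_col_end,
        region_length = g$truth$region_length,
        n_species = g$truth$n_species, cag_prob = g$truth$cag_prob,
        stringsAsFactors = FALSE)
      proteins[[idx]] <- data.frame(
        set_id = set_id, protein_id = g$alignment$ids, label = category,
        protein_length = nchar(gsub("-", "", g$alignment$seqs, fixed = TRUE)),
        stringsAsFactors = FALSE)
      truths[[idx]] <- g$truth
    }
  }
  manifest <- do.call(rbind, manifest)
  proteins <- do.call(rbind, proteins)
  lk <- generate_links_table(proteins, spec, seed = derive_seed(seed, 999983L))
  utils::write.table(lk$links, file.path(out_dir, "links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, proteins = proteins, planted = lk$planted))
}
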