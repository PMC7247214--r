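#' Pipeline configuration
#'
#' Collects every path and threshold of the full analysis in one validated
#' object. The defaults are the canonical parameters of the method: 4-in-6
#' detection, 80%/20% column-conservation thresholds, at least five species
#' per ortholog set, links score > 0.7, context flank 10, structure-window
#' flank 20.
#'
#' @param alignments_dir Directory of aligned FASTA files (one per set).
#' @param out_dir Output directory for tables and the summary.
#' @param cds_dir Optional directory of CDS FASTA files named like their
#'   alignment (same base name); enables the codon-usage stage.
#' @param links_file Optional STRING-style links table; enables the
#'   interaction stage.
#' @param ss_file Optional FASTA of secondary-structure strings keyed by
#'   window id; enables structure aggregation.
#' @param min_q,window PolyQ detection rule (default 4-in-6).
#' @param conserved,uncat Column classification thresholds.
#' @param min_rows Minimum species per retained set.
#' @param links_threshold High-confidence interaction cutoff (strict).
#' @param flank Context-profile flank (positions on each side).
#' @param ss_flank Structure-window flank.
#' @param context_residues Residues profiled around the repeats.
#' @param seed Seed for the representative selection.
#' @param drop_uninformative Exclude categories 4-5 (undefined,
#'   uncategorized) from the feature stages (default `TRUE`).
#' @return Object of class `polyq_run_config`.
#' @export
run_config <- function(alignments_dir, out_dir,
                       cds_dir = NULL, links_file = NULL, ss_file = NULL,
                       min_q = 4L, window = 6L,
                       conserved = 0.8, uncat = 0.2, min_rows = 5L,
                       links_threshold = 0.7, flank = 10L, ss_flank = 20L,
                       context_residues = c("L", "P"),
                       seed = 1L, drop_uninformative = TRUE) {
  stopifnot(min_q >= 1L, min_q <= window, conserved > uncat,
            conserved > 0, conserved <= 1, uncat >= 0,
            links_threshold >= 0, links_threshold <= 1,
            flank >= 1L, ss_flank >= flank, min_rows >= 2L)
  structure(list(alignments_dir = alignments_dir, out_dir = out_dir,
                 cds_dir = cds_dir, links_file = links_file, ss_file = ss_file,
                 min_q = as.integer(min_q), window = as.integer(window),
                 conserved = conserved, uncat = uncat,
                 min_rows = as.integer(min_rows),
                 links_threshold = links_threshold,
                 flank = as.integer(flank), ss_flank = as.integer(ss_flank),
                 context_residues = context_residues,
                 seed = as.integer(seed),
                 drop_uninformative = isTRUE(drop_uninformative)),
            class = "polyq_run_config")
}

#' Run the full polyQ stability pipeline
#'
#' Orchestrates scan, categorization and the feature stages over a
#' directory of ortholog-set alignments: every set is read, sets with too
#' few species are dropped, orthologous polyQ regions are detected and
#' categorized, and — depending on the configured inputs — per-region codon
#' usage, leucine/proline context profiles, structure windows (plus
#' aggregation when structure strings are supplied) and interactor-count
#' comparisons are computed. Stage outputs are written as TSV under
#' `out_dir` together with a JSON summary that reports per-category region
#' counts and the number of discarded (undefined/uncategorized) regions. A
#' fatal error in any stage aborts the run with a stage-tagged message and
#' removes the partial outputs of this run.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with elements `regions`, `codon_usage`,
#'   `codon_comparisons`, `context`, `windows`, `structure`, `interactors`,
#'   `interactor_comparisons`, `summary`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "polyq_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0L)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- "input"
  res <- tryCatch({
    files <- sort(list.files(config$alignments_dir,
                             pattern = "\\.(fa|fasta|faa)$", full.names = TRUE))
    if (!length(files)) stop("no input sets in ", config$alignments_dir, call. = FALSE)
    alignments <- lapply(files, read_alignment_fasta)
    names(alignments) <- vapply(alignments, `[[`, character(1L), "set_id")
    n_read <- length(alignments)
    alignments <- filter_sets(alignments, min_rows = config$min_rows)

    stage <- "categorize"
    cats <- lapply(alignments, categorize_alignment,
                   min_q = config$min_q, window = config$window,
                   conserved = config$conserved, uncat = config$uncat)
    regions <- do.call(rbind, c(lapply(cats, `[[`, "regions"),
                                list(make.row.names = FALSE)))
    emit(regions, "regions.tsv")
    informative <- if (config$drop_uninformative) {
      regions$region_id[regions$category <= 3L]
    } else {
      regions$region_id
    }

    stage <- "codon_usage"
    codon <- NULL; codon_cmp <- NULL
    if (!is.null(config$cds_dir)) {
      usage <- list()
      for (sid in names(alignments)) {
        cds_path <- list.files(config$cds_dir, full.names = TRUE,
                               pattern = paste0("^", sid, "\\.(fa|fasta|fna)$"))
        if (!length(cds_path)) next
        paired <- pair_cds_with_protein(alignments[[sid]], read_cds_fasta(cds_path[1L]))
        usage[[sid]] <- region_codon_usage(cats[[sid]], alignments[[sid]], paired)
      }
      if (!length(usage)) stop("no CDS file matches any alignment set", call. = FALSE)
      codon <- do.call(rbind, c(usage, list(make.row.names = FALSE)))
      codon <- codon[codon$region_id %in% informative, , drop = FALSE]
      emit(codon, "codon_usage.tsv")
      codon_cmp <- compare_category_distributions(codon$pct_cag, codon$label)
      emit(codon_cmp, "codon_usage_comparisons.tsv")
    }

    stage <- "context"
    reps <- list()
    for (i in seq_along(alignments)) {
      sid <- names(alignments)[i]
      reps[[sid]] <- select_representatives(cats[[sid]], alignments[[sid]],
                                            seed = derive_seed(config$seed, i))
    }
    reps <- do.call(rbind, c(reps, list(make.row.names = FALSE)))
    reps_inf <- reps[reps$region_id %in% informative, , drop = FALSE]
    corpus <- unlist(lapply(alignments, `[[`, "seqs"), use.names = FALSE)
    context <- NULL
    if (nrow(reps_inf)) {
      prof <- lapply(config$context_residues, function(res) {
        p <- residue_context_profile(reps_inf, res, flank = config$flank)
        p$background <- background_frequency(corpus, res)
        p
      })
      context <- do.call(rbind, c(prof, list(make.row.names = FALSE)))
      emit(context, "context_profiles.tsv")
    }

    stage <- "structure"
    windows <- NULL; structure_prof <- NULL
    if (nrow(reps_inf)) {
      windows <- extract_structure_windows(reps_inf, flank = config$ss_flank)
      write_windows_fasta(windows, file.path(config$out_dir, "ss_windows.fasta"))
      written <- c(written, file.path(config$out_dir, "ss_windows.fasta"))
      if (!is.null(config$ss_file)) {
        structure_prof <- aggregate_structure(windows, read_ss_fasta(config$ss_file),
                                              flank = config$flank)
        emit(structure_prof, "structure_context.tsv")
      }
    }

    stage <- "interactions"
    interactors <- NULL; inter_cmp <- NULL
    if (!is.null(config$links_file)) {
      counts <- parse_links(config$links_file, threshold = config$links_threshold)
      proteins <- do.call(rbind, lapply(alignments, function(a) {
        data.frame(set_id = a$set_id, protein_id = a$ids,
                   protein_length = nchar(gsub("-", "", a$seqs, fixed = TRUE)),
                   stringsAsFactors = FALSE)
      }))
      reg_inf <- regions[regions$region_id %in% informative, , drop = FALSE]
      interactors <- attach_categories(counts, reg_inf, proteins)
      emit(interactors, "interactors.tsv")
      inter_cmp <- compare_counts_and_lengths(interactors)
      emit(inter_cmp$interactors, "interactor_comparisons.tsv")
      emit(inter_cmp$lengths, "length_comparisons.tsv")
      # Per-category protein id lists, ready for any enrichment tool.
      for (lab in unique(interactors$label)) {
        writeLines(sort(unique(interactors$protein_id[interactors$label == lab])),
                   file.path(config$out_dir, paste0("proteins_", lab, ".txt")))
        written <- c(written, file.path(config$out_dir, paste0("proteins_", lab, ".txt")))
      }
    }

    stage <- "summary"
    cat_counts <- as.list(table(factor(regions$label, levels = stability_levels())))
    summary <- list(
      n_sets_read = n_read,
      n_sets_retained = length(alignments),
      n_regions = nrow(regions),
      regions_per_category = cat_counts,
      n_discarded = sum(regions$category > 3L),
      config = unclass(config))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(regions = regions, codon_usage = codon, codon_comparisons = codon_cmp,
         context = context, windows = windows, structure = structure_prof,
         interactors = interactors, interactor_comparisons = inter_cmp,
         summary = summary)
  }, error = function(e) {
    unlink(written)
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
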