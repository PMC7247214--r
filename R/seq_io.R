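# Amino-acid alphabet accepted in alignments: 20 standard letters, X for
# unknown residues, '-' for gaps ('.' is normalized to '-' on input).
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_ALPHABET <- c(.AA20, "X", "-")

#' Construct an ortholog alignment object
#'
#' An `ortholog_alignment` is an aligned set of same-length gapped protein
#' sequences with species labels, the unit on which polyQ regions are
#' detected and their evolutionary stability is classified.
#'
#' @param seqs Named character vector of aligned (gapped) amino-acid
#'   sequences. Names are the row identifiers and must be unique.
#' @param set_id Identifier of the ortholog set.
#' @param species Optional character vector of species labels, one per row.
#' @return An object of class `ortholog_alignment` with elements `set_id`,
#'   `ids`, `species`, `seqs` (uppercase, gaps as `-`) and `n_columns`.
#' @examples
#' ortholog_alignment(c(sp1 = "AQQQQA", sp2 = "AQ-QQA"), set_id = "demo")
#' @export
ortholog_alignment <- function(seqs, set_id = "set", species = NULL) {
  if (length(seqs) < 2L) {
    stop("alignment must contain at least 2 sequences", call. = FALSE)
  }
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stop("all sequences must carry non-empty identifiers", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- chartr(".", "-", toupper(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: row lengths ", paste(sort(unique(widths)), collapse = ", "),
         call. = FALSE)
  }
  if (widths[1L] < 1L) stop("alignment has zero columns", call. = FALSE)
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]),
                 .AA_ALPHABET)
  if (length(bad)) {
    stop("invalid residue characters: ", paste(bad, collapse = " "), call. = FALSE)
  }
  if (is.null(species)) species <- ids
  stopifnot(length(species) == length(seqs))
  structure(
    list(set_id = set_id, ids = unname(ids), species = unname(species),
         seqs = stats::setNames(unname(seqs), ids), n_columns = unname(widths[1L])),
    class = "ortholog_alignment"
  )
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat(sprintf("<ortholog_alignment> set '%s': %d sequences x %d columns\n",
              x$set_id, length(x$ids), x$n_columns))
  invisible(x)
}

#' Read a protein multiple alignment from aligned FASTA
#'
#' Sequences are uppercased and `.` gap characters are normalized to `-`.
#' The record identifier is the first whitespace-delimited token of the
#' header; any remainder is kept as the species label.
#'
#' @param path Path to an aligned FASTA file with at least two records.
#' @param set_id Ortholog-set identifier; defaults to the file base name.
#' @return An [ortholog_alignment()] object.
#' @export
read_alignment_fasta <- function(path, set_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aa <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("cannot parse FASTA '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(aa) < 2L) stop("alignment FASTA needs >= 2 records: ", path, call. = FALSE)
  headers <- names(aa)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1L), 1L)
  rest <- sub("^\\S+\\s*", "", headers)
  species <- ifelse(nzchar(rest), rest, ids)
  seqs <- stats::setNames(as.character(aa), ids)
  if (is.null(set_id)) set_id <- tools::file_path_sans_ext(basename(path))
  ortholog_alignment(seqs, set_id = set_id, species = species)
}

#' Write an ortholog alignment to FASTA
#'
#' @param alignment An [ortholog_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  x <- Biostrings::BStringSet(alignment$seqs)
  lab <- ifelse(alignment$species == alignment$ids, alignment$ids,
                paste(alignment$ids, alignment$species))
  names(x) <- lab
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read coding sequences and split them into codons
#'
#' Each record is split into nucleotide triplets; a trailing stop codon
#' (TAA/TAG/TGA) is dropped when present. Records whose length is not a
#' multiple of three are excluded with a warning, never silently dropped.
#'
#' @param path Path to an (unaligned) nucleotide FASTA file.
#' @return Named list of codon character vectors, one element per valid
#'   record. Excluded record ids are available in attribute `"excluded"`.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nt <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(nt), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate CDS identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(nt))
  bad_alpha <- !grepl("^[ACGTN]*$", seqs)
  bad_len <- nchar(seqs) %% 3L != 0L
  drop <- bad_alpha | bad_len
  if (any(drop)) {
    warning(sum(drop), " CDS record(s) excluded (non-ACGTN or length not divisible by 3): ",
            paste(utils::head(ids[drop], 5L), collapse = ", "), call. = FALSE)
  }
  out <- lapply(which(!drop), function(i) {
    s <- seqs[i]
    n <- nchar(s)
    if (n == 0L) return(character(0L))
    cod <- substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
    k <- length(cod)
    if (k > 0L && cod[k] %in% c("TAA", "TAG", "TGA")) cod <- cod[-k]
    cod
  })
  names(out) <- ids[!drop]
  attr(out, "excluded") <- ids[drop]
  out
}

#' Pair CDS codon records with alignment rows
#'
#' For every alignment row with a CDS of matching id, checks that the codon
#' count equals the ungapped residue count and that every glutamine residue
#' is coded by CAG or CAA. Rows failing either check are excluded from codon
#' analyses only (status `"length_mismatch"` / `"codon_mismatch"`); the
#' protein rows themselves remain available for all protein-level analyses.
#'
#' @param alignment An [ortholog_alignment()].
#' @param cds Named list of codon vectors, as from [read_cds_fasta()].
#' @return List with `codons` (named list of codon vectors for valid rows),
#'   `residues` (named character vector of the matching ungapped proteins)
#'   and `status` (data frame: `row_id`, `status` in
#'   ok/missing/length_mismatch/codon_mismatch).
#' @export
pair_cds_with_protein <- function(alignment, cds) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  ids <- alignment$ids
  if (!length(intersect(ids, names(cds)))) {
    stop("no CDS identifier overlaps the alignment rows", call. = FALSE)
  }
  ungapped <- gsub("-", "", alignment$seqs, fixed = TRUE)
  status <- character(length(ids))
  names(status) <- ids
  for (id in ids) {
    if (!id %in% names(cds)) { status[id] <- "missing"; next }
    cod <- cds[[id]]
    prot <- ungapped[[id]]
    if (length(cod) != nchar(prot)) { status[id] <- "length_mismatch"; next }
    qpos <- which(strsplit(prot, "", fixed = TRUE)[[1L]] == "Q")
    if (length(qpos) && !all(cod[qpos] %in% c("CAG", "CAA"))) {
      status[id] <- "codon_mismatch"
      next
    }
    status[id] <- "ok"
  }
  keep <- names(status)[status == "ok"]
  n_bad <- sum(status != "ok" & status != "missing")
  if (n_bad > 0L) {
    message(n_bad, " row(s) excluded from codon analyses in set '",
            alignment$set_id, "' (", paste(ids[status %in% c("length_mismatch", "codon_mismatch")],
                                           collapse = ", "), ")")
  }
  list(codons = cds[keep],
       residues = ungapped[keep],
       status = data.frame(row_id = ids, status = unname(status[ids]),
                           stringsAsFactors = FALSE))
}

#' Map alignment columns to ungapped residue positions
#'
#' Builds, for every row, the bijection between non-gap alignment columns
#' and 1-based residue indices, in both directions.
#'
#' @param alignment An [ortholog_alignment()].
#' @return A `column_map`: list with per-row elements `res_to_col` (integer
#'   vector, residue index -> column) and `col_to_res` (integer vector of
#'   length `n_columns`, `NA` at gap columns).
#' @export
build_column_map <- function(alignment) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  nc <- alignment$n_columns
  maps <- lapply(alignment$seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    res_to_col <- which(chars != "-")
    col_to_res <- rep(NA_integer_, nc)
    col_to_res[res_to_col] <- seq_along(res_to_col)
    list(res_to_col = res_to_col, col_to_res = col_to_res)
  })
  structure(maps, class = "column_map", n_columns = nc)
}

#' Average percentage identity of an alignment
#'
#' Mean over all unordered row pairs of the fraction of identical columns,
#' computed per pair over the columns where at least one of the two rows has
#' a residue: double-gap columns are excluded from the denominator and a gap
#' aligned to a residue counts as a mismatch.
#'
#' @param alignment An [ortholog_alignment()].
#' @return Percentage in `[0, 100]`.
#' @export
average_identity <- function(alignment) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  stopifnot(n >= 2L)
  vals <- numeric(0L)
  for (i in seq_len(n - 1L)) {
    gi <- m[i, ] == "-"
    for (j in seq.int(i + 1L, n)) {
      gj <- m[j, ] == "-"
      denom <- sum(!(gi & gj))
      if (denom == 0L) next
      ident <- sum(m[i, ] == m[j, ] & !gi)
      vals <- c(vals, ident / denom)
    }
  }
  if (!length(vals)) return(NA_real_)
  100 * mean(vals)
}

# Internal: alignment as a character matrix (rows = sequences).
alignment_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  m <- matrix(unlist(strsplit(alignment$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(alignment$ids), byrow = TRUE)
  rownames(m) <- alignment$ids
  m
}
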