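# Reading aligned protein sequences and group assignments, plus the column
# bookkeeping (gap fractions, reference-column maps) the scoring stage needs.

#' Standard amino acid alphabet
#'
#' The 20 standard one-letter amino acid codes in the order used throughout
#' the package (the conventional substitution-matrix row order).
#'
#' @export
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Ambiguity / non-standard codes normalized to the gap symbol: the composition
# model is a distribution over exactly 20 residue types.
.AMBIGUITY_CODES <- c("X", "B", "Z", "J", "U", "O", ".", "~")

#' Construct a grouped alignment
#'
#' A `grouped_alignment` holds equal-length aligned rows over the 20 standard
#' amino acid letters plus the gap symbol `-`, an optional map from sequence
#' id to group label, and an optional designated reference sequence (the
#' structure-bearing sequence, e.g. CXCR4).
#'
#' @param ids character vector of unique sequence identifiers.
#' @param rows character vector of aligned sequences (same length as `ids`),
#'   or a character matrix with one row per sequence.
#' @param groups optional named character vector mapping id -> group label.
#' @param reference_id optional id of the reference sequence.
#' @return An object of class `grouped_alignment` with elements `ids`,
#'   `matrix` (n x L character matrix, rownames = ids), `groups`,
#'   `reference_id`.
#' @export
grouped_alignment <- function(ids, rows, groups = NULL, reference_id = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.matrix(rows)) {
    mat <- rows
  } else {
    rows <- toupper(as.character(rows))
    if (length(rows) != length(ids))
      stop("ids and rows differ in length")
    lens <- nchar(rows)
    if (length(unique(lens)) != 1L)
      stop("alignment-shape error: rows have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  }
  if (ncol(mat) < 1L) stop("alignment has zero columns")
  mat[mat %in% .AMBIGUITY_CODES] <- "-"
  bad <- !(mat %in% c(AA_ALPHABET20, "-"))
  dim(bad) <- dim(mat)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error: unknown residue letter '%s' in sequence '%s' at column %d",
                 mat[w[1L], w[2L]], ids[w[1L]], w[2L]))
  }
  rownames(mat) <- ids
  aln <- structure(list(ids = ids, matrix = mat, groups = NULL,
                        reference_id = NULL),
                   class = "grouped_alignment")
  if (!is.null(groups)) aln <- assign_groups(aln, groups)
  if (!is.null(reference_id)) {
    if (!reference_id %in% ids)
      stop("reference_id '", reference_id, "' not among sequence ids")
    aln$reference_id <- reference_id
  }
  aln
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat(sprintf("grouped_alignment: %d sequences x %d columns\n",
              length(x$ids), ncol(x$matrix)))
  if (!is.null(x$groups))
    cat("  groups:", paste(sprintf("%s (n=%d)", names(table(x$groups)),
                                   table(x$groups)), collapse = ", "), "\n")
  if (!is.null(x$reference_id))
    cat("  reference:", x$reference_id, "\n")
  invisible(x)
}

#' Number of alignment columns
#' @param aln a `grouped_alignment`.
#' @return integer column count.
#' @export
n_columns <- function(aln) ncol(aln$matrix)

#' Read a protein multiple alignment
#'
#' Reads an aligned FASTA or Clustal file. Letters are uppercased; `X`, other
#' ambiguity codes and `.` are normalized to the gap symbol `-`. Group labels
#' are attached separately with [assign_groups()].
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return A `grouped_alignment` without group labels.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    aa <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(aa))
    rows <- as.character(aa)
  } else {
    rows <- as.character(Biostrings::readAAMultipleAlignment(path,
                                                             format = "clustal"))
    ids <- names(rows)
  }
  grouped_alignment(ids, rows)
}

#' Write an alignment as FASTA
#'
#' @param aln a `grouped_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  rows <- apply(aln$matrix, 1L, paste, collapse = "")
  writeLines(paste0(">", aln$ids, "\n", rows), path)
  invisible(path)
}

#' Read a two-column group-assignment table
#'
#' Whitespace- or tab-delimited text, two columns: sequence id, group label.
#'
#' @param path path to the table.
#' @return Named character vector mapping id -> label.
#' @export
read_groups <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "label"),
                           colClasses = "character")
  if (anyDuplicated(tab$id))
    stop("duplicate id in group table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  stats::setNames(tab$label, tab$id)
}

#' Attach group labels to an alignment
#'
#' Joins a label map onto the alignment. Exactly two distinct labels must be
#' used among the alignment's sequences (the divergence score compares two
#' groups); ids in the map but absent from the alignment are reported.
#'
#' @param aln a `grouped_alignment`.
#' @param groups named character vector id -> label (as from [read_groups()]).
#' @return The alignment with `groups` set.
#' @export
assign_groups <- function(aln, groups) {
  missing_in_aln <- setdiff(names(groups), aln$ids)
  if (length(missing_in_aln))
    warning("ids in group table absent from alignment: ",
            paste(missing_in_aln, collapse = ", "))
  unlabelled <- setdiff(aln$ids, names(groups))
  if (length(unlabelled))
    stop("sequences without a group label: ",
         paste(unlabelled, collapse = ", "))
  g <- groups[aln$ids]
  labs <- unique(g)
  if (length(labs) != 2L)
    stop("comparison-arity error: exactly two group labels required, got ",
         length(labs), " (", paste(labs, collapse = ", "), ")")
  aln$groups <- g
  aln
}

#' Per-column gap fraction
#'
#' Unweighted fraction of sequences (both groups pooled) carrying a gap at
#' each requested column. Columns where this exceeds one half are skipped by
#' the scoring stage.
#'
#' @param aln a `grouped_alignment`.
#' @param col column index (1-based) or vector of indices; defaults to all.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
column_gap_fraction <- function(aln, col = seq_len(n_columns(aln))) {
  L <- n_columns(aln)
  if (any(col < 1L | col > L)) stop("column index out of range 1..", L)
  colMeans(aln$matrix[, col, drop = FALSE] == "-")
}

#' Map alignment columns to reference residue numbers
#'
#' The k-th non-gap character of the reference sequence maps to residue
#' number `k + pdb_offset`; columns where the reference is gapped are
#' collected separately. Selected sites falling in reference-gap columns are
#' dropped downstream because they cannot be mapped onto the structure.
#'
#' @param aln a `grouped_alignment` with `reference_id` set.
#' @param pdb_offset integer added to the 1-based ungapped position so that
#'   mapped numbers match the structure's author numbering.
#' @return A `reference_column_map`: list with `column_to_residue` (integer
#'   vector named by column index) and `gapped_columns` (integer vector).
#' @export
map_reference_columns <- function(aln, pdb_offset = 0L) {
  if (is.null(aln$reference_id))
    stop("alignment has no reference_id")
  refrow <- aln$matrix[aln$reference_id, ]
  nongap <- which(refrow != "-")
  res <- seq_along(nongap) + as.integer(pdb_offset)
  structure(list(
    column_to_residue = stats::setNames(as.integer(res), nongap),
    gapped_columns = setdiff(seq_along(refrow), nongap)
  ), class = "reference_column_map")
}
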