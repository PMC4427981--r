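#' @importFrom stats setNames
NULL

#' The twenty standard amino-acid one-letter codes
#'
#' Alphabetical single-letter codes for the 20 standard amino acids, the
#' symbol set over which column residue distributions are estimated.
#' `X` (unknown residue) and `-` (gap) are legal in alignments but are
#' excluded from distribution estimates.
#'
#' @return A character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.msa_alphabet <- function() c(amino_acids(), "X", "-")

#' Construct a validated multiple sequence alignment object
#'
#' Builds an `idr_msa` from parallel vectors of identifiers and aligned
#' sequences. Sequences are upper-cased and `.` gaps converted to `-`
#' (with a warning). All alignment invariants are enforced: at least two
#' records, equal lengths, unique identifiers, characters restricted to the
#' 20 standard residues plus `X` and `-`, and a non-empty ungapped query.
#'
#' @param ids Character vector of unique record identifiers.
#' @param seqs Character vector of aligned sequences (same length as `ids`).
#' @param query_index Integer index of the designated query record.
#' @return An object of class `idr_msa`: a list with elements `ids`, `seqs`,
#'   `query_index` and `n_columns`. Coordinates are 1-based throughout.
#' @export
new_msa <- function(ids, seqs, query_index = 1L) {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length", call. = FALSE)
  if (length(ids) < 2L)
    stop("an alignment needs at least 2 records; conservation over one ",
         "sequence is undefined", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate record identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)

  seqs <- toupper(seqs)
  if (any(grepl(".", seqs, fixed = TRUE))) {
    warning("'.' gap characters converted to '-'", call. = FALSE)
    seqs <- gsub(".", "-", seqs, fixed = TRUE)
  }

  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    ref <- widths[1L]
    bad <- which(widths != ref)[1L]
    stop(sprintf(
      "ragged alignment: record '%s' has length %d, expected %d",
      ids[bad], widths[bad], ref), call. = FALSE)
  }
  if (widths[1L] < 1L)
    stop("alignment has zero columns", call. = FALSE)

  legal <- .msa_alphabet()
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    bad <- which(!(chars %in% legal))
    if (length(bad))
      stop(sprintf(
        "illegal character '%s' in record '%s' at column %d",
        chars[bad[1L]], ids[i], bad[1L]), call. = FALSE)
  }

  query_index <- as.integer(query_index)
  if (is.na(query_index) || query_index < 1L || query_index > length(ids))
    stop("query_index out of range", call. = FALSE)
  if (!nzchar(gsub("-", "", seqs[query_index], fixed = TRUE)))
    stop(sprintf("query record '%s' has an empty ungapped sequence",
                 ids[query_index]), call. = FALSE)

  structure(
    list(ids = ids, seqs = seqs, query_index = query_index,
         n_columns = widths[1L]),
    class = "idr_msa")
}

#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment in aligned FASTA (any line wrapping)
#' and validates it. The query record is resolved from `query_id`; when
#' `NULL`, the first record is the query (reported via a message).
#'
#' @param path Path to an aligned FASTA file with at least two records.
#' @param query_id Identifier of the query record, or `NULL` for the first
#'   record.
#' @return An [new_msa()] object.
#' @export
read_msa <- function(path, query_id = NULL) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L)
    stop("alignment file has fewer than 2 records: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (is.null(query_id)) {
    qi <- 1L
    message("no query_id given; using first record '", ids[1L],
            "' as the query")
  } else {
    qi <- match(query_id, ids)
    if (is.na(qi))
      stop(sprintf("query_id '%s' not found in alignment", query_id),
           call. = FALSE)
  }
  new_msa(ids, seqs, qi)
}

#' Write an alignment as aligned FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param msa An `idr_msa`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "idr_msa"))
  set <- Biostrings::BStringSet(setNames(msa$seqs, msa$ids))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

.msa_row <- function(msa, seq_id) {
  i <- match(seq_id, msa$ids)
  if (is.na(i))
    stop(sprintf("unknown sequence id '%s'", seq_id), call. = FALSE)
  i
}

#' Column/residue coordinate map for one aligned sequence
#'
#' Returns the bijection between alignment columns and ungapped residue
#' positions of one record. Both directions are 1-based: `col_to_res` has
#' one entry per alignment column (`NA` at gap columns), `res_to_col` one
#' entry per residue.
#'
#' @param msa An `idr_msa`.
#' @param seq_id Record identifier.
#' @return A list with elements `seq_id`, `col_to_res` (integer, length
#'   `n_columns`, `NA` where the sequence is gapped) and `res_to_col`
#'   (integer, length of the ungapped sequence).
#' @export
coordinate_map <- function(msa, seq_id) {
  stopifnot(inherits(msa, "idr_msa"))
  i <- .msa_row(msa, seq_id)
  chars <- strsplit(msa$seqs[i], "", fixed = TRUE)[[1L]]
  nongap <- chars != "-"
  col_to_res <- rep(NA_integer_, msa$n_columns)
  col_to_res[nongap] <- seq_len(sum(nongap))
  list(seq_id = seq_id,
       col_to_res = col_to_res,
       res_to_col = which(nongap))
}

#' Ungapped sequence of one alignment record
#'
#' @param msa An `idr_msa`.
#' @param seq_id Record identifier.
#' @return The record's sequence with all `-` characters removed.
#' @export
ungap <- function(msa, seq_id) {
  stopifnot(inherits(msa, "idr_msa"))
  gsub("-", "", msa$seqs[.msa_row(msa, seq_id)], fixed = TRUE)
}

#' @export
print.idr_msa <- function(x, ...) {
  cat(sprintf("idr_msa: %d sequences x %d columns; query '%s' (%d residues)\n",
              length(x$ids), x$n_columns, x$ids[x$query_index],
              nchar(ungap(x, x$ids[x$query_index]))))
  invisible(x)
}

# character matrix view of the alignment (rows = records)
.msa_matrix <- function(msa) {
  m <- matrix("", nrow = length(msa$ids), ncol = msa$n_columns,
              dimnames = list(msa$ids, NULL))
  for (i in seq_along(msa$ids))
    m[i, ] <- strsplit(msa$seqs[i], "", fixed = TRUE)[[1L]]
  m
}
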