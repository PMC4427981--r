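#' Classify a residue position from its paired conservation bins
#'
#' The four-category rule over the binned (0-9) sequence- and
#' disorder-conservation scores:
#' \describe{
#'   \item{S (structured)}{disorder bin 0 - the column completely lacks
#'     disorder.}
#'   \item{C (constrained)}{both bins 5 or greater - sequence and disorder
#'     are conserved.}
#'   \item{F (flexible)}{disorder bin 5 or greater but sequence bin below
#'     5 - disorder is conserved, the underlying sequence is not.}
#'   \item{N (non-conserved)}{disorder bin 1-4 - partial, non-conserved
#'     disorder.}
#' }
#' The thresholds are constants of the method, not tunable parameters.
#'
#' @param seq_bin Integer vector of sequence-conservation bins in 0..9.
#' @param dis_bin Integer vector of disorder-conservation bins in 0..9
#'   (recycled against `seq_bin` if needed).
#' @return Character vector of category letters `"C"`, `"F"`, `"N"`, `"S"`.
#' @export
classify_category <- function(seq_bin, dis_bin) {
  seq_bin <- as.integer(seq_bin)
  dis_bin <- as.integer(dis_bin)
  if (anyNA(seq_bin) || anyNA(dis_bin) ||
      any(seq_bin < 0L | seq_bin > 9L) || any(dis_bin < 0L | dis_bin > 9L))
    stop("conservation bins must be integers in 0..9", call. = FALSE)
  ifelse(dis_bin == 0L, "S",
         ifelse(dis_bin >= 5L,
                ifelse(seq_bin >= 5L, "C", "F"),
                "N"))
}

#' Build the per-residue classification profile of the query
#'
#' Projects the per-column scores onto the query's ungapped coordinates:
#' one record per query residue, in sequence order; alignment columns where
#' the query is gapped produce no record.
#'
#' @param msa An `idr_msa`.
#' @param scores Per-column scores from [score_columns()] covering all
#'   alignment columns.
#' @return A data frame of class `idr_profile` with columns `query_pos`
#'   (1-based residue index), `residue`, `column` (1-based alignment
#'   column), `seq_bin`, `dis_bin`, `category`, and attribute `query_id`.
#' @export
build_profile <- function(msa, scores) {
  stopifnot(inherits(msa, "idr_msa"))
  if (!all(seq_len(msa$n_columns) %in% scores$column))
    stop("scores do not cover every alignment column", call. = FALSE)
  query_id <- msa$ids[msa$query_index]
  cmap <- coordinate_map(msa, query_id)
  cols <- cmap$res_to_col
  residues <- strsplit(ungap(msa, query_id), "", fixed = TRUE)[[1L]]
  idx <- match(cols, scores$column)
  prof <- data.frame(
    query_pos = seq_along(cols),
    residue = residues,
    column = cols,
    seq_bin = scores$seq_bin[idx],
    dis_bin = scores$dis_bin[idx],
    category = classify_category(scores$seq_bin[idx], scores$dis_bin[idx]),
    stringsAsFactors = FALSE)
  attr(prof, "query_id") <- query_id
  class(prof) <- c("idr_profile", "data.frame")
  prof
}

#' Fraction of query residues in each conservation category
#'
#' @param profile An `idr_profile` from [build_profile()].
#' @return A list of class `idr_category_fractions` with elements
#'   `fraction_C`, `fraction_F`, `fraction_N`, `fraction_S` (summing to 1)
#'   and `n_positions`.
#' @export
category_fractions <- function(profile) {
  if (!nrow(profile))
    stop("empty profile", call. = FALSE)
  n <- nrow(profile)
  counts <- vapply(c("C", "F", "N", "S"),
                   function(k) sum(profile$category == k), integer(1))
  structure(
    list(fraction_C = counts[["C"]] / n,
         fraction_F = counts[["F"]] / n,
         fraction_N = counts[["N"]] / n,
         fraction_S = counts[["S"]] / n,
         n_positions = n),
    class = "idr_category_fractions")
}

#' Maximal consecutive runs of constrained residues
#'
#' Extracts every maximal run of category-C positions of length at least
#' `min_length`, in query coordinates. Such consecutive constrained
#' stretches are candidate functional elements (linear-motif- or MoRF-like
#' binding regions) within disordered segments.
#'
#' @param profile An `idr_profile`.
#' @param min_length Minimum run length to report (default 5, the smallest
#'   stratum used when relating constrained runs to known motifs).
#' @return A data frame of class `idr_segments` with columns `start`,
#'   `end` (1-based inclusive query positions) and `sequence`; attribute
#'   `query_id` carried over from the profile. Segments are disjoint and
#'   sorted by `start`.
#' @export
constrained_segments <- function(profile, min_length = 5L) {
  min_length <- as.integer(min_length)
  if (is.na(min_length) || min_length < 1L)
    stop("min_length must be >= 1", call. = FALSE)
  runs <- rle(profile$category == "C")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_length
  seqs <- vapply(which(keep), function(k) {
    paste(profile$residue[starts[k]:ends[k]], collapse = "")
  }, character(1))
  out <- data.frame(start = profile$query_pos[starts[keep]],
                    end = profile$query_pos[ends[keep]],
                    sequence = seqs,
                    stringsAsFactors = FALSE)
  attr(out, "query_id") <- attr(profile, "query_id")
  class(out) <- c("idr_segments", "data.frame")
  out
}
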