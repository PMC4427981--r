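#' Kyte-Doolittle hydropathy scale
#'
#' The standard Kyte & Doolittle (1982) per-residue hydropathy values used
#' by the charge-hydropathy fold index. Values range from -4.5 (Arg) to
#' 4.5 (Ile). `X` has no defined hydropathy and is excluded from window
#' averages.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
    G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
    M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)
}

# formal residue charges at neutral pH; His carries 0, termini ignored
.residue_charge <- function() {
  ch <- setNames(numeric(20), amino_acids())
  ch[c("K", "R")] <- 1
  ch[c("D", "E")] <- -1
  ch
}

#' Charge-hydropathy fold index along a sequence
#'
#' Computes, for every residue of an ungapped protein sequence, the
#' unfoldability index `2.785 * <H> - |<R>| - 1.151`, where `<H>` is the
#' mean Kyte-Doolittle hydropathy rescaled to `[0, 1]` via `(KD + 4.5) / 9`
#' and `<R>` is the mean net charge (K, R = +1; D, E = -1; H = 0), both
#' averaged over a sliding window centred on the residue. Windows are
#' truncated at the sequence ends (the mean runs over in-bounds residues
#' only). `X` residues are excluded from both means (the window is
#' renormalised over the known residues). A positive index predicts a
#' folded residue, a negative index a disordered one.
#'
#' @param sequence Ungapped amino-acid sequence (single string), letters
#'   from the 20 standard residues plus `X`.
#' @param window Odd window length (number of residues averaged), >= 1.
#'   Default 21: short enough to resolve functional elements on the
#'   MoRF/linear-motif scale (5-25 residues) instead of averaging them
#'   into their flanks, while still smoothing single-residue noise.
#'   Larger windows (charge-hydropathy profiles are often smoothed over
#'   51 residues) give smoother whole-protein profiles at the cost of
#'   boundary resolution.
#' @return Numeric vector, one index per residue. `NA` where a window
#'   contains no known residue.
#' @export
foldindex_scores <- function(sequence, window = 21L) {
  sequence <- toupper(as.character(sequence)[1L])
  if (is.na(sequence) || !nzchar(sequence))
    stop("empty sequence", call. = FALSE)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% c(amino_acids(), "X")))
  if (length(bad))
    stop(sprintf("illegal residue '%s' at position %d", chars[bad[1L]],
                 bad[1L]), call. = FALSE)

  kd <- kyte_doolittle()
  ch <- .residue_charge()
  h <- unname((kd[chars] + 4.5) / 9)   # NA for X
  r <- unname(ch[chars])
  known <- as.numeric(chars != "X")
  h[is.na(h)] <- 0
  r[is.na(r)] <- 0

  L <- length(chars)
  half <- (window - 1L) %/% 2L
  # windowed sums via cumulative sums, truncated at the ends
  csh <- cumsum(c(0, h))
  csr <- cumsum(c(0, r))
  csn <- cumsum(c(0, known))
  i <- seq_len(L)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, L)
  n <- csn[hi + 1L] - csn[lo]
  mh <- ifelse(n > 0, (csh[hi + 1L] - csh[lo]) / n, NA_real_)
  mr <- ifelse(n > 0, (csr[hi + 1L] - csr[lo]) / n, NA_real_)
  2.785 * mh - abs(mr) - 1.151
}

#' Binarise per-residue disorder scores
#'
#' External predictors report disorder propensity on a `[0, 1]` scale;
#' a residue with score >= 0.5 is called disordered. The fold index is a
#' signed scale whose published decision boundary is zero: a residue is
#' called disordered iff its index is strictly negative.
#'
#' @param raw Numeric vector of per-residue scores.
#' @param predictor `"external"` (0.5-threshold rule) or `"foldindex"`
#'   (sign rule).
#' @return Integer vector of flags (1 = disordered, 0 = ordered).
#' @export
binarize <- function(raw, predictor = c("external", "foldindex")) {
  predictor <- match.arg(predictor)
  if (!length(raw))
    stop("empty score track", call. = FALSE)
  if (anyNA(raw)) {
    warning("NA disorder scores treated as ordered", call. = FALSE)
    raw[is.na(raw)] <- if (predictor == "external") 0 else 1
  }
  if (predictor == "external") as.integer(raw >= 0.5) else as.integer(raw < 0)
}

#' Construct a per-residue disorder track
#'
#' @param seq_id Sequence identifier the track belongs to.
#' @param raw Numeric per-residue scores on the predictor's native scale.
#' @param predictor `"external"` or `"foldindex"`; sets the binarisation
#'   rule (see [binarize()]).
#' @return An object of class `idr_disorder_track` with fields `seq_id`,
#'   `raw`, `binary` and `predictor`.
#' @export
disorder_track <- function(seq_id, raw, predictor = c("external", "foldindex")) {
  predictor <- match.arg(predictor)
  structure(
    list(seq_id = as.character(seq_id), raw = as.numeric(raw),
         binary = binarize(raw, predictor), predictor = predictor),
    class = "idr_disorder_track")
}

#' Read an external per-residue disorder score file
#'
#' Parses a two-column whitespace- or tab-separated file of
#' `(1-based residue index, score)` rows; `#` comment lines are skipped.
#' Scores are binarised by the 0.5-or-greater rule. Every residue of the
#' sequence must be covered exactly once.
#'
#' @param path Path to the score file.
#' @param seq_id Identifier of the (ungapped) sequence the file describes.
#' @param expected_length Ungapped sequence length the track must cover.
#' @return An [disorder_track()] with `predictor = "external"`.
#' @export
read_disorder_file <- function(path, seq_id, expected_length) {
  if (!file.exists(path))
    stop("no such disorder file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("residue", "score"),
                           colClasses = c("integer", "numeric"))
  expected_length <- as.integer(expected_length)
  if (nrow(tab) != expected_length)
    stop(sprintf(
      "disorder file '%s' for '%s' has %d rows but the sequence has %d residues",
      path, seq_id, nrow(tab), expected_length), call. = FALSE)
  if (anyDuplicated(tab$residue))
    stop(sprintf("duplicate residue index %d in '%s'",
                 tab$residue[duplicated(tab$residue)][1L], path),
         call. = FALSE)
  missing <- setdiff(seq_len(expected_length), tab$residue)
  if (length(missing))
    stop(sprintf("disorder file '%s' does not cover residue %d",
                 path, missing[1L]), call. = FALSE)
  tab <- tab[order(tab$residue), ]
  disorder_track(seq_id, tab$score, "external")
}

#' Project per-sequence disorder tracks into alignment-column space
#'
#' Builds the aligned disorder matrix: one row per alignment record, one
#' column per alignment column; cell `(s, c)` is the sequence's binary
#' disorder flag at the residue occupying column `c`, or `NA` where the
#' sequence is gapped.
#'
#' @param msa An `idr_msa`.
#' @param tracks Named list of [disorder_track()] objects, one per
#'   alignment record (names or `seq_id` fields match record identifiers).
#' @return Integer matrix (rows named by record id) with values 0, 1, `NA`.
#' @export
align_disorder <- function(msa, tracks) {
  stopifnot(inherits(msa, "idr_msa"))
  ids <- vapply(tracks, function(t) t$seq_id, character(1))
  mat <- matrix(NA_integer_, nrow = length(msa$ids), ncol = msa$n_columns,
                dimnames = list(msa$ids, NULL))
  for (id in msa$ids) {
    k <- match(id, ids)
    if (is.na(k))
      stop(sprintf("no disorder track for record '%s'", id), call. = FALSE)
    track <- tracks[[k]]
    cmap <- coordinate_map(msa, id)
    L <- length(cmap$res_to_col)
    if (length(track$binary) != L)
      stop(sprintf(
        "track for '%s' has %d residues but the ungapped sequence has %d",
        id, length(track$binary), L), call. = FALSE)
    mat[id, cmap$res_to_col] <- track$binary
  }
  mat
}

#' Compute disorder tracks for every sequence of an alignment
#'
#' Runs the bundled fold-index predictor on each ungapped sequence, or
#' ingests one external score file per sequence via a manifest.
#'
#' @param msa An `idr_msa`.
#' @param predictor `"foldindex"` or `"external"`.
#' @param manifest For `predictor = "external"`: named character vector or
#'   list mapping every record id to a score-file path.
#' @param foldindex_window Window length passed to [foldindex_scores()].
#' @return Named list of [disorder_track()] objects, in alignment order.
#' @export
disorder_tracks <- function(msa, predictor = c("foldindex", "external"),
                            manifest = NULL, foldindex_window = 21L) {
  stopifnot(inherits(msa, "idr_msa"))
  predictor <- match.arg(predictor)
  tracks <- vector("list", length(msa$ids))
  names(tracks) <- msa$ids
  for (id in msa$ids) {
    seq <- ungap(msa, id)
    if (predictor == "foldindex") {
      raw <- foldindex_scores(seq, window = foldindex_window)
      tracks[[id]] <- disorder_track(id, raw, "foldindex")
    } else {
      path <- manifest[[id]]
      if (is.null(path))
        stop(sprintf("disorder manifest has no entry for record '%s'", id),
             call. = FALSE)
      tracks[[id]] <- read_disorder_file(path, id, nchar(seq))
    }
  }
  tracks
}
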