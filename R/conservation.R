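#' Background amino-acid frequencies from the BLOSUM62 derivation
#'
#' The marginal amino-acid frequencies of the BLOSUM62 substitution-matrix
#' training alignments, the customary background distribution for
#' divergence-based conservation scoring. Renormalised to sum to exactly 1.
#'
#' @return Named numeric probability vector over the 20 standard residues,
#'   in [amino_acids()] order.
#' @export
blosum62_frequencies <- function() {
  f <- c(A = 0.078, R = 0.051, N = 0.041, D = 0.052, C = 0.024,
         Q = 0.034, E = 0.059, G = 0.083, H = 0.025, I = 0.062,
         L = 0.092, K = 0.056, M = 0.024, F = 0.044, P = 0.043,
         S = 0.059, T = 0.055, W = 0.014, Y = 0.034, V = 0.072)
  f <- f / sum(f)
  f[amino_acids()]
}

#' Uniform background distribution over the 20 amino acids
#' @return Named numeric vector, each entry 1/20.
#' @export
uniform20 <- function() {
  setNames(rep(1 / 20, 20), amino_acids())
}

#' Conservation scoring configuration
#'
#' Bundles the parameters of column-wise sequence-conservation scoring.
#' Defaults follow the Jensen-Shannon divergence scoring framework:
#' JSD against the BLOSUM62 background with lambda 0.5, Henikoff
#' position-based sequence weighting, a tiny pseudocount, gap penalisation
#' and +/-3-column window smoothing with half weight.
#'
#' @param method `"jsd"` (Jensen-Shannon divergence from background) or
#'   `"shannon_entropy"` (1 - normalised column entropy).
#' @param background `"blosum62_frequencies"` or `"uniform20"`.
#' @param lambda_prior Mixing weight of the column distribution in the JSD,
#'   in (0, 1). With 0.5 and base-2 entropies the JSD is bounded by 1.
#' @param pseudocount Added to every weighted residue count before
#'   normalisation; the tiny default regularises zero counts without
#'   visibly moving scores.
#' @param gap_penalty Multiply each column score by (1 - gap fraction)?
#' @param window_size Half-width of the smoothing window in columns
#'   (0 disables smoothing).
#' @param window_weight Weight of the window mean in the smoothed score,
#'   in `[0, 1]`.
#' @param sequence_weighting `"henikoff"` (position-based) or `"uniform"`.
#' @return A list of class `idr_conservation_config`.
#' @export
conservation_config <- function(method = c("jsd", "shannon_entropy"),
                                background = c("blosum62_frequencies",
                                               "uniform20"),
                                lambda_prior = 0.5,
                                pseudocount = 1e-7,
                                gap_penalty = TRUE,
                                window_size = 3L,
                                window_weight = 0.5,
                                sequence_weighting = c("henikoff", "uniform")) {
  method <- match.arg(method)
  background <- match.arg(background)
  sequence_weighting <- match.arg(sequence_weighting)
  stopifnot(lambda_prior > 0, lambda_prior < 1,
            pseudocount >= 0,
            is.logical(gap_penalty), length(gap_penalty) == 1L,
            window_size >= 0,
            window_weight >= 0, window_weight <= 1)
  structure(
    list(method = method, background = background,
         lambda_prior = lambda_prior, pseudocount = pseudocount,
         gap_penalty = gap_penalty, window_size = as.integer(window_size),
         window_weight = window_weight,
         sequence_weighting = sequence_weighting),
    class = "idr_conservation_config")
}

#' Per-record sequence weights
#'
#' Henikoff & Henikoff position-based weights: at every column, each
#' distinct symbol (gaps and `X` count as symbols) receives an equal share
#' of the column's weight, split equally among the sequences carrying it;
#' a sequence's weight is its mean share over all columns, normalised so
#' the weights sum to 1. The uniform scheme returns 1/n for each record.
#'
#' @param msa An `idr_msa`.
#' @param scheme `"henikoff"` or `"uniform"`.
#' @return Numeric vector of weights (named by record id) summing to 1.
#' @export
sequence_weights <- function(msa, scheme = c("henikoff", "uniform")) {
  stopifnot(inherits(msa, "idr_msa"))
  scheme <- match.arg(scheme)
  n <- length(msa$ids)
  if (scheme == "uniform")
    return(setNames(rep(1 / n, n), msa$ids))
  m <- .msa_matrix(msa)
  w <- numeric(n)
  for (c in seq_len(ncol(m))) {
    col <- m[, c]
    counts <- table(col)
    r <- length(counts)
    w <- w + 1 / (r * as.numeric(counts[col]))
  }
  w <- w / ncol(m)
  setNames(w / sum(w), msa$ids)
}

#' Weighted residue distribution of one alignment column
#'
#' Estimates the probability distribution over the 20 standard amino acids
#' at a column from the weighted residue counts plus a pseudocount,
#' renormalised to sum to 1. Gaps and `X` are excluded from the estimate.
#' A column with no scoreable residue returns an all-`NA` vector flagged
#' with `attr(, "undefined") = TRUE`.
#'
#' @param msa An `idr_msa`.
#' @param column 1-based column index.
#' @param weights Per-record weights (defaults to uniform).
#' @param pseudocount Non-negative regulariser added to each count.
#' @return Named numeric probability vector over [amino_acids()].
#' @export
column_distribution <- function(msa, column, weights = NULL,
                                pseudocount = 0) {
  stopifnot(inherits(msa, "idr_msa"))
  column <- as.integer(column)
  if (is.na(column) || column < 1L || column > msa$n_columns)
    stop(sprintf("column %s out of range 1..%d", column, msa$n_columns),
         call. = FALSE)
  if (is.null(weights))
    weights <- rep(1 / length(msa$ids), length(msa$ids))
  chars <- substr(msa$seqs, column, column)
  keep <- chars %in% amino_acids()
  if (!any(keep)) {
    p <- setNames(rep(NA_real_, 20), amino_acids())
    attr(p, "undefined") <- TRUE
    return(p)
  }
  counts <- setNames(rep(pseudocount, 20), amino_acids())
  tallied <- tapply(weights[keep], chars[keep], sum)
  counts[names(tallied)] <- counts[names(tallied)] + tallied
  p <- counts / sum(counts)
  attr(p, "undefined") <- FALSE
  p
}

.entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence between a column distribution and a background
#'
#' `JSD(p, q) = H(lambda p + (1 - lambda) q) - lambda H(p) - (1 - lambda) H(q)`
#' with entropies in bits. For `lambda = 0.5` the value lies in `[0, 1]`;
#' high values mark conserved, background-atypical columns.
#'
#' @param p Column probability vector (length 20, sums to 1 within 1e-9).
#' @param q Background probability vector (same constraint).
#' @param lambda_prior Mixing weight in (0, 1).
#' @return The divergence (non-negative scalar).
#' @export
jsd_score <- function(p, q, lambda_prior = 0.5) {
  if (abs(sum(p) - 1) > 1e-9)
    stop("p is not normalized (sum deviates from 1 beyond 1e-9)",
         call. = FALSE)
  if (abs(sum(q) - 1) > 1e-9)
    stop("q is not normalized (sum deviates from 1 beyond 1e-9)",
         call. = FALSE)
  stopifnot(lambda_prior > 0, lambda_prior < 1)
  m <- lambda_prior * p + (1 - lambda_prior) * q
  d <- .entropy_bits(m) - lambda_prior * .entropy_bits(p) -
    (1 - lambda_prior) * .entropy_bits(q)
  max(d, 0)
}

#' Gap penalisation and window smoothing of per-column scores
#'
#' Applies, in order: the gap penalty `score * (1 - gap_fraction)` (when
#' enabled), then window smoothing
#' `(1 - w) * score + w * mean(scores in column +/- window_size)` with the
#' mean truncated at the alignment ends and including the centre column.
#' The result is clamped to `[0, 1]`.
#'
#' @param raw_scores Numeric per-column scores.
#' @param gap_fractions Numeric per-column gap fractions (same length).
#' @param config An [conservation_config()].
#' @return Numeric vector of adjusted scores.
#' @export
apply_gap_penalty_and_window <- function(raw_scores, gap_fractions, config) {
  stopifnot(length(raw_scores) == length(gap_fractions))
  s <- raw_scores
  if (isTRUE(config$gap_penalty))
    s <- s * (1 - gap_fractions)
  ws <- config$window_size
  if (ws > 0L && length(s) > 1L) {
    n <- length(s)
    cs <- cumsum(c(0, s))
    i <- seq_len(n)
    lo <- pmax(i - ws, 1L)
    hi <- pmin(i + ws, n)
    wm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    s <- (1 - config$window_weight) * s + config$window_weight * wm
  }
  pmin(pmax(s, 0), 1)
}

#' Disordered fraction at one alignment column
#'
#' The fraction of non-gap sequences whose residue at the column is flagged
#' disordered: `(# cells == 1) / (# non-NA cells)`. Gaps (`NA` cells) are
#' excluded from the denominator; a gap is not a residue.
#'
#' @param matrix Aligned disorder matrix from [align_disorder()].
#' @param column 1-based column index.
#' @return Fraction in `[0, 1]`.
#' @export
disorder_conservation <- function(matrix, column) {
  column <- as.integer(column)
  if (is.na(column) || column < 1L || column > ncol(matrix))
    stop(sprintf("column %s out of range 1..%d", column, ncol(matrix)),
         call. = FALSE)
  cells <- matrix[, column]
  n <- sum(!is.na(cells))
  if (n == 0L)
    stop(sprintf("column %d has no aligned residue (all gaps)", column),
         call. = FALSE)
  sum(cells == 1L, na.rm = TRUE) / n
}

#' Bin a raw conservation score onto the 0-9 scale
#'
#' `bin = clamp(floor(10 * raw), 0, 9)`: decile binning, under which the
#' printed "5 or greater" category thresholds correspond to raw scores
#' >= 0.5, and a raw score of exactly 1 maps to 9.
#'
#' @param raw Numeric scores in `[0, 1]` (values outside by <= 1e-9 are
#'   clamped; anything further out is an error).
#' @return Integer bins in 0..9.
#' @export
bin_score <- function(raw) {
  if (any(raw < -1e-9 | raw > 1 + 1e-9, na.rm = TRUE))
    stop("raw score outside [0, 1]", call. = FALSE)
  raw <- pmin(pmax(raw, 0), 1)
  pmin(pmax(as.integer(floor(10 * raw)), 0L), 9L)
}

#' Score every alignment column for sequence and disorder conservation
#'
#' The column-level driver: computes sequence weights, per-column residue
#' distributions, the configured conservation score (JSD against the
#' configured background, or 1 - normalised Shannon entropy), applies gap
#' penalisation and window smoothing, computes the per-column disordered
#' fraction from the aligned disorder matrix, and bins both scores onto
#' the 0-9 scale. Columns that are all-gap (sequence side) or all-`NA`
#' (disorder side) are assigned a raw score of 0 with a warning rather
#' than aborting the run.
#'
#' @param msa An `idr_msa`.
#' @param disorder_matrix Matrix from [align_disorder()].
#' @param config An [conservation_config()].
#' @return A data frame of class `idr_column_scores` with columns
#'   `column`, `seq_raw`, `dis_raw`, `seq_bin`, `dis_bin`, `n_nongap`.
#' @export
score_columns <- function(msa, disorder_matrix,
                          config = conservation_config()) {
  stopifnot(inherits(msa, "idr_msa"))
  stopifnot(ncol(disorder_matrix) == msa$n_columns)
  w <- sequence_weights(msa, config$sequence_weighting)
  q <- switch(config$background,
              blosum62_frequencies = blosum62_frequencies(),
              uniform20 = uniform20())
  nc <- msa$n_columns
  seq_raw <- numeric(nc)
  dis_raw <- numeric(nc)
  gap_fr <- numeric(nc)
  n_nongap <- integer(nc)
  chars_by_seq <- .msa_matrix(msa)

  for (col in seq_len(nc)) {
    colchars <- chars_by_seq[, col]
    scoreable <- colchars %in% amino_acids()
    gap_fr[col] <- mean(!scoreable)
    n_nongap[col] <- sum(colchars != "-")
    p <- column_distribution(msa, col, w, config$pseudocount)
    if (isTRUE(attr(p, "undefined"))) {
      warning(sprintf("column %d has no scoreable residue; score set to 0",
                      col), call. = FALSE)
      seq_raw[col] <- 0
    } else if (config$method == "jsd") {
      seq_raw[col] <- jsd_score(p, q, config$lambda_prior)
    } else {
      seq_raw[col] <- 1 - .entropy_bits(p) / log2(20)
    }
    cells <- disorder_matrix[, col]
    if (all(is.na(cells))) {
      warning(sprintf(
        "column %d has no disorder call (all gaps); fraction set to 0", col),
        call. = FALSE)
      dis_raw[col] <- 0
    } else {
      dis_raw[col] <- disorder_conservation(disorder_matrix, col)
    }
  }
  seq_raw <- apply_gap_penalty_and_window(seq_raw, gap_fr, config)
  out <- data.frame(column = seq_len(nc),
                    seq_raw = seq_raw, dis_raw = dis_raw,
                    seq_bin = bin_score(seq_raw),
                    dis_bin = bin_score(dis_raw),
                    n_nongap = n_nongap)
  class(out) <- c("idr_column_scores", "data.frame")
  out
}
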