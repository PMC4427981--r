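# independent brute-force oracle for Henikoff position-based weights:
# literal per-column symbol-sharing, no vectorisation shared with the
# implementation
henikoff_oracle <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  w <- rep(0, nrow(mat))
  for (j in seq_len(ncol(mat))) {
    symbols <- unique(mat[, j])
    for (i in seq_len(nrow(mat))) {
      n_carrying <- sum(mat[, j] == mat[i, j])
      w[i] <- w[i] + 1 / (length(symbols) * n_carrying)
    }
  }
  w <- w / ncol(mat)
  w / sum(w)
}

test_that("sequence weights: uniform scheme and symmetric families", {
  msa <- toy_msa(c("ACDE", "ACDE", "ACDE"))
  expect_equal(unname(sequence_weights(msa, "uniform")), rep(1 / 3, 3))
  expect_equal(unname(sequence_weights(msa, "henikoff")), rep(1 / 3, 3))
  two <- toy_msa(c("AC", "AC"))
  expect_equal(unname(sequence_weights(two, "henikoff")), c(0.5, 0.5))
})

test_that("henikoff weights match the brute-force sharing rule", {
  seqs <- c("AA", "AA", "AA", "AC")
  msa <- toy_msa(seqs)
  expect_equal(unname(sequence_weights(msa, "henikoff")),
               henikoff_oracle(seqs))
  expect_equal(unname(sequence_weights(msa, "henikoff")),
               c(5, 5, 5, 9) / 24)
  # random families, including gaps and X as shared symbols
  set.seed(99)
  for (i in 1:20) {
    seqs <- replicate(sample(2:8, 1), paste(
      sample(c("A", "C", "D", "X", "-"), 12, replace = TRUE),
      collapse = ""))
    seqs[1] <- gsub("-", "A", seqs[1])  # keep a valid query
    w <- sequence_weights(toy_msa(seqs), "henikoff")
    expect_equal(unname(w), henikoff_oracle(seqs))
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0))
  }
})

test_that("column distributions count weighted non-gap residues", {
  msa <- toy_msa(c("AA", "AA", "CA", "-A"))
  p <- column_distribution(msa, 1, pseudocount = 0)
  expect_equal(unname(p["A"]), 2 / 3)
  expect_equal(unname(p["C"]), 1 / 3)
  expect_equal(sum(p), 1)
  # delta column
  d <- column_distribution(msa, 2, pseudocount = 0)
  expect_equal(unname(d["A"]), 1)
  expect_error(column_distribution(msa, 0), "out of range")
  expect_error(column_distribution(msa, 3), "out of range")
})

test_that("all-gap and X-only columns are flagged undefined", {
  msa <- toy_msa(c("A-X", "A-X"))
  for (col in 2:3) {
    p <- column_distribution(msa, col)
    expect_true(attr(p, "undefined"))
    expect_true(all(is.na(p)))
  }
})

test_that("JSD limit cases match direct entropy arithmetic", {
  q <- uniform20()
  expect_equal(jsd_score(q, q), 0)
  # point mass vs uniform background, all three entropy terms by hand:
  # H(m) with m = (delta + u)/2, H(p) = 0, H(u) = log2(20)
  m_top <- (1 + 1 / 20) / 2
  m_rest <- (1 / 20) / 2
  expected <- -(m_top * log2(m_top) + 19 * m_rest * log2(m_rest)) -
    0.5 * log2(20)
  p <- setNames(numeric(20), amino_acids()); p["E"] <- 1
  expect_equal(jsd_score(p, q), expected, tolerance = 1e-12)
  expect_equal(jsd_score(p, q), 0.855, tolerance = 1e-3)
  expect_error(jsd_score(p * 1.01, q), "not normalized")
})

test_that("point mass maximises JSD against a fixed background", {
  set.seed(31)
  q <- blosum62_frequencies()
  best <- max(vapply(1:20, function(i) {
    d <- setNames(numeric(20), amino_acids()); d[i] <- 1
    jsd_score(d, q)
  }, numeric(1)))
  for (i in 1:100) {
    p <- rexp(20); p <- p / sum(p)
    expect_lte(jsd_score(p, q), best + 1e-12)
    expect_gte(jsd_score(p, q), 0)
  }
})

test_that("gap penalty and window smoothing follow the stated formulae", {
  cfg <- conservation_config(gap_penalty = TRUE, window_size = 0L)
  expect_equal(apply_gap_penalty_and_window(0.8, 0.5, cfg), 0.4)
  expect_equal(apply_gap_penalty_and_window(c(0.3, 0.7), c(0, 0), cfg),
               c(0.3, 0.7))
  cfg_w <- conservation_config(gap_penalty = FALSE, window_size = 1L,
                               window_weight = 0.5)
  out <- apply_gap_penalty_and_window(c(1, 0, 1), c(0, 0, 0), cfg_w)
  expect_equal(out[2], 0.5 * 0 + 0.5 * (2 / 3))
  expect_equal(out[1], 0.5 * 1 + 0.5 * (1 / 2))
  # identity when both features are off
  cfg_off <- conservation_config(gap_penalty = FALSE, window_size = 0L)
  x <- runif(10)
  expect_equal(apply_gap_penalty_and_window(x, runif(10), cfg_off), x)
})

test_that("disorder conservation is the disordered fraction over non-gap cells", {
  m <- rbind(c(1, 0, 1), c(1, 0, NA), c(0, 0, NA), c(1, 0, NA))
  expect_equal(disorder_conservation(m, 1), 0.75)
  expect_equal(disorder_conservation(m, 2), 0)
  expect_equal(disorder_conservation(m, 3), 1)  # gaps excluded
  expect_error(disorder_conservation(m, 4), "out of range")
  expect_error(disorder_conservation(cbind(c(NA, NA)), 1), "all gaps")
})

test_that("disorder conservation equals a brute-force tally on random matrices", {
  set.seed(55)
  for (i in 1:300) {
    nr <- sample(2:10, 1); nc <- sample(1:8, 1)
    m <- matrix(sample(c(0L, 1L, NA), nr * nc, replace = TRUE), nr, nc)
    for (j in seq_len(nc)) {
      cells <- m[, j]
      if (all(is.na(cells))) {
        expect_error(disorder_conservation(m, j), "all gaps")
      } else {
        ones <- 0; denom <- 0
        for (v in cells) {
          if (!is.na(v)) { denom <- denom + 1; if (v == 1) ones <- ones + 1 }
        }
        expect_equal(disorder_conservation(m, j), ones / denom)
      }
    }
  }
})

test_that("decile binning maps raw scores to 0..9 with floor semantics", {
  expect_equal(bin_score(0), 0L)
  expect_equal(bin_score(1), 9L)
  expect_equal(bin_score(0.75), 7L)
  expect_equal(bin_score(0.5), 5L)    # '5 or greater' corresponds to >= 0.5
  expect_equal(bin_score(0.0999), 0L)
  expect_equal(bin_score(c(0.1, 0.49)), c(1L, 4L))
  expect_equal(bin_score(1 + 1e-10), 9L)  # tolerance clamp
  expect_error(bin_score(1.01), "outside")
  expect_error(bin_score(-0.1), "outside")
  # monotone non-decreasing
  x <- sort(runif(100))
  expect_true(all(diff(bin_score(x)) >= 0))
})

test_that("column scores are permutation-invariant across rows", {
  cfg <- conservation_config(sequence_weighting = "uniform",
                             pseudocount = 0, gap_penalty = FALSE,
                             window_size = 0L)
  seqs <- c("ACDE", "AADE", "CCDR", "ACWE")
  msa1 <- toy_msa(seqs)
  msa2 <- toy_msa(seqs[c(3, 1, 4, 2)])
  dis1 <- matrix(0L, 4, 4); dis2 <- matrix(0L, 4, 4)
  s1 <- suppressWarnings(score_columns(msa1, dis1, cfg))
  s2 <- suppressWarnings(score_columns(msa2, dis2, cfg))
  expect_equal(s1$seq_raw, s2$seq_raw)
})

test_that("entropy and JSD methods agree on the rank of extreme columns", {
  # 20 identical rows: column 1 fully conserved, column 2 maximally
  # diverse (all 20 residues)
  seqs <- paste0("A", amino_acids())
  msa <- toy_msa(seqs)
  dis <- matrix(0L, 20, 2)
  for (method in c("jsd", "shannon_entropy")) {
    cfg <- conservation_config(method = method, gap_penalty = FALSE,
                               window_size = 0L,
                               sequence_weighting = "uniform")
    s <- score_columns(msa, dis, cfg)
    expect_gt(s$seq_raw[1], s$seq_raw[2])
  }
})

test_that("score_columns output satisfies the column-score invariants", {
  fam <- generate_family(default_family_plan(seed = 3))
  tracks <- disorder_tracks(fam$msa, "foldindex")
  scores <- score_columns(fam$msa, align_disorder(fam$msa, tracks))
  expect_equal(scores$column, seq_len(fam$msa$n_columns))
  expect_true(all(scores$seq_raw >= 0 & scores$seq_raw <= 1))
  expect_true(all(scores$dis_raw >= 0 & scores$dis_raw <= 1))
  expect_equal(scores$seq_bin, bin_score(scores$seq_raw))
  expect_equal(scores$dis_bin, bin_score(scores$dis_raw))
  expect_equal(scores$dis_bin == 0, scores$dis_raw < 0.1)
  expect_true(all(scores$n_nongap == 20L))
})

test_that("all-gap columns score zero with a warning instead of aborting", {
  msa <- new_msa(c("a", "b"), c("A-C", "A-C"))
  dis <- rbind(c(1L, NA, 0L), c(1L, NA, 0L))
  cfg <- conservation_config(window_size = 0L)
  w <- capture_warnings(s <- score_columns(msa, dis, cfg))
  expect_length(w, 2L)              # one per score axis
  expect_match(w, "column 2", all = TRUE)
  expect_equal(s$seq_raw[2], 0)
  expect_equal(s$dis_raw[2], 0)
})
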