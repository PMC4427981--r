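# independent exhaustive oracle for the four-category rule, written as a
# literal transcription of the published thresholds
category_oracle <- function(seq_bin, dis_bin) {
  if (dis_bin == 0) return("S")
  if (dis_bin >= 5 && seq_bin >= 5) return("C")
  if (dis_bin >= 5 && seq_bin < 5) return("F")
  "N"
}

test_that("classification agrees with the exhaustive 100-pair oracle", {
  for (s in 0:9) for (d in 0:9)
    expect_equal(classify_category(s, d), category_oracle(s, d),
                 info = sprintf("seq=%d dis=%d", s, d))
})

test_that("classification boundary cases sit exactly at the printed thresholds", {
  expect_equal(classify_category(5, 5), "C")
  expect_equal(classify_category(4, 9), "F")
  expect_equal(classify_category(9, 4), "N")
  expect_equal(classify_category(9, 0), "S")
  expect_equal(classify_category(0, 1), "N")
  expect_error(classify_category(10, 0), "0..9")
  expect_error(classify_category(3, -1), "0..9")
})

test_that("profiles project scores onto ungapped query coordinates", {
  msa <- toy_msa(c("A-C", "AAC"), ids = c("q", "h"))
  scores <- data.frame(column = 1:3,
                       seq_raw = c(0.95, 0, 0.95), dis_raw = c(0.95, 0, 0),
                       seq_bin = c(9L, 0L, 9L), dis_bin = c(9L, 0L, 0L),
                       n_nongap = c(2L, 1L, 2L))
  prof <- build_profile(msa, scores)
  expect_equal(nrow(prof), 2L)
  expect_equal(prof$query_pos, 1:2)
  expect_equal(prof$residue, c("A", "C"))
  expect_equal(prof$column, c(1L, 3L))
  expect_equal(prof$category, c("C", "S"))
  expect_equal(attr(prof, "query_id"), "q")
  expect_error(build_profile(msa, scores[1:2, ]), "every alignment column")
})

test_that("profile length always equals the ungapped query length", {
  for (seed in c(2, 9)) {
    plan <- default_family_plan(seed = seed)
    plan$indel_rate <- 0.05
    fam <- suppressWarnings(generate_family(plan))
    res <- run_family(fam)
    expect_equal(nrow(res$profile),
                 nchar(ungap(fam$msa, "Q1")))
    expect_equal(res$profile$query_pos, seq_len(nrow(res$profile)))
  }
})

test_that("category fractions count categories and sum to one", {
  prof <- data.frame(
    query_pos = 1:10, residue = strsplit("MKEEDSPLKE", "")[[1]],
    column = 1:10, seq_bin = 5L, dis_bin = 5L,
    category = c("C", "C", "C", "C", "F", "F", "N", "N", "N", "S"))
  class(prof) <- c("idr_profile", "data.frame")
  fr <- category_fractions(prof)
  expect_equal(fr$fraction_C, 0.4)
  expect_equal(fr$fraction_F, 0.2)
  expect_equal(fr$fraction_N, 0.3)
  expect_equal(fr$fraction_S, 0.1)
  expect_equal(fr$n_positions, 10L)
  expect_equal(fr$fraction_C + fr$fraction_F + fr$fraction_N + fr$fraction_S,
               1, tolerance = 1e-12)
  expect_error(category_fractions(prof[0, ]), "empty")

  single <- prof; single$category <- "S"
  expect_equal(category_fractions(single)$fraction_S, 1)
})

test_that("fractions on a generated family equal brute-force counts", {
  res <- run_family(generate_family(default_family_plan(seed = 4)))
  fr <- res$fractions
  n <- nrow(res$profile)
  for (k in c("C", "F", "N", "S"))
    expect_equal(fr[[paste0("fraction_", k)]],
                 sum(res$profile$category == k) / n)
  expect_equal(fr$n_positions, n)
})

make_profile_from_categories <- function(categories) {
  prof <- data.frame(
    query_pos = seq_along(categories),
    residue = rep_len(strsplit("MKEEDSPLKEM", "")[[1]], length(categories)),
    column = seq_along(categories), seq_bin = 5L, dis_bin = 5L,
    category = categories, stringsAsFactors = FALSE)
  attr(prof, "query_id") <- "q"
  class(prof) <- c("idr_profile", "data.frame")
  prof
}

test_that("constrained segments are maximal runs above the length cutoff", {
  prof <- make_profile_from_categories(strsplit("SSCCCCCFFCCNNS", "")[[1]])
  seg <- constrained_segments(prof, min_length = 3L)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 3L)
  expect_equal(seg$end, 7L)
  expect_equal(seg$sequence,
               paste(prof$residue[3:7], collapse = ""))

  expect_equal(nrow(constrained_segments(
    make_profile_from_categories(c("C", "C")), 3L)), 0L)
  expect_error(constrained_segments(prof, 0L), ">= 1")
})

test_that("min_length 1 segments partition the constrained positions", {
  set.seed(12)
  for (i in 1:25) {
    cats <- sample(c("C", "F", "N", "S"), sample(5:60, 1), replace = TRUE)
    prof <- make_profile_from_categories(cats)
    seg <- constrained_segments(prof, 1L)
    covered <- as.integer(sort(unlist(
      mapply(seq, seg$start, seg$end, SIMPLIFY = FALSE))))
    expect_equal(covered, which(cats == "C"))
    # maximality: neighbours of every segment are not C
    for (k in seq_len(nrow(seg))) {
      if (seg$start[k] > 1) expect_false(cats[seg$start[k] - 1] == "C")
      if (seg$end[k] < length(cats)) expect_false(cats[seg$end[k] + 1] == "C")
    }
    # monotonicity: raising min_length never increases count or coverage
    prev_n <- nrow(seg); prev_cov <- length(covered)
    for (ml in 2:4) {
      s2 <- constrained_segments(prof, ml)
      cov2 <- sum(s2$end - s2$start + 1)
      expect_lte(nrow(s2), prev_n)
      expect_lte(cov2, prev_cov)
      expect_true(all(s2$end - s2$start + 1 >= ml))
      prev_n <- nrow(s2); prev_cov <- cov2
    }
  }
})
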