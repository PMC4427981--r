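#' Residue sampling distributions used by the family generator
#'
#' The generator plants disorder through composition, so the bundled
#' charge-hydropathy predictor sees realistic signal rather than injected
#' scores. Three distributions are used:
#' \describe{
#'   \item{disordered}{acidic-biased draw over the disorder-promoting
#'     letters E, K, D, R, S, P, Q. The strong net negative charge and low
#'     hydropathy keep the fold index clearly negative, as in natural
#'     acidic IDRs.}
#'   \item{flexible}{a broad linker-like distribution (14 letters, adding
#'     the small/polar residues G, N, T, H, Y, A, M) that keeps the acidic
#'     bias. The breadth matters: with families of realistic size, columns
#'     restricted to a handful of letters still score as moderately
#'     conserved under divergence-from-background scoring, whereas a
#'     diverged linker column drawn from this distribution falls below the
#'     conservation threshold while its net charge keeps the fold index
#'     negative.}
#'   \item{ordered}{hydrophobic core letters I, L, V, F, A, W weighted
#'     towards the milder alanine, giving a clearly positive but not
#'     extreme fold index, as in ordinary globular segments.}
#' }
#'
#' @param kind `"disordered"`, `"flexible"` or `"ordered"`.
#' @return Named numeric probability vector over the letters of the
#'   alphabet.
#' @export
fixture_alphabet <- function(kind = c("disordered", "flexible", "ordered")) {
  kind <- match.arg(kind)
  w <- switch(kind,
    disordered = c(E = 0.45, D = 0.27, K = 0.04, R = 0.01,
                   S = 0.08, P = 0.09, Q = 0.06),
    flexible   = c(E = 0.23, D = 0.17, K = 0.03, R = 0.02, S = 0.08,
                   P = 0.08, Q = 0.07, G = 0.07, N = 0.06, T = 0.05,
                   H = 0.04, Y = 0.04, A = 0.04, M = 0.02),
    ordered    = c(A = 0.38, W = 0.15, L = 0.13, I = 0.11,
                   V = 0.11, F = 0.12))
  w / sum(w)
}

.fixture_labels <- c(constrained = "C", flexible = "F",
                     nonconserved = "N", structured = "S")

#' Describe a synthetic homolog family
#'
#' A region plan is the blueprint for [generate_family()]: an ordered list
#' of labelled regions with lengths, the family size, per-label
#' substitution rates, an indel rate, and the seed. The same plan and seed
#' always produce the same family.
#'
#' Default substitution rates: constrained regions diverge slowly (0.15)
#' within the disorder-promoting alphabet - strong but imperfect
#' conservation, as in real linear-motif elements; flexible regions
#' diverge completely (1.0) within the broad linker alphabet, so their
#' columns lose sequence conservation while staying disordered;
#' structured regions diverge slowly (0.05) within the hydrophobic
#' alphabet.
#'
#' Non-conserved disorder means disorder that is present in some homologs
#' but lost in others. The generator models this as a per-homolog gradient
#' of disorder loss: each descendant mutates its non-conserved regions at
#' the given rate, drawing replacements from a pool that mixes the
#' hydrophobic and disordered alphabets with a descendant-specific
#' hydrophobic share, stratified evenly across `nonconserved_share_range`.
#' Homologs at the low end of the range keep a negative fold index
#' (disordered), those at the high end cross to positive (ordered), so
#' each column's disordered fraction settles strictly between 0 and the
#' conserved-disorder threshold instead of collapsing to all-or-none.
#'
#' @param regions Data frame (or coercible) with columns `label` (one of
#'   `"constrained"`, `"flexible"`, `"nonconserved"`, `"structured"`) and
#'   `length` (positive integers).
#' @param n_sequences Family size (>= 2), default 20.
#' @param mutation_rates Named numeric vector of per-label substitution
#'   probabilities in `[0, 1]`.
#' @param indel_rate Per-position deletion probability in non-structured
#'   regions of each descendant (indels are modelled as deletions, which
#'   keep the family aligned by construction). Default 0.
#' @param nonconserved_share_range Length-2 numeric in `[0, 1]`: range of
#'   the per-descendant hydrophobic share of the non-conserved mutation
#'   pool.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A list of class `idr_region_plan`.
#' @export
region_plan <- function(regions,
                        n_sequences = 20L,
                        mutation_rates = c(constrained = 0.15,
                                           flexible = 1.0,
                                           nonconserved = 0.9,
                                           structured = 0.05),
                        indel_rate = 0,
                        nonconserved_share_range = c(0.55, 1),
                        seed = 1L) {
  regions <- as.data.frame(regions)
  stopifnot(all(c("label", "length") %in% names(regions)))
  regions$label <- as.character(regions$label)
  regions$length <- as.integer(regions$length)
  if (!all(regions$label %in% names(.fixture_labels)))
    stop("unknown region label(s): ",
         paste(setdiff(regions$label, names(.fixture_labels)), collapse = ", "),
         call. = FALSE)
  stopifnot(all(regions$length >= 1L), sum(regions$length) >= 1L,
            n_sequences >= 2L,
            all(mutation_rates >= 0 & mutation_rates <= 1),
            indel_rate >= 0, indel_rate <= 1,
            length(nonconserved_share_range) == 2L,
            all(nonconserved_share_range >= 0),
            all(nonconserved_share_range <= 1),
            nonconserved_share_range[1L] <= nonconserved_share_range[2L])
  missing_rates <- setdiff(unique(regions$label), names(mutation_rates))
  if (length(missing_rates))
    stop("no mutation rate for label(s): ",
         paste(missing_rates, collapse = ", "), call. = FALSE)
  structure(
    list(regions = regions, n_sequences = as.integer(n_sequences),
         mutation_rates = mutation_rates, indel_rate = indel_rate,
         nonconserved_share_range = nonconserved_share_range,
         seed = as.integer(seed)),
    class = "idr_region_plan")
}

#' The default four-region benchmark plan
#'
#' Two 60-residue structured flanks around a 20-residue constrained region
#' and a 40-residue flexible region: the canonical architecture used for
#' end-to-end recovery checks (ordered core, short conserved disordered
#' element, diverged disordered linker).
#'
#' @param seed Integer seed.
#' @param n_sequences Family size, default 20.
#' @return An [region_plan()].
#' @export
default_family_plan <- function(seed = 1L, n_sequences = 20L) {
  region_plan(
    data.frame(label = c("structured", "constrained", "flexible",
                         "structured"),
               length = c(60L, 20L, 40L, 60L)),
    n_sequences = n_sequences, seed = seed)
}

# sampling pool for a region; `share` is the hydrophobic share used for
# non-conserved regions (ancestor and each descendant have their own)
.region_pool <- function(label, share = 0) {
  switch(label,
    constrained = fixture_alphabet("disordered"),
    flexible = fixture_alphabet("flexible"),
    structured = fixture_alphabet("ordered"),
    nonconserved = {
      w <- c(share * fixture_alphabet("ordered"),
             (1 - share) * fixture_alphabet("disordered"))
      v <- tapply(w, names(w), sum)
      v / sum(v)
    })
}

#' Generate a synthetic homolog family with planted architecture
#'
#' Draws an ancestor sequence region by region from the plan's sampling
#' distributions, then derives `n_sequences - 1` descendants by
#' independent per-position substitution at the per-label rates (the
#' replacement is drawn from the region's own distribution and may equal
#' the original). The ancestor itself is the first record and the query,
#' so truth labels align 1:1 with query positions. Optional indels are
#' deletions restricted to non-structured regions of descendants.
#'
#' Regions much shorter than the fold-index smoothing window are
#' attenuated by their neighbours and may not be fully recoverable; a
#' warning is issued for plans with regions shorter than half the window.
#'
#' @param plan An [region_plan()].
#' @param foldindex_window Window used only for the shortness warning.
#' @return A list with elements `msa` (an `idr_msa`, query = record 1,
#'   id `"Q1"`), `truth` (character vector of planted category letters
#'   C/F/N/S, one per query position) and `plan`.
#' @export
generate_family <- function(plan, foldindex_window = 21L) {
  stopifnot(inherits(plan, "idr_region_plan"))
  if (any(plan$regions$length < (foldindex_window + 1L) %/% 2L))
    warning("plan contains region(s) shorter than half the fold-index ",
            "window; their planted labels may be only partially recoverable",
            call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(plan$seed)

  labels <- rep(plan$regions$label, plan$regions$length)
  L <- length(labels)

  # ancestor: non-conserved regions start from the disordered pool (the
  # ancestral state is disordered; descendants lose disorder to varying
  # degrees)
  ancestor <- character(L)
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    pool <- .region_pool(if (lab == "nonconserved") "constrained" else lab)
    ancestor[idx] <- sample(names(pool), length(idx), replace = TRUE,
                            prob = pool)
  }

  n <- plan$n_sequences
  shares <- seq(plan$nonconserved_share_range[1L],
                plan$nonconserved_share_range[2L],
                length.out = n - 1L)
  rows <- matrix(rep(ancestor, each = n), nrow = n)
  for (i in seq_len(n)[-1L]) {
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      rate <- plan$mutation_rates[[lab]]
      hit <- idx[stats::runif(length(idx)) < rate]
      if (length(hit)) {
        pool <- .region_pool(lab, share = shares[i - 1L])
        rows[i, hit] <- sample(names(pool), length(hit), replace = TRUE,
                               prob = pool)
      }
    }
    if (plan$indel_rate > 0) {
      idx <- which(labels != "structured")
      del <- idx[stats::runif(length(idx)) < plan$indel_rate]
      if (length(del)) rows[i, del] <- "-"
    }
  }

  ids <- c("Q1", sprintf("H%02d", seq_len(n)[-1L]))
  msa <- new_msa(ids, apply(rows, 1L, paste, collapse = ""), 1L)
  list(msa = msa, truth = unname(.fixture_labels[labels]), plan = plan)
}

#' Write the truth labels of a generated family as a two-column TSV
#'
#' @param family Result of [generate_family()].
#' @param path Output path; columns are `query_pos` and `label`.
#' @return `path`, invisibly.
#' @export
write_truth <- function(family, path) {
  utils::write.table(
    data.frame(query_pos = seq_along(family$truth), label = family$truth),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
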