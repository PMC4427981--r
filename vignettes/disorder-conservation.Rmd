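---
title: "Classifying residues by joint sequence and disorder conservation"
author: "idrcons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying residues by joint sequence and disorder conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Intrinsically disordered regions (IDRs) often evolve fast at the sequence
level while the *property* of being disordered is preserved. A standard
conservation analysis therefore under-reports their functional importance:
an entropic linker can be essential while sharing almost no residues across
homologs. Conversely, short binding elements inside IDRs (molecular
recognition features, linear motifs) keep both their sequence and their
disorder. Distinguishing these situations requires scoring the two kinds of
conservation *jointly*, per alignment column.

`idrcons` implements this joint analysis for a user-supplied multiple
sequence alignment with one designated query row. Every query residue is
assigned one of four categories from its paired, binned (0–9) conservation
scores:

| category | disorder bin | sequence bin | typical biology |
|---|---|---|---|
| C (constrained) | ≥ 5 | ≥ 5 | SLiM/MoRF-like binding elements |
| F (flexible) | ≥ 5 | < 5 | entropic linkers and spacers |
| N (non-conserved) | 1–4 | any | disorder not maintained across homologs |
| S (structured) | 0 | any | columns completely lacking disorder |

The thresholds are constants of the method, not tunable parameters: they
define the categories.

## Pipeline model

1. **Alignment ingest** (`read_msa`): aligned FASTA, ≥ 2 records, unique
   identifiers, residues restricted to the 20 standard letters plus `X`
   and `-`. All user-facing coordinates are 1-based; per-sequence
   column↔residue maps (`coordinate_map`) are exact bijections over
   non-gap columns.
2. **Disorder tracks** (`disorder_tracks`): one per-residue binary track
   per sequence, computed on the *ungapped* sequence (gaps are not
   residues). Either the bundled charge–hydropathy fold index, or
   externally computed per-residue scores (IUPred/VSL2/ESpritz-style
   `[0, 1]` scales) read from two-column files. External scores are
   binarised by the published rule: disordered iff score ≥ 0.5. The fold
   index is a signed scale; its published decision boundary is zero, so
   disordered iff index < 0 (an index of exactly 0 is ordered).
3. **Column scoring** (`score_columns`):
   - *Disorder conservation* of a column is the fraction of non-gap
     sequences flagged disordered there. Gaps are excluded from the
     denominator — "fraction of disordered residues" means residues.
   - *Sequence conservation* is the Jensen–Shannon divergence between the
     column's weighted residue distribution and a background
     distribution, `JSD(p, q) = H(λp + (1−λ)q) − λH(p) − (1−λ)H(q)`,
     entropies in bits. With λ = 0.5 the score is bounded by 1 without
     further normalisation. High divergence from background marks
     conserved, atypical columns.
4. **Binning and classification** (`bin_score`, `build_profile`): both
   raw scores are mapped to 0–9 by `clamp(floor(10·raw), 0, 9)`. Decile
   flooring is the simplest rule under which the "5 or greater" category
   thresholds correspond to raw ≥ 0.5 — deliberately the same constant as
   the disorder binarisation threshold. A raw score of exactly 1 maps
   to 9.
5. **Outputs** (`run_pipeline` with an output prefix): a per-residue
   profile TSV, a category-fraction table, and a FASTA of maximal runs of
   constrained residues (default minimum length 5, the smallest stratum
   commonly used when relating constrained runs to known motifs). The
   pipeline is deterministic: identical inputs and configuration yield
   byte-identical outputs.

## Parameters that matter

`conservation_config()` holds the scoring parameters. Defaults follow the
established JSD-scoring practice:

- **method** `jsd` (alternative: `shannon_entropy`, 1 − normalised column
  entropy; useful for sensitivity checks, ranks extremes identically).
- **background** `blosum62_frequencies` — the amino-acid marginals of the
  BLOSUM62 training data, embedded with the package; `uniform20` is
  available for controlled experiments.
- **lambda_prior** 0.5; together with base-2 entropies this bounds the
  JSD by 1, so the decile binning needs no extra normalising constant.
- **pseudocount** 1e-7 — breaks zero-count degeneracies without visibly
  moving any score.
- **gap_penalty** on: each column's sequence score is multiplied by
  (1 − gap fraction), so heavily gapped columns cannot look conserved on
  the few sequences they retain. `X` counts as unscoreable alongside `-`.
- **window_size** 3 and **window_weight** 0.5: the final score is half
  the column's own score, half the mean over columns ± 3 (truncated at
  the alignment ends). Smoothing stabilises single-column noise in small
  families.
- **sequence_weighting** `henikoff`: position-based weights; at every
  column each distinct symbol (gaps and `X` included as symbols) shares
  the column's weight equally among the sequences carrying it. This
  down-weights redundant subfamilies.

The bundled predictor (`foldindex_scores`) computes
`2.785·⟨H⟩ − |⟨R⟩| − 1.151` over a sliding window, where `⟨H⟩` is mean
Kyte–Doolittle hydropathy rescaled to `[0, 1]` and `⟨R⟩` is mean net
charge (K, R = +1; D, E = −1; His neutral; termini ignored; `X` excluded
with the window renormalised over known residues). Windows are truncated
at the sequence ends. The **window default is 21 residues**: this package
exists to resolve functional elements on the MoRF/SLiM scale (roughly
5–25 residues), and a window must be comparable to the element to resolve
it — a 51-residue window (a common choice for whole-protein
charge–hydropathy profiles, and available via `foldindex_window`) averages
a 20-residue constrained element into its flanks and blurs every
order/disorder boundary by ±25 residues. Users reproducing whole-protein
unfoldability profiles should set 51; users hunting short conserved
disordered elements should keep 21.

## The synthetic family generator

`generate_family()` produces homolog families with known ("planted")
per-residue labels, so the whole pipeline — predictor included — can be
validated end to end without external data. Design choices:

- **Disorder is planted through composition, not injected scores.** The
  ancestor's disordered regions are drawn from an acidic, low-hydropathy
  pool (E/D-rich with S, P, Q, K, R), its structured regions from a
  hydrophobic pool (A-rich with I, L, V, F, W). The fold index then
  *discovers* the architecture, exercising the real code path.
- **Constrained regions** substitute at rate 0.15 within the disordered
  pool: strong but imperfect conservation, as in real linear-motif
  elements. Near-zero rates are counter-productive in small families:
  with 20 sequences an invariant column scores JSD ≈ 0.85 and window
  smoothing smears that high score several columns into the neighbouring
  linker.
- **Flexible regions** substitute at rate 1.0 from a broad 14-letter
  linker-like pool (acidic bias plus G, N, T, H, Y, A, M). Both choices
  are forced by small-sample statistics: with n = 20, a column that
  retains its ancestral residue in half the sequences scores smoothed
  JSD ≈ 0.55 — above the C/F threshold — and even a fully randomised
  column restricted to 7 letters scores ≈ 0.46, because restriction to a
  small support is itself divergence from the 20-letter background. Only
  full divergence over a broad (but still disorder-compatible, net-acidic)
  pool drops the score floor to ≈ 0.38 while the net charge keeps the
  fold index negative.
- **Non-conserved regions** model what non-conservation of disorder *is*:
  homologs that have lost disorder to different degrees. Each descendant
  mutates at rate 0.9 from a pool mixing the hydrophobic and disordered
  alphabets with a descendant-specific hydrophobic share, stratified
  evenly over `[0.55, 1]`. Homologs at the low end stay disordered, those
  at the high end cross to ordered, so per-column disordered fractions
  land strictly between 0 and 0.5 instead of collapsing family-wide to
  all-or-none (which is what a single shared mutation pool produces,
  because disorder calls are correlated through the shared ancestor and
  the windowed predictor).
- **Indels** are modelled as deletions restricted to non-structured
  regions, which keeps the family aligned by construction and the truth
  labels 1:1 with query positions; they default off and are exercised by
  the gap-handling tests.
- All randomness flows from the plan's single seed; the caller's RNG
  state is saved and restored.

The default benchmark plan is structured(60) — constrained(20) —
flexible(40) — structured(60) with 20 sequences; the non-conserved regime
is validated on structured(60) — non-conserved(100) — structured(60)
(non-conserved dynamics need structured flanks and enough interior to
separate boundary effects from the partial-disorder signal). These sizes
keep a full five-seed validation under half a minute on one core. All
compositions and rates above were fixed once, at design time, from the
boundary arithmetic of the fold index and the small-sample behaviour of
the JSD; they are package defaults, not per-run tuning knobs.

**What passing these checks does and does not show.** The generator
produces the four column regimes with realistic alphabets, but real
homolog families differ in ways it does not emulate: phylogenetic
correlation between sequences (a tree, not independent descendants),
alignment errors precisely in the regions where disorder makes aligning
hard, length variation far beyond scattered deletions, and disorder that
predictors other than a charge–hydropathy index would call differently
(e.g. low-charge, Q/N-rich disorder). Recovery rates on planted families
are therefore an internal-consistency result, not a benchmark claim about
biological data.

## Numerical choices and degenerate inputs

- Raw scores are validated to `[−1e-9, 1+1e-9]` and clamped before
  binning; distributions must sum to 1 within 1e-9.
- All-gap (or all-`X`) columns cannot be scored; they are assigned raw 0
  on both axes with a warning rather than aborting a whole run, and they
  never appear in the query profile anyway (a query residue occupies its
  column).
- A column whose disorder cells are all `NA` can only arise for columns
  gapped in every sequence, handled as above.
- Fold-index windows at sequence ends are truncated means, not padded;
  an all-`X` window yields `NA`, which binarises to ordered with a
  warning.
- Ties: `binarize` uses ≥ 0.5 (external) and < 0 (fold index) exactly as
  stated; `bin_score(0.5) = 5`, so every "5 or greater" rule is inclusive
  at raw 0.5.

## Limitations

- Conservation is column-wise; no phylogeny-aware correction beyond
  Henikoff weighting is applied.
- The bundled predictor sees only charge and hydropathy; families whose
  disorder is not charge-driven should use external score files
  (`predictor = "external"`).
- Homolog search and alignment construction are out of scope by design:
  the quality of the input alignment bounds the quality of every
  downstream number, and aligning disordered regions is exactly where
  automated pipelines are weakest. Curate the alignment first.
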