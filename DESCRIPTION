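Package: idrcons
Title: Joint Conservation of Sequence and Intrinsic Disorder in Protein Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies, for every column of a protein multiple sequence
    alignment, the evolutionary conservation of both the amino-acid sequence
    (Jensen-Shannon divergence against a background distribution, with
    Henikoff position-based weighting, gap penalisation and window smoothing)
    and of predicted structural disorder (the fraction of homologs predicted
    disordered at the column, using a bundled charge-hydropathy predictor or
    externally supplied per-residue scores). Each residue of a designated
    query sequence is classified as constrained (C), flexible (F),
    non-conserved (N) or structured (S) from the paired 0-9 conservation
    scores, and per-residue profiles, category fractions and consecutive
    constrained segments are exported. Includes a deterministic generator of
    synthetic homolog families with planted regional architecture for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
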