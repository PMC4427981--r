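#' Assemble a validated pipeline run configuration
#'
#' Merges, in increasing precedence: package defaults, a flat key-value
#' YAML config file, and arguments given here. The resolved configuration
#' drives [run_pipeline()].
#'
#' @param msa_path Path to the aligned FASTA input.
#' @param query_id Query record id, or `NULL` for the first record.
#' @param predictor `"foldindex"` (bundled predictor) or `"external"`
#'   (per-residue score files).
#' @param disorder_manifest For external predictors: named list/vector
#'   mapping record ids to score-file paths, or the path of a two-column
#'   (id, path) TSV manifest file. Must cover every alignment record.
#' @param conservation An [conservation_config()]; individual fields can
#'   also be set through `config_file`.
#' @param foldindex_window Window length for the bundled predictor.
#' @param min_length Minimum constrained-segment length for FASTA export.
#' @param out Output prefix; when non-`NULL`, [run_pipeline()] writes
#'   `{out}.profile.tsv`, `{out}.fractions.tsv`, `{out}.constrained.fasta`.
#' @param config_file Optional YAML file of defaults (flat keys matching
#'   these argument names and [conservation_config()] fields).
#' @param verbose Log resolved parameters and stage progress?
#' @return A list of class `idr_run_config`.
#' @export
run_config <- function(msa_path, query_id = NULL,
                       predictor = c("foldindex", "external"),
                       disorder_manifest = NULL,
                       conservation = conservation_config(),
                       foldindex_window = 21L,
                       min_length = 5L,
                       out = NULL,
                       config_file = NULL,
                       verbose = FALSE) {
  predictor <- match.arg(predictor)
  if (!is.null(config_file)) {
    cfg <- yaml::read_yaml(config_file)
    cons_keys <- intersect(names(cfg), names(conservation_config()))
    if (length(cons_keys) && missing(conservation))
      conservation <- do.call(conservation_config, cfg[cons_keys])
    if (!is.null(cfg$predictor) && missing(predictor))
      predictor <- match.arg(cfg$predictor, c("foldindex", "external"))
    if (!is.null(cfg$foldindex_window) && missing(foldindex_window))
      foldindex_window <- cfg$foldindex_window
    if (!is.null(cfg$min_length) && missing(min_length))
      min_length <- cfg$min_length
    if (!is.null(cfg$query_id) && is.null(query_id))
      query_id <- cfg$query_id
  }
  if (predictor == "external") {
    if (is.null(disorder_manifest))
      stop("predictor 'external' requires a disorder manifest", call. = FALSE)
    if (is.character(disorder_manifest) && length(disorder_manifest) == 1L &&
        file.exists(disorder_manifest) && is.null(names(disorder_manifest))) {
      tab <- utils::read.table(disorder_manifest, header = FALSE,
                               comment.char = "#",
                               col.names = c("seq_id", "path"),
                               colClasses = "character")
      disorder_manifest <- setNames(as.list(tab$path), tab$seq_id)
    }
  }
  stopifnot(inherits(conservation, "idr_conservation_config"))
  structure(
    list(msa_path = msa_path, query_id = query_id, predictor = predictor,
         disorder_manifest = disorder_manifest,
         conservation = conservation,
         foldindex_window = as.integer(foldindex_window),
         min_length = as.integer(min_length),
         out = out, verbose = isTRUE(verbose)),
    class = "idr_run_config")
}

.log_config <- function(config) {
  cc <- config$conservation
  message(sprintf(
    paste0("resolved configuration: predictor=%s, foldindex_window=%d, ",
           "method=%s, background=%s, lambda=%g, pseudocount=%g, ",
           "gap_penalty=%s, window_size=%d, window_weight=%g, weighting=%s, ",
           "binning=floor(10*raw) clamped to 0..9, category thresholds ",
           "seq>=5 & dis>=5 -> C, dis>=5 -> F, dis in 1..4 -> N, dis=0 -> S, ",
           "min_segment_length=%d"),
    config$predictor, config$foldindex_window, cc$method, cc$background,
    cc$lambda_prior, cc$pseudocount, cc$gap_penalty, cc$window_size,
    cc$window_weight, cc$sequence_weighting, config$min_length))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full disorder-conservation pipeline
#'
#' Executes, in order: alignment reading and validation, per-sequence
#' disorder prediction (or external score ingestion), column scoring of
#' sequence- and disorder conservation, and residue classification. When
#' the configuration has an output prefix, writes the profile TSV, the
#' category-fraction table, and the constrained-segment FASTA. The
#' pipeline is deterministic: identical inputs and configuration produce
#' byte-identical outputs.
#'
#' @param config An [run_config()] (or arguments to build one, via `...`).
#' @param ... When `config` is a path, further arguments passed to
#'   [run_config()] for convenience.
#' @return A list of class `idr_result` with elements `msa`, `scores`,
#'   `profile`, `fractions`, `segments`, `config`.
#' @export
run_pipeline <- function(config, ...) {
  if (!inherits(config, "idr_run_config"))
    config <- run_config(config, ...)
  if (config$verbose) .log_config(config)

  msa <- .stage("alignment_io", {
    if (config$verbose) message("reading alignment: ", config$msa_path)
    if (is.null(config$query_id)) read_msa(config$msa_path)
    else read_msa(config$msa_path, config$query_id)
  })
  tracks <- .stage("disorder_profiles", {
    if (config$predictor == "external") {
      missing_ids <- setdiff(msa$ids, names(config$disorder_manifest))
      if (length(missing_ids))
        stop("disorder manifest does not cover record(s): ",
             paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    disorder_tracks(msa, config$predictor,
                    manifest = config$disorder_manifest,
                    foldindex_window = config$foldindex_window)
  })
  dismat <- .stage("disorder_profiles", align_disorder(msa, tracks))
  scores <- .stage("conservation",
                   score_columns(msa, dismat, config$conservation))
  profile <- .stage("classification", build_profile(msa, scores))
  fractions <- .stage("classification", category_fractions(profile))
  segments <- .stage("classification",
                     constrained_segments(profile, config$min_length))

  if (!is.null(config$out)) {
    .stage("cli_outputs", {
      write_profile(profile, paste0(config$out, ".profile.tsv"))
      write_fractions(fractions, paste0(config$out, ".fractions.tsv"))
      write_segments_fasta(segments, attr(profile, "query_id"),
                           paste0(config$out, ".constrained.fasta"))
      if (config$verbose)
        message("outputs written with prefix: ", config$out)
    })
  }
  structure(
    list(msa = msa, scores = scores, profile = profile,
         fractions = fractions, segments = segments, config = config),
    class = "idr_result")
}

#' @export
print.idr_result <- function(x, ...) {
  f <- x$fractions
  cat(sprintf(
    paste0("idr_result: query '%s', %d residues\n",
           "  fractions: C=%.3f F=%.3f N=%.3f S=%.3f\n",
           "  constrained segments (>= %d residues): %d\n"),
    attr(x$profile, "query_id"), f$n_positions,
    f$fraction_C, f$fraction_F, f$fraction_N, f$fraction_S,
    x$config$min_length, nrow(x$segments)))
  invisible(x)
}

#' Write / read the per-residue profile TSV
#'
#' Tab-separated with a header line and columns `query_pos`, `residue`,
#' `column`, `seq_bin`, `dis_bin`, `category`; one row per query residue.
#'
#' @param profile An `idr_profile`.
#' @param path Output path.
#' @return `path` invisibly ([write_profile()]); an `idr_profile`
#'   ([read_profile()]).
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  prof <- utils::read.delim(path, header = TRUE,
                            colClasses = c("integer", "character", "integer",
                                           "integer", "integer", "character"))
  class(prof) <- c("idr_profile", "data.frame")
  prof
}

#' Write / read the category-fraction table
#'
#' Two-column key/value TSV with rows `fraction_C`, `fraction_F`,
#' `fraction_N`, `fraction_S` and `n_positions`.
#'
#' @param fractions An `idr_category_fractions`.
#' @param path Output path.
#' @return `path` invisibly ([write_fractions()]); an
#'   `idr_category_fractions` ([read_fractions()]).
#' @export
write_fractions <- function(fractions, path) {
  keys <- c("fraction_C", "fraction_F", "fraction_N", "fraction_S",
            "n_positions")
  tab <- data.frame(key = keys,
                    value = vapply(keys, function(k)
                      format(fractions[[k]], digits = 15), character(1)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fractions
#' @export
read_fractions <- function(path) {
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("key", "value"),
                           colClasses = c("character", "numeric"))
  vals <- setNames(as.list(tab$value), tab$key)
  structure(
    list(fraction_C = vals$fraction_C, fraction_F = vals$fraction_F,
         fraction_N = vals$fraction_N, fraction_S = vals$fraction_S,
         n_positions = as.integer(vals$n_positions)),
    class = "idr_category_fractions")
}

#' Write constrained segments as FASTA
#'
#' One record per segment with header `>{query_id}|constrained|{start}-{end}`
#' (1-based inclusive query coordinates). An empty segment list produces an
#' empty file (zero records), not an error.
#'
#' @param segments An `idr_segments` data frame.
#' @param query_id Query identifier used in the headers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_fasta <- function(segments, query_id, path) {
  if (!nrow(segments)) {
    file.create(path)
    return(invisible(path))
  }
  headers <- sprintf("%s|constrained|%d-%d",
                     query_id, segments$start, segments$end)
  set <- Biostrings::BStringSet(setNames(segments$sequence, headers))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a constrained-segment FASTA written by [write_segments_fasta()]
#'
#' @param path FASTA path.
#' @return An `idr_segments` data frame (with `query_id` attribute when
#'   the file is non-empty).
#' @export
read_segments_fasta <- function(path) {
  if (file.size(path) == 0) {
    out <- data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
    class(out) <- c("idr_segments", "data.frame")
    return(out)
  }
  set <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(set), "|", fixed = TRUE)
  coords <- strsplit(vapply(parts, `[`, character(1), 3L), "-", fixed = TRUE)
  out <- data.frame(
    start = vapply(coords, function(x) as.integer(x[1L]), integer(1)),
    end = vapply(coords, function(x) as.integer(x[2L]), integer(1)),
    sequence = unname(as.character(set)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "query_id") <- parts[[1L]][1L]
  class(out) <- c("idr_segments", "data.frame")
  out
}
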