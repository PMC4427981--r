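# shared helpers: small alignments and end-to-end pipeline runs on
# generated families (all fixtures are built in code, nothing on disk)

toy_msa <- function(seqs, ids = paste0("S", seq_along(seqs)), query = 1L) {
  new_msa(ids, seqs, query)
}

# write a generated family to a temp FASTA and run the default pipeline
run_family <- function(family, ...) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  write_msa(family$msa, path)
  suppressWarnings(suppressMessages(
    run_pipeline(run_config(path, query_id = "Q1", ...))))
}

# per-class agreement between pipeline categories and planted truth
class_recovery <- function(result, truth, classes = c("C", "F", "N", "S")) {
  got <- result$profile$category
  vapply(classes, function(k) {
    if (!any(truth == k)) return(NA_real_)
    mean(got[truth == k] == k)
  }, numeric(1))
}

nonconserved_test_plan <- function(seed) {
  region_plan(
    data.frame(label = c("structured", "nonconserved", "structured"),
               length = c(60L, 100L, 60L)),
    seed = seed)
}
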