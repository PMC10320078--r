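#' Export classification results as tab-delimited text
#'
#' One row per sample: id, analysed range, top haplogroup, quality, top-level
#' cluster, status and the expected / found / remaining variant counts. An
#' empty batch writes a header-only file.
#'
#' @param results A `haplo_results` tibble from [classify_profiles()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_results_tsv <- function(results, file) {
  out <- tibble::tibble(
    SampleID = results$id,
    Range = results$range,
    Haplogroup = results$haplogroup,
    Quality = round(results$quality, 4),
    Cluster = results$cluster,
    Status = results$status,
    Expected = results$n_expected,
    Found = results$n_found,
    Remaining = results$n_remaining
  )
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}

#' Export a QC report as tab-delimited text
#'
#' One row per check per scope: `scope`, `id`, `check`, `value`, `status`,
#' `detail`.
#'
#' @param qc A `haplo_qc` report from [run_vcf_qc()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_qc_tsv <- function(qc, file) {
  readr::write_tsv(qc$flags, file, progress = FALSE)
  invisible(file)
}

#' Export a cluster summary as tab-delimited text
#'
#' @param summary A `haplo_cluster_summary` from [summarize_clusters()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_clusters_tsv <- function(summary, file) {
  out <- tibble::tibble(
    Cluster = summary$cluster,
    Samples = summary$n_samples,
    OK = summary$n_ok,
    Warning = summary$n_warning,
    Haplogroups = vapply(summary$haplogroups, paste, "", collapse = ";")
  )
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}
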