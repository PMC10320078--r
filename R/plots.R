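#' Plot the quality distribution of classified samples
#'
#' @param object A `haplo_results` tibble.
#' @param ... Unused.
#' @return A ggplot: top-hit quality per sample, coloured by status.
#' @method autoplot haplo_results
#' @export
autoplot.haplo_results <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quality, fill = .data$status)) +
    ggplot2::geom_histogram(binwidth = 0.01, boundary = 1) +
    ggplot2::scale_fill_manual(values = c(ok = "#2c7fb8", warning = "#e6550d")) +
    ggplot2::labs(x = "top-hit quality", y = "samples", fill = NULL,
                  title = "Haplogroup classification quality") +
    ggplot2::theme_minimal()
}

#' Plot samples per top-level cluster
#'
#' @param summary A `haplo_cluster_summary` from [summarize_clusters()].
#' @return A ggplot bar chart with ok/warning stacking.
#' @export
plot_cluster_summary <- function(summary) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(summary), "cluster", "n_ok", "n_warning"),
    c("n_ok", "n_warning"), names_to = "status", values_to = "n")
  long$status <- sub("^n_", "", long$status)
  ggplot2::ggplot(long, ggplot2::aes(
      x = stats::reorder(.data$cluster, -.data$n, sum),
      y = .data$n, fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(ok = "#2c7fb8", warning = "#e6550d")) +
    ggplot2::labs(x = "top-level cluster", y = "samples", fill = NULL,
                  title = "Samples by top-level haplogroup cluster") +
    ggplot2::theme_minimal()
}

#' Plot per-sample call rates from a QC report
#'
#' @param object A `haplo_qc` report.
#' @param ... Unused.
#' @return A ggplot of per-sample call rates with the warn/fail thresholds.
#' @method autoplot haplo_qc
#' @export
autoplot.haplo_qc <- function(object, ...) {
  ggplot2::ggplot(object$sample_rates,
                  ggplot2::aes(x = stats::reorder(.data$id, .data$call_rate),
                               y = .data$call_rate)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = c(0.9, 0.5), linetype = "dashed",
                        colour = c("#fdae6b", "#e6550d")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "call rate",
                  title = "Per-sample VCF call rate") +
    ggplot2::theme_minimal()
}
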