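#' Assign a haplogroup to its top-level cluster
#'
#' Computes the tree distance from the haplogroup to every cluster label in
#' the tree package and returns the closest one. Ties are broken by
#' preferring a cluster that is an ancestor of the haplogroup, then
#' lexicographically.
#'
#' @param tree A `phylotree` whose package defines cluster labels
#'   (`clusters.txt`).
#' @param haplogroup Haplogroup name.
#' @return The cluster name.
#' @export
assign_cluster <- function(tree, haplogroup) {
  if (length(tree$clusters) == 0) {
    stop("tree package defines no top-level clusters", call. = FALSE)
  }
  haplogroup <- lookup_haplogroup(tree, haplogroup)
  d <- vapply(tree$clusters, function(cl) tree_distance(tree, haplogroup, cl), 0)
  best <- tree$clusters[d == min(d)]
  if (length(best) > 1) {
    anc <- best[best %in% ancestors_of(tree, haplogroup)]
    best <- if (length(anc)) anc else best
    best <- sort(best)
  }
  best[1]
}

# haplogroup and its chain of ancestors up to the root
ancestors_of <- function(tree, haplogroup) {
  parent <- stats::setNames(tree$nodes$parent, tree$nodes$haplogroup)
  chain <- haplogroup
  while (!is.na(parent[[chain[length(chain)]]])) {
    chain <- c(chain, parent[[chain[length(chain)]]])
  }
  chain
}

#' Summarize classified samples by top-level cluster
#'
#' Counts every sample once under the cluster of its top hit, with ok/warning
#' tallies and the member haplogroups observed per cluster.
#'
#' @param results A `haplo_results` tibble from [classify_profiles()].
#' @param tree Optional `phylotree`; needed only when `results` lacks a
#'   `cluster` column.
#' @return A `haplo_cluster_summary` tibble: `cluster`, `n_samples`, `n_ok`,
#'   `n_warning`, `haplogroups` (list-column of member haplogroups).
#' @export
summarize_clusters <- function(results, tree = NULL) {
  if (nrow(results) == 0 ||
      (all(is.na(results$cluster)) && is.null(tree))) {
    out <- tibble::tibble(cluster = character(0), n_samples = integer(0),
                          n_ok = integer(0), n_warning = integer(0),
                          haplogroups = list())
    class(out) <- c("haplo_cluster_summary", class(out))
    return(out)
  }
  res <- tibble::as_tibble(results)
  if (all(is.na(res$cluster))) {
    res$cluster <- vapply(res$haplogroup, function(h) assign_cluster(tree, h), "")
  }
  out <- dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(res, .data$cluster),
      n_samples = dplyr::n(),
      n_ok = sum(.data$status == "ok"),
      n_warning = sum(.data$status == "warning"),
      haplogroups = list(sort(unique(.data$haplogroup)))
    ),
    dplyr::desc(.data$n_samples), .data$cluster)
  class(out) <- c("haplo_cluster_summary", class(out))
  out
}
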