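#' Classify one sample profile against every haplogroup of a tree
#'
#' Scores the sample's observed variant set against the expected profile of
#' every haplogroup in the tree. Both sides are restricted to the sample's
#' analysed range and stripped of hotspot positions before scoring; hits are
#' ranked by quality (ties broken lexicographically by haplogroup name) and
#' truncated to `top_n`.
#'
#' @param tree A `phylotree`.
#' @param profile A single profile: a list (or one-row tibble) with `id`,
#'   `range` (a `haplo_range`, or a range string) and `variants` (character
#'   vector of labels).
#' @param metric `"kulczynski"` (default), `"jaccard"` or `"hamming"`.
#' @param top_n Number of ranked hits to keep (default 20).
#' @param quality_threshold,max_remaining Passed to [quality_flag()].
#' @return A `haplo_classification` object: `id`, `range`, `metric`, a ranked
#'   `hits` tibble (haplogroup, quality, found / expected_missing / remaining
#'   list-columns, counts, status, flags) and sample-level `warnings`.
#' @export
classify_sample <- function(tree, profile, metric = "kulczynski", top_n = 20,
                            quality_threshold = 0.9, max_remaining = 5) {
  stopifnot(top_n >= 1)
  qfun <- metric_fun(metric)
  if (is.data.frame(profile)) profile <- as.list(profile[1, ])
  range <- profile$range
  if (is.list(range) && !is.data.frame(range)) range <- range[[1]]
  if (is.character(range)) range <- parse_range(range)
  if (is.null(range)) range <- full_range(nchar(tree$reference))
  if (nrow(range) == 0) stop("profile '", profile$id, "' has an empty range",
                             call. = FALSE)
  obs <- unlist(profile$variants, use.names = FALSE)
  obs <- unique(strip_back_mark(obs %||% character(0)))

  L <- nchar(tree$reference)
  warnings <- character(0)
  obs_pos <- variant_positions(obs)
  keep_obs <- !obs_pos %in% tree$hotspot_positions & range_contains(obs_pos, range)
  obs <- obs[keep_obs]
  full_cover <- range_is_full(range, L)
  if (length(obs) == 0 && full_cover) {
    warnings <- c(warnings, "no variants relative to the reference: sample is identical to the reference haplotype")
  }

  obs_w <- variant_weight(tree, obs)
  w_obs_total <- sum(obs_w)

  names <- tree$nodes$haplogroup
  qualities <- numeric(length(names))
  exps <- vector("list", length(names))
  for (i in seq_along(names)) {
    pos <- tree$profile_pos[[i]]
    keep <- !pos %in% tree$hotspot_positions & range_contains(pos, range)
    exp <- tree$profiles[[i]][keep]
    exps[[i]] <- exp
    shared <- obs %in% exp
    w_shared <- sum(obs_w[shared])
    w_exp <- sum(tree$profile_w[[i]][keep])
    qualities[i] <- quality_from_weights(metric, w_shared, w_exp, w_obs_total)
  }

  ord <- order(-qualities, names)[seq_len(min(top_n, length(names)))]
  hits <- tibble::tibble(
    rank = seq_along(ord),
    haplogroup = names[ord],
    quality = qualities[ord],
    found = lapply(exps[ord], function(e) sort_variant_labels(intersect(obs, e))),
    expected_missing = lapply(exps[ord], function(e) sort_variant_labels(setdiff(e, obs))),
    remaining = lapply(exps[ord], function(e) sort_variant_labels(setdiff(obs, e)))
  )
  hits$n_expected <- lengths(hits$found) + lengths(hits$expected_missing)
  hits$n_found <- lengths(hits$found)
  hits$n_remaining <- lengths(hits$remaining)
  flags <- purrr::pmap(
    list(hits$quality, lengths(hits$expected_missing), hits$n_remaining),
    function(q, miss, rem) {
      quality_flag(q, n_expected_missing = miss, n_remaining = rem,
                   full_coverage = full_cover,
                   quality_threshold = quality_threshold,
                   max_remaining = max_remaining)
    })
  hits$status <- vapply(flags, `[[`, "", "status")
  hits$flags <- lapply(flags, `[[`, "rules")

  structure(list(id = profile$id, range = range, metric = metric,
                 hits = hits, warnings = warnings),
            class = "haplo_classification")
}

quality_from_weights <- function(metric, w_shared, w_exp, w_obs) {
  switch(metric,
    kulczynski = {
      t1 <- if (w_exp == 0) 1 else w_shared / w_exp
      t2 <- if (w_obs == 0) 1 else w_shared / w_obs
      (t1 + t2) / 2
    },
    jaccard = {
      u <- w_exp + w_obs - w_shared
      if (u == 0) 1 else w_shared / u
    },
    hamming = {
      tot <- w_exp + w_obs
      if (tot == 0) 1 else 1 - (tot - 2 * w_shared) / tot
    })
}

#' Rule-based quality status of a hit
#'
#' A hit is flagged `"warning"` when its quality falls below
#' `quality_threshold`, when expected variants are missing although the
#' analysed range covers the whole genome, or when at least `max_remaining`
#' non-hotspot variants remain unexplained; otherwise `"ok"`. The names of
#' the triggered rules are reported.
#'
#' @param quality Hit quality in \[0, 1\].
#' @param n_expected_missing Number of expected-but-unobserved variants.
#' @param n_remaining Number of observed-but-unexpected (non-hotspot) variants.
#' @param full_coverage Does the analysed range cover the full genome?
#' @param quality_threshold Warn below this quality (default 0.9).
#' @param max_remaining Warn at this many remaining variants (default 5).
#' @return A list with `status` (`"ok"` or `"warning"`) and `rules` (the
#'   triggered rule names).
#' @export
quality_flag <- function(quality, n_expected_missing = 0, n_remaining = 0,
                         full_coverage = TRUE, quality_threshold = 0.9,
                         max_remaining = 5) {
  rules <- character(0)
  if (quality < quality_threshold) rules <- c(rules, "low_quality")
  if (n_expected_missing > 0 && full_coverage) rules <- c(rules, "expected_missing")
  if (n_remaining >= max_remaining) rules <- c(rules, "many_remaining")
  list(status = if (length(rules)) "warning" else "ok", rules = rules)
}

#' Classify a batch of sample profiles
#'
#' Data-frame-first front end: takes the profile tibble produced by
#' [read_profiles()], [parse_hsd()], [parse_vcf()] or [parse_fasta()],
#' classifies every sample and returns one row per sample with the top hit,
#' its top-level cluster (when the tree defines clusters) and the full ranked
#' hit table nested in a list-column.
#'
#' @param profiles Tibble with columns `id`, `range`, `variants` (and
#'   optionally `source`, `warnings`).
#' @param tree A `phylotree`.
#' @inheritParams classify_sample
#' @param skip_rules Skip the tree's nomenclature rule table (generic indel
#'   right-alignment was already applied at parse time).
#' @return A `haplo_results` tibble: `id`, `range`, `haplogroup`, `quality`,
#'   `cluster`, `status`, `flags`, `n_expected`, `n_found`, `n_remaining`,
#'   `hits` (nested ranked hits) and `warnings`.
#' @export
classify_profiles <- function(profiles, tree, metric = "kulczynski", top_n = 20,
                              quality_threshold = 0.9, max_remaining = 5,
                              skip_rules = FALSE) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1)
  has_clusters <- length(tree$clusters) > 0
  rows <- purrr::map(seq_len(nrow(profiles)), function(i) {
    prof <- list(id = profiles$id[i],
                 range = profiles$range[[i]],
                 variants = profiles$variants[[i]])
    res <- classify_sample(tree, prof, metric = metric, top_n = top_n,
                           quality_threshold = quality_threshold,
                           max_remaining = max_remaining)
    top <- res$hits[1, ]
    prior <- character(0)
    if ("warnings" %in% names(profiles)) prior <- unlist(profiles$warnings[[i]])
    tibble::tibble(
      id = res$id,
      range = render_range(res$range),
      haplogroup = top$haplogroup,
      quality = top$quality,
      cluster = if (has_clusters) assign_cluster(tree, top$haplogroup) else NA_character_,
      status = top$status,
      flags = top$flags,
      n_expected = top$n_expected,
      n_found = top$n_found,
      n_remaining = top$n_remaining,
      hits = list(res$hits),
      warnings = list(c(prior, res$warnings))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("haplo_results", class(out))
  attr(out, "metric") <- metric
  attr(out, "tree") <- tree$metadata$name
  out
}

#' @export
print.haplo_classification <- function(x, ...) {
  cat("<haplo_classification> sample ", x$id, " (", x$metric, " metric)\n", sep = "")
  cat("  range: ", render_range(x$range), "\n", sep = "")
  top <- x$hits[1, ]
  cat("  top hit: ", top$haplogroup, "  quality ", format(round(top$quality, 4)),
      "  [", top$status, "]\n", sep = "")
  cat("  expected ", top$n_expected, ", found ", top$n_found,
      ", remaining ", top$n_remaining, "; ", nrow(x$hits), " ranked hits\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Tidy ranked hits of a classification
#'
#' @param x A `haplo_classification` or `haplo_results` object.
#' @param ... Unused.
#' @return One row per ranked hit (per sample for `haplo_results`), with
#'   variant partitions as counts.
#' @method tidy haplo_classification
#' @export
tidy.haplo_classification <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$hits, "rank", "haplogroup", "quality", "status",
                  "n_expected", "n_found", "n_remaining"),
    id = x$id, .before = 1)
}

#' @rdname tidy.haplo_classification
#' @method tidy haplo_results
#' @export
tidy.haplo_results <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(tibble::as_tibble(x), "id", "hits"), "hits")[
      , c("id", "rank", "haplogroup", "quality", "status",
          "n_expected", "n_found", "n_remaining")]
}

#' One-row batch summary of classification results
#'
#' @param x A `haplo_results` tibble.
#' @param ... Unused.
#' @return A tibble with sample counts, warning share and mean top-hit quality.
#' @method glance haplo_results
#' @export
glance.haplo_results <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    n_ok = sum(x$status == "ok"),
    n_warning = sum(x$status == "warning"),
    pct_ok = 100 * mean(x$status == "ok"),
    mean_quality = mean(x$quality),
    metric = attr(x, "metric") %||% NA_character_
  )
}
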