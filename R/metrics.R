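#' Weighted set-similarity metrics for haplogroup matching
#'
#' All three metrics compare the observed variant set of a sample with the
#' expected variant set of a haplogroup, each variant contributing its
#' phylogenetic weight, and return a quality in \[0, 1\] (1 = perfect match).
#'
#' The Kulczynski quality is
#' \deqn{S = \tfrac12\left(\frac{W_{shared}}{W_{expected}} +
#'   \frac{W_{shared}}{W_{observed}}\right)}
#' where \eqn{W} sums the weights of the respective set. An empty expected
#' (or observed) side contributes its term as 1, so two empty sets score 1.
#' The weighted Jaccard quality is \eqn{W_{shared} / W_{union}} and the
#' Hamming-derived quality is
#' \eqn{1 - W_{symdiff} / (W_{expected} + W_{observed})}, both with the
#' convention 0/0 = 1.
#'
#' @param observed,expected Character vectors of variant labels (already
#'   range-restricted and hotspot-filtered by the caller).
#' @param weights Named numeric vector of per-variant weights; variants
#'   without an entry receive `default_weight`. All weights must be positive.
#' @param default_weight Weight used for variants absent from `weights`.
#' @return A quality score in \[0, 1\].
#' @examples
#' kulczynski_quality(c("263G", "8860G"), c("263G", "8860G"))
#' kulczynski_quality(c("263G", "152C"), c("263G", "73A"),
#'                    weights = c(`263G` = 10, `152C` = 5, `73A` = 5))
#' @export
kulczynski_quality <- function(observed, expected, weights = numeric(0),
                               default_weight = 10) {
  w <- metric_weights(observed, expected, weights, default_weight)
  t1 <- if (w$expected == 0) 1 else w$shared / w$expected
  t2 <- if (w$observed == 0) 1 else w$shared / w$observed
  (t1 + t2) / 2
}

#' @rdname kulczynski_quality
#' @export
jaccard_quality <- function(observed, expected, weights = numeric(0),
                            default_weight = 10) {
  w <- metric_weights(observed, expected, weights, default_weight)
  union <- w$expected + w$observed - w$shared
  if (union == 0) 1 else w$shared / union
}

#' @rdname kulczynski_quality
#' @export
hamming_quality <- function(observed, expected, weights = numeric(0),
                            default_weight = 10) {
  w <- metric_weights(observed, expected, weights, default_weight)
  total <- w$expected + w$observed
  if (total == 0) 1 else 1 - (total - 2 * w$shared) / total
}

metric_weights <- function(observed, expected, weights, default_weight) {
  if (any(weights <= 0) || default_weight <= 0) {
    stop("variant weights must be positive", call. = FALSE)
  }
  lookup <- function(labels) {
    if (!length(labels)) return(0)
    w <- weights[labels]
    w[is.na(w)] <- default_weight
    sum(w)
  }
  list(observed = lookup(observed),
       expected = lookup(expected),
       shared = lookup(intersect(observed, expected)))
}

metric_fun <- function(metric) {
  switch(metric,
    kulczynski = kulczynski_quality,
    jaccard = jaccard_quality,
    hamming = hamming_quality,
    stop("unknown metric '", metric, "' (available: kulczynski, jaccard, hamming)",
         call. = FALSE)
  )
}
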