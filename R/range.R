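#' Analysed-range handling on the circular mitochondrial genome
#'
#' A range is a union of inclusive 1-based intervals. An interval whose start
#' exceeds its end wraps the origin, e.g. the control region `16024-576` on
#' the 16,569 bp rCRS covers 16024..16569 and 1..576.
#'
#' @param text Range string: intervals `"a-b"` (or single positions `"a"`)
#'   joined by `";"`.
#' @return A tibble with columns `start` and `end`, class `haplo_range`.
#' @examples
#' parse_range("16024-16569;1-576")
#' @export
parse_range <- function(text) {
  parts <- stringr::str_split(stringr::str_trim(text), ";")[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) stop("empty range string", call. = FALSE)
  m <- stringr::str_match(parts, "^\\s*([0-9]+)\\s*(?:-\\s*([0-9]+)\\s*)?$")
  if (anyNA(m[, 2])) {
    stop("malformed range interval(s): ",
         paste(parts[is.na(m[, 2])], collapse = ", "), call. = FALSE)
  }
  new_range(as.integer(m[, 2]),
            ifelse(is.na(m[, 3]), as.integer(m[, 2]), as.integer(m[, 3])))
}

new_range <- function(start, end) {
  out <- tibble::tibble(start = as.integer(start), end = as.integer(end))
  if (any(out$start < 1L) || any(out$end < 1L)) {
    stop("range positions must be >= 1", call. = FALSE)
  }
  class(out) <- c("haplo_range", class(out))
  out
}

#' @rdname parse_range
#' @param range A `haplo_range` tibble.
#' @export
render_range <- function(range) {
  paste(ifelse(range$start == range$end,
               as.character(range$start),
               paste0(range$start, "-", range$end)),
        collapse = ";")
}

#' @rdname parse_range
#' @param length Reference length `L`.
#' @export
full_range <- function(length) {
  new_range(1L, as.integer(length))
}

#' Test positions for membership in a range
#'
#' @param positions Integer vector of 1-based positions.
#' @param range A `haplo_range`.
#' @return Logical vector; wrap-around intervals (`start > end`) cover
#'   `start..L` and `1..end`.
#' @export
range_contains <- function(positions, range) {
  hit <- rep(FALSE, length(positions))
  for (i in seq_len(nrow(range))) {
    s <- range$start[i]; e <- range$end[i]
    hit <- hit | if (s <= e) positions >= s & positions <= e
                 else positions >= s | positions <= e
  }
  hit
}

# does the range cover every position 1..L?
range_is_full <- function(range, length) {
  all(range_contains(seq_len(length), range))
}

#' Restrict a variant set to an analysed range
#'
#' Keeps the variants whose position (the anchor position, for insertions)
#' falls inside the range union; wrap-around intervals are honoured.
#'
#' @param labels Character vector of variant labels.
#' @param range A `haplo_range`.
#' @return The subset of `labels` inside the range.
#' @export
restrict_to_range <- function(labels, range) {
  if (length(labels) == 0) return(labels)
  labels[range_contains(variant_positions(labels), range)]
}

#' Derive the analysed range of a genotyping array from its typed sites
#'
#' Array VCFs only assay a subset of positions; expected variants at untyped
#' positions must not count against a sample. The derived range is exactly
#' the typed positions, with adjacent positions merged into intervals.
#'
#' @param sites Integer vector of typed positions (at least one).
#' @return A `haplo_range` of merged single-position intervals.
#' @examples
#' derive_chip_range(c(263, 264, 750))
#' @export
derive_chip_range <- function(sites) {
  if (length(sites) == 0) stop("no sites to derive a range from", call. = FALSE)
  p <- sort(unique(as.integer(sites)))
  brk <- c(TRUE, diff(p) > 1L)
  grp <- cumsum(brk)
  new_range(tapply(p, grp, min), tapply(p, grp, max))
}
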