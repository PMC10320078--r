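#' Read sample profiles from an hsd file
#'
#' hsd is the tab-delimited profile format: one sample per line with
#' `SampleID<TAB>Range<TAB>Haplogroup<TAB>variant<TAB>variant...`, the range
#' written as `"a-b"` intervals joined by `";"` and the haplogroup column
#' usually `"?"` for unclassified input. A header line is optional.
#'
#' @param file Path to the hsd file.
#' @return A profile tibble: `id`, `range` (list of `haplo_range`),
#'   `variants` (list of label vectors), `source`, `warnings` (malformed
#'   variant tokens are collected per sample, not fatal).
#' @export
parse_hsd <- function(file) {
  lines <- readr::read_lines(file)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) {
    warning("empty hsd file: ", file, call. = FALSE)
    return(empty_profiles("hsd"))
  }
  first <- tolower(stringr::str_split(lines[1], "\t")[[1]][1])
  if (first %in% c("sampleid", "sample_id", "id", "sample")) lines <- lines[-1]
  if (length(lines) == 0) return(empty_profiles("hsd"))

  rows <- purrr::map(lines, function(line) {
    f <- stringr::str_split(line, "\t")[[1]]
    if (length(f) < 2 || !nzchar(f[1])) {
      stop("malformed hsd line (need at least SampleID and Range): ",
           substr(line, 1, 60), call. = FALSE)
    }
    tokens <- if (length(f) >= 4) stringr::str_trim(f[-(1:3)]) else character(0)
    tokens <- tokens[nzchar(tokens)]
    parsed <- parse_variants(tokens, strict = FALSE)
    bad <- tokens[is.na(parsed$label)]
    warnings <- if (length(bad)) {
      paste0("unparseable variant token(s): ", paste(bad, collapse = ", "))
    } else character(0)
    tibble::tibble(
      id = f[1],
      range = list(parse_range(f[2])),
      haplogroup = if (length(f) >= 3) f[3] else "?",
      variants = list(parsed$label[!is.na(parsed$label)]),
      warnings = list(warnings)
    )
  })
  out <- dplyr::bind_rows(rows)
  dup <- unique(out$id[duplicated(out$id)])
  if (length(dup)) {
    stop("duplicate sample IDs in hsd file: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out$source <- "hsd"
  out[, c("id", "range", "variants", "source", "haplogroup", "warnings")]
}

empty_profiles <- function(source) {
  tibble::tibble(id = character(0), range = list(), variants = list(),
                 source = character(0), haplogroup = character(0),
                 warnings = list())
}

#' Write sample profiles as an hsd file
#'
#' Inverse of [parse_hsd()]: `parse_hsd(write_hsd(p))` reproduces the ranges
#' and variant sets of `p`.
#'
#' @param profiles Profile tibble (`id`, `range`, `variants`; an optional
#'   `haplogroup` column is written through, otherwise `"?"`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_hsd <- function(profiles, file) {
  hg <- if ("haplogroup" %in% names(profiles)) profiles$haplogroup else
    rep("?", nrow(profiles))
  lines <- c("SampleID\tRange\tHaplogroup\tPolymorphisms",
             vapply(seq_len(nrow(profiles)), function(i) {
               paste(c(profiles$id[i], render_range(profiles$range[[i]]), hg[i],
                       profiles$variants[[i]]), collapse = "\t")
             }, character(1)))
  readr::write_lines(lines, file)
  invisible(file)
}
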