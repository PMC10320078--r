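#' Load a variant annotation table
#'
#' Annotation tables are generic TSVs keyed by `POS` and `ALT` with any
#' number of additional data columns (population frequencies, functional
#' prediction scores, ...). They decorate classification output and never
#' influence it.
#'
#' @param file Path to the TSV (header must contain `POS` and `ALT` plus at
#'   least one data column).
#' @param name Table name recorded as provenance (default: file name).
#' @param version Version string recorded as provenance.
#' @return A `haplo_annotation` tibble with a `.key` column (`POS:ALT`).
#' @export
load_annotation_table <- function(file, name = basename(file), version = "0") {
  tab <- readr::read_tsv(file, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  if (!all(c("POS", "ALT") %in% names(tab))) {
    stop("annotation table ", file, " must have POS and ALT columns",
         call. = FALSE)
  }
  if (ncol(tab) < 3) {
    stop("annotation table ", file, " has no data columns", call. = FALSE)
  }
  tab$.key <- paste0(tab$POS, ":", toupper(as.character(tab$ALT)))
  dup <- unique(tab$.key[duplicated(tab$.key)])
  if (length(dup)) {
    stop("annotation table ", file, " has duplicate key(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  attr(tab, "name") <- name
  attr(tab, "version") <- version
  class(tab) <- c("haplo_annotation", class(tab))
  tab
}

# annotation key of a variant label: anchor position + alternate allele
# (deletions key on "d" and insertions on ".<i><alt>", mirroring nomenclature)
annotation_keys <- function(labels) {
  v <- parse_variants(strip_back_mark(labels))
  alt <- dplyr::case_when(
    v$kind == "deletion" ~ "D",
    v$kind == "insertion" ~ paste0(".", v$insertion_index, v$alt),
    TRUE ~ v$alt)
  paste0(v$position, ":", alt)
}

#' Look up annotations for variant labels
#'
#' @param labels Character vector of variant labels.
#' @param tables List of `haplo_annotation` tables.
#' @return A long tibble: `variant`, `table`, `field`, `value` (one row per
#'   annotated field; variants absent from a table contribute no rows).
#' @export
annotate_variants <- function(labels, tables) {
  if (length(labels) == 0 || length(tables) == 0) {
    return(tibble::tibble(variant = character(0), table = character(0),
                          field = character(0), value = character(0)))
  }
  keys <- annotation_keys(labels)
  out <- list()
  for (tab in tables) {
    hit <- match(keys, tab$.key)
    fields <- setdiff(names(tab), c("POS", "ALT", ".key"))
    for (i in which(!is.na(hit))) {
      row <- tab[hit[i], fields]
      out[[length(out) + 1L]] <- tibble::tibble(
        variant = labels[i],
        table = attr(tab, "name") %||% "annotation",
        field = fields,
        value = unname(vapply(row, function(x) as.character(x)[1], character(1))))
    }
  }
  if (!length(out)) {
    return(tibble::tibble(variant = character(0), table = character(0),
                          field = character(0), value = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Attach variant annotations to classification results
#'
#' Joins every loaded annotation table onto the variants of each sample's top
#' hit (found, expected-missing and remaining partitions). Decoration only:
#' qualities, ordering and variant sets are untouched.
#'
#' @param results A `haplo_results` tibble.
#' @param tables List of `haplo_annotation` tables (e.g. `tree$annotations`).
#' @return `results` with an `annotations` list-column (a long tibble per
#'   sample: `variant`, `partition`, `table`, `field`, `value`).
#' @export
annotate_result <- function(results, tables) {
  if (length(tables) == 0) return(results)
  results$annotations <- purrr::map(results$hits, function(hits) {
    top <- hits[1, ]
    parts <- list(found = top$found[[1]],
                  expected_missing = top$expected_missing[[1]],
                  remaining = top$remaining[[1]])
    ann <- purrr::imap(parts, function(labels, part) {
      a <- annotate_variants(labels, tables)
      if (nrow(a)) a$partition <- part
      a
    })
    out <- dplyr::bind_rows(ann)
    if (nrow(out)) out[, c("variant", "partition", "table", "field", "value")]
    else tibble::tibble(variant = character(0), partition = character(0),
                        table = character(0), field = character(0),
                        value = character(0))
  })
  results
}

#' Export per-variant annotations of classified samples
#'
#' @param results An annotated `haplo_results` tibble (see
#'   [annotate_result()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_annotations_tsv <- function(results, file) {
  if (!"annotations" %in% names(results)) {
    stop("results carry no annotations; run annotate_result() first",
         call. = FALSE)
  }
  long <- dplyr::bind_rows(purrr::map2(results$id, results$annotations,
                                       function(id, a) dplyr::mutate(a, SampleID = id)))
  if (!nrow(long)) {
    long <- tibble::tibble(SampleID = character(0), variant = character(0),
                           partition = character(0), table = character(0),
                           field = character(0), value = character(0))
  }
  readr::write_tsv(dplyr::relocate(long, "SampleID"), file, progress = FALSE)
  invisible(file)
}
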