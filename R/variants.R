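#' Parse variant labels in Phylotree nomenclature
#'
#' Variants are written relative to the reference sequence: substitutions as
#' `"263G"` (position then alternate base), insertions as `"309.1C"` (anchor
#' position, insertion index, inserted base(s)), deletions as `"249d"`.
#' A trailing `"!"` marks a back mutation, i.e. a reversion on a descendant
#' branch of a variant acquired on an ancestral branch.
#'
#' @param labels Character vector of variant labels.
#' @param strict If `TRUE` (default) malformed labels raise an error; if
#'   `FALSE` they yield `NA` rows (callers collect them as parse warnings).
#' @return A tibble with one row per label: `label` (canonical rendering),
#'   `position`, `kind` (`"substitution"`, `"insertion"` or `"deletion"`),
#'   `alt` (empty string for deletions), `insertion_index` (0 unless an
#'   insertion) and `back_mutation`.
#' @examples
#' parse_variants(c("263G", "309.1C", "249d", "16189C!"))
#' @export
parse_variants <- function(labels, strict = TRUE) {
  labels <- as.character(labels)
  x <- stringr::str_trim(labels)
  bang <- stringr::str_ends(x, stringr::fixed("!"))
  core <- ifelse(bang, stringr::str_sub(x, 1L, -2L), x)

  m_del <- stringr::str_match(core, "^([0-9]+)[dD]$")
  m_ins <- stringr::str_match(core, "^([0-9]+)\\.([0-9]+)([ACGTNacgtn]+)$")
  m_sub <- stringr::str_match(core, "^([0-9]+)([ACGTNacgtn]+)$")

  kind <- dplyr::case_when(
    !is.na(m_del[, 1]) ~ "deletion",
    !is.na(m_ins[, 1]) ~ "insertion",
    !is.na(m_sub[, 1]) ~ "substitution",
    TRUE ~ NA_character_
  )
  if (strict && anyNA(kind)) {
    bad <- unique(labels[is.na(kind)])
    stop("malformed variant label(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }

  position <- dplyr::case_when(
    kind == "deletion" ~ as.integer(m_del[, 2]),
    kind == "insertion" ~ as.integer(m_ins[, 2]),
    kind == "substitution" ~ as.integer(m_sub[, 2]),
    TRUE ~ NA_integer_
  )
  alt <- dplyr::case_when(
    kind == "deletion" ~ "",
    kind == "insertion" ~ toupper(m_ins[, 4]),
    kind == "substitution" ~ toupper(m_sub[, 3]),
    TRUE ~ NA_character_
  )
  insertion_index <- dplyr::if_else(kind == "insertion", as.integer(m_ins[, 3]), 0L)
  if (strict && any(insertion_index == 0L & kind == "insertion", na.rm = TRUE)) {
    stop("insertion with zero insertion index", call. = FALSE)
  }

  out <- tibble::tibble(
    position = position,
    kind = kind,
    alt = alt,
    insertion_index = insertion_index,
    back_mutation = bang & !is.na(kind)
  )
  out$label <- render_variants(out)
  out$label[is.na(kind)] <- NA_character_
  dplyr::relocate(out, "label")
}

#' Render parsed variants back to canonical labels
#'
#' Inverse of [parse_variants()]: `parse_variants(render_variants(v))`
#' reproduces `v`.
#'
#' @param v A tibble as returned by [parse_variants()] (the `label` column is
#'   ignored).
#' @return Character vector of canonical labels.
#' @export
render_variants <- function(v) {
  base <- dplyr::case_when(
    v$kind == "deletion" ~ paste0(v$position, "d"),
    v$kind == "insertion" ~ paste0(v$position, ".", v$insertion_index, v$alt),
    TRUE ~ paste0(v$position, v$alt)
  )
  ifelse(isTRUE_vec(v$back_mutation), paste0(base, "!"), base)
}

isTRUE_vec <- function(x) !is.na(x) & x

# event key used for back-mutation matching: same position + kind
# (+ insertion slot); the alternate allele is deliberately not part of the key.
variant_event_key <- function(v) {
  paste(v$position, v$kind, v$insertion_index, sep = "|")
}

# position of a parsed variant vector of labels (insertions anchor at their
# anchor position)
variant_positions <- function(labels) {
  parse_variants(labels)$position
}

# strip a trailing "!" so sample-side labels compare against profile labels
strip_back_mark <- function(labels) {
  sub("!$", "", labels)
}

#' Apply a variant set to a reference sequence
#'
#' Builds the haplotype sequence implied by a set of variants, used by the
#' synthetic-data generator to emit FASTA records and by tests to verify that
#' indel right-alignment leaves the implied sequence unchanged.
#'
#' @param reference Reference sequence as a single string.
#' @param labels Character vector of variant labels (back-mutation marks are
#'   ignored; a back mutation never appears in a resolved profile).
#' @return The edited sequence as a single string.
#' @export
apply_variants <- function(reference, labels) {
  ref <- strsplit(reference, "", fixed = TRUE)[[1]]
  if (length(labels) == 0) {
    return(paste(ref, collapse = ""))
  }
  v <- parse_variants(strip_back_mark(labels))
  if (any(v$position < 1 | v$position > length(ref))) {
    stop("variant position outside reference", call. = FALSE)
  }
  # per-position slots: substitution/deletion rewrite the base, insertions
  # append after the base in insertion-index order
  keep <- ref
  ins <- vector("list", length(ref))
  for (i in seq_len(nrow(v))) {
    p <- v$position[i]
    if (v$kind[i] == "substitution") {
      keep[p] <- v$alt[i]
    } else if (v$kind[i] == "deletion") {
      keep[p] <- ""
    } else {
      slot <- ins[[p]]
      slot[[as.character(v$insertion_index[i])]] <- v$alt[i]
      ins[[p]] <- slot
    }
  }
  pieces <- vapply(seq_along(ref), function(p) {
    slot <- ins[[p]]
    if (is.null(slot)) {
      keep[p]
    } else {
      ord <- order(as.integer(names(slot)))
      paste0(keep[p], paste(unlist(slot)[ord], collapse = ""))
    }
  }, character(1))
  paste(pieces, collapse = "")
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

complement_base <- function(b) {
  unname(DNA_COMPLEMENT[toupper(b)])
}
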