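#' Right-align insertions and deletions
#'
#' Pairwise aligners conventionally left-align indels, but mitochondrial
#' phylogenetic nomenclature places them at the rightmost equivalent position
#' (e.g. a C insertion in the 303–315 homopolymer is written 315.1C, not
#' 303.1C). Each indel is shifted right as long as the shifted call implies
#' exactly the same haplotype sequence; substitutions are never touched.
#'
#' @param labels Character vector of variant labels.
#' @param reference Reference sequence as a single string.
#' @return The labels with every shiftable indel moved to its rightmost
#'   equivalent position.
#' @examples
#' # reference AACCCCT: a C deletion reported at the first C moves to the last
#' right_align_indels("3d", "AACCCCT")
#' @export
right_align_indels <- function(labels, reference) {
  if (length(labels) == 0) return(labels)
  v <- parse_variants(labels)
  L <- nchar(reference)
  if (any(v$position > L | v$position < 1)) {
    stop("indel position outside the reference", call. = FALSE)
  }
  ref <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  out <- labels
  for (i in seq_len(nrow(v))) {
    if (v$kind[i] == "deletion") {
      p <- v$position[i]
      while (p < L && ref[p + 1L] == ref[p]) p <- p + 1L
      v$position[i] <- p
      out[i] <- render_variants(v[i, ])
    } else if (v$kind[i] == "insertion" && v$insertion_index[i] == 1L) {
      # inserting X after p equals inserting rotate(X) after p+1 when the
      # first inserted base matches the next reference base
      p <- v$position[i]
      alt <- strsplit(v$alt[i], "", fixed = TRUE)[[1]]
      while (p < L && alt[1L] == ref[p + 1L]) {
        alt <- c(alt[-1L], alt[1L])
        p <- p + 1L
      }
      v$position[i] <- p
      v$alt[i] <- paste(alt, collapse = "")
      out[i] <- render_variants(v[i, ])
    }
  }
  out
}

empty_rules <- function() {
  tibble::tibble(id = character(0), source = list(), target = list())
}

#' Parse a nomenclature rule file
#'
#' Each non-comment line is `source-variants<TAB>target-variants`, variants
#' space-separated; the target side may be empty (the rule then only removes
#' its sources). Rules capture aligner-specific calls that generic
#' right-alignment cannot fix and rewrite them to the spelling the
#' phylogenetic tree expects.
#'
#' @param lines Character vector of rule-file lines (`#` starts a comment).
#' @return A tibble with columns `id`, `source` and `target` (list-columns of
#'   variant labels).
#' @export
parse_rules <- function(lines) {
  keep <- which(nzchar(stringr::str_trim(lines)) & !startsWith(stringr::str_trim(lines), "#"))
  if (!length(keep)) return(empty_rules())
  parts <- stringr::str_split(lines[keep], "\t")
  parse_side <- function(txt, line_no, side) {
    txt <- stringr::str_trim(txt %||% "")
    if (!nzchar(txt)) return(character(0))
    tryCatch(parse_variants(stringr::str_split_1(txt, "\\s+"))$label,
             error = function(e) stop("rules line ", line_no, " (", side, "): ",
                                      conditionMessage(e), call. = FALSE))
  }
  src <- tgt <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    if (length(parts[[k]]) < 1 || length(parts[[k]]) > 2) {
      stop("rules line ", keep[k], ": expected source<TAB>target", call. = FALSE)
    }
    src[[k]] <- parse_side(parts[[k]][1], keep[k], "source")
    tgt[[k]] <- parse_side(if (length(parts[[k]]) > 1) parts[[k]][2] else "",
                           keep[k], "target")
    if (!length(src[[k]])) {
      stop("rules line ", keep[k], ": empty source side", call. = FALSE)
    }
  }
  tibble::tibble(id = paste0("rule", seq_along(keep)), source = src, target = tgt)
}

#' Apply nomenclature rules to a variant set
#'
#' Rules are applied in file order; a rule fires only when every one of its
#' source variants is present, in which case the sources are removed and the
#' targets added. Applying a rule set twice gives the same result as applying
#' it once (rule targets must not re-match rule sources).
#'
#' @param labels Character vector of variant labels.
#' @param rules Rule tibble from [parse_rules()].
#' @return A list with `variants` (the rewritten labels) and `log` (a
#'   character vector naming the rules that fired).
#' @export
apply_rules <- function(labels, rules) {
  log <- character(0)
  for (k in seq_len(nrow(rules))) {
    if (all(rules$source[[k]] %in% labels)) {
      labels <- c(setdiff(labels, rules$source[[k]]), rules$target[[k]])
      log <- c(log, rules$id[k])
    }
  }
  list(variants = sort_variant_labels(unique(labels)), log = log)
}

# full normalization applied to alignment- and VCF-derived calls before
# classification: generic right-alignment first, then the tree's rule table
normalize_variants <- function(labels, tree, skip_rules = FALSE) {
  labels <- right_align_indels(labels, tree$reference)
  if (skip_rules) {
    list(variants = sort_variant_labels(unique(labels)), log = character(0))
  } else {
    apply_rules(labels, tree$rules)
  }
}
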