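#' Read sample profiles from FASTA sequences
#'
#' Each record is aligned to the tree's reference with a pluggable pairwise
#' aligner (built-in: Biostrings global-local alignment with affine gap
#' penalties, so partial sequences such as control-region fragments align to
#' the matching reference span). Mismatches, insertions and deletions in the
#' alignment become variants; indels are right-aligned and passed through the
#' tree's nomenclature rules. The analysed range is the reference span
#' covered by the alignment minus positions aligned to `N`.
#'
#' Records whose alignment identity falls below `min_identity` are kept but
#' flagged (`flagged = TRUE`) and should not be classified.
#'
#' @param file Path to a FASTA file.
#' @param tree A `phylotree`.
#' @param aligner `NULL` for the built-in aligner, or a
#'   `function(sample_seq, reference)` returning a list with `ref_start`
#'   (1-based reference offset of the alignment), `aligned_sample`,
#'   `aligned_ref` (equal-length gapped strings) and `identity` (fraction).
#' @param min_identity Identity below which a record is flagged (default 0.7).
#' @param skip_rules Skip the tree's nomenclature rule table.
#' @return A profile tibble (as [parse_hsd()]) with a logical `flagged`
#'   column.
#' @export
parse_fasta <- function(file, tree, aligner = NULL, min_identity = 0.7,
                        skip_rules = FALSE) {
  if (is.null(aligner)) aligner <- biostrings_aligner
  seqs <- Biostrings::readDNAStringSet(file)
  rows <- list()
  for (i in seq_along(seqs)) {
    id <- stringr::str_split_1(names(seqs)[i], "\\s+")[1]
    s <- toupper(as.character(seqs[[i]]))
    if (!nzchar(s)) {
      warning("FASTA record '", id, "' is empty; skipped", call. = FALSE)
      next
    }
    aln <- aligner(s, tree$reference)
    if (aln$identity < min_identity) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = id, range = list(full_range(nchar(tree$reference))),
        variants = list(character(0)), source = "fasta", haplogroup = "?",
        flagged = TRUE,
        warnings = list(sprintf(
          "alignment identity %.2f below %.2f: not classified",
          aln$identity, min_identity)))
      next
    }
    call <- call_alignment_variants(aln)
    norm <- normalize_variants(call$labels, tree, skip_rules = skip_rules)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = id, range = list(derive_chip_range(call$covered)),
      variants = list(norm$variants), source = "fasta", haplogroup = "?",
      flagged = FALSE, warnings = list(call$warnings))
  }
  if (!length(rows)) return(dplyr::mutate(empty_profiles("fasta"), flagged = logical(0)))
  out <- dplyr::bind_rows(rows)
  out[, c("id", "range", "variants", "source", "haplogroup", "flagged", "warnings")]
}

# built-in pairwise aligner (pattern-global / subject-local, affine gaps);
# the IUPAC-aware scores let N align to any base instead of forcing gaps
biostrings_aligner <- function(sample_seq, reference) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sample_seq), Biostrings::DNAString(reference),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 1)
  list(ref_start = Biostrings::start(Biostrings::subject(aln)),
       aligned_sample = as.character(Biostrings::alignedPattern(aln)),
       aligned_ref = as.character(Biostrings::alignedSubject(aln)),
       identity = Biostrings::pid(aln) / 100)
}

# walk the aligned strings column by column, emitting variant labels and the
# covered reference positions (positions aligned to N are not covered)
call_alignment_variants <- function(aln) {
  rc <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1]]
  sc <- strsplit(aln$aligned_sample, "", fixed = TRUE)[[1]]
  stopifnot(length(rc) == length(sc))
  refpos <- aln$ref_start - 1L
  labels <- character(0)
  covered <- integer(0)
  n_pos <- integer(0)
  warnings <- character(0)
  i <- 1L
  while (i <= length(rc)) {
    if (rc[i] == "-") {
      j <- i
      while (j < length(rc) && rc[j + 1L] == "-") j <- j + 1L
      ins <- sc[i:j]
      if (refpos == 0L) {
        warnings <- c(warnings, "insertion before reference start dropped")
      } else if (any(ins == "N")) {
        warnings <- c(warnings, sprintf("insertion with N at %d dropped", refpos))
      } else {
        labels <- c(labels, paste0(refpos, ".", seq_along(ins), ins))
      }
      i <- j + 1L
    } else {
      refpos <- refpos + 1L
      if (sc[i] == "-") {
        labels <- c(labels, paste0(refpos, "d"))
        covered <- c(covered, refpos)
      } else if (sc[i] == "N") {
        n_pos <- c(n_pos, refpos)
      } else {
        covered <- c(covered, refpos)
        if (sc[i] != rc[i]) labels <- c(labels, paste0(refpos, sc[i]))
      }
      i <- i + 1L
    }
  }
  list(labels = labels, covered = covered, n_positions = n_pos,
       warnings = warnings)
}

#' Read sample profiles with format autodetection
#'
#' Dispatches to [parse_hsd()], [parse_vcf()] or [parse_fasta()]. The format
#' is taken from the file extension, falling back to content sniffing
#' (`##fileformat` means VCF, a leading `>` means FASTA, anything else hsd).
#'
#' @param file Input path.
#' @param tree A `phylotree` (required for VCF and FASTA input).
#' @param format `"auto"` (default), `"hsd"`, `"vcf"` or `"fasta"`.
#' @param ... Passed to the format-specific parser.
#' @return A profile tibble.
#' @export
read_profiles <- function(file, tree = NULL, format = "auto", ...) {
  if (format == "auto") format <- detect_format(file)
  switch(format,
    hsd = parse_hsd(file),
    vcf = parse_vcf(file, tree, ...),
    fasta = parse_fasta(file, tree, ...),
    stop("unknown input format '", format, "'", call. = FALSE))
}

detect_format <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "hsd") return("hsd")
  if (ext %in% c("vcf")) return("vcf")
  if (ext %in% c("fasta", "fa", "fsa", "fna")) return("fasta")
  head <- readr::read_lines(file, n_max = 5)
  head <- head[nzchar(head)]
  if (length(head) && startsWith(head[1], "##fileformat")) return("vcf")
  if (length(head) && startsWith(head[1], ">")) return("fasta")
  "hsd"
}
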