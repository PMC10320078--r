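#' Read sample profiles from a multi-sample VCF
#'
#' Converts called ALT alleles into variant labels per sample. Multi-allelic
#' records are split, MNPs are decomposed into per-base substitutions, and
#' indels are normalized (right-aligned, then rewritten through the tree's
#' nomenclature rules) before classification. Heteroplasmic calls carry their
#' allele fraction in a per-genotype `AF`, `HF` or `VAF` field (first one
#' found); calls below `het_threshold` are excluded.
#'
#' For genotyping-array input (`mode = "array"`) the analysed range is derived
#' from the typed sites via [derive_chip_range()], so expected variants at
#' untyped positions do not penalize the sample; sequencing input gets the
#' full reference range.
#'
#' @param file Path to a VCF (one mitochondrial contig).
#' @param tree A `phylotree` (supplies the reference and the rule table).
#' @param mode `"sequencing"` (default) or `"array"`.
#' @param het_threshold Heteroplasmy fraction below which a call is excluded
#'   (default 0.9).
#' @param het_handling `"drop"` (default) excludes sub-threshold calls;
#'   `"keep-above-threshold"` does the same but records the fraction of every
#'   retained heteroplasmic call in the `heteroplasmy` list-column.
#' @param skip_rules Skip the tree's nomenclature rule table.
#' @return A profile tibble (as [parse_hsd()]) with an extra `heteroplasmy`
#'   list-column; site table and genotype matrix for QC are attached as
#'   attributes `"sites"` and `"genotypes"`.
#' @export
parse_vcf <- function(file, tree, mode = c("sequencing", "array"),
                      het_threshold = 0.9,
                      het_handling = c("drop", "keep-above-threshold"),
                      skip_rules = FALSE) {
  mode <- match.arg(mode)
  het_handling <- match.arg(het_handling)
  stopifnot(het_threshold >= 0, het_threshold <= 1)
  L <- nchar(tree$reference)

  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  # a single-record VCF collapses to a bare vector
  if (!is.matrix(fix)) fix <- t(as.matrix(fix))
  if (nrow(fix) == 0) stop("VCF contains no records: ", file, call. = FALSE)
  contigs <- unique(fix[, "CHROM"])
  if (length(contigs) > 1) {
    stop("VCF must contain a single mitochondrial contig, found: ",
         paste(contigs, collapse = ", "), call. = FALSE)
  }
  pos <- as.integer(fix[, "POS"])
  if (any(pos < 1 | pos > L)) {
    stop("contig '", contigs, "' has positions outside the reference (length ",
         L, ")", call. = FALSE)
  }
  samples <- colnames(v@gt)[-1]
  if (length(samples) == 0) stop("VCF contains no samples: ", file, call. = FALSE)

  as_site_matrix <- function(m) {
    if (!is.null(m) && !is.matrix(m)) {
      m <- matrix(m, nrow = nrow(fix), dimnames = list(NULL, samples))
    }
    m
  }
  gt <- as_site_matrix(vcfR::extract.gt(v, element = "GT"))
  het <- NULL
  for (field in c("AF", "HF", "VAF")) {
    m <- suppressWarnings(
      tryCatch(vcfR::extract.gt(v, element = field, as.numeric = TRUE),
               error = function(e) NULL))
    if (!is.null(m) && any(!is.na(m))) { het <- as_site_matrix(m); break }
  }

  warnings_file <- character(0)
  # per record and alternate allele: the variant labels it implies
  alt_split <- stringr::str_split(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",")
  allele_labels <- vector("list", nrow(fix))
  for (r in seq_len(nrow(fix))) {
    allele_labels[[r]] <- lapply(alt_split[[r]], function(a) {
      res <- vcf_allele_to_labels(pos[r], fix[r, "REF"], a)
      if (is.null(res$labels) && nzchar(res$note)) {
        warnings_file <<- c(warnings_file,
                            paste0("site ", pos[r], ": ", res$note))
      }
      res$labels
    })
  }

  rows <- purrr::map(samples, function(s) {
    labels <- character(0)
    hets <- numeric(0)
    for (r in seq_len(nrow(fix))) {
      g <- gt[r, s]
      if (is.na(g)) next
      alleles <- suppressWarnings(as.integer(stringr::str_split_1(g, "[/|]")))
      for (k in seq_along(allele_labels[[r]])) {
        if (!k %in% alleles) next
        lab <- allele_labels[[r]][[k]]
        if (is.null(lab)) next
        frac <- if (!is.null(het)) het[r, s] else NA_real_
        if (!is.na(frac) && frac < het_threshold) next
        labels <- c(labels, lab)
        if (het_handling == "keep-above-threshold" && !is.na(frac)) {
          hets <- c(hets, stats::setNames(rep(frac, length(lab)), lab))
        }
      }
    }
    norm <- normalize_variants(labels, tree, skip_rules = skip_rules)
    tibble::tibble(id = s, variants = list(norm$variants),
                   heteroplasmy = list(hets),
                   warnings = list(character(0)))
  })
  out <- dplyr::bind_rows(rows)
  range <- if (mode == "array") derive_chip_range(pos) else full_range(L)
  out$range <- rep(list(range), nrow(out))
  out$source <- "vcf"
  out$haplogroup <- "?"
  out <- out[, c("id", "range", "variants", "source", "haplogroup",
                 "heteroplasmy", "warnings")]
  attr(out, "sites") <- tibble::tibble(
    chrom = fix[, "CHROM"], pos = pos,
    ref = toupper(fix[, "REF"]), alt = toupper(fix[, "ALT"]))
  attr(out, "genotypes") <- gt
  attr(out, "file_warnings") <- unique(warnings_file)
  out
}

# translate one REF/ALT pair into variant labels; returns list(labels, note)
vcf_allele_to_labels <- function(pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (alt %in% c("", ".", "*", "<NON_REF>") || alt == ref) {
    return(list(labels = NULL, note = ""))
  }
  # minimal representation: trim shared suffix, then shared prefix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) {
    rb <- strsplit(ref, "")[[1]]; ab <- strsplit(alt, "")[[1]]
    d <- which(rb != ab)
    return(list(labels = paste0(pos + d - 1L, ab[d]), note = ""))
  }
  if (nr > na && substr(ref, 1, 1) == substr(alt, 1, 1) && na == 1) {
    return(list(labels = paste0(pos + seq_len(nr - 1L), "d"), note = ""))
  }
  if (na > nr && substr(ref, 1, 1) == substr(alt, 1, 1) && nr == 1) {
    ins <- strsplit(substr(alt, 2, na), "")[[1]]
    return(list(labels = paste0(pos, ".", seq_along(ins), ins), note = ""))
  }
  list(labels = NULL,
       note = paste0("complex allele ", ref, ">", alt, " skipped"))
}
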