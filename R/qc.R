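#' Pre-classification quality control for a VCF batch
#'
#' Heterogeneous VCF sources (arrays, whole-genome sequencing, long reads)
#' carry characteristic defects that silently lower haplogroup quality or
#' misclassify samples. Before classification this step computes, on the
#' batch returned by [parse_vcf()]:
#' file-level counts (samples, sites), the overlap of VCF sites with the
#' tree's haplogroup-defining positions, monomorphic sites (every called
#' genotype identical), sites whose REF disagrees with the tree reference,
#' strand-flip suspects among those (REF/ALT equal to the complement of the
#' reference base / a tree-known alternate at that position), and per-sample
#' and per-variant call rates.
#'
#' @param batch Profile tibble from [parse_vcf()] (carries the site table and
#'   genotype matrix as attributes).
#' @param tree A `phylotree`.
#' @param sample_call_warn,sample_call_fail Per-sample call-rate thresholds
#'   (warn below 0.9, fail below 0.5 by default).
#' @param overlap_warn Warn when fewer than this fraction of sites occur on
#'   tree branches (default 0.5; array data legitimately sits near it).
#' @return A `haplo_qc` object: `summary` (one-row tibble), `sample_rates`,
#'   `variant_rates` and `flags` (scope, id, check, value, status, detail).
#' @export
run_vcf_qc <- function(batch, tree, sample_call_warn = 0.9,
                       sample_call_fail = 0.5, overlap_warn = 0.5) {
  sites <- attr(batch, "sites")
  gt <- attr(batch, "genotypes")
  if (is.null(sites) || is.null(gt)) {
    stop("batch lacks site/genotype attributes; was it produced by parse_vcf()?",
         call. = FALSE)
  }
  flags <- list()
  add_flag <- function(scope, id, check, value, status, detail = "") {
    if (status != "pass" && !nzchar(detail)) detail <- check
    flags[[length(flags) + 1L]] <<- tibble::tibble(
      scope = scope, id = id, check = check,
      value = round(as.numeric(value), 6), status = status, detail = detail)
  }

  n_sites <- nrow(sites)
  n_samples <- ncol(gt)
  if (n_sites == 0) {
    add_flag("file", ".", "site_count", 0, "fail", "VCF contains no usable sites")
    return(new_haplo_qc(summary = tibble::tibble(
      n_samples = n_samples, n_sites = 0, tree_overlap = NA_real_,
      n_monomorphic = 0L, n_ref_mismatch = 0L, n_strand_flip_suspect = 0L),
      sample_rates = tibble::tibble(id = colnames(gt), call_rate = NA_real_),
      variant_rates = tibble::tibble(pos = integer(0), call_rate = numeric(0)),
      flags = dplyr::bind_rows(flags), blocked = TRUE))
  }

  add_flag("file", ".", "sample_count", n_samples, "pass")
  add_flag("file", ".", "site_count", n_sites, "pass")

  # overlap with the phylogeny: sites at haplogroup-defining positions
  edge_vars <- parse_variants(unlist(tree$nodes$variants, use.names = FALSE))
  tree_pos <- unique(edge_vars$position)
  overlap <- mean(sites$pos %in% tree_pos)
  add_flag("file", ".", "tree_overlap", overlap,
           ifelse(overlap < overlap_warn, "warn", "pass"),
           ifelse(overlap < overlap_warn,
                  sprintf("only %.0f%% of sites occur on tree branches", 100 * overlap), ""))

  called <- !is.na(gt)
  mono <- vapply(seq_len(n_sites), function(r) {
    g <- gt[r, called[r, , drop = TRUE]]
    length(g) > 0 && length(unique(g)) == 1L
  }, logical(1))
  add_flag("file", ".", "monomorphic_sites", sum(mono),
           ifelse(any(mono), "warn", "pass"),
           ifelse(any(mono), sprintf("%d site(s) carry no genotype variation", sum(mono)), ""))

  # reference concordance and strand-flip screen
  ref_at <- function(p, n) substr(tree$reference, p, p + n - 1L)
  vcf_ref1 <- substr(sites$ref, 1, 1)
  true_ref <- vapply(seq_len(n_sites),
                     function(r) ref_at(sites$pos[r], nchar(sites$ref[r])),
                     character(1))
  mismatch <- sites$ref != true_ref
  sub_alts <- edge_vars[edge_vars$kind == "substitution", ]
  flip <- rep(FALSE, n_sites)
  for (r in which(mismatch)) {
    if (nchar(sites$ref[r]) != 1) next
    true1 <- substr(true_ref[r], 1, 1)
    if (is.na(complement_base(vcf_ref1[r])) ||
        complement_base(vcf_ref1[r]) != true1) next
    alts <- stringr::str_split_1(sites$alt[r], ",")
    alts <- alts[nchar(alts) == 1]
    known <- sub_alts$alt[sub_alts$position == sites$pos[r]]
    flip[r] <- length(alts) > 0 &&
      (length(known) == 0 || any(vapply(alts, complement_base, "") %in% known))
  }
  add_flag("file", ".", "reference_mismatch", sum(mismatch),
           ifelse(any(mismatch), "fail", "pass"),
           ifelse(any(mismatch),
                  paste0("REF disagrees with the tree reference at position(s) ",
                         paste(utils::head(sites$pos[mismatch], 5), collapse = ", ")), ""))
  add_flag("file", ".", "strand_flip_suspect", sum(flip),
           ifelse(any(flip), "fail", "pass"),
           ifelse(any(flip),
                  paste0("possible strand flips at position(s) ",
                         paste(utils::head(sites$pos[flip], 5), collapse = ", ")), ""))

  sample_rates <- tibble::tibble(id = colnames(gt),
                                 call_rate = unname(colMeans(called)))
  for (i in seq_len(nrow(sample_rates))) {
    cr <- sample_rates$call_rate[i]
    status <- if (cr < sample_call_fail) "fail" else
              if (cr < sample_call_warn) "warn" else "pass"
    add_flag("sample", sample_rates$id[i], "call_rate", cr, status,
             if (status == "pass") "" else
               sprintf("sample call rate %.3f below %.2f", cr,
                       if (status == "fail") sample_call_fail else sample_call_warn))
  }
  variant_rates <- tibble::tibble(pos = sites$pos,
                                  call_rate = unname(rowMeans(called)))
  for (r in seq_len(n_sites)) {
    cr <- variant_rates$call_rate[r]
    if (cr < sample_call_warn) {
      add_flag("variant", as.character(sites$pos[r]), "call_rate", cr,
               ifelse(cr < sample_call_fail, "fail", "warn"),
               sprintf("variant call rate %.3f", cr))
    }
  }

  new_haplo_qc(
    summary = tibble::tibble(
      n_samples = n_samples, n_sites = n_sites, tree_overlap = overlap,
      n_monomorphic = sum(mono), n_ref_mismatch = sum(mismatch),
      n_strand_flip_suspect = sum(flip)),
    sample_rates = sample_rates, variant_rates = variant_rates,
    flags = dplyr::bind_rows(flags),
    blocked = FALSE)
}

new_haplo_qc <- function(summary, sample_rates, variant_rates, flags, blocked) {
  structure(list(summary = summary, sample_rates = sample_rates,
                 variant_rates = variant_rates, flags = flags,
                 blocked = blocked),
            class = "haplo_qc")
}

#' @export
print.haplo_qc <- function(x, ...) {
  s <- x$summary
  cat("<haplo_qc> ", s$n_samples, " sample(s), ", s$n_sites, " site(s)\n", sep = "")
  cat("  tree overlap ", sprintf("%.2f", s$tree_overlap),
      "; monomorphic ", s$n_monomorphic,
      "; ref mismatches ", s$n_ref_mismatch,
      "; strand-flip suspects ", s$n_strand_flip_suspect, "\n", sep = "")
  tab <- table(x$flags$status)
  cat("  flags:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @rdname tidy.haplo_classification
#' @method tidy haplo_qc
#' @export
tidy.haplo_qc <- function(x, ...) x$flags

#' @rdname glance.haplo_results
#' @method glance haplo_qc
#' @export
glance.haplo_qc <- function(x, ...) {
  dplyr::mutate(x$summary,
                n_fail = sum(x$flags$status == "fail"),
                n_warn = sum(x$flags$status == "warn"))
}

#' Did any QC check fail?
#'
#' @param qc A `haplo_qc` report.
#' @return `TRUE` when the report contains a fail-level flag (or the batch had
#'   no usable sites).
#' @export
qc_failed <- function(qc) {
  isTRUE(qc$blocked) || any(qc$flags$status == "fail")
}
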