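test_that("a clean batch passes every check with unit call rates", {
  tree <- tiny_tree()
  b <- function(p) substr(tree$reference, p, p)
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2", "##contig=<ID=chrM,length=500>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("chrM", 263, ".", b(263), "G", ".", "PASS", ".", "GT", "1", "0"),
          collapse = "\t"),
    paste(c("chrM", 152, ".", b(152), "C", ".", "PASS", ".", "GT", "0", "1"),
          collapse = "\t"),
    paste(c("chrM", 300, ".", b(300), "A", ".", "PASS", ".", "GT", "1", "0"),
          collapse = "\t")), f)
  qc <- run_vcf_qc(parse_vcf(f, tree), tree)
  expect_false(qc_failed(qc))
  expect_true(all(qc$sample_rates$call_rate == 1))
  expect_true(all(qc$variant_rates$call_rate == 1))
  expect_equal(qc$summary$n_samples, 2)
  expect_equal(qc$summary$n_sites, 3)
  expect_equal(qc$summary$tree_overlap, 2 / 3)
  expect_equal(qc$summary$n_monomorphic, 0)
  expect_equal(qc$summary$n_ref_mismatch, 0)
})

test_that("a complement-swapped site is counted as a strand-flip suspect", {
  # the tree knows 263G on an A reference; a flipped array would report T>C
  tree <- tiny_tree()
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2", "##contig=<ID=chrM,length=500>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    paste(c("chrM", 263, ".", "T", "C", ".", "PASS", ".", "GT", "1"),
          collapse = "\t")), f)
  qc <- run_vcf_qc(parse_vcf(f, tree), tree)
  expect_equal(qc$summary$n_ref_mismatch, 1)
  expect_equal(qc$summary$n_strand_flip_suspect, 1)
  expect_true(qc_failed(qc))
  expect_match(qc$flags$detail[qc$flags$check == "strand_flip_suspect"], "263")
})

test_that("masked genotypes lower call rates by exactly the masked counts", {
  spec <- simulation_spec(n_haplogroups = 30, n_samples = 15,
                          missing_rate = 0.1, seed = 91)
  tree <- load_tree_package(make_tree_package(spec))
  batch <- make_samples(tree, spec)
  p <- parse_vcf(batch$vcf, tree)
  qc <- run_vcf_qc(p, tree)
  n_sites <- nrow(batch$mask)
  expect_equal(qc$summary$n_sites, n_sites)
  expect_equal(qc$sample_rates$call_rate,
               unname(1 - colSums(batch$mask) / n_sites))
  expect_equal(qc$variant_rates$call_rate,
               unname(1 - rowSums(batch$mask) / ncol(batch$mask)))
  expect_equal(mean(qc$sample_rates$call_rate), 0.9, tolerance = 0.1)
})

test_that("monomorphic and polymorphic sites partition the site count", {
  spec <- simulation_spec(n_haplogroups = 25, n_samples = 12, seed = 97)
  tree <- load_tree_package(make_tree_package(spec))
  batch <- make_samples(tree, spec)
  p <- parse_vcf(batch$vcf, tree)
  qc <- run_vcf_qc(p, tree)
  gt <- attr(p, "genotypes")
  poly <- sum(vapply(seq_len(nrow(gt)), function(r) {
    g <- gt[r, !is.na(gt[r, ])]
    length(unique(g)) > 1
  }, logical(1)))
  expect_equal(qc$summary$n_monomorphic + poly, qc$summary$n_sites)
})

test_that("the report is deterministic and per-sample rows just permute", {
  spec <- simulation_spec(n_haplogroups = 20, n_samples = 8, seed = 103)
  tree <- load_tree_package(make_tree_package(spec))
  batch <- make_samples(tree, spec)
  qc1 <- run_vcf_qc(parse_vcf(batch$vcf, tree), tree)
  qc2 <- run_vcf_qc(parse_vcf(batch$vcf, tree), tree)
  expect_identical(qc1$flags, qc2$flags)

  # permute sample columns in the VCF
  lines <- readLines(batch$vcf)
  h <- which(startsWith(lines, "#CHROM"))
  reorder_fields <- function(line, ord) {
    f <- strsplit(line, "\t")[[1]]
    paste(c(f[1:9], f[-(1:9)][ord]), collapse = "\t")
  }
  set.seed(5)
  ord <- sample(spec$n_samples)
  lines[h:length(lines)] <- vapply(lines[h:length(lines)], reorder_fields,
                                   character(1), ord = ord)
  f2 <- tempfile(fileext = ".vcf")
  writeLines(lines, f2)
  qc3 <- run_vcf_qc(parse_vcf(f2, tree), tree)
  expect_identical(qc3$summary, qc1$summary)
  expect_identical(dplyr::arrange(qc3$sample_rates, id),
                   dplyr::arrange(qc1$sample_rates, id))
})
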