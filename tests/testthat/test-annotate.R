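write_annotation <- function(df, file = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, file, progress = FALSE)
  file
}

test_that("annotation tables load, index and reject bad input", {
  tab <- load_annotation_table(write_annotation(tibble::tibble(
    POS = c(263, 152, 100), ALT = c("G", "C", "T"),
    freq = c(0.5, 0.01, 0.001), pred = c("benign", "benign", "damaging"))))
  expect_equal(nrow(tab), 3)
  hit <- annotate_variants("263G", list(tab))
  expect_equal(nrow(hit), 2)
  expect_setequal(hit$field, c("freq", "pred"))
  expect_identical(hit$value[hit$field == "freq"], "0.5")
  # absent key: empty annotation, not an error
  expect_equal(nrow(annotate_variants("9999A", list(tab))), 0)

  expect_error(load_annotation_table(write_annotation(
    tibble::tibble(POS = c(1, 1), ALT = c("G", "G"), x = 1:2))), "duplicate")
  expect_error(load_annotation_table(write_annotation(
    tibble::tibble(position = 1, ALT = "G", x = 1))), "POS")
  expect_error(load_annotation_table(write_annotation(
    tibble::tibble(POS = 1, ALT = "G"))), "data columns")
})

test_that("bulk lookups equal a linear scan", {
  set.seed(131)
  n <- 5000
  tab_df <- tibble::tibble(POS = sample.int(16569, n, replace = TRUE),
                           ALT = sample(c("A", "C", "G", "T"), n, TRUE),
                           score = round(stats::runif(n), 3))
  tab_df <- tab_df[!duplicated(paste(tab_df$POS, tab_df$ALT)), ]
  tab <- load_annotation_table(write_annotation(tab_df))
  labs <- paste0(sample.int(16569, 300), sample(c("A", "C", "G", "T"), 300, TRUE))
  got <- annotate_variants(labs, list(tab))
  for (l in unique(labs)) {
    p <- as.integer(sub("[ACGT]$", "", l)); a <- sub("^[0-9]+", "", l)
    scan <- tab_df$score[tab_df$POS == p & tab_df$ALT == a]
    mine <- got$value[got$variant == l]
    if (length(scan)) expect_identical(unique(mine), as.character(scan))
    else expect_length(mine, 0)
  }
})

test_that("annotation decorates results without altering them", {
  spec <- simulation_spec(n_haplogroups = 25, n_samples = 5, seed = 137)
  tree <- load_tree_package(make_tree_package(spec))
  batch <- make_samples(tree, spec)
  res <- classify_profiles(parse_hsd(batch$hsd), tree)

  some <- parse_variants(res$hits[[1]]$found[[1]])
  some <- some[some$kind == "substitution", ]
  t1 <- load_annotation_table(write_annotation(tibble::tibble(
    POS = some$position[1], ALT = some$alt[1], freq = 0.42)), name = "t1")
  t2 <- load_annotation_table(write_annotation(tibble::tibble(
    POS = 99999, ALT = "G", other = 1)), name = "t2")

  ann <- annotate_result(res, list(t1, t2))
  expect_identical(ann$haplogroup, res$haplogroup)
  expect_identical(ann$quality, res$quality)
  expect_identical(ann$hits, res$hits)
  a1 <- ann$annotations[[1]]
  # present in one of two tables: one populated map, one empty
  expect_true(all(a1$table == "t1"))
  expect_identical(annotate_result(res, list()), res)

  f <- tempfile(fileext = ".tsv")
  write_annotations_tsv(ann, f)
  out <- readr::read_tsv(f, show_col_types = FALSE)
  expect_identical(names(out), c("SampleID", "variant", "partition", "table",
                                 "field", "value"))
})
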