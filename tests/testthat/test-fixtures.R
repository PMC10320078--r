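test_that("generated tree packages load and have the requested shape", {
  spec <- simulation_spec(n_haplogroups = 10, seed = 1)
  dir <- make_tree_package(spec)
  tree <- load_tree_package(dir)
  expect_equal(nrow(tree$nodes), 10)
  expect_length(tree$clusters, 4)
  expect_true(all(file.exists(file.path(dir, c("tree.xml", "weights.txt",
                                               "hotspots.txt", "rules.txt",
                                               "reference.fasta", "clusters.txt",
                                               "metadata.yaml")))))
})

test_that("the same seed reproduces a byte-identical package and batch", {
  spec <- simulation_spec(n_haplogroups = 15, n_samples = 5, seed = 5)
  d1 <- make_tree_package(spec); d2 <- make_tree_package(spec)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  tree <- load_tree_package(d1)
  b1 <- make_samples(tree, spec); b2 <- make_samples(tree, spec)
  for (f in c("hsd", "vcf", "fasta")) {
    expect_identical(readLines(b1[[f]]), readLines(b2[[f]]), label = f)
  }
})

test_that("a sweep of random specs yields loadable, valid packages", {
  set.seed(200)
  for (k in 1:25) {
    spec <- simulation_spec(
      n_haplogroups = sample(5:40, 1),
      max_depth = sample(2:6, 1),
      variants_per_edge = sort(sample(1:3, 2, replace = TRUE)),
      back_mutation_rate = stats::runif(1, 0, 0.2),
      indel_rate = stats::runif(1, 0, 0.3),
      n_clusters = 2,
      reference_length = sample(c(800, 2000), 1),
      seed = k)
    tree <- load_tree_package(make_tree_package(spec))
    expect_equal(nrow(tree$nodes), spec$n_haplogroups)
    expect_identical(tree$root, "Root")
    # unique forward positions except deliberate back mutations
    fwd <- unlist(tree$nodes$variants)
    fwd <- fwd[!grepl("!$", fwd)]
    expect_false(anyDuplicated(vapply(fwd, function(x) oracle_parse(x)$pos, 0)) > 0)
  }
})

test_that("infeasible specs are rejected up front", {
  expect_error(simulation_spec(n_haplogroups = 200, reference_length = 500),
               "infeasible")
})

test_that("noiseless batches classify back to their planting nodes at quality 1", {
  spec <- simulation_spec(n_haplogroups = 30, n_samples = 15,
                          extra_variant_rate = 0, seed = 151)
  tree <- load_tree_package(make_tree_package(spec))
  batch <- make_samples(tree, spec)
  res <- classify_profiles(parse_hsd(batch$hsd), tree)
  expect_identical(res$haplogroup, batch$truth$haplogroup)
  expect_true(all(res$quality == 1))
})
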