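test_that("a minimal tree package loads with nodes and edge variants linked", {
  tree <- tiny_tree()
  expect_s3_class(tree, "phylotree")
  expect_equal(nrow(tree$nodes), 3)
  expect_equal(sum(lengths(tree$nodes$variants)), 2)
  expect_identical(tree$root, "Root")
  expect_identical(tree$metadata$name, "test-tree")
})

test_that("a package without a weights file loads with a warning and default weights", {
  dir <- write_test_tree(
    c("haplogroup\tparent\tvariants", "Root\t\t", "A\tRoot\t263G"))
  expect_warning(tree <- load_tree_package(dir), "default weight")
  expect_length(tree$weights, 0)
  # scoring then degrades to unweighted counting at the default weight
  res <- classify_sample(tree, list(id = "s", range = "1-500", variants = "263G"))
  expect_equal(res$hits$quality[1], 1)
})

test_that("malformed weight entries and unknown cluster names are load errors", {
  dir <- tiny_tree_dir()
  writeLines(c("263G\t10", "oops\t5"), file.path(dir, "weights.txt"))
  expect_error(load_tree_package(dir), "weights.txt")
  dir2 <- tiny_tree_dir(clusters = "NoSuchGroup")
  expect_error(load_tree_package(dir2), "NoSuchGroup")
  dir3 <- tempfile()
  dir.create(dir3)
  writeLines("<phylotree><haplogroup name='Root'/>", file.path(dir3, "tree.xml"))
  writeLines(c(">r", ref_seq(100)), file.path(dir3, "reference.fasta"))
  expect_error(load_tree_package(dir3), "parse")
})

test_that("expected profiles accumulate along the path and honour back mutations", {
  tree <- tiny_tree()
  expect_identical(expected_profile(tree, "Root"), character(0))
  expect_setequal(expected_profile(tree, "A1"), c("263G", "152C"))

  bm <- load_tree_package(write_test_tree(
    c("haplogroup\tparent\tvariants",
      "Root\t\t",
      "A\tRoot\t263G",
      "A1\tA\t152C",
      "A1a\tA1\t263G!"),
    weights = c(`263G` = 10, `152C` = 10)))
  expect_identical(expected_profile(bm, "A1a"), "152C")
  expect_false(any(grepl("!", unlist(bm$profiles))))
})

test_that("unknown haplogroups raise a lookup error naming near matches", {
  tree <- tiny_tree()
  expect_error(expected_profile(tree, "A2"), "nearest.*A")
  expect_error(tree_distance(tree, "Root", "Zzz"), "unknown haplogroup")
})

test_that("profiles match an independent event-replay oracle on random trees", {
  for (seed in 1:20) {
    spec <- simulation_spec(n_haplogroups = 15, reference_length = 800,
                            back_mutation_rate = 0.1, seed = seed)
    tree <- load_tree_package(make_tree_package(spec))
    for (hg in tree$nodes$haplogroup) {
      expect_setequal(expected_profile(tree, hg),
                      oracle_profile(tree$nodes, hg))
    }
  }
})

test_that("child profiles differ from parents exactly by their edge events", {
  spec <- simulation_spec(n_haplogroups = 25, back_mutation_rate = 0.15, seed = 5)
  tree <- load_tree_package(make_tree_package(spec))
  for (i in seq_len(nrow(tree$nodes))[-1]) {
    child <- tree$nodes$haplogroup[i]
    parentp <- expected_profile(tree, tree$nodes$parent[i])
    childp <- expected_profile(tree, child)
    edge <- tree$nodes$variants[[i]]
    added <- edge[!grepl("!$", edge)]
    expect_setequal(setdiff(childp, parentp), added)
    for (rm in sub("!$", "", edge[grepl("!$", edge)])) {
      expect_false(rm %in% childp)
      expect_true(rm %in% parentp)
    }
  }
})

test_that("tree distance is the resolved profile difference along the path", {
  tree <- tiny_tree()
  expect_equal(tree_distance(tree, "A", "A"), 0)
  expect_equal(tree_distance(tree, "A", "A1"), 1)
  expect_equal(tree_distance(tree, "Root", "A1"), 2)

  spec <- simulation_spec(n_haplogroups = 30, back_mutation_rate = 0.1, seed = 9)
  tree <- load_tree_package(make_tree_package(spec))
  set.seed(99)
  for (k in 1:50) {
    pair <- sample(tree$nodes$haplogroup, 2)
    p1 <- oracle_profile(tree$nodes, pair[1])
    p2 <- oracle_profile(tree$nodes, pair[2])
    hot <- vapply(tree$hotspots, function(h) oracle_parse(h)$pos, 0)
    p1 <- p1[!vapply(p1, function(x) oracle_parse(x)$pos, 0) %in% hot]
    p2 <- p2[!vapply(p2, function(x) oracle_parse(x)$pos, 0) %in% hot]
    d_oracle <- length(setdiff(p1, p2)) + length(setdiff(p2, p1))
    expect_equal(tree_distance(tree, pair[1], pair[2]), d_oracle)
    expect_equal(tree_distance(tree, pair[2], pair[1]), d_oracle)
  }
})

test_that("tree distance satisfies the triangle inequality", {
  spec <- simulation_spec(n_haplogroups = 20, back_mutation_rate = 0.1, seed = 3)
  tree <- load_tree_package(make_tree_package(spec))
  hgs <- tree$nodes$haplogroup
  d <- outer(seq_along(hgs), seq_along(hgs),
             Vectorize(function(i, j) tree_distance(tree, hgs[i], hgs[j])))
  expect_true(all(d == t(d)))
  expect_true(all(diag(d) == 0))
  for (i in seq_along(hgs)) {
    for (j in seq_along(hgs)) {
      expect_true(all(d[i, j] <= d[i, ] + d[, j]))
    }
  }
})

test_that("load -> serialize -> re-load reproduces the tree package", {
  spec <- simulation_spec(n_haplogroups = 25, seed = 13)
  tree <- load_tree_package(make_tree_package(spec))
  dir2 <- tempfile()
  write_tree_package(tree, dir2)
  tree2 <- load_tree_package(dir2)
  expect_identical(tree2$nodes, tree$nodes)
  expect_identical(tree2$profiles, tree$profiles)
  expect_identical(tree2$weights, tree$weights)
  expect_identical(tree2$hotspots, tree$hotspots)
  expect_identical(tree2$clusters, tree$clusters)
  expect_identical(tree2$reference, tree$reference)
})
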