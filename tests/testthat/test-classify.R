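test_that("a profile planted at a node is recovered with quality exactly 1", {
  spec <- simulation_spec(n_haplogroups = 40, seed = 17)
  tree <- load_tree_package(make_tree_package(spec))
  hg <- tree$nodes$haplogroup[25]
  res <- classify_sample(tree, list(id = "s1",
                                    range = full_range(nchar(tree$reference)),
                                    variants = expected_profile(tree, hg)))
  expect_identical(res$hits$haplogroup[1], hg)
  expect_identical(res$hits$quality[1], 1)
  expect_identical(res$hits$status[1], "ok")
  expect_length(res$hits$remaining[[1]], 0)
})

test_that("the default run returns exactly min(20, #haplogroups) ranked hits", {
  spec <- simulation_spec(n_haplogroups = 40, seed = 17)
  tree <- load_tree_package(make_tree_package(spec))
  res <- classify_sample(tree, list(id = "s", range = "1-2000",
                                    variants = expected_profile(tree, "A")))
  expect_equal(nrow(res$hits), 20)
  expect_true(all(diff(res$hits$quality) <= 0))
  small <- tiny_tree()
  expect_equal(nrow(classify_sample(small, list(id = "s", range = "1-500",
                                                variants = "263G"))$hits), 3)
})

test_that("profiles with private extras still land on or next to the plant", {
  spec <- simulation_spec(n_haplogroups = 40, seed = 19)
  tree <- load_tree_package(make_tree_package(spec))
  used <- unique(c(vapply(unlist(tree$nodes$variants), function(x) oracle_parse(x)$pos, 0),
                   vapply(tree$hotspots, function(x) oracle_parse(x)$pos, 0)))
  pool <- setdiff(2:(nchar(tree$reference) - 1), used)
  set.seed(77)
  hits <- 0
  for (k in 1:200) {
    hg <- sample(tree$nodes$haplogroup, 1)
    n_extra <- sample(0:2, 1)
    extras <- if (n_extra) paste0(sample(pool, n_extra), "A") else character(0)
    res <- classify_sample(tree, list(id = "s", range = "1-2000",
                                      variants = c(expected_profile(tree, hg), extras)))
    top <- res$hits$haplogroup[1]
    if (top == hg) hits <- hits + 1
    expect_lte(tree_distance(tree, top, hg), 1)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("quality flags follow the rule book", {
  expect_identical(quality_flag(1, 0, 0)$status, "ok")
  f <- quality_flag(0.85, 0, 0)
  expect_identical(f$status, "warning")
  expect_identical(f$rules, "low_quality")
  expect_identical(quality_flag(0.95, 2, 0, full_coverage = FALSE)$status, "ok")
  expect_identical(quality_flag(0.95, 2, 0, full_coverage = TRUE)$rules,
                   "expected_missing")

  # six private extras always trip the remaining-variants rule
  spec <- simulation_spec(n_haplogroups = 30, seed = 23)
  tree <- load_tree_package(make_tree_package(spec))
  used <- vapply(c(unlist(tree$nodes$variants), tree$hotspots),
                 function(x) oracle_parse(x)$pos, 0)
  pool <- setdiff(2:(nchar(tree$reference) - 1), used)
  set.seed(88)
  for (k in 1:20) {
    hg <- sample(tree$nodes$haplogroup[-1], 1)
    extras <- paste0(sample(pool, 6), "A")
    res <- classify_sample(tree, list(id = "s", range = "1-2000",
                                      variants = c(expected_profile(tree, hg), extras)))
    expect_true("many_remaining" %in% res$hits$flags[[1]])
    expect_identical(res$hits$status[1], "warning")
  }
})

test_that("out-of-range variants and hotspots never influence the ranking", {
  spec <- simulation_spec(n_haplogroups = 30, seed = 29)
  tree <- load_tree_package(make_tree_package(spec))
  hg <- tree$nodes$haplogroup[12]
  prof <- expected_profile(tree, hg)
  r <- parse_range("1-1000")
  base <- classify_sample(tree, list(id = "s", range = r, variants = prof))
  # dropping what the range excludes anyway changes nothing
  trimmed <- classify_sample(tree, list(id = "s", range = r,
                                        variants = restrict_to_range(prof, r)))
  expect_identical(trimmed$hits$haplogroup, base$hits$haplogroup)
  expect_identical(trimmed$hits$quality, base$hits$quality)
  # neither does adding hotspot variants
  full <- full_range(nchar(tree$reference))
  base2 <- classify_sample(tree, list(id = "s", range = full, variants = prof))
  spiked <- classify_sample(tree, list(id = "s", range = full,
                                       variants = c(prof, tree$hotspots)))
  expect_identical(spiked$hits$quality, base2$hits$quality)
  expect_identical(spiked$hits$haplogroup, base2$hits$haplogroup)
})

test_that("a reference-identical sample classifies to the root with a notice", {
  tree <- tiny_tree()
  res <- classify_sample(tree, list(id = "s", range = "1-500",
                                    variants = character(0)))
  expect_identical(res$hits$haplogroup[1], "Root")
  expect_identical(res$hits$quality[1], 1)
  expect_match(res$warnings, "identical to the reference")
  expect_error(classify_sample(tree, list(id = "s", range = parse_range("5")[0, ],
                                          variants = "263G")), "empty range")
})

test_that("quality ties break lexicographically by haplogroup name", {
  tree <- load_tree_package(write_test_tree(
    c("haplogroup\tparent\tvariants",
      "Root\t\t",
      "B\tRoot\t100G",
      "A\tRoot\t100G"),
    weights = c(`100G` = 10)))
  res <- classify_sample(tree, list(id = "s", range = "1-500", variants = "100G"))
  expect_identical(res$hits$haplogroup[1:2], c("A", "B"))
})

test_that("batch classification matches per-sample calls and tidies cleanly", {
  spec <- simulation_spec(n_haplogroups = 30, n_samples = 8, seed = 37)
  tree <- load_tree_package(make_tree_package(spec))
  batch <- make_samples(tree, spec)
  profiles <- parse_hsd(batch$hsd)
  res <- classify_profiles(profiles, tree)
  for (i in seq_len(nrow(profiles))) {
    single <- classify_sample(tree, profiles[i, ])
    expect_identical(res$haplogroup[i], single$hits$haplogroup[1])
    expect_identical(res$quality[i], single$hits$quality[1])
  }
  td <- tidy(res)
  expect_true(all(td$rank <= 20))
  expect_equal(nrow(glance(res)), 1)
  expect_equal(glance(res)$n_samples, 8)
})
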