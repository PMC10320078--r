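# programmatic fixtures: everything is built in code at test time

# deterministic pseudo-random reference (a periodic one would make partial
# alignments ambiguous)
ref_seq <- function(len = 500) {
  paste(withr::with_seed(len + 99, sample(c("A", "C", "G", "T"), len, TRUE)),
        collapse = "")
}

# write a tree package directory from raw pieces (exercises the public loader)
write_test_tree <- function(tsv,
                            reference = ref_seq(500),
                            weights = NULL,
                            hotspots = character(0),
                            rules = NULL,
                            clusters = character(0),
                            metadata = c("name: test-tree", "version: '1'"),
                            dir = tempfile("treepkg")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(tsv, file.path(dir, "tree.tsv"))
  writeLines(c(">reference", reference), file.path(dir, "reference.fasta"))
  if (!is.null(weights)) {
    writeLines(paste(names(weights), weights, sep = "\t"),
               file.path(dir, "weights.txt"))
  }
  writeLines(hotspots, file.path(dir, "hotspots.txt"))
  if (!is.null(rules)) writeLines(rules, file.path(dir, "rules.txt"))
  writeLines(clusters, file.path(dir, "clusters.txt"))
  writeLines(metadata, file.path(dir, "metadata.yaml"))
  dir
}

# 3-node chain: Root -> A (263G) -> A1 (152C); the reference carries A at the
# two defining positions so both labels are genuine alternates
tiny_ref <- function(len = 500) {
  r <- strsplit(ref_seq(len), "", fixed = TRUE)[[1]]
  r[c(152, 263)] <- "A"
  paste(r, collapse = "")
}

tiny_tree_dir <- function(...) {
  write_test_tree(
    c("haplogroup\tparent\tvariants",
      "Root\t\t",
      "A\tRoot\t263G",
      "A1\tA\t152C"),
    reference = tiny_ref(),
    weights = c(`263G` = 10, `152C` = 10),
    ...)
}

tiny_tree <- function(...) load_tree_package(tiny_tree_dir(...))

# one-row profile tibble for classify_profiles()
profile_row <- function(id, variants, range = "1-500") {
  tibble::tibble(id = id, range = list(parse_range(range)),
                 variants = list(variants))
}

random_profiles <- function(n, len = 500, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("R%03d", seq_len(n)),
    range = replicate(n, {
      k <- sample(1:2, 1)
      s <- sort(sample.int(len, 2 * k))
      r <- parse_range(paste(paste0(s[seq(1, 2 * k, 2)], "-", s[seq(2, 2 * k, 2)]),
                             collapse = ";"))
      r
    }, simplify = FALSE),
    variants = replicate(n, {
      k <- sample(0:6, 1)
      pos <- sample.int(len - 2, k) + 1
      vapply(pos, function(p) {
        kind <- sample(3, 1)
        if (kind == 1) paste0(p, sample(c("A", "C", "G", "T"), 1))
        else if (kind == 2) paste0(p, ".1", sample(c("A", "C", "G", "T"), 1))
        else paste0(p, "d")
      }, character(1))
    }, simplify = FALSE)
  )
}
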