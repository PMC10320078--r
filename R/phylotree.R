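#' Load a phylogenetic tree package
#'
#' A tree package is a directory decoupling the phylogeny from the classifier.
#' It contains:
#' \describe{
#'   \item{`tree.xml` (or `tree.tsv`)}{the rooted tree; every haplogroup node
#'     lists the variants defining its branch in Phylotree nomenclature,
#'     including back mutations marked `"!"`.}
#'   \item{`weights.txt`}{tab-delimited `variant<TAB>weight` phylogenetic
#'     weights used by the classification metrics; variants without an entry
#'     receive the default weight 10.}
#'   \item{`hotspots.txt`}{hypervariable positions (one variant per line)
#'     excluded from phylogenetic interpretation.}
#'   \item{`reference.fasta`}{the reference sequence (e.g. the 16,569 bp rCRS).}
#'   \item{`clusters.txt`}{names of the top-level haplogroups used for
#'     cluster summaries (optional but required for clustering).}
#'   \item{`rules.txt`}{nomenclature rewrite rules (optional, see
#'     [parse_rules()]).}
#'   \item{`metadata.yaml`}{`name:`, `version:` and an optional `annotations:`
#'     list of annotation TSV files.}
#' }
#'
#' @param dir Path to the tree package directory.
#' @return A `phylotree` object: nodes tibble (`haplogroup`, `parent`,
#'   `variants` list-column), `weights` (named numeric), `default_weight`,
#'   `hotspots`, `reference`, `rules`, `clusters`, `metadata`, plus a cache of
#'   every haplogroup's expected variant profile.
#' @export
load_tree_package <- function(dir) {
  if (!dir.exists(dir)) stop("tree package directory not found: ", dir, call. = FALSE)

  xml_path <- file.path(dir, "tree.xml")
  tsv_path <- file.path(dir, "tree.tsv")
  nodes <- if (file.exists(xml_path)) {
    read_tree_xml(xml_path)
  } else if (file.exists(tsv_path)) {
    read_tree_tsv(tsv_path)
  } else {
    stop("tree package has neither tree.xml nor tree.tsv: ", dir, call. = FALSE)
  }

  ref_path <- file.path(dir, "reference.fasta")
  if (!file.exists(ref_path)) stop("tree package missing reference.fasta", call. = FALSE)
  ref_set <- Biostrings::readDNAStringSet(ref_path)
  reference <- toupper(as.character(ref_set[[1]]))

  weights <- numeric(0)
  w_path <- file.path(dir, "weights.txt")
  if (file.exists(w_path)) {
    weights <- read_weights(w_path)
  } else {
    warning("tree package has no weights.txt; all variants get the default weight",
            call. = FALSE)
  }

  hotspots <- character(0)
  h_path <- file.path(dir, "hotspots.txt")
  if (file.exists(h_path)) {
    lines <- readr::read_lines(h_path)
    lines <- stringr::str_trim(lines)
    hotspots <- parse_variants(lines[nzchar(lines) & !startsWith(lines, "#")])$label
  }

  rules <- empty_rules()
  r_path <- file.path(dir, "rules.txt")
  if (file.exists(r_path)) rules <- parse_rules(readr::read_lines(r_path))

  clusters <- character(0)
  c_path <- file.path(dir, "clusters.txt")
  if (file.exists(c_path)) {
    clusters <- stringr::str_trim(readr::read_lines(c_path))
    clusters <- clusters[nzchar(clusters)]
  }

  metadata <- list(name = basename(dir), version = "0")
  m_path <- file.path(dir, "metadata.yaml")
  if (file.exists(m_path)) {
    metadata <- utils::modifyList(metadata, yaml::read_yaml(m_path))
  }

  annotations <- list()
  for (a in metadata$annotations %||% character(0)) {
    annotations[[a]] <- load_annotation_table(file.path(dir, a))
  }

  new_phylotree(nodes, reference, weights = weights, hotspots = hotspots,
                rules = rules, clusters = clusters, metadata = metadata,
                annotations = annotations)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

read_weights <- function(path) {
  lines <- readr::read_lines(path)
  keep <- nzchar(stringr::str_trim(lines)) & !startsWith(lines, "#")
  parts <- stringr::str_split(lines[keep], "\t")
  bad <- which(lengths(parts) < 2)
  if (length(bad)) {
    stop("weights.txt line ", which(keep)[bad[1]], ": expected variant<TAB>weight",
         call. = FALSE)
  }
  labels <- vapply(parts, `[[`, "", 1L)
  parsed <- tryCatch(parse_variants(labels), error = function(e) {
    stop("weights.txt: ", conditionMessage(e), call. = FALSE)
  })
  w <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(w) || any(w <= 0)) {
    stop("weights.txt line ", which(keep)[which(is.na(w) | w <= 0)[1]],
         ": weight must be a positive number", call. = FALSE)
  }
  stats::setNames(w, parsed$label)
}

read_tree_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("cannot parse tree XML: ", conditionMessage(e), call. = FALSE)
  })
  roots <- xml2::xml_find_all(doc, "./haplogroup")
  if (length(roots) != 1) {
    stop("tree XML must contain exactly one root <haplogroup>", call. = FALSE)
  }
  rows <- list()
  walk <- function(node, parent) {
    name <- xml2::xml_attr(node, "name")
    if (is.na(name) || !nzchar(name)) stop("haplogroup without a name", call. = FALSE)
    vtxt <- xml2::xml_attr(node, "variants")
    vars <- if (is.na(vtxt) || !nzchar(stringr::str_trim(vtxt))) character(0) else
      parse_variants(stringr::str_split_1(stringr::str_trim(vtxt), "\\s+"))$label
    rows[[length(rows) + 1L]] <<- list(haplogroup = name, parent = parent,
                                       variants = vars)
    for (child in xml2::xml_find_all(node, "./haplogroup")) walk(child, name)
  }
  walk(roots[[1]], NA_character_)
  tibble::tibble(
    haplogroup = vapply(rows, `[[`, "", "haplogroup"),
    parent = vapply(rows, `[[`, "", "parent"),
    variants = lapply(rows, `[[`, "variants")
  )
}

read_tree_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("haplogroup", "parent", "variants")
  if (!all(need %in% names(df))) {
    stop("tree.tsv needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    haplogroup = df$haplogroup,
    parent = dplyr::if_else(is.na(df$parent) | df$parent == "", NA_character_, df$parent),
    variants = lapply(df$variants, function(v) {
      if (is.na(v) || !nzchar(stringr::str_trim(v))) character(0) else
        parse_variants(stringr::str_split_1(stringr::str_trim(v), "\\s+"))$label
    })
  )
}

new_phylotree <- function(nodes, reference, weights = numeric(0),
                          default_weight = 10, hotspots = character(0),
                          rules = empty_rules(), clusters = character(0),
                          metadata = list(name = "tree", version = "0"),
                          annotations = list()) {
  if (anyDuplicated(nodes$haplogroup)) {
    stop("duplicate haplogroup names: ",
         paste(unique(nodes$haplogroup[duplicated(nodes$haplogroup)]), collapse = ", "),
         call. = FALSE)
  }
  root <- nodes$haplogroup[is.na(nodes$parent)]
  if (length(root) != 1) stop("tree must have exactly one root", call. = FALSE)
  if (!all(stats::na.omit(nodes$parent) %in% nodes$haplogroup)) {
    stop("parent names referencing unknown haplogroups", call. = FALSE)
  }
  bad_clusters <- setdiff(clusters, nodes$haplogroup)
  if (length(bad_clusters)) {
    stop("clusters.txt names unknown haplogroup(s): ",
         paste(bad_clusters, collapse = ", "), call. = FALSE)
  }
  hp <- variant_positions(hotspots)
  L <- nchar(reference)
  all_pos <- unlist(lapply(nodes$variants, variant_positions))
  if (length(all_pos) && (any(all_pos < 1) || any(all_pos > L))) {
    stop("edge variant position outside the reference (length ", L, ")", call. = FALSE)
  }

  tree <- structure(
    list(nodes = nodes, root = root, reference = reference,
         weights = weights, default_weight = default_weight,
         hotspots = hotspots, hotspot_positions = hp,
         rules = rules, clusters = clusters, metadata = metadata,
         annotations = annotations),
    class = "phylotree")
  tree$profiles <- compute_profiles(tree)   # replay cache, root first
  tree$depth <- compute_depths(tree)
  # per-node position/weight caches so classification avoids re-parsing labels
  tree$profile_pos <- lapply(tree$profiles, variant_positions)
  tree$profile_w <- lapply(tree$profiles, function(p) variant_weight(tree, p))
  tree
}

# replay edge events from the root down; a back mutation removes the matching
# ancestral event (same position/kind/slot, any allele) and is itself dropped,
# a repeated forward event supersedes the earlier allele at that slot
replay_edge_events <- function(profile, edge_variants) {
  if (length(edge_variants) == 0) return(profile)
  ev <- parse_variants(edge_variants)
  keys <- variant_event_key(ev)
  prof_keys <- if (length(profile)) variant_event_key(parse_variants(profile)) else character(0)
  for (i in seq_len(nrow(ev))) {
    drop <- prof_keys == keys[i]
    profile <- profile[!drop]
    prof_keys <- prof_keys[!drop]
    if (!ev$back_mutation[i]) {
      profile <- c(profile, strip_back_mark(ev$label[i]))
      prof_keys <- c(prof_keys, keys[i])
    }
  }
  profile
}

compute_profiles <- function(tree) {
  nodes <- tree$nodes
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$haplogroup)
  profiles <- vector("list", nrow(nodes))
  names(profiles) <- nodes$haplogroup
  children <- split(nodes$haplogroup, factor(nodes$parent, levels = nodes$haplogroup))
  visit <- function(name, profile) {
    profile <- replay_edge_events(profile, nodes$variants[[idx[[name]]]])
    profiles[[name]] <<- sort_variant_labels(profile)
    for (child in children[[name]]) visit(child, profile)
  }
  old <- options(expressions = max(getOption("expressions"), 50000L))
  on.exit(options(old))
  visit(tree$root, character(0))
  if (any(vapply(profiles, is.null, TRUE))) {
    stop("tree contains nodes unreachable from the root (cycle?)", call. = FALSE)
  }
  profiles
}

compute_depths <- function(tree) {
  nodes <- tree$nodes
  parent <- stats::setNames(nodes$parent, nodes$haplogroup)
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$haplogroup)
  depth[tree$root] <- 0L
  repeat {
    todo <- names(depth)[is.na(depth) & !is.na(depth[parent[names(depth)]])]
    if (!length(todo)) break
    depth[todo] <- depth[parent[todo]] + 1L
  }
  depth
}

sort_variant_labels <- function(labels) {
  if (length(labels) < 2) return(labels)
  v <- parse_variants(labels)
  labels[order(v$position, v$insertion_index, v$label)]
}

#' @export
print.phylotree <- function(x, ...) {
  cat("<phylotree> ", x$metadata$name, " v", x$metadata$version, "\n", sep = "")
  cat("  haplogroups: ", nrow(x$nodes),
      "; reference length: ", nchar(x$reference), " bp\n", sep = "")
  cat("  weights: ", length(x$weights), " entries (default ", x$default_weight,
      "); hotspots: ", length(x$hotspots),
      "; rules: ", nrow(x$rules),
      "; clusters: ", length(x$clusters), "\n", sep = "")
  invisible(x)
}

lookup_haplogroup <- function(tree, haplogroup) {
  if (!haplogroup %in% tree$nodes$haplogroup) {
    near <- utils::head(tree$nodes$haplogroup[
      order(utils::adist(haplogroup, tree$nodes$haplogroup))], 3)
    stop("unknown haplogroup '", haplogroup, "'; nearest names: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  haplogroup
}

#' Expected variant profile of a haplogroup
#'
#' Accumulates the branch-defining variants on the path from the root to the
#' haplogroup. A back mutation on a descendant branch removes the matching
#' ancestral variant (same position and kind, any allele) and never appears in
#' the result itself; a later forward event at the same position re-adds it.
#'
#' @param tree A `phylotree`.
#' @param haplogroup Haplogroup name.
#' @return Character vector of variant labels, sorted by position.
#' @export
expected_profile <- function(tree, haplogroup) {
  tree$profiles[[lookup_haplogroup(tree, haplogroup)]]
}

#' Phylogenetic distance between two haplogroups
#'
#' The number of variants by which the two haplogroups' expected profiles
#' differ after back mutations along the connecting path are resolved,
#' with hotspot variants excluded. Symmetric, zero for identical profiles,
#' and satisfies the triangle inequality.
#'
#' @param tree A `phylotree`.
#' @param hg1,hg2 Haplogroup names.
#' @return A non-negative integer.
#' @export
tree_distance <- function(tree, hg1, hg2) {
  p1 <- expected_profile(tree, hg1)
  p2 <- expected_profile(tree, hg2)
  p1 <- p1[!variant_positions(p1) %in% tree$hotspot_positions]
  p2 <- p2[!variant_positions(p2) %in% tree$hotspot_positions]
  length(setdiff(p1, p2)) + length(setdiff(p2, p1))
}

variant_weight <- function(tree, labels) {
  w <- tree$weights[labels]
  w[is.na(w)] <- tree$default_weight
  unname(w)
}

#' Write a phylotree back out as a tree package directory
#'
#' Emits the same layout [load_tree_package()] reads, so that loading,
#' serializing and re-loading reproduces an identical node and variant
#' structure. Used by the synthetic-data generator.
#'
#' @param tree A `phylotree`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tree_package <- function(tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  doc <- xml2::xml_new_root("phylotree", name = tree$metadata$name,
                            version = as.character(tree$metadata$version))
  nodes <- tree$nodes
  children <- split(seq_len(nrow(nodes)), factor(nodes$parent, levels = nodes$haplogroup))
  emit <- function(parent_xml, i) {
    attrs <- list(name = nodes$haplogroup[i])
    if (length(nodes$variants[[i]])) {
      attrs$variants <- paste(nodes$variants[[i]], collapse = " ")
    }
    node_xml <- do.call(xml2::xml_add_child, c(list(parent_xml, "haplogroup"), attrs))
    for (j in children[[nodes$haplogroup[i]]]) emit(node_xml, j)
  }
  emit(doc, which(is.na(nodes$parent)))
  xml2::write_xml(doc, file.path(dir, "tree.xml"))

  if (length(tree$weights)) {
    readr::write_lines(paste(names(tree$weights), tree$weights, sep = "\t"),
                       file.path(dir, "weights.txt"))
  }
  readr::write_lines(tree$hotspots, file.path(dir, "hotspots.txt"))
  readr::write_lines(tree$clusters, file.path(dir, "clusters.txt"))
  if (nrow(tree$rules)) {
    readr::write_lines(
      paste(vapply(tree$rules$source, paste, "", collapse = " "),
            vapply(tree$rules$target, paste, "", collapse = " "), sep = "\t"),
      file.path(dir, "rules.txt"))
  }
  ref <- Biostrings::DNAStringSet(tree$reference)
  names(ref) <- "reference"
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fasta"), width = 70L)
  yaml::write_yaml(list(name = tree$metadata$name,
                        version = as.character(tree$metadata$version)),
                   file.path(dir, "metadata.yaml"))
  invisible(dir)
}
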