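#' Specification for a synthetic tree package and sample batch
#'
#' The simulator makes every pipeline stage testable without downloading a
#' published tree: it emits a random rooted phylogeny with unique
#' haplogroup-defining variants (plus deliberate back mutations), random
#' phylogenetic weights, a hotspot list, a small rule file, a random
#' reference genome and cluster labels, then plants samples at known nodes
#' and renders them consistently as hsd, VCF and FASTA.
#'
#' @param n_haplogroups Number of tree nodes including the root (default 40).
#' @param max_depth Maximum tree depth (default 6).
#' @param variants_per_edge Integer range `c(min, max)` of variants per
#'   branch (default 1–3).
#' @param back_mutation_rate Probability that an edge-variant slot is a back
#'   mutation of an ancestral variant (default 0.05).
#' @param indel_rate Fraction of new edge variants that are indels, split
#'   evenly between insertions and deletions (default 0.1).
#' @param n_clusters Number of depth-1 nodes used as top-level clusters
#'   (default 4).
#' @param n_samples Samples per batch (default 20).
#' @param extra_variant_rate Poisson mean of private (non-phylogenetic) extra
#'   variants per sample (default 1).
#' @param missing_rate Per-genotype masking probability in the emitted VCF
#'   (default 0).
#' @param reference_length Synthetic reference genome length in bp
#'   (default 2000; a desk-scale stand-in for the 16,569 bp rCRS).
#' @param seed Integer seed fixing all randomness.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_haplogroups = 40, max_depth = 6,
                            variants_per_edge = c(1, 3),
                            back_mutation_rate = 0.05, indel_rate = 0.1,
                            n_clusters = 4, n_samples = 20,
                            extra_variant_rate = 1, missing_rate = 0,
                            reference_length = 2000, seed = 1) {
  spec <- list(n_haplogroups = as.integer(n_haplogroups),
               max_depth = as.integer(max_depth),
               variants_per_edge = as.integer(variants_per_edge),
               back_mutation_rate = back_mutation_rate,
               indel_rate = indel_rate,
               n_clusters = as.integer(n_clusters),
               n_samples = as.integer(n_samples),
               extra_variant_rate = extra_variant_rate,
               missing_rate = missing_rate,
               reference_length = as.integer(reference_length),
               seed = as.integer(seed))
  stopifnot(spec$n_haplogroups >= 2, spec$max_depth >= 1,
            length(spec$variants_per_edge) == 2,
            spec$variants_per_edge[1] >= 1,
            spec$variants_per_edge[2] >= spec$variants_per_edge[1],
            spec$back_mutation_rate >= 0, spec$back_mutation_rate <= 1,
            spec$indel_rate >= 0, spec$indel_rate <= 1,
            spec$n_clusters >= 1,
            spec$n_clusters <= min(spec$n_haplogroups - 1L, 26L),
            spec$n_samples >= 1,
            spec$extra_variant_rate >= 0,
            spec$missing_rate >= 0, spec$missing_rate <= 1,
            spec$reference_length >= 100)
  # every edge needs fresh positions; leave headroom for hotspots, rules and
  # per-sample private variants
  need <- (spec$n_haplogroups - 1L) * spec$variants_per_edge[2] + 20L
  if (need > spec$reference_length / 2) {
    stop("infeasible simulation spec: ", need, " variant positions needed on a ",
         spec$reference_length, " bp reference", call. = FALSE)
  }
  structure(spec, class = "simulation_spec")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_fixed_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

letter_name <- function(k) {
  if (k <= 26) letters[k] else paste0(letters[(k - 1L) %/% 26L], letters[(k - 1L) %% 26L + 1L])
}

#' Generate a synthetic tree package
#'
#' Writes a complete, loadable tree package directory for the given
#' simulation spec. The same spec (same seed) always produces a
#' byte-identical package.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (default: a fresh temporary directory).
#' @return The package directory path.
#' @export
make_tree_package <- function(spec, dir = tempfile("treepkg")) {
  stopifnot(inherits(spec, "simulation_spec"))
  tree <- with_fixed_seed(spec$seed, build_random_tree(spec))
  write_tree_package(tree, dir)
  dir
}

build_random_tree <- function(spec) {
  L <- spec$reference_length
  reference <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = "")
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  used <- logical(L)
  used[c(1L, L)] <- TRUE  # keep genome ends variant-free (VCF/alignment anchors)

  draw_variant <- function() {
    for (try in 1:100) {
      pos <- sample.int(L, 1L)
      if (used[pos]) next
      u <- stats::runif(1)
      if (u >= spec$indel_rate) {
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref_chars[pos]), 1L)
        label <- paste0(pos, alt)
      } else if (u < spec$indel_rate / 2) {
        if (pos < 2L) next
        label <- right_align_indels(paste0(pos, "d"), reference)
      } else {
        label <- right_align_indels(paste0(pos, ".1", sample(c("A", "C", "G", "T"), 1L)),
                                    reference)
      }
      final_pos <- variant_positions(label)
      if (used[final_pos] || final_pos < 2L) next
      used[pos] <<- TRUE
      used[final_pos] <<- TRUE
      return(label)
    }
    stop("could not place a variant; spec too dense for the reference",
         call. = FALSE)
  }

  n <- spec$n_haplogroups
  name <- character(n); parent <- character(n); depth <- integer(n)
  variants <- vector("list", n)
  profiles <- vector("list", n)
  name[1] <- "Root"; parent[1] <- NA_character_; depth[1] <- 0L
  variants[[1]] <- character(0); profiles[[1]] <- character(0)
  n_children <- integer(n)

  for (i in 2:n) {
    if (i <= spec$n_clusters + 1L) {
      p <- 1L
    } else {
      eligible <- which(depth[2:(i - 1L)] < spec$max_depth) + 1L
      if (!length(eligible)) eligible <- 2:(i - 1L)
      p <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    }
    n_children[p] <- n_children[p] + 1L
    name[i] <- if (p == 1L) LETTERS[n_children[1L]] else
      paste0(name[p], if (depth[p] %% 2L == 1L) n_children[p] else letter_name(n_children[p]))
    parent[i] <- name[p]
    depth[i] <- depth[p] + 1L

    n_vars <- sample(seq(spec$variants_per_edge[1], spec$variants_per_edge[2]), 1L)
    edge <- character(0)
    for (k in seq_len(n_vars)) {
      pool <- setdiff(profiles[[p]], strip_back_mark(edge))
      if (stats::runif(1) < spec$back_mutation_rate && length(pool)) {
        pick <- if (length(pool) == 1L) pool else sample(pool, 1L)
        edge <- c(edge, paste0(pick, "!"))
      } else {
        edge <- c(edge, draw_variant())
      }
    }
    variants[[i]] <- edge
    profiles[[i]] <- replay_edge_events(profiles[[p]], edge)
  }

  all_labels <- unique(strip_back_mark(unlist(variants)))
  n_weighted <- floor(0.85 * length(all_labels))
  weighted <- sort(sample(all_labels, n_weighted))
  weights <- stats::setNames(sample(1:15, n_weighted, replace = TRUE), weighted)

  hotspots <- character(0)
  for (k in 1:3) hotspots <- c(hotspots, draw_variant())
  rule_src <- draw_variant(); rule_tgt <- draw_variant()
  rule_src2 <- draw_variant(); rule_tgt2 <- draw_variant()
  rules <- parse_rules(c(paste(rule_src, rule_tgt, sep = "\t"),
                         paste(rule_src2, rule_tgt2, sep = "\t")))

  new_phylotree(
    tibble::tibble(haplogroup = name, parent = parent, variants = variants),
    reference,
    weights = weights, hotspots = hotspots, rules = rules,
    clusters = name[2:(spec$n_clusters + 1L)],
    metadata = list(name = paste0("synthetic-", n, "-seed", spec$seed),
                    version = "1.0"))
}

#' Plant a synthetic sample batch at known tree nodes
#'
#' Each sample is planted at a random haplogroup: its variant set is the
#' node's expected profile plus a Poisson number of private extra
#' substitutions at positions unused by the tree. The batch is rendered
#' consistently in all three input formats (hsd, VCF 4.2 and FASTA built by
#' actually mutating the reference sequence), alongside a ground-truth table.
#'
#' @param tree A `phylotree` (typically loaded from [make_tree_package()]).
#' @param spec The [simulation_spec()] (uses `n_samples`,
#'   `extra_variant_rate`, `missing_rate` and `seed`).
#' @param dir Output directory (default: a fresh temporary directory).
#' @return A list: `hsd`, `vcf`, `fasta`, `truth_file` (paths), `truth`
#'   (tibble `id`, `haplogroup`, `variants` list-column) and `mask` (logical
#'   site-by-sample matrix of masked VCF genotypes).
#' @export
make_samples <- function(tree, spec, dir = tempfile("samples")) {
  stopifnot(inherits(tree, "phylotree"), inherits(spec, "simulation_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_fixed_seed(spec$seed + 1L, {
    L <- nchar(tree$reference)
    ref_chars <- strsplit(tree$reference, "", fixed = TRUE)[[1]]
    reserved <- unique(c(
      1L, L,
      parse_variants(unlist(tree$nodes$variants, use.names = FALSE))$position,
      variant_positions(tree$hotspots),
      variant_positions(unlist(c(tree$rules$source, tree$rules$target)))))
    pool <- setdiff(seq_len(L), reserved)

    ids <- sprintf("S%03d", seq_len(spec$n_samples))
    planted <- sample(tree$nodes$haplogroup, spec$n_samples, replace = TRUE)
    n_extra <- stats::rpois(spec$n_samples, spec$extra_variant_rate)
    extra_pos <- if (sum(n_extra) > 0) sample(pool, sum(n_extra)) else integer(0)
    offsets <- cumsum(c(0L, n_extra))
    variants <- lapply(seq_len(spec$n_samples), function(i) {
      ep <- extra_pos[seq_len(n_extra[i]) + offsets[i]]
      extras <- vapply(ep, function(p) {
        paste0(p, sample(setdiff(c("A", "C", "G", "T"), ref_chars[p]), 1L))
      }, character(1))
      sort_variant_labels(c(expected_profile(tree, planted[i]), extras))
    })

    truth <- tibble::tibble(id = ids, haplogroup = planted, variants = variants)

    # hsd
    hsd_file <- file.path(dir, "samples.hsd")
    write_hsd(tibble::tibble(id = ids,
                             range = rep(list(full_range(L)), length(ids)),
                             variants = variants), hsd_file)

    # VCF: one record per distinct variant label across the batch
    labels <- sort_variant_labels(unique(unlist(variants)))
    vcf_file <- file.path(dir, "samples.vcf")
    mask <- NULL
    if (length(labels)) {
      enc <- vcf_encode_labels(labels, tree$reference)
      present <- vapply(variants, function(v) labels %in% v,
                        logical(length(labels)))
      present <- matrix(present, nrow = length(labels),
                        dimnames = list(labels, ids))
      mask <- matrix(stats::runif(length(present)) < spec$missing_rate,
                     nrow = nrow(present), dimnames = dimnames(present))
      gt <- ifelse(mask, "./.", ifelse(present, "1", "0"))
      ord <- order(enc$pos, labels)
      lines <- c(
        "##fileformat=VCFv4.2",
        paste0("##contig=<ID=chrM,length=", L, ">"),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                "FORMAT", ids), collapse = "\t"),
        vapply(ord, function(r) {
          paste(c("chrM", enc$pos[r], ".", enc$ref[r], enc$alt[r], ".", "PASS",
                  ".", "GT", gt[r, ]), collapse = "\t")
        }, character(1)))
      readr::write_lines(lines, vcf_file)
      mask <- mask[ord, , drop = FALSE]
    } else {
      readr::write_lines(c(
        "##fileformat=VCFv4.2",
        paste0("##contig=<ID=chrM,length=", L, ">"),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                "FORMAT", ids), collapse = "\t")), vcf_file)
    }

    # FASTA: actually mutate the reference so the aligner path is exercised
    fasta_file <- file.path(dir, "samples.fasta")
    fa <- Biostrings::DNAStringSet(vapply(variants, function(v) {
      apply_variants(tree$reference, v)
    }, character(1)))
    names(fa) <- ids
    Biostrings::writeXStringSet(fa, fasta_file, width = 70L)

    truth_file <- file.path(dir, "truth.tsv")
    readr::write_tsv(tibble::tibble(id = ids, haplogroup = planted),
                     truth_file, progress = FALSE)

    list(hsd = hsd_file, vcf = vcf_file, fasta = fasta_file,
         truth_file = truth_file, truth = truth, mask = mask)
  })
}

# VCF 4.x encoding of variant labels (substitution / single-base insertion
# with index 1 / deletion); anchors one base left for indels
vcf_encode_labels <- function(labels, reference) {
  v <- parse_variants(labels)
  ref_at <- function(p, n = 1L) substr(reference, p, p + n - 1L)
  pos <- integer(nrow(v)); ref <- character(nrow(v)); alt <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    p <- v$position[i]
    if (v$kind[i] == "substitution") {
      pos[i] <- p; ref[i] <- ref_at(p); alt[i] <- v$alt[i]
    } else if (v$kind[i] == "insertion") {
      pos[i] <- p; ref[i] <- ref_at(p); alt[i] <- paste0(ref_at(p), v$alt[i])
    } else {
      if (p < 2L) stop("cannot encode a deletion at position 1", call. = FALSE)
      pos[i] <- p - 1L; ref[i] <- ref_at(p - 1L, 2L); alt[i] <- ref_at(p - 1L)
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}
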