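# independent reference implementations used as oracles; they share no code
# with the package internals they check

oracle_parse <- function(lab) {
  bang <- grepl("!$", lab)
  core <- sub("!$", "", lab)
  pos <- as.integer(sub("^([0-9]+).*$", "\\1", core))
  rest <- sub("^[0-9]+", "", core)
  if (rest %in% c("d", "D")) {
    kind <- "del"; idx <- 0L; alt <- ""
  } else if (startsWith(rest, ".")) {
    kind <- "ins"
    idx <- as.integer(sub("^\\.([0-9]+).*$", "\\1", rest))
    alt <- sub("^\\.[0-9]+", "", rest)
  } else {
    kind <- "sub"; idx <- 0L; alt <- rest
  }
  list(key = paste(pos, kind, idx), bang = bang, core = core, pos = pos,
       kind = kind, idx = idx, alt = alt)
}

# brute-force event replay along the root -> node path
oracle_profile <- function(nodes, name) {
  parent <- stats::setNames(nodes$parent, nodes$haplogroup)
  path <- name
  while (!is.na(parent[[path[1]]])) path <- c(parent[[path[1]]], path)
  prof <- character(0)
  for (nm in path) {
    for (lab in nodes$variants[[match(nm, nodes$haplogroup)]]) {
      o <- oracle_parse(lab)
      if (length(prof)) {
        keys <- vapply(prof, function(x) oracle_parse(x)$key, "", USE.NAMES = FALSE)
        prof <- prof[keys != o$key]
      }
      if (!o$bang) prof <- c(prof, o$core)
    }
  }
  prof
}

# weighted set arithmetic by explicit loops
oracle_weight <- function(labels, weights, default = 10) {
  s <- 0
  for (l in labels) s <- s + (if (l %in% names(weights)) weights[[l]] else default)
  s
}
oracle_kulczynski <- function(obs, exp, weights = c(), default = 10) {
  ws <- oracle_weight(intersect(obs, exp), weights, default)
  we <- oracle_weight(exp, weights, default)
  wo <- oracle_weight(obs, weights, default)
  ((if (we == 0) 1 else ws / we) + (if (wo == 0) 1 else ws / wo)) / 2
}
oracle_jaccard <- function(obs, exp, weights = c(), default = 10) {
  ws <- oracle_weight(intersect(obs, exp), weights, default)
  wu <- oracle_weight(union(obs, exp), weights, default)
  if (wu == 0) 1 else ws / wu
}
oracle_hamming <- function(obs, exp, weights = c(), default = 10) {
  wd <- oracle_weight(c(setdiff(obs, exp), setdiff(exp, obs)), weights, default)
  wt <- oracle_weight(exp, weights, default) + oracle_weight(obs, weights, default)
  if (wt == 0) 1 else 1 - wd / wt
}

# apply a single variant to a sequence by plain string surgery
oracle_edit <- function(reference, lab) {
  o <- oracle_parse(lab)
  p <- o$pos
  if (o$kind == "sub") {
    paste0(substr(reference, 1, p - 1), o$alt,
           substr(reference, p + 1, nchar(reference)))
  } else if (o$kind == "del") {
    paste0(substr(reference, 1, p - 1),
           substr(reference, p + 1, nchar(reference)))
  } else {
    paste0(substr(reference, 1, p), o$alt,
           substr(reference, p + 1, nchar(reference)))
  }
}

# every position where the same-kind indel implies the same edited sequence
oracle_equivalent_positions <- function(reference, lab) {
  o <- oracle_parse(lab)
  target <- oracle_edit(reference, lab)
  keep <- integer(0)
  for (p in seq_len(nchar(reference))) {
    cand <- if (o$kind == "del") paste0(p, "d") else paste0(p, ".1", o$alt)
    if (o$kind == "ins" || p <= nchar(reference)) {
      if (oracle_edit(reference, cand) == target) keep <- c(keep, p)
    }
  }
  keep
}
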