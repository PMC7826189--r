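# Taxonomic groups recognized by the gene-tree sorter. alpha_cyanobacteria
# is nested in cyanobacteria, which is nested in bacteria.
TAXON_GROUPS <- c("query", "other_paulinella", "bacteria", "cyanobacteria",
                  "alpha_cyanobacteria", "eukarya", "archaea", "unknown")

group_expand <- function(group) {
  switch(group,
         bacteria = c("bacteria", "cyanobacteria", "alpha_cyanobacteria"),
         cyanobacteria = c("cyanobacteria", "alpha_cyanobacteria"),
         group)
}

#' Map leaf labels to taxonomic groups by prefix
#'
#' @param labels Leaf labels.
#' @param prefixes Named character vector mapping label prefixes to group
#'   names (e.g. `c(QRY = "query", BAC = "bacteria")`). Longest matching
#'   prefix wins; unmatched labels become `"unknown"`.
#' @return Named character vector label -> group.
#' @export
make_taxon_groups <- function(labels, prefixes) {
  stopifnot(all(prefixes %in% TAXON_GROUPS))
  ord <- order(nchar(names(prefixes)), decreasing = TRUE)
  prefixes <- prefixes[ord]
  out <- rep("unknown", length(labels))
  for (i in seq_along(prefixes)) {
    hit <- startsWith(labels, names(prefixes)[i]) & out == "unknown"
    out[hit] <- prefixes[[i]]
  }
  setNames(out, labels)
}

#' Sorting thresholds for HGT/EGT gene-tree classification
#'
#' Defaults follow the study design: clade support at least 70 (percent
#' scale), at least 70% of the tree's target-group leaves inside the
#' clade, clade composition at least 95% target, and trees discarded below
#' 10 leaves or 5 bacterial taxa.
#'
#' @param min_support Minimum node support (0-100 scale; absent support
#'   counts as 0).
#' @param min_prop_target Minimum fraction of the tree's target-group
#'   leaves that the clade must contain.
#' @param clade_exclusivity Minimum fraction of clade leaves belonging to
#'   the target groups.
#' @param min_leaves,min_bacteria Discard-filter thresholds.
#' @return List of class `sort_params`.
#' @export
sort_params <- function(min_support = 70, min_prop_target = 0.7,
                        clade_exclusivity = 0.95, min_leaves = 10,
                        min_bacteria = 5) {
  stopifnot(min_support >= 0, min_support <= 100,
            min_prop_target > 0, min_prop_target <= 1,
            clade_exclusivity > 0, clade_exclusivity <= 1)
  structure(list(min_support = min_support,
                 min_prop_target = min_prop_target,
                 clade_exclusivity = clade_exclusivity,
                 min_leaves = min_leaves, min_bacteria = min_bacteria),
            class = "sort_params")
}

resolve_groups <- function(tree, groups) {
  g <- groups[tree$tip.label]
  if (anyNA(g))
    stop("leaf label(s) not resolvable to a taxon group: ",
         paste(tree$tip.label[is.na(g)], collapse = ", "))
  unname(g)
}

#' Pre-classification discard filters for a gene tree
#'
#' Reasons, checked in order with the first failure reported:
#' `"leaves<L"` (fewer than `min_leaves` leaves), `"bacteria<B"` (fewer
#' than `min_bacteria` distinct bacterial taxa, cyanobacteria included),
#' and `"paulinella_polyphyly"` (more than one query/other-Paulinella leaf
#' and they do not form one side of any edge of the unrooted topology).
#'
#' @param tree `phylo` gene tree.
#' @param groups Leaf-label -> group map (see [make_taxon_groups()]).
#' @param params A [sort_params()].
#' @return `"pass"` or the discard reason string.
#' @export
apply_discard_filters <- function(tree, groups, params = sort_params()) {
  g <- resolve_groups(tree, groups)
  ntip <- length(tree$tip.label)
  if (ntip < params$min_leaves)
    return(sprintf("leaves<%d", params$min_leaves))
  n_bac <- sum(g %in% group_expand("bacteria"))
  if (n_bac < params$min_bacteria)
    return(sprintf("bacteria<%d", params$min_bacteria))
  pau <- which(g %in% c("query", "other_paulinella"))
  if (length(pau) > 1) {
    idx <- tree_index(tree)
    pau_mask <- seq_len(ntip) %in% pau
    mono <- FALSE
    for (v in seq_len(idx$nnode)) {
      if (v == idx$root) next
      side <- idx$below[v, ]
      if (identical(unname(side), pau_mask) ||
          identical(unname(!side), pau_mask)) { mono <- TRUE; break }
    }
    if (!mono) return("paulinella_polyphyly")
  }
  "pass"
}

#' Candidate donor clades of a gene tree
#'
#' Both sides of every internal edge are evaluated (so the result does not
#' depend on the rooting). A side is a candidate when (a) the subtending
#' support is at least `min_support`, (b) at least `clade_exclusivity` of
#' its leaves belong to the target groups (query, other Paulinella, and
#' the donor group with its subgroups), (c) it holds at least
#' `min_prop_target` of all target-group leaves present in the tree, and
#' (d) it contains at least one query leaf and one donor-group leaf.
#'
#' @param tree `phylo` gene tree with numeric node labels as supports.
#' @param groups Leaf-label -> group map.
#' @param params A [sort_params()].
#' @param donor_group `"bacteria"` (HGT) or `"cyanobacteria"` (EGT).
#' @return Data.frame of candidates, smallest side first: `node`, `side`
#'   (`"below"`/`"above"`), `size`, `support`, `n_target`, `n_query`,
#'   `n_donor`, `n_alpha`.
#' @export
find_target_clades <- function(tree, groups, params = sort_params(),
                               donor_group = "bacteria") {
  g <- resolve_groups(tree, groups)
  ntip <- length(tree$tip.label)
  if (ntip < 4) stop("tree has fewer than 4 leaves: no internal edge")
  donor_set <- group_expand(donor_group)
  target_set <- c("query", "other_paulinella", donor_set)
  is_target <- g %in% target_set
  is_query <- g == "query"
  is_donor <- g %in% donor_set
  is_alpha <- g == "alpha_cyanobacteria"
  total_target <- sum(is_target)
  if (total_target == 0) return(candidate_df())
  idx <- tree_index(tree)
  sup <- node_support(tree)
  root_children <- which(idx$parent == idx$root)
  root_bifurcating <- length(root_children) == 2
  rows <- list()
  for (v in (ntip + 1):idx$nnode) {
    if (v == idx$root) next
    s <- sup[v - ntip]
    s <- if (is.na(s)) 0 else s
    for (side in c("below", "above")) {
      # at a bifurcating root, the "above" side of one child is exactly
      # the sibling's clade: that bipartition is evaluated with the
      # sibling's own support, so skip the duplicate here
      if (side == "above" && root_bifurcating && idx$parent[v] == idx$root)
        next
      mask <- if (side == "below") idx$below[v, ] else !idx$below[v, ]
      size <- sum(mask)
      if (size < 2 || size >= ntip) next
      n_target <- sum(is_target & mask)
      if (s < params$min_support) next
      if (n_target / size < params$clade_exclusivity) next
      if (n_target / total_target < params$min_prop_target) next
      if (sum(is_query & mask) < 1 || sum(is_donor & mask) < 1) next
      rows[[length(rows) + 1]] <-
        data.frame(node = v, side = side, size = size, support = s,
                   n_target = n_target, n_query = sum(is_query & mask),
                   n_donor = sum(is_donor & mask),
                   n_alpha = sum(is_alpha & mask),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||% candidate_df()
  out[order(out$size), , drop = FALSE]
}

candidate_df <- function() {
  data.frame(node = integer(), side = character(), size = integer(),
             support = numeric(), n_target = integer(),
             n_query = integer(), n_donor = integer(), n_alpha = integer(),
             stringsAsFactors = FALSE)
}

#' Classify one gene tree as HGT, EGT, negative, or discarded
#'
#' Discard filters are applied first. The tree is an HGT candidate when a
#' supported clade of query plus bacterial leaves passes
#' [find_target_clades()] with donor `"bacteria"`; it is an EGT candidate
#' (which takes precedence) when a cyanobacterial donor clade containing
#' at least one alpha-cyanobacterium passes. The reported clade is the
#' smallest candidate.
#'
#' @inheritParams find_target_clades
#' @return List of class `sort_outcome`: `verdict` (`"HGT"`, `"EGT"`,
#'   `"negative"`, `"discarded"`), `discard_reason` (or `NA`), `clade`
#'   (one-row data.frame or `NULL`).
#' @export
sort_tree <- function(tree, groups, params = sort_params()) {
  filt <- apply_discard_filters(tree, groups, params)
  if (filt != "pass")
    return(structure(list(verdict = "discarded", discard_reason = filt,
                          clade = NULL), class = "sort_outcome"))
  egt <- find_target_clades(tree, groups, params, "cyanobacteria")
  egt <- egt[egt$n_alpha >= 1, , drop = FALSE]
  if (nrow(egt) > 0)
    return(structure(list(verdict = "EGT", discard_reason = NA_character_,
                          clade = egt[1, ]), class = "sort_outcome"))
  hgt <- find_target_clades(tree, groups, params, "bacteria")
  if (nrow(hgt) > 0)
    return(structure(list(verdict = "HGT", discard_reason = NA_character_,
                          clade = hgt[1, ]), class = "sort_outcome"))
  structure(list(verdict = "negative", discard_reason = NA_character_,
                 clade = NULL), class = "sort_outcome")
}

#' @export
print.sort_outcome <- function(x, ...) {
  cat("sort_outcome:", x$verdict,
      if (x$verdict == "discarded") paste0("(", x$discard_reason, ")") else "",
      "\n")
  invisible(x)
}

#' Classify a batch of gene trees
#'
#' @param trees Named list of `phylo` trees.
#' @param groups Leaf-label -> group map covering all trees.
#' @param params A [sort_params()].
#' @return Data.frame: `tree_id`, `verdict`, `discard_reason`.
#' @export
sort_trees <- function(trees, groups, params = sort_params()) {
  out <- lapply(names(trees), function(id) {
    o <- sort_tree(trees[[id]], groups, params)
    data.frame(tree_id = id, verdict = o$verdict,
               discard_reason = o$discard_reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
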