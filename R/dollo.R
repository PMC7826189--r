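# Tree bookkeeping shared by the Dollo and tree-sorting code. Nodes use
# ape numbering: tips 1..Ntip, internals Ntip+1..Ntip+Nnode, root first.

tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  parent <- integer(nnode)
  parent[edge[, 2]] <- edge[, 1]
  root <- setdiff(edge[, 1], edge[, 2])[1]
  parent[root] <- 0L
  # tips below each node (postorder accumulation: child edges first)
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(1:ntip, 1:ntip)] <- TRUE
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; c <- edge[e, 2]
    below[p, ] <- below[p, ] | below[c, ]
  }
  clade_size <- rowSums(below)
  # descendant-or-self relation via repeated parent walks is O(n^2); fine
  # at the tree sizes used here
  is_desc <- matrix(FALSE, nnode, nnode)  # is_desc[a, d]: d inside clade of a
  for (d in seq_len(nnode)) {
    v <- d
    while (v != 0L) { is_desc[v, d] <- TRUE; v <- parent[v] }
  }
  list(ntip = ntip, nnode = nnode, parent = parent, root = root,
       below = below, clade_size = clade_size, is_desc = is_desc,
       tips = tree$tip.label)
}

#' Dollo-parsimony reconstruction of gene-family gains and losses
#'
#' Each family is gained exactly once, at the most recent common ancestor
#' (MRCA) of the species that carry it; a node inside the gain clade is
#' ancestrally present iff its subtree contains at least one carrier, and
#' a loss is counted on the branch into every node whose parent is present
#' but which is absent. Per-branch gains/losses and per-node ancestral
#' family counts are aggregated over families. Polytomies are handled
#' without modification.
#'
#' @param fm A [family_matrix()].
#' @param tree Rooted `phylo` species tree whose tip set matches the
#'   matrix's species.
#' @return Object of class `dollo_result`: `gain_node` (named integer per
#'   family), `loss_branches` (list of child-node ids per family),
#'   `node_counts` (ancestral family count per node), `branch_gains` /
#'   `branch_losses` (per child node), `tree`, `node_names`.
#' @export
dollo_reconstruct <- function(fm, tree) {
  idx <- tree_index(tree)
  missing_sp <- setdiff(fm$species, idx$tips)
  if (length(missing_sp) > 0) {
    fam_bad <- fm$families[rowSums(fm$presence[, missing_sp, drop = FALSE]) > 0][1]
    stop("species '", missing_sp[1], "' (family '", fam_bad %||% "?",
         "') is absent from the tree")
  }
  tip_of_sp <- match(fm$species, idx$tips)
  nfam <- length(fm$families)
  gain_node <- integer(nfam)
  loss_branches <- vector("list", nfam)
  node_counts <- integer(idx$nnode)
  branch_gains <- integer(idx$nnode)
  branch_losses <- integer(idx$nnode)
  for (f in seq_len(nfam)) {
    pres_tips <- tip_of_sp[fm$presence[f, ]]
    below_cnt <- as.integer(idx$below[, pres_tips, drop = FALSE] %*%
                              rep(1L, length(pres_tips)))
    cover <- which(below_cnt == length(pres_tips))
    gain <- cover[which.min(idx$clade_size[cover])]
    present <- below_cnt > 0L & idx$is_desc[gain, ]
    losses <- which(!present & idx$parent != 0L &
                      present[pmax(idx$parent, 1L)])
    gain_node[f] <- gain
    loss_branches[[f]] <- losses
    node_counts <- node_counts + present
    branch_gains[gain] <- branch_gains[gain] + 1L
    branch_losses[losses] <- branch_losses[losses] + 1L
  }
  names(gain_node) <- fm$families
  names(loss_branches) <- fm$families
  node_names <- c(idx$tips, paste0("node", (idx$ntip + 1):idx$nnode))
  structure(list(gain_node = gain_node, loss_branches = loss_branches,
                 node_counts = setNames(node_counts, node_names),
                 branch_gains = setNames(branch_gains, node_names),
                 branch_losses = setNames(branch_losses, node_names),
                 tree = tree, node_names = node_names, root = idx$root,
                 parent = idx$parent),
            class = "dollo_result")
}

#' @export
print.dollo_result <- function(x, ...) {
  cat("dollo_result:", length(x$gain_node), "families;",
      sum(x$branch_gains), "gains,", sum(x$branch_losses),
      "losses; root count", x$node_counts[x$root], "\n")
  invisible(x)
}

#' Ancestral family count at a node
#'
#' Count of families reconstructed as present at the node. Satisfies
#' `count(v) = count(parent(v)) + gains(v) - losses(v)` on every branch.
#'
#' @param result A `dollo_result`.
#' @param node Node id (ape numbering) or node name (tip label or
#'   `"node<k>"`).
#' @export
ancestral_counts <- function(result, node) {
  if (is.character(node)) {
    k <- match(node, result$node_names)
    if (is.na(k)) stop("unknown node: ", node)
    node <- k
  }
  if (node < 1 || node > length(result$node_counts))
    stop("unknown node id: ", node)
  unname(result$node_counts[node])
}

#' Phylostratigraphic relative age of each family
#'
#' A family's age is the oldest (first-listed) stratum whose species set
#' intersects the family's presence set; the ladder is ordered oldest to
#' youngest along the focal lineage.
#'
#' @param fm A [family_matrix()].
#' @param ladder Named list of character vectors (stratum name -> species),
#'   ordered oldest first.
#' @return Named factor (family -> stratum, levels in ladder order).
#' @export
assign_relative_age <- function(fm, ladder) {
  stopifnot(length(ladder) > 0, !is.null(names(ladder)))
  covered <- unique(unlist(ladder))
  if (!all(fm$species %in% covered))
    stop("species not in any stratum: ",
         paste(setdiff(fm$species, covered), collapse = ", "))
  strat <- vapply(fm$families, function(f) {
    sp <- fm$species[fm$presence[f, ]]
    for (s in names(ladder)) if (any(sp %in% ladder[[s]])) return(s)
    stop("family '", f, "' intersects no stratum")
  }, "")
  factor(strat, levels = names(ladder))
}

#' Rhythmic orthogroup membership and overlap across species
#'
#' An orthologous gene family (OGF) is rhythmic in a species iff at least
#' one of its genes in that species is rhythmic. Returns per-species
#' membership and the full inclusion-exclusion (Venn) table over the
#' requested species.
#'
#' @param rhythmic_genes_per_species Named list (species -> character
#'   vector of rhythmic gene ids).
#' @param fm A [family_matrix()].
#' @param species_subset Species to tabulate (default: names of the list).
#' @return List: `membership` (logical OGF x species matrix),
#'   `venn` (data.frame `cell` e.g. `"spA&spB"`, `count` of OGFs rhythmic
#'   in exactly that species set), `n_unmapped` (rhythmic genes not found
#'   in any family; logged and skipped).
#' @export
rhythmic_ogf_overlap <- function(rhythmic_genes_per_species, fm,
                                 species_subset = names(rhythmic_genes_per_species)) {
  stopifnot(all(species_subset %in% names(rhythmic_genes_per_species)))
  n_unmapped <- 0L
  membership <- matrix(FALSE, length(fm$families), length(species_subset),
                       dimnames = list(fm$families, species_subset))
  for (sp in species_subset) {
    genes <- rhythmic_genes_per_species[[sp]]
    fams <- fm$gene2family[genes]
    miss <- sum(is.na(fams))
    if (miss > 0) {
      message("rhythmic_ogf_overlap: ", miss, " rhythmic gene(s) of ", sp,
              " not in any family; skipped")
      n_unmapped <- n_unmapped + miss
    }
    membership[unique(fams[!is.na(fams)]), sp] <- TRUE
  }
  rhythmic_any <- rowSums(membership) > 0
  pattern <- apply(membership, 1, function(r)
    paste(species_subset[r], collapse = "&"))
  cells <- table(pattern[rhythmic_any])
  venn <- data.frame(cell = names(cells), count = as.integer(cells),
                     stringsAsFactors = FALSE)
  list(membership = membership, venn = venn, n_unmapped = n_unmapped)
}
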