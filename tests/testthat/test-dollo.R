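test_that("trivial reconstructions are forced", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  fm <- family_matrix(list(
    ALL = list(A = "gA", B = "gB", C = "gC", D = "gD"),
    ONLY_A = list(A = "gA2", B = character(0), C = character(0),
                  D = character(0))))
  dr <- dollo_reconstruct(fm, tree)
  root <- dr$root
  expect_identical(unname(dr$gain_node["ALL"]), root)
  expect_identical(sum(dr$branch_losses), 0L)
  # singleton family gained on the terminal branch to A
  expect_identical(unname(dr$gain_node["ONLY_A"]),
                   which(tree$tip.label == "A"))
  expect_identical(ancestral_counts(dr, "A"), 2L)
  expect_identical(ancestral_counts(dr, "D"), 1L)
  expect_error(ancestral_counts(dr, "nosuch"), "unknown")
})

test_that("reconstruction agrees with exhaustive single-gain enumeration", {
  set.seed(401)
  for (tree in dollo_test_trees()) {
    ntip <- length(tree$tip.label)
    for (rep in 1:40) {
      pres <- runif(ntip) < 0.5
      if (!any(pres)) pres[sample(ntip, 1)] <- TRUE
      gm <- list(F1 = setNames(lapply(seq_len(ntip), function(i)
        if (pres[i]) paste0(tree$tip.label[i], "_g") else character(0)),
        tree$tip.label))
      dr <- dollo_reconstruct(family_matrix(gm), tree)
      oracle <- dollo_oracle(tree, pres)
      expect_identical(length(dr$loss_branches$F1), as.integer(oracle$losses))
      expect_identical(unname(dr$gain_node["F1"]), oracle$gain)
    }
  }
})

test_that("ancestral counts satisfy the per-branch additivity identity", {
  cfg <- small_config(seed = 43, n_families = 80)
  sim <- simulate_family_evolution(cfg)
  dr <- dollo_reconstruct(sim$fm, sim$tree)
  for (v in seq_along(dr$node_counts)) {
    p <- dr$parent[v]
    if (p == 0) next
    expect_identical(dr$node_counts[[v]],
                     dr$node_counts[[p]] + dr$branch_gains[[v]] -
                       dr$branch_losses[[v]])
  }
  # leaf states equal observations
  for (sp in sim$fm$species)
    expect_identical(ancestral_counts(dr, sp),
                     sum(sim$fm$presence[, sp]))
})

test_that("reconstruction recovers the generative truth", {
  # loss-free evolution: exact recovery at every node
  cfg0 <- small_config(seed = 44, n_families = 80,
                       gain_loss_rates = c(1, 0))
  sim0 <- simulate_family_evolution(cfg0)
  dr0 <- dollo_reconstruct(sim0$fm, sim0$tree)
  truth_counts <- integer(length(dr0$node_counts))
  idx <- chromaforge:::tree_index(sim0$tree)
  for (f in seq_len(nrow(sim0$truth)))
    truth_counts <- truth_counts +
      idx$is_desc[sim0$truth$gain_node[f], ]
  expect_equal(unname(dr0$node_counts), truth_counts)
  # lossy evolution: parsimony can only undercount losses
  cfg1 <- small_config(seed = 45, n_families = 80,
                       gain_loss_rates = c(1, 0.1))
  sim1 <- simulate_family_evolution(cfg1)
  dr1 <- dollo_reconstruct(sim1$fm, sim1$tree)
  expect_true(all(lengths(dr1$loss_branches) <= sim1$truth$n_losses))
})

test_that("species missing from the tree raise a named error", {
  tree <- ape::read.tree(text = "((A,B),C);")
  fm <- family_matrix(list(F1 = list(A = "g1", B = character(0),
                                     Z = "g2")))
  expect_error(dollo_reconstruct(fm, tree), "Z")
})

test_that("relative age takes the oldest intersecting stratum", {
  fm <- family_matrix(list(
    OLD = list(prok = "p1", algae = "a1", focal = "f1"),
    MID = list(prok = character(0), algae = "a2", focal = "f2"),
    YOUNG = list(prok = character(0), algae = character(0), focal = "f3")))
  ladder <- list(prokaryotic = "prok", archaeplastida = "algae",
                 species_specific = "focal")
  ages <- assign_relative_age(fm, ladder)
  expect_identical(as.character(ages[c("OLD", "MID", "YOUNG")]),
                   c("prokaryotic", "archaeplastida", "species_specific"))
  # adding a species never makes a family younger
  fm2 <- family_matrix(list(
    OLD = list(prok = "p1", algae = "a1", focal = "f1"),
    MID = list(prok = character(0), algae = "a2", focal = "f2"),
    YOUNG = list(prok = character(0), algae = "a3", focal = "f3")))
  ages2 <- assign_relative_age(fm2, ladder)
  expect_true(all(as.integer(ages2) <= as.integer(ages)))
  expect_error(assign_relative_age(fm, ladder[-1]), "stratum")
})

test_that("rhythmic orthogroup overlap obeys inclusion-exclusion", {
  gm <- list(OG1 = list(s1 = c("s1_a", "s1_b"), s2 = "s2_a", s3 = "s3_a"),
             OG2 = list(s1 = "s1_c", s2 = character(0), s3 = "s3_b"),
             OG3 = list(s1 = character(0), s2 = "s2_b", s3 = "s3_c"))
  fm <- family_matrix(gm)
  # no rhythmic genes at all
  none <- rhythmic_ogf_overlap(list(s1 = character(0), s2 = character(0),
                                    s3 = character(0)), fm)
  expect_identical(nrow(none$venn), 0L)
  # OG1 rhythmic in exactly s1 and s2 -> one pairwise-exclusive cell
  r <- rhythmic_ogf_overlap(list(s1 = "s1_a", s2 = "s2_a",
                                 s3 = character(0)), fm)
  expect_identical(r$venn$cell, "s1&s2")
  expect_identical(r$venn$count, 1L)
  # random fixture: venn cells sum to the rhythmic-OGF total, and match
  # brute-force set arithmetic
  set.seed(402)
  rg <- list(s1 = sample(c("s1_a", "s1_b", "s1_c"), 2),
             s2 = sample(c("s2_a", "s2_b"), 1),
             s3 = sample(c("s3_a", "s3_b", "s3_c"), 2))
  rr <- rhythmic_ogf_overlap(rg, fm)
  expect_identical(sum(rr$venn$count),
                   sum(rowSums(rr$membership) > 0))
  brute <- lapply(names(rg), function(sp)
    unique(unname(fm$gene2family[rg[[sp]]])))
  names(brute) <- names(rg)
  for (og in rownames(rr$membership))
    for (sp in names(rg))
      expect_identical(rr$membership[og, sp], og %in% brute[[sp]])
  # unmapped rhythmic genes are counted, not fatal
  expect_message(
    rm_res <- rhythmic_ogf_overlap(list(s1 = "nonexistent_gene",
                                        s2 = character(0),
                                        s3 = character(0)), fm),
    "not in any family")
  expect_identical(rm_res$n_unmapped, 1L)
})
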