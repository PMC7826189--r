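groups_fixture <- function(labels) {
  make_taxon_groups(labels, c(QRY = "query", PAU = "other_paulinella",
                              ACY = "alpha_cyanobacteria",
                              CYA = "cyanobacteria", BAC = "bacteria",
                              EUK = "eukarya"))
}

tree_of <- function(txt) ape::read.tree(text = txt)

test_that("discard filters fire in order with the stated reasons", {
  g <- groups_fixture(c(paste0("BAC", 1:8), paste0("EUK", 1:4),
                        "QRY1", "PAU1"))
  # 9 leaves
  t9 <- tree_of("((QRY1,(BAC1,BAC2)90)95,(BAC3,(BAC4,(BAC5,(EUK1,EUK2)80)85)90)95);")
  expect_identical(apply_discard_filters(t9, g), "leaves<10")
  # 12 leaves but 4 bacteria
  t12 <- tree_of(paste0("((QRY1,(EUK1,EUK2)90)95,((BAC1,BAC2)99,",
                        "((BAC3,BAC4)98,(EUK3,(EUK4,(PAU1,",
                        "(EUK1x,EUK2x)70)75)80)85)90)95);"))
  g12 <- groups_fixture(t12$tip.label)
  expect_identical(apply_discard_filters(t12, g12), "bacteria<5")
  # two Paulinella leaves never on one side of any edge
  tp <- tree_of(paste0("(((QRY1,EUK1)90,(EUK2,EUK3)90)95,",
                       "((PAU1,BAC1)90,(BAC2,(BAC3,(BAC4,BAC5)90)90)90)95);"))
  gp <- groups_fixture(tp$tip.label)
  expect_identical(apply_discard_filters(tp, gp), "paulinella_polyphyly")
  # a clean monophyletic pair passes
  tok <- tree_of(paste0("(((QRY1,PAU1)99,(BAC1,(BAC2,BAC3)90)90)95,",
                        "((BAC4,BAC5)90,(EUK1,(EUK2,EUK3)80)85)90);"))
  gok <- groups_fixture(tok$tip.label)
  expect_identical(apply_discard_filters(tok, gok), "pass")
  expect_error(apply_discard_filters(t9, g[1:3]), "resolvable")
})

test_that("candidate clades require support, exclusivity and target proportion", {
  mk <- function(sup) tree_of(sprintf(
    "((QRY1,(BAC1,(BAC2,(BAC3,(BAC4,(BAC5,(BAC6,(BAC7,BAC8)99)99)99)99)99)99)99)%s,(EUK1,(EUK2,(EUK3,EUK4)90)90)90);",
    sup))
  g <- groups_fixture(mk(100)$tip.label)
  # support 100: the query+bacteria side qualifies
  cands <- find_target_clades(mk(100), g, sort_params(), "bacteria")
  expect_gt(nrow(cands), 0)
  expect_identical(cands$n_query[1], 1L)
  # same topology, support 50 < 70: nothing qualifies
  expect_identical(nrow(find_target_clades(mk(50), g, sort_params(),
                                           "bacteria")), 0L)
  # exclusivity below 0.95 disqualifies: 18 target of 20 leaves = 0.90
  sub <- "(BAC16,BAC17)99"
  for (i in 15:1) sub <- sprintf("(BAC%d,%s)99", i, sub)
  t20 <- tree_of(sprintf(
    "((QRY1,(EUK1,(EUK2,%s)99)99)100,(EUK3,(EUK4,EUK5)90)90);", sub))
  g20 <- groups_fixture(t20$tip.label)
  c20 <- find_target_clades(t20, g20, sort_params(), "bacteria")
  expect_false(any(c20$size == 20))
  expect_error(find_target_clades(tree_of("(A,B,C);"),
                                  groups_fixture(c("A", "B", "C")),
                                  sort_params(), "bacteria"),
               "fewer than 4")
})

test_that("verdicts match planted truth and EGT overrides HGT", {
  # query nested among alpha-cyanobacteria -> EGT
  tegt <- tree_of(paste0("((QRY1,(ACY1,(ACY2,(ACY3,ACY4)99)99)99)100,",
                         "((BAC1,(BAC2,BAC3)90)90,",
                         "(EUK1,(EUK2,EUK3)80)85)90);"))
  g <- groups_fixture(tegt$tip.label)
  out <- sort_tree(tegt, g)
  expect_identical(out$verdict, "EGT")
  expect_gte(out$clade$n_alpha, 1L)
  # query among eukaryotes -> negative
  tneg <- tree_of(paste0("(((EUK1,(QRY1,EUK2)85)90,(EUK3,EUK4)90)95,",
                         "(BAC1,(BAC2,(BAC3,(BAC4,BAC5)99)99)99)99);"))
  gneg <- groups_fixture(tneg$tip.label)
  expect_identical(sort_tree(tneg, gneg)$verdict, "negative")
})

test_that("verdicts are invariant under re-rooting and leaf permutation", {
  cfg <- small_config(seed = 51, n_gene_trees = 30)
  gt <- simulate_gene_trees(cfg)
  base <- sort_trees(gt$trees, gt$groups)
  set.seed(502)
  for (id in names(gt$trees)) {
    tr <- gt$trees[[id]]
    new_tip <- sample(tr$tip.label, 1)
    rerooted <- ape::root(tr, outgroup = new_tip, edgelabel = TRUE)
    v <- sort_tree(rerooted, gt$groups)$verdict
    expect_identical(v, base$verdict[base$tree_id == id], info = id)
  }
})

test_that("raising thresholds never creates new positives", {
  cfg <- small_config(seed = 52, n_gene_trees = 30)
  gt <- simulate_gene_trees(cfg)
  lax <- sort_trees(gt$trees, gt$groups, sort_params(min_support = 70))
  strict <- sort_trees(gt$trees, gt$groups, sort_params(min_support = 99.5))
  for (id in lax$tree_id) {
    vl <- lax$verdict[lax$tree_id == id]
    vs <- strict$verdict[strict$tree_id == id]
    if (vl == "negative") expect_identical(vs, "negative")
  }
})
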