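test_that("FASTA reading preserves order, ids and descriptions, and round-trips", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a first protein", "MKV", ">b", "MLLVV"), f)
  recs <- read_fasta(f)
  expect_identical(names(recs), c("a", "b"))
  expect_identical(as.character(recs), c("MKV", "MLLVV"))
  expect_identical(attr(recs, "descriptions"), c("first protein", ""))

  f2 <- withr::local_tempfile(fileext = ".faa")
  write_fasta(recs, f2)
  back <- read_fasta(f2)
  expect_identical(unname(back), unname(recs))
  expect_identical(names(back), names(recs))
})

test_that("FASTA reader rejects duplicate ids and handles the empty file", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a", "MKV", ">a", "MLL"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  writeLines(character(0), f)
  expect_length(read_fasta(f), 0)
})

test_that("Newick parsing keeps supports, polytomies, and rescales fractional support", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B)95,C);", f)
  tr <- read_newick(f)
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  expect_true(95 %in% node_support(tr))

  writeLines("(A,B,C);", f)
  expect_equal(read_newick(f)$Nnode, 1)  # root polytomy preserved

  writeLines("((A,B)0.95,C);", f)
  tr3 <- read_newick(f, support_scale = "fraction")
  expect_true(95 %in% node_support(tr3))

  writeLines("((A,B,C);", f)
  expect_error(read_newick(f), "[Uu]nbalanced")
})

test_that("BED intervals parse as 0-based half-open with validation", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t10\t20\tviral", f)
  iv <- read_intervals(f, "bed")
  expect_identical(iv$start, 10L)
  expect_identical(iv$end, 20L)
  expect_identical(iv$label, "viral")
  expect_equal(iv$end - iv$start, 10)  # half-open length

  writeLines("c1\t20\t10\tx", f)
  expect_error(read_intervals(f, "bed"), "line 1")
  writeLines("c1\t-5\t10\tx", f)
  expect_error(read_intervals(f, "bed"), "line 1")
})

test_that("SAM records convert via reference-consuming CIGAR ops; unmapped are skipped", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "r1\t0\tc1\t11\t60\t5M2I5M\t*\t0\t0\t*\t*",
               "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
               "r3\t0\tc1\t1\t60\t3M2D4M\t*\t0\t0\t*\t*"), f)
  iv <- suppressMessages(read_intervals(f, "sam"))
  # POS=11 (1-based), CIGAR 5M2I5M consumes 10 reference bases
  expect_identical(iv$start[iv$label == "r1"], 10L)
  expect_identical(iv$end[iv$label == "r1"], 20L)
  # 3M2D4M consumes 9
  expect_identical(iv$end[iv$label == "r3"], 9L)
  expect_false("r2" %in% iv$label)
  expect_identical(attr(iv, "n_unmapped"), 1L)
})

test_that("orthogroup tables parse presence and gene maps with integrity checks", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family\tS1\tS2\tS3",
               "OG1\tg1,g2\t\tg7",
               "OG2\tg3\tg4\t"), f)
  fm <- read_ogf_table(f)
  expect_true(fm$presence["OG1", "S1"])
  expect_false(fm$presence["OG1", "S2"])
  expect_true(fm$presence["OG1", "S3"])
  expect_identical(unname(fm$gene2family["g7"]), "OG1")

  # all-empty family rejected with warning
  writeLines(c("family\tS1\tS2", "OG1\tg1\t", "OG2\t\t"), f)
  expect_warning(fm2 <- read_ogf_table(f), "zero species")
  expect_identical(fm2$families, "OG1")

  # duplicate gene across families is an error naming the gene
  writeLines(c("family\tS1\tS2", "OG1\tg1\t", "OG2\tg1\t"), f)
  expect_error(read_ogf_table(f), "g1")
})

test_that("orthogroup and count tables round-trip through their writers", {
  gm <- list(OG1 = list(S1 = c("g1", "g2"), S2 = character(0)),
             OG2 = list(S1 = "g3", S2 = "g4"))
  fm <- family_matrix(gm)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ogf_table(fm, f)
  back <- read_ogf_table(f)
  expect_identical(back$presence, fm$presence)
  expect_identical(back$gene_map, fm$gene_map)

  vals <- matrix(1:12, 2, 6,
                 dimnames = list(c("gA", "gB"), NULL))
  samples <- data.frame(condition = "ctrl",
                        timepoint_h = rep(c(0, 6, 12), each = 2),
                        replicate = rep(1:2, 3))
  cf <- withr::local_tempfile(fileext = ".tsv")
  write_counts(vals, samples, cf)
  cc <- read_counts(cf)
  expect_equal(unname(cc$values), unname(vals))
  expect_equal(cc$samples$timepoint_h, samples$timepoint_h)
  expect_equal(cc$samples$replicate, samples$replicate)
})
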