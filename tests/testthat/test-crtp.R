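test_that("profile emissions follow the pseudocount formula", {
  # toy column (A, A, C), pseudocount 0.5: P(A) = 2.5/13, P(C) = 1.5/13
  aln <- c(s1 = "AMK", s2 = "AMK", s3 = "CMK")
  p <- build_profile(aln, background = rep(1 / 20, 20) |>
                       setNames(chromaforge:::AA_ALPHABET[1:20]))
  pA <- unname(2 ^ p$emissions[1, "A"] * (1 / 20))
  pC <- unname(2 ^ p$emissions[1, "C"] * (1 / 20))
  expect_equal(pA, 2.5 / 13)
  expect_equal(pC, 1.5 / 13)
  # each emission row is a distribution
  for (k in 1:3) {
    probs <- 2 ^ p$emissions[k, 1:20] / 20
    expect_equal(sum(probs), 1, tolerance = 1e-9)
  }
})

test_that("gap-heavy columns are excluded from match states", {
  aln <- c(a = "A-K", b = "A-K", c = "AMK", d = "AMK", e = "A-K")
  # column 2 has 60% gaps -> not a match state
  p <- build_profile(aln)
  expect_identical(p$match_cols, c(1L, 3L))
  # identical gap-free sequences: all columns match, consensus maximal
  p2 <- build_profile(c(a = "MKV", b = "MKV", c = "MKV"))
  expect_identical(p2$match_cols, 1:3)
  expect_identical(p2$consensus, "MKV")
  expect_identical(chromaforge:::AA_ALPHABET[apply(p2$emissions[, 1:20], 1,
                                                   which.max)],
                   c("M", "K", "V"))
  expect_error(build_profile(c(a = "---", b = "---", c = "AAA")),
               "match state")
})

test_that("profile Viterbi equals exhaustive path enumeration on toy profiles", {
  set.seed(301)
  for (trial in 1:25) {
    L <- sample(2:5, 1)
    seqs <- vapply(1:3, function(i) random_protein(L), "")
    names(seqs) <- paste0("s", 1:3)
    p <- build_profile(seqs)
    target <- random_protein(sample((L + 1):8, 1))
    got <- profile_score(p, target)
    expect_equal(got$score, viterbi_score_oracle(p, target),
                 tolerance = 1e-9, info = trial)
  }
})

test_that("calibration is deterministic and matches its own null", {
  set.seed(302)
  seqs <- setNames(vapply(1:5, function(i) random_protein(40), ""),
                   paste0("s", 1:5))
  p <- build_profile(seqs)
  c1 <- calibrate_profile(p, n_decoys = 300, decoy_length = 150, seed = 4)
  c2 <- calibrate_profile(p, n_decoys = 300, decoy_length = 150, seed = 4)
  expect_identical(c1$calibration, c2$calibration)
  # median E-value of fresh decoys (drawn from the same background as
  # the calibration decoys) is near the fitted null's prediction
  n_db <- 100
  ev <- replicate(200, {
    dec <- paste(sample(AA20, 150, TRUE, prob = c1$background[AA20]),
                 collapse = "")
    profile_evalue(c1, profile_score(c1, dec)$score, n_db)
  })
  expect_gt(median(ev) / n_db, 0.25)
  expect_lt(median(ev) / n_db, 1.5)
  expect_error(scan_proteome(p, c(x = "MKVL")), "not calibrated")
})

crtp_fixture <- local({
  cfg <- small_config(seed = 31)
  sim <- simulate_proteome(cfg)
  res <- crtp_pipeline(sim$proteome, sim$seed_crtps,
                       n_decoys = 300, decoy_length = 300, seed = 31)
  list(cfg = cfg, sim = sim, res = res)
})

test_that("seed discovery recovers planted proteins and fails cleanly on noise", {
  sim <- crtp_fixture$sim
  seeds <- crtp_fixture$res$seeds
  planted <- sim$truth$planted$id
  # every seed is a crTP-carrying protein (planted or decoy; both carry
  # the block), and no background protein sneaks in
  carriers <- c(planted, sim$truth$decoys$id)
  expect_true(all(seeds$ids %in% carriers))
  expect_gt(length(intersect(seeds$ids, planted)), 0)
  # exact copies of validated crTPs are self-recovered
  prot2 <- c(sim$seed_crtps, bg = random_protein(300))
  s2 <- find_seeds(sim$seed_crtps, prot2)
  expect_setequal(s2$ids, names(sim$seed_crtps))
  # unrelated proteome: zero seeds is an error advising relaxation
  set.seed(303)
  unrelated <- setNames(vapply(1:10, function(i) random_protein(200), ""),
                        paste0("u", 1:10))
  expect_error(find_seeds(sim$seed_crtps, unrelated), "relax")
})

test_that("the profile scan applies the E-value, start and mature filters", {
  sim <- crtp_fixture$sim
  res <- crtp_fixture$res
  planted <- sim$truth$planted$id
  pred <- res$combined$protein_id
  tp <- length(intersect(pred, planted))
  expect_gte(tp / length(pred), 0.9)
  expect_gte(tp / length(planted), 0.9)
  # planted hits start near the true block start
  hits <- res$hmm_hits[res$hmm_hits$protein_id %in% planted, ]
  tru <- sim$truth$planted[match(hits$protein_id, sim$truth$planted$id), ]
  expect_true(all(abs(hits$start - tru$start) <= 5))
  # every decoy is rejected, with the planted defect among the reasons
  rej <- attr(res$hmm_hits, "rejections")
  for (i in seq_len(nrow(sim$truth$decoys))) {
    d <- sim$truth$decoys[i, ]
    expect_false(d$id %in% pred)
    reasons <- rej$reasons[rej$protein_id == d$id]
    expect_length(reasons, 1)
    expect_match(reasons, d$expected_reason)
  }
  # determinism: re-running the scan reproduces the hit table exactly
  again <- scan_proteome(res$profile, sim$proteome)
  expect_identical(again$protein_id, res$hmm_hits$protein_id)
  expect_identical(again$bits, res$hmm_hits$bits)
})

test_that("reciprocal extension recovers diverged crTPs the profile misses", {
  sim <- crtp_fixture$sim
  cfg <- crtp_fixture$cfg
  profile <- crtp_fixture$res$profile
  # a protein whose block is 35% mutated: below the profile cutoff but
  # within pairwise reach of a strong hit's crTP region
  set.seed(304)
  diverged <- paste0(random_protein(10),
                     chromaforge:::mutate_seq(sim$consensus, 0.35),
                     random_protein(300))
  prot <- c(sim$proteome, div1 = diverged)
  hmm <- scan_proteome(profile, prot)
  ext <- extend_candidates(hmm, prot)
  if (!"div1" %in% hmm$protein_id) {
    expect_true("div1" %in% ext$protein_id)
    # verify by direct pairwise E-value computation against one query
    q <- hmm[1, ]
    qseq <- substr(prot[[q$protein_id]], q$start + 1, q$end)
    hit <- smith_waterman(qseq, diverged)
    ev <- estimate_evalue(hit$score, nchar(qseq),
                          sum(nchar(prot[!names(prot) %in% hmm$protein_id])))
    expect_lt(ev, 1e-10)
  }
  # proteins found by the profile are never duplicated by the extension
  expect_length(intersect(ext$protein_id, hmm$protein_id), 0)
  # when the scan already found everything, the extension adds nothing
  expect_identical(nrow(crtp_fixture$res$extension_hits), 0L)
})

test_that("shared candidates are reciprocal best hits, each id used once", {
  set.seed(305)
  base <- vapply(1:6, function(i) random_protein(120), "")
  a <- setNames(base, paste0("a", 1:6))
  b <- setNames(vapply(base, chromaforge:::mutate_seq, "", rate = 0.2),
                paste0("b", 1:6))
  # identical sets pair perfectly
  pairs_id <- shared_candidates(a, setNames(a, paste0("b", 1:6)))
  expect_identical(nrow(pairs_id), 6L)
  # orthologs at 80% identity plus species-specific extras
  b_plus <- c(b, bx = random_protein(120))
  a_plus <- c(a, ax = random_protein(120))
  pairs <- shared_candidates(a_plus, b_plus)
  expect_setequal(pairs$a_id, paste0("a", 1:6))
  expect_identical(sub("b", "a", pairs$b_id), pairs$a_id)
  expect_false(any(duplicated(pairs$a_id)) || any(duplicated(pairs$b_id)))
  # unrelated sets yield nothing
  set.seed(306)
  u <- setNames(vapply(1:4, function(i) random_protein(100), ""),
                paste0("u", 1:4))
  v <- setNames(vapply(1:4, function(i) random_protein(100), ""),
                paste0("v", 1:4))
  expect_identical(nrow(shared_candidates(u, v)), 0L)
})
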