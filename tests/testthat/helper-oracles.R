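# Independent reference implementations used to validate the package's
# optimized routines. These deliberately use the plainest possible
# algorithms (full quadratic DP, exhaustive enumeration, per-base
# counting) and share no code with the implementation under test.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# Textbook Gotoh affine-gap local alignment, score only. A gap of length
# k costs open + k * ext.
sw_score_oracle <- function(q, t, smat, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + smat[qc[i - 1], tc[j - 1]],
                   E[i, j], F[i, j])
    if (H[i, j] > best) best <- H[i, j]
  }
  best
}

# Exhaustive enumeration of all state paths through a small profile
# (global in profile, local in sequence), mirroring the model: entry at
# M1 (free) or via an initial D chain (t_md then t_dd), exit at M_L or
# D_L, I from M/I only, D from M/D only.
viterbi_score_oracle <- function(profile, seq) {
  s <- match(strsplit(seq, "")[[1]], chromaforge:::AA_ALPHABET)
  emis <- profile$emissions
  tr <- profile$trans  # mm mi im ii md dm dd
  L <- nrow(emis); n <- length(s)
  best <- -Inf
  rec <- function(j, i, state, sc) {
    if (j == L && state %in% c("M", "D")) best <<- max(best, sc)
    if (state == "M") {
      if (j < L && i < n)
        rec(j + 1, i + 1, "M", sc + tr[1] + emis[j + 1, s[i + 1]])
      if (i < n) rec(j, i + 1, "I", sc + tr[2])
      if (j < L) rec(j + 1, i, "D", sc + tr[5])
    } else if (state == "I") {
      if (j < L && i < n)
        rec(j + 1, i + 1, "M", sc + tr[3] + emis[j + 1, s[i + 1]])
      if (i < n) rec(j, i + 1, "I", sc + tr[4])
    } else {
      if (j < L && i < n)
        rec(j + 1, i + 1, "M", sc + tr[6] + emis[j + 1, s[i + 1]])
      if (j < L) rec(j + 1, i, "D", sc + tr[7])
    }
  }
  for (i0 in seq_len(n)) rec(1, i0, "M", emis[1, s[i0]])
  for (i0 in 0:n) rec(1, i0, "D", tr[5])
  best
}

# Exhaustive single-gain (Dollo) enumeration: all assignments of
# present/absent to internal nodes consistent with the observed leaves,
# restricted to those where the present set is one connected subtree
# (single origin), minimizing the number of loss branches.
dollo_oracle <- function(tree, presence_tips) {
  ntip <- length(tree$tip.label)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode)
  parent[edge[, 2]] <- edge[, 1]
  root <- setdiff(edge[, 1], edge[, 2])[1]
  parent[root] <- 0L
  internals <- (ntip + 1):nnode
  best_losses <- Inf; best_gain <- NA_integer_
  for (mask in 0:(2^length(internals) - 1)) {
    state <- logical(nnode)
    state[seq_len(ntip)] <- presence_tips
    state[internals] <- bitwAnd(mask, 2^(seq_along(internals) - 1)) > 0
    pres <- which(state)
    if (length(pres) == 0) next
    tops <- pres[vapply(pres, function(v)
      v == root || !state[parent[v]], logical(1))]
    if (length(tops) != 1) next
    losses <- sum(vapply(seq_len(nnode), function(v)
      v != root && !state[v] && state[parent[v]], logical(1)))
    if (losses < best_losses) { best_losses <- losses; best_gain <- tops }
  }
  list(losses = best_losses, gain = best_gain)
}

# All permutations of 1..n as a matrix (rows).
perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  p <- perms(n - 1)
  out <- matrix(0L, n * nrow(p), n)
  r <- 0
  for (k in seq_len(n)) {
    block <- cbind(k, p + (p >= k))
    out[r + seq_len(nrow(p)), ] <- block
    r <- r + nrow(p)
  }
  out
}

# Exact S distribution against a tied reference by enumerating all
# permutations of distinct data values.
jtk_null_oracle <- function(tie_pattern) {
  n <- sum(tie_pattern)
  ref <- rep(seq_along(tie_pattern), tie_pattern)
  P <- perms(n)
  pair_i <- combn(n, 2)
  sgn_ref <- sign(ref[pair_i[2, ]] - ref[pair_i[1, ]])
  S <- integer(nrow(P))
  for (r in seq_len(nrow(P))) {
    x <- P[r, ]
    S[r] <- sum(sign(x[pair_i[2, ]] - x[pair_i[1, ]]) * sgn_ref)
  }
  tab <- table(S)
  data.frame(S = as.integer(names(tab)),
             prob = as.numeric(tab) / nrow(P))
}

# Random 0-based half-open intervals on contig "c1".
random_intervals <- function(n, contig_len, label) {
  if (n == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), label = character(),
                      stringsAsFactors = FALSE))
  start <- sample(0:(contig_len - 2), n, replace = TRUE)
  len <- sample(1:50, n, replace = TRUE)
  data.frame(contig = "c1", start = start,
             end = pmin(start + len, contig_len), label = label,
             stringsAsFactors = FALSE)
}

# Per-base breadth of coverage oracle on a single contig.
breadth_oracle <- function(regions, alignments, contig_len) {
  covered <- logical(contig_len)
  for (i in seq_len(nrow(alignments)))
    covered[(alignments$start[i] + 1):alignments$end[i]] <- TRUE
  out <- list()
  for (cl in unique(regions$label)) {
    in_class <- logical(contig_len)
    sub <- regions[regions$label == cl, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      in_class[(sub$start[i] + 1):sub$end[i]] <- TRUE
    out[[cl]] <- list(total = sum(in_class),
                      covered = sum(in_class & covered))
  }
  out
}

# Small fixed tree set spanning 3-6 leaves, caterpillar, balanced and
# polytomous shapes, used for exhaustive Dollo checks.
dollo_test_trees <- function() {
  txt <- c("((A,B),C);",
           "(A,B,C);",
           "(((A,B),C),D);",
           "((A,B),(C,D));",
           "(A,B,C,D);",
           "((((A,B),C),D),E);",
           "(((A,B),(C,D)),E);",
           "((A,B,C),(D,E));",
           "(((((A,B),C),D),E),F);",
           "(((A,B),(C,D)),(E,F));",
           "((A,B),(C,D),(E,F));")
  lapply(txt, function(x) ape::read.tree(text = x))
}

# Compact synthetic configuration for fast unit tests; any default can
# be overridden through `...`.
small_config <- function(seed = 11, ...) {
  defaults <- list(n_proteins = 60, n_planted_crtp = 10,
                   n_decoy_crtp = 6, n_seed_crtps = 4, crtp_length = 120,
                   n_genes_expr = 60, frac_rhythmic = 0.25,
                   n_gene_trees = 20, genome_len = 40000)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, c(list(seed = seed), args))
}
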