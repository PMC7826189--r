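#' Find crTP seed proteins in a proteome
#'
#' Each validated chromatophore transit peptide (crTP) is used as a local
#' alignment query against the proteome; proteome members hit at
#' `E <= cutoff` become the seed set for profile construction. The matched
#' region on each seed (0-based half-open) is retained.
#'
#' @param validated_crtps Named character vector of validated crTP
#'   sequences.
#' @param proteome Named character vector of proteins.
#' @param cutoff Seed-discovery E-value cutoff (default 1e-20).
#' @param matrix Scoring scheme from [default_submatrix()].
#' @return List with `ids`, `records` (seed protein sequences), and
#'   `regions` (data.frame `id`, `start`, `end`, `evalue`), ordered by
#'   discovery (proteome) order.
#' @export
find_seeds <- function(validated_crtps, proteome, cutoff = 1e-20,
                       matrix = default_submatrix()) {
  stopifnot(length(validated_crtps) > 0, length(proteome) > 0)
  db_res <- sum(nchar(proteome))
  go <- abs(matrix$gap_open)
  ge <- abs(matrix$gap_extend)
  enc_val <- lapply(validated_crtps, aa_encode)
  rows <- lapply(names(proteome), function(pid) {
    pe <- aa_encode(proteome[[pid]])
    best <- NULL; best_q <- NULL
    for (vid in names(validated_crtps)) {
      r <- sw_align_cpp(enc_val[[vid]], pe, matrix$matrix, go, ge)
      if (r$score > 0 && (is.null(best) || r$score > best$score)) {
        best <- r; best_q <- vid
      }
    }
    if (is.null(best)) return(NULL)
    ev <- estimate_evalue(best$score, nchar(validated_crtps[[best_q]]),
                          db_res, matrix$lambda, matrix$K)
    if (ev > cutoff) return(NULL)
    data.frame(id = pid, start = best$t_start, end = best$t_end,
               evalue = ev, stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, rows)
  if (is.null(regions))
    stop("no seed proteins found at E <= ", cutoff,
         "; consider relaxing the cutoff")
  list(ids = regions$id, records = proteome[regions$id], regions = regions)
}

#' Progressive master-slave alignment of seed crTP regions
#'
#' The first seed region (discovery order) is the master; every other
#' region is aligned to it globally and projected onto the master's
#' columns (insertions relative to the master are dropped). The result is
#' a fixed-width alignment suitable for [build_profile()]. A hand-curated
#' alignment supplied by the user takes precedence over this automatic one.
#'
#' @param regions Named character vector of seed region sequences, master
#'   first.
#' @return Character vector of equal-length aligned sequences (gap `-`).
#' @export
align_seeds <- function(regions) {
  stopifnot(length(regions) >= 2)
  master <- regions[[1]]
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  out <- vapply(seq_along(regions), function(i) {
    if (i == 1L) return(master)
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(regions[[i]]),
      subject = Biostrings::AAString(master),
      substitutionMatrix = data_env$BLOSUM62,
      gapOpening = 10, gapExtension = 1, type = "global")
    sl <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    ms <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    paste(sl[ms != "-"], collapse = "")
  }, "")
  names(out) <- names(regions)
  stopifnot(all(nchar(out) == nchar(master)))
  out
}

#' Build a position-specific profile from an aligned seed set
#'
#' Columns with at most 50% gaps become match states. Match emissions are
#' `(count + pseudocount) / (n_residues + 20 * pseudocount)` with
#' pseudocount 0.5, stored as log2-odds against the background (X has
#' log-odds 0). Transition penalties are estimated from the alignment's
#' gap structure with Laplace (+1) smoothing and are shared across
#' positions.
#'
#' @param alignment Character vector of equal-length aligned sequences.
#' @param background Named residue frequency vector (20 residues, sums
#'   to 1). Defaults to the package background.
#' @param pseudocount Emission pseudocount (default 0.5).
#' @param max_gap_frac Maximum gap fraction for a match column (default
#'   0.5).
#' @return Object of class `crtp_profile`: `emissions` (L x 21 log2-odds),
#'   `trans` (log2 of mm, mi, im, ii, md, dm, dd), `background`,
#'   `match_cols`, `consensus`, `calibration` (NULL until
#'   [calibrate_profile()]).
#' @export
build_profile <- function(alignment, background = AA_BACKGROUND,
                          pseudocount = 0.5, max_gap_frac = 0.5) {
  stopifnot(length(alignment) >= 2,
            length(unique(nchar(alignment))) == 1)
  background <- background / sum(background)
  chars <- do.call(rbind, strsplit(toupper(alignment), ""))
  gap_frac <- colMeans(chars == "-")
  match_cols <- which(gap_frac <= max_gap_frac)
  if (length(match_cols) == 0)
    stop("no alignment column qualifies as a match state (all > ",
         max_gap_frac * 100, "% gaps)")
  aa20 <- AA_ALPHABET[1:20]
  emis <- matrix(0, length(match_cols), 21,
                 dimnames = list(NULL, AA_ALPHABET))
  consensus <- character(length(match_cols))
  for (k in seq_along(match_cols)) {
    col <- chars[, match_cols[k]]
    res <- col[col != "-" & col != "X"]
    cnt <- table(factor(res, levels = aa20))
    p <- (as.numeric(cnt) + pseudocount) /
      (length(res) + 20 * pseudocount)
    emis[k, aa20] <- log2(p / background[aa20])
    consensus[k] <- aa20[which.max(p)]
  }
  # transition counts from the per-row state strings (M/D on match
  # columns, I for residues on non-match columns)
  cnt <- c(mm = 0, mi = 0, im = 0, ii = 0, md = 0, dm = 0, dd = 0)
  is_match_col <- seq_len(ncol(chars)) %in% match_cols
  for (r in seq_len(nrow(chars))) {
    states <- character(0)
    for (j in seq_len(ncol(chars))) {
      if (is_match_col[j]) states <- c(states, if (chars[r, j] == "-") "D" else "M")
      else if (chars[r, j] != "-") states <- c(states, "I")
    }
    if (length(states) > 1) {
      pairs <- paste0(tolower(states[-length(states)]),
                      tolower(states[-1]))
      for (p in pairs) if (p %in% names(cnt)) cnt[p] <- cnt[p] + 1
    }
  }
  from_m <- cnt["mm"] + cnt["mi"] + cnt["md"] + 3
  from_i <- cnt["im"] + cnt["ii"] + 2
  from_d <- cnt["dm"] + cnt["dd"] + 2
  trans <- log2(c(mm = (cnt[["mm"]] + 1) / from_m,
                  mi = (cnt[["mi"]] + 1) / from_m,
                  im = (cnt[["im"]] + 1) / from_i,
                  ii = (cnt[["ii"]] + 1) / from_i,
                  md = (cnt[["md"]] + 1) / from_m,
                  dm = (cnt[["dm"]] + 1) / from_d,
                  dd = (cnt[["dd"]] + 1) / from_d))
  structure(list(emissions = emis, trans = unname(trans),
                 trans_named = trans, background = background,
                 match_cols = match_cols,
                 consensus = paste(consensus, collapse = ""),
                 calibration = NULL),
            class = "crtp_profile")
}

#' @export
print.crtp_profile <- function(x, ...) {
  cat("crtp_profile:", nrow(x$emissions), "match states;",
      if (is.null(x$calibration)) "uncalibrated"
      else sprintf("calibrated (mu=%.2f, lambda=%.4f)",
                   x$calibration$mu, x$calibration$lambda), "\n")
  invisible(x)
}

#' Viterbi score of a profile against one sequence
#'
#' Best-path alignment, global in the profile and local in the sequence
#' (free flanks), over match/insert/delete states.
#'
#' @param profile A `crtp_profile`.
#' @param seq Protein sequence (character string).
#' @return List with `score` (bits), `start`, `end` (0-based half-open
#'   emitted region).
#' @export
profile_score <- function(profile, seq) {
  profile_viterbi_cpp(aa_encode(seq), profile$emissions, profile$trans)
}

#' Calibrate a profile's score distribution on random decoys
#'
#' Decoy sequences are drawn i.i.d. from the background distribution, the
#' maximum Viterbi score is computed for each, and a Gumbel distribution is
#' fitted by the method of moments. E-values are subsequently
#' `n_db * exp(-lambda * (S - mu))`.
#'
#' @param profile A `crtp_profile`.
#' @param n_decoys Number of decoys (default 1000, minimum 200).
#' @param decoy_length Decoy length in residues (default 400).
#' @param seed RNG seed for decoy generation.
#' @return The profile with its `calibration` slot filled.
#' @export
calibrate_profile <- function(profile, n_decoys = 1000, decoy_length = 400,
                              seed = 1) {
  stopifnot(n_decoys >= 200)
  aa20 <- AA_ALPHABET[1:20]
  scores <- with_seed(seed, vapply(seq_len(n_decoys), function(i) {
    dec <- paste(sample(aa20, decoy_length, replace = TRUE,
                        prob = profile$background[aa20]), collapse = "")
    profile_score(profile, dec)$score
  }, 0))
  s <- sd(scores)
  if (s < 1e-9) stop("degenerate decoy score distribution (all identical)")
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.5772156649 / lambda
  profile$calibration <- list(mu = mu, lambda = lambda,
                              n_decoys = n_decoys,
                              decoy_length = decoy_length, seed = seed)
  profile
}

#' E-value of a profile Viterbi score
#'
#' @param profile Calibrated `crtp_profile`.
#' @param score Viterbi score in bits.
#' @param n_db Number of sequences in the searched database.
#' @export
profile_evalue <- function(profile, score, n_db) {
  if (is.null(profile$calibration)) stop("profile is not calibrated")
  cal <- profile$calibration
  n_db * exp(-cal$lambda * (score - cal$mu))
}

#' Scan a proteome for crTP-bearing proteins
#'
#' Each protein receives its best Viterbi profile alignment; a hit is
#' reported when (i) its E-value is at most `evalue_cutoff`, (ii) the
#' profile match starts within the first `max_start` residues (1-based
#' position <= `max_start`, i.e. 0-based start < `max_start`), and (iii)
#' the mature protein downstream of the match is longer than `min_mature`
#' residues. At most one hit per protein. Proteins failing any filter are
#' recorded with their failed filters in the `"rejections"` attribute.
#'
#' @param profile Calibrated `crtp_profile`.
#' @param proteome Named character vector of proteins.
#' @param evalue_cutoff Default 1e-5.
#' @param max_start Default 50 (1-based).
#' @param min_mature Default 250; mature length must strictly exceed it.
#' @return Data.frame of hits: `protein_id`, `bits`, `evalue`, `start`,
#'   `end` (0-based half-open), `mature_length`, `route = "hmm"`; attribute
#'   `rejections` is a data.frame (`protein_id`, `reasons` --
#'   comma-separated subset of `evalue`, `start`, `mature`).
#' @export
scan_proteome <- function(profile, proteome, evalue_cutoff = 1e-5,
                          max_start = 50, min_mature = 250) {
  if (is.null(profile$calibration)) stop("profile is not calibrated")
  n_db <- length(proteome)
  hits <- vector("list", n_db)
  rej <- vector("list", n_db)
  for (k in seq_along(proteome)) {
    pid <- names(proteome)[k]
    v <- profile_score(profile, proteome[[k]])
    ev <- profile_evalue(profile, v$score, n_db)
    mature <- nchar(proteome[[k]]) - v$end
    fails <- c(if (ev > evalue_cutoff) "evalue",
               if (v$start >= max_start) "start",
               if (mature <= min_mature) "mature")
    if (length(fails) == 0) {
      hits[[k]] <- data.frame(protein_id = pid, bits = v$score,
                              evalue = ev, start = v$start, end = v$end,
                              mature_length = mature, route = "hmm",
                              stringsAsFactors = FALSE)
    } else {
      rej[[k]] <- data.frame(protein_id = pid,
                             reasons = paste(fails, collapse = ","),
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)]) %||%
    empty_hits_df()
  attr(out, "rejections") <-
    do.call(rbind, rej[!vapply(rej, is.null, TRUE)]) %||%
    data.frame(protein_id = character(), reasons = character())
  out
}

empty_hits_df <- function() {
  data.frame(protein_id = character(), bits = numeric(),
             evalue = numeric(), start = integer(), end = integer(),
             mature_length = integer(), route = character(),
             stringsAsFactors = FALSE)
}

#' Reciprocal extension of the profile hit set
#'
#' Each profile hit's crTP region is used as a pairwise local-alignment
#' query against the proteins not already found by the profile scan.
#' Targets hit at `E <= cutoff` whose matched region passes the same
#' start/mature filters are appended (best E per target kept).
#'
#' @param hmm_hits Hit table from [scan_proteome()].
#' @param proteome Named character vector (the full proteome).
#' @param cutoff Pairwise E-value cutoff (default 1e-10).
#' @param max_start,min_mature Positional filters, as in
#'   [scan_proteome()].
#' @param matrix Scoring scheme.
#' @return Data.frame in the same shape as [scan_proteome()] hits with
#'   `route = "extension"`.
#' @export
extend_candidates <- function(hmm_hits, proteome, cutoff = 1e-10,
                              max_start = 50, min_mature = 250,
                              matrix = default_submatrix()) {
  targets <- proteome[setdiff(names(proteome), hmm_hits$protein_id)]
  if (length(targets) == 0 || nrow(hmm_hits) == 0) return(empty_hits_df())
  queries <- setNames(
    substr(proteome[hmm_hits$protein_id], hmm_hits$start + 1, hmm_hits$end),
    hmm_hits$protein_id)
  db_res <- sum(nchar(targets))
  go <- abs(matrix$gap_open)
  ge <- abs(matrix$gap_extend)
  enc_q <- lapply(queries, aa_encode)
  rows <- lapply(names(targets), function(tid) {
    te <- aa_encode(targets[[tid]])
    best <- NULL; best_q <- NULL
    for (qid in names(queries)) {
      r <- sw_align_cpp(enc_q[[qid]], te, matrix$matrix, go, ge)
      if (r$score > 0 && (is.null(best) || r$score > best$score)) {
        best <- r; best_q <- qid
      }
    }
    if (is.null(best)) return(NULL)
    ev <- estimate_evalue(best$score, nchar(queries[[best_q]]), db_res,
                          matrix$lambda, matrix$K)
    mature <- nchar(targets[[tid]]) - best$t_end
    if (ev > cutoff || best$t_start >= max_start || mature <= min_mature)
      return(NULL)
    data.frame(protein_id = tid,
               bits = bit_score(best$score, matrix$lambda, matrix$K),
               evalue = ev, start = best$t_start, end = best$t_end,
               mature_length = mature, route = "extension",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||% empty_hits_df()
}

#' Reciprocal-best-hit pairing of two candidate sets
#'
#' Full-length pairwise local alignment between the two sets; a pair is
#' reported when each member is the other's best hit (by raw score) and
#' the E-value is at most `cutoff`. Each id appears in at most one pair.
#'
#' @param seqs_a,seqs_b Named character vectors of candidate proteins from
#'   the two species.
#' @param cutoff E-value cutoff (default 1e-10).
#' @param matrix Scoring scheme.
#' @return Data.frame: `a_id`, `b_id`, `evalue`.
#' @export
shared_candidates <- function(seqs_a, seqs_b, cutoff = 1e-10,
                              matrix = default_submatrix()) {
  if (length(seqs_a) == 0 || length(seqs_b) == 0)
    return(data.frame(a_id = character(), b_id = character(),
                      evalue = numeric()))
  ab <- search_best_hits(seqs_a, seqs_b, matrix)
  ba <- search_best_hits(seqs_b, seqs_a, matrix)
  back <- setNames(ba$target_id, ba$query_id)
  keep <- ab$evalue <= cutoff & !is.na(back[ab$target_id]) &
    back[ab$target_id] == ab$query_id
  out <- ab[keep, c("query_id", "target_id", "evalue")]
  names(out) <- c("a_id", "b_id", "evalue")
  rownames(out) <- NULL
  out
}

#' Full crTP import-candidate prediction pipeline
#'
#' Seed discovery, automatic seed alignment (unless one is supplied),
#' profile construction, decoy calibration, the calibrated profile scan
#' with positional filters, and the reciprocal pairwise extension, in
#' order.
#'
#' @param proteome Named character vector of proteins to search.
#' @param validated_crtps Named character vector of validated crTPs from a
#'   related species.
#' @param seed_alignment Optional pre-aligned seed set (overrides
#'   [align_seeds()]).
#' @param evalue_seed,evalue_scan,evalue_extend Stage E-value cutoffs
#'   (defaults 1e-20, 1e-5, 1e-10).
#' @param max_start,min_mature Positional filters (defaults 50, 250).
#' @param n_decoys,decoy_length,seed Calibration settings.
#' @return Object of class `import_candidates`: `hmm_hits`,
#'   `extension_hits`, `combined` (row-bound, disjoint by construction),
#'   `profile`, `seeds`.
#' @export
crtp_pipeline <- function(proteome, validated_crtps, seed_alignment = NULL,
                          evalue_seed = 1e-20, evalue_scan = 1e-5,
                          evalue_extend = 1e-10, max_start = 50,
                          min_mature = 250, n_decoys = 1000,
                          decoy_length = 400, seed = 1) {
  seeds <- find_seeds(validated_crtps, proteome, evalue_seed)
  if (is.null(seed_alignment)) {
    regions <- setNames(
      substr(proteome[seeds$regions$id], seeds$regions$start + 1,
             seeds$regions$end),
      seeds$regions$id)
    seed_alignment <- align_seeds(regions)
  }
  profile <- build_profile(seed_alignment)
  profile <- calibrate_profile(profile, n_decoys = n_decoys,
                               decoy_length = decoy_length, seed = seed)
  hmm_hits <- scan_proteome(profile, proteome, evalue_scan, max_start,
                            min_mature)
  ext_hits <- extend_candidates(hmm_hits, proteome, evalue_extend,
                                max_start, min_mature)
  combined <- rbind(hmm_hits, ext_hits)
  attr(combined, "rejections") <- attr(hmm_hits, "rejections")
  structure(list(hmm_hits = hmm_hits, extension_hits = ext_hits,
                 combined = combined, profile = profile, seeds = seeds),
            class = "import_candidates")
}

#' @export
print.import_candidates <- function(x, ...) {
  cat("import_candidates:", nrow(x$hmm_hits), "profile hits +",
      nrow(x$extension_hits), "extension hits =",
      nrow(x$combined), "candidates\n")
  invisible(x)
}
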