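#' Default protein scoring scheme
#'
#' BLOSUM62 with affine gap penalties (open -11, extend -1) and gapped
#' Karlin-Altschul parameters lambda = 0.267, K = 0.041 -- the standard
#' defaults of BLASTP-style searches. X scores 0 against every residue.
#'
#' @return List with `matrix` (21 x 21 over the package alphabet),
#'   `gap_open`, `gap_extend` (negative integers), `lambda`, `K`.
#' @export
default_submatrix <- function() {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  b62 <- data_env$BLOSUM62
  m <- matrix(0, 21, 21, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  aa20 <- AA_ALPHABET[1:20]
  m[aa20, aa20] <- b62[aa20, aa20]
  m["X", ] <- 0; m[, "X"] <- 0
  list(matrix = m, gap_open = -11L, gap_extend = -1L,
       lambda = 0.267, K = 0.041)
}

#' Optimal local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman. A gap of length k costs
#' `|gap_open| + k * |gap_extend|`. Ties are broken toward the smallest
#' `(q_start, t_start)`. Coordinates are 0-based half-open.
#'
#' @param query,target Protein sequences (single character strings).
#' @param matrix Scoring scheme from [default_submatrix()].
#' @return List with `score`, `q_start`, `q_end`, `t_start`, `t_end`, or
#'   `NULL` when no positive-scoring local alignment exists.
#' @export
smith_waterman <- function(query, target, matrix = default_submatrix()) {
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  res <- sw_align_cpp(aa_encode(query), aa_encode(target), matrix$matrix,
                      abs(matrix$gap_open),
                      abs(matrix$gap_extend))
  if (res$score <= 0) return(NULL)
  res
}

#' Approximate E-value of a local alignment score
#'
#' Karlin-Altschul: `E = K * m * n * exp(-lambda * S)` with `m` the query
#' length and `n` the total residue count of the database. No edge-effect
#' correction is applied.
#'
#' @param score Raw alignment score.
#' @param query_len Query length (residues).
#' @param db_residues Total residues in the searched database.
#' @param lambda,K Karlin-Altschul parameters.
#' @return Positive number (monotone decreasing in `score`).
#' @export
estimate_evalue <- function(score, query_len, db_residues,
                            lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0, query_len > 0, db_residues > 0)
  K * query_len * db_residues * exp(-lambda * score)
}

#' Bit score of a raw alignment score
#' @inheritParams estimate_evalue
#' @export
bit_score <- function(score, lambda = 0.267, K = 0.041) {
  (lambda * score - log(K)) / log(2)
}

#' All-vs-all best hits between a query set and a database
#'
#' For each query, the best-scoring local alignment over all database
#' sequences, with its E-value against the whole database.
#'
#' @param queries,db Named character vectors of protein sequences.
#' @param matrix Scoring scheme.
#' @return Data.frame: `query_id`, `target_id`, `score`, `bits`, `evalue`,
#'   `q_start`, `q_end`, `t_start`, `t_end` (0-based half-open); one row per
#'   query with at least one positive-scoring hit.
#' @export
search_best_hits <- function(queries, db, matrix = default_submatrix()) {
  stopifnot(length(db) > 0)
  db_res <- sum(nchar(db))
  enc_db <- lapply(db, aa_encode)
  go <- abs(matrix$gap_open)
  ge <- abs(matrix$gap_extend)
  rows <- lapply(names(queries), function(qid) {
    qe <- aa_encode(queries[[qid]])
    best <- NULL
    for (tid in names(db)) {
      r <- sw_align_cpp(qe, enc_db[[tid]], matrix$matrix, go, ge)
      if (r$score > 0 && (is.null(best) || r$score > best$score)) {
        best <- r; best$target_id <- tid
      }
    }
    if (is.null(best)) return(NULL)
    data.frame(query_id = qid, target_id = best$target_id,
               score = best$score,
               bits = bit_score(best$score, matrix$lambda, matrix$K),
               evalue = estimate_evalue(best$score, nchar(queries[[qid]]),
                                        db_res, matrix$lambda, matrix$K),
               q_start = best$q_start, q_end = best$q_end,
               t_start = best$t_start, t_end = best$t_end,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(query_id = character(), target_id = character(),
               score = numeric(), bits = numeric(), evalue = numeric(),
               q_start = integer(), q_end = integer(),
               t_start = integer(), t_end = integer())
}

#' Partition proteins into dark and annotated
#'
#' A protein is "dark" when its best local-alignment hit against the
#' reference database has E-value above the cutoff, or it has no hit at
#' all; otherwise it is annotated. The partition is exhaustive and
#' disjoint.
#'
#' @param proteins Named character vector of query proteins.
#' @param reference_db Named character vector of reference proteins.
#' @param cutoff E-value cutoff (default 1e-5).
#' @param matrix Scoring scheme.
#' @return List with character vectors `dark` and `annotated` (protein
#'   ids) and the best-hit table in `hits`.
#' @export
classify_dark <- function(proteins, reference_db, cutoff = 1e-5,
                          matrix = default_submatrix()) {
  if (length(proteins) == 0)
    return(list(dark = character(0), annotated = character(0),
                hits = NULL))
  if (length(reference_db) == 0) {
    warning("empty reference database: all proteins classified dark")
    return(list(dark = names(proteins), annotated = character(0),
                hits = NULL))
  }
  hits <- search_best_hits(proteins, reference_db, matrix)
  annotated <- hits$query_id[hits$evalue <= cutoff]
  dark <- setdiff(names(proteins), annotated)
  list(dark = dark, annotated = annotated, hits = hits)
}
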