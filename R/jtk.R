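#' Exact null distribution of the Kendall S statistic against a tied
#' reference
#'
#' Distribution of `S = sum_{i<j} sign(x_i - x_j) * sign(r_i - r_j)` when
#' the data ranks are an exchangeable random permutation (no data ties)
#' and the reference `r` has tie groups of the given sizes. The
#' Jonckheere-Terpstra statistic `J` over the reference groups satisfies
#' `S = 2J - M`, with `M` the number of between-group pairs, and the exact
#' count of orderings with a given `J` is the coefficient of a product of
#' Gaussian-binomial polynomials (Harding's recursion, the core of
#' JTK-style tests).
#'
#' @param tie_pattern Integer vector of reference tie-group sizes (ordered
#'   by reference value; the distribution does not depend on the order).
#' @return Data.frame with columns `S` and `prob`; symmetric about 0,
#'   total mass 1.
#' @export
jtk_null_distribution <- function(tie_pattern) {
  tie_pattern <- as.integer(tie_pattern)
  if (length(tie_pattern) == 0 || any(tie_pattern < 1))
    stop("empty or invalid tie pattern")
  k <- length(tie_pattern)
  M <- if (k < 2) 0L else
    sum(outer(tie_pattern, tie_pattern)[upper.tri(diag(k))])
  poly <- 1
  N <- tie_pattern[1]
  if (k > 1) for (i in 2:k) {
    poly <- poly_mult(poly, gaussian_binomial(N, tie_pattern[i]))
    N <- N + tie_pattern[i]
  }
  probs <- poly / sum(poly)
  data.frame(S = 2 * (seq_along(probs) - 1) - M, prob = probs)
}

# Coefficients (exponents 0..m*n) of the Gaussian binomial
# [m + n choose n]_q via G(a, b) = G(a-1, b) + q^a * G(a, b-1).
gaussian_binomial <- function(m, n) {
  old <- rep(list(1), m + 1)           # G(a, 0) = 1
  for (b in seq_len(n)) {
    new <- vector("list", m + 1)
    new[[1]] <- 1                      # G(0, b) = 1
    for (a in seq_len(m))
      new[[a + 1]] <- poly_add(new[[a]], c(numeric(a), old[[a + 1]]))
    old <- new
  }
  old[[m + 1]]
}

poly_add <- function(p, q) {
  n <- max(length(p), length(q))
  c(p, numeric(n - length(p))) + c(q, numeric(n - length(q)))
}

poly_mult <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1)
  for (i in seq_along(p)) if (p[i] != 0) {
    idx <- i:(i + length(q) - 1)
    out[idx] <- out[idx] + p[i] * q
  }
  out
}

# Kendall S between data x and reference r (sign(0) = 0 convention for
# data ties; reference ties define the null's tie pattern).
kendall_s <- function(x, r) {
  sum(sign(outer(x, x, "-")) * sign(outer(r, r, "-"))) / 2
}

# Two-tailed exact p-value P(|S_null| >= |s|) for a reference tie pattern.
jtk_pvalue <- function(s, null_dist) {
  sum(null_dist$prob[abs(null_dist$S) >= abs(s) - 1e-9])
}

#' JTK rhythmicity test for one gene's time course
#'
#' For every phase lag and cosine sign, the reference value of observation
#' `i` is `cos(2*pi*(t_i - lag)/period)`; replicates at a timepoint share
#' the reference value, creating the tie pattern of the exact null.
#' `S` is the Kendall sum against that reference, the raw p-value is the
#' exact two-tailed mass from [jtk_null_distribution()], and the reported
#' p-value is the minimum over the distinct lag/sign references multiplied
#' by their number (Bonferroni), capped at 1. Lag/sign combinations with
#' identical reference rankings (a sign flip equals a half-period lag
#' shift when the lags cover the full period) are counted once.
#'
#' @param values Numeric vector of observations (all replicates pooled).
#' @param timepoints_h Numeric vector, hours, parallel to `values`.
#' @param lags_h Candidate phase lags (default: the distinct timepoints).
#' @param period_h Period in hours (default 24).
#' @return List of class `jtk_result`: `S`, `tau` (`S` over the maximum
#'   attainable given the reference tie pattern), `best_lag_h`, `p`
#'   (Bonferroni-adjusted), `p_raw`, `n_tests`.
#' @export
jtk_test <- function(values, timepoints_h, lags_h = NULL, period_h = 24) {
  stopifnot(length(values) == length(timepoints_h),
            all(is.finite(values)))
  tps <- sort(unique(timepoints_h))
  if (length(tps) < 3) stop("need at least 3 distinct timepoints")
  if (is.null(lags_h)) lags_h <- tps
  combos <- expand.grid(lag = lags_h, sgn = c(1, -1))
  # rounding zaps numerically-nonzero cosines at quarter periods so that
  # equal reference values are exact ties
  refs <- lapply(seq_len(nrow(combos)), function(i)
    round(combos$sgn[i] *
            cos(2 * pi * (timepoints_h - combos$lag[i]) / period_h), 9))
  # deduplicate identical reference rankings
  keys <- vapply(refs, function(r) paste(rank(r), collapse = ","), "")
  keep <- !duplicated(keys)
  refs <- refs[keep]
  combos <- combos[keep, , drop = FALSE]
  n_tests <- length(refs)
  null_cache <- list()
  best <- list(p = Inf, S = 0, tau = 0, lag = lags_h[1])
  for (i in seq_along(refs)) {
    r <- refs[[i]]
    pat <- sort(table(r), decreasing = TRUE)
    key <- paste(sort(as.integer(pat)), collapse = ",")
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- jtk_null_distribution(as.integer(pat))
    nd <- null_cache[[key]]
    s <- kendall_s(values, r)
    maxS <- max(nd$S)
    p <- jtk_pvalue(s, nd)
    if (p < best$p || (p == best$p && s > best$S)) {
      eff_lag <- if (combos$sgn[i] > 0) combos$lag[i]
                 else (combos$lag[i] + period_h / 2) %% period_h
      best <- list(p = p, S = s, tau = if (maxS > 0) s / maxS else 0,
                   lag = eff_lag)
    }
  }
  structure(list(S = best$S, tau = best$tau, best_lag_h = best$lag,
                 p = min(1, best$p * n_tests), p_raw = best$p,
                 n_tests = n_tests),
            class = "jtk_result")
}

#' @export
print.jtk_result <- function(x, ...) {
  cat(sprintf("jtk_result: S=%g tau=%.3f lag=%gh p=%.3g (raw %.3g x %d)\n",
              x$S, x$tau, x$best_lag_h, x$p, x$p_raw, x$n_tests))
  invisible(x)
}

#' JTK scan over a count matrix
#'
#' Applies [jtk_test()] to every gene of a replicated time-course matrix.
#' The Bonferroni adjustment inside each test covers lags and signs; no
#' adjustment across genes is applied to `p` (a Benjamini-Hochberg column
#' `p_bh` is emitted alongside for convenience).
#'
#' @param values Numeric genes x samples matrix.
#' @param samples Sample metadata data.frame with `timepoint_h` (as from
#'   [read_counts()]).
#' @param lags_h,period_h Passed to [jtk_test()].
#' @return Data.frame: `gene_id`, `S`, `tau`, `best_lag_h`, `p`, `p_bh`.
#' @export
jtk_scan <- function(values, samples, lags_h = NULL, period_h = 24) {
  stopifnot(nrow(samples) == ncol(values))
  res <- lapply(rownames(values), function(g) {
    r <- jtk_test(values[g, ], samples$timepoint_h, lags_h, period_h)
    data.frame(gene_id = g, S = r$S, tau = r$tau,
               best_lag_h = r$best_lag_h, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- p.adjust(out$p, method = "BH")
  out
}

#' Filter a differential-expression table
#'
#' Keeps genes with `padj < padj_max` and `|log2fc| > min_abs_log2fc`
#' (both strict, matching the conventional "padj < 0.05 and |log2FC| > 1"
#' rule).
#'
#' @param table Data.frame with `gene_id`, `log2fc`, `padj`.
#' @param padj_max Default 0.05.
#' @param min_abs_log2fc Default 1.
#' @return Character vector of gene ids.
#' @export
filter_degs <- function(table, padj_max = 0.05, min_abs_log2fc = 1) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(table)))
  bad <- which(is.na(table$padj) | table$padj < 0 | table$padj > 1)
  if (length(bad) > 0)
    stop("padj outside [0, 1] at row(s): ", paste(head(bad, 5), collapse = ", "))
  unique(table$gene_id[table$padj < padj_max &
                         abs(table$log2fc) > min_abs_log2fc])
}

#' Intersection of differentially expressed and rhythmic gene sets
#'
#' @param deg_genes,rhythmic_genes Character vectors of gene ids.
#' @return Character vector (the intersection); input and output sizes are
#'   reported via `message()`.
#' @export
intersect_deg_rhythmic <- function(deg_genes, rhythmic_genes) {
  out <- intersect(deg_genes, rhythmic_genes)
  message("intersect_deg_rhythmic: |DEG|=", length(unique(deg_genes)),
          " |rhythmic|=", length(unique(rhythmic_genes)),
          " |overlap|=", length(out))
  out
}
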