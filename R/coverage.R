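# Convert a 0-based half-open interval frame to an IRanges list per
# contig (1-based closed internally; widths are preserved).
intervals_to_iranges <- function(df) {
  split(IRanges::IRanges(start = df$start + 1L, end = df$end),
        df$contig)
}

#' Breadth of coverage per region class
#'
#' For every region class (interval label), the fraction of its bases
#' covered by at least one alignment interval. Same-class regions and
#' alignments are unioned first (interval sweep via `IRanges::reduce`),
#' so duplicate alignments never change the result. Alignments on contigs
#' absent from the region map are excluded and counted.
#'
#' @param regions Data.frame of class-labeled intervals (`contig`,
#'   `start`, `end`, `label`; 0-based half-open).
#' @param alignments Data.frame of alignment intervals (same convention).
#' @param mode_label Free-text label of the alignment mode (e.g.
#'   `"global"`, `"local"`), carried into the report.
#' @return Data.frame of class `coverage_report`: `class`, `total_bases`,
#'   `covered_bases`, `fraction`; attributes `mode_label` and
#'   `n_excluded_alignments`.
#' @export
breadth_per_class <- function(regions, alignments, mode_label = "default") {
  stopifnot(all(c("contig", "start", "end", "label") %in% names(regions)))
  known <- unique(regions$contig)
  excl <- 0L
  if (nrow(alignments) > 0) {
    drop <- !(alignments$contig %in% known)
    excl <- sum(drop)
    if (excl > 0) {
      message("breadth_per_class: excluded ", excl,
              " alignment(s) on contig(s) absent from the region map")
      alignments <- alignments[!drop, , drop = FALSE]
    }
  }
  aln_by_contig <- if (nrow(alignments) > 0)
    lapply(intervals_to_iranges(alignments), IRanges::reduce)
  else list()
  classes <- sort(unique(regions$label))
  rows <- lapply(classes, function(cl) {
    sub <- regions[regions$label == cl, , drop = FALSE]
    reg <- lapply(intervals_to_iranges(sub), IRanges::reduce)
    total <- sum(vapply(reg, function(r) sum(IRanges::width(r)), 0))
    covered <- 0
    for (ctg in names(reg)) {
      a <- aln_by_contig[[ctg]]
      if (is.null(a)) next
      covered <- covered +
        sum(IRanges::width(IRanges::intersect(reg[[ctg]], a)))
    }
    data.frame(class = cl, total_bases = total, covered_bases = covered,
               fraction = covered / total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mode_label") <- mode_label
  attr(out, "n_excluded_alignments") <- excl
  class(out) <- c("coverage_report", class(out))
  out
}

#' Extract one class row from a coverage report, keeping the mode label
#'
#' @param report A `coverage_report`.
#' @param class Class label to extract.
#' @return One-row `coverage_report`.
#' @export
coverage_class <- function(report, class) {
  row <- report[report$class == class, , drop = FALSE]
  if (nrow(row) != 1) stop("class not found in report: ", class)
  attr(row, "mode_label") <- attr(report, "mode_label")
  class(row) <- c("coverage_report", "data.frame")
  row
}

#' Compare breadth of coverage between two region classes
#'
#' Purely descriptive (fractions, ratio, absolute difference); both
#' reports must carry the same alignment-mode label.
#'
#' @param report_a,report_b Single-class rows of a `coverage_report`
#'   (data.frames with one row each).
#' @return List: `class_a`, `class_b`, `fraction_a`, `fraction_b`,
#'   `ratio` (a/b), `abs_difference`, `mode_label`.
#' @export
compare_classes <- function(report_a, report_b) {
  ma <- attr(report_a, "mode_label")
  mb <- attr(report_b, "mode_label")
  if (!identical(ma, mb))
    stop("mismatched mode labels: '", ma, "' vs '", mb, "'")
  stopifnot(nrow(report_a) == 1, nrow(report_b) == 1)
  fa <- report_a$fraction; fb <- report_b$fraction
  list(class_a = report_a$class, class_b = report_b$class,
       fraction_a = fa, fraction_b = fb,
       ratio = if (fb > 0) fa / fb else ifelse(fa > 0, Inf, NaN),
       abs_difference = abs(fa - fb), mode_label = ma)
}
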