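#' Read a protein or nucleotide FASTA file
#'
#' Sequences are returned as a named character vector (names are the ids,
#' i.e. the first whitespace-delimited token of each header); the remainder
#' of each header is kept in the `"descriptions"` attribute. Record order is
#' preserved and whitespace inside sequences is stripped.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences with a `descriptions`
#'   attribute (character vector parallel to the records).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    out <- character(0)
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs)))
    stop("empty sequence for id: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  names(seqs) <- ids
  attr(seqs, "descriptions") <- desc
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences (as from [read_fasta()]).
#' @param path Output path. Lines are wrapped at 60 columns, LF endings.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  desc <- attr(seqs, "descriptions") %||% rep("", length(seqs))
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    hdr <- if (nzchar(desc[i])) paste(names(seqs)[i], desc[i]) else names(seqs)[i]
    body <- gsub("(.{60})", "\\1\n", seqs[[i]])
    body <- sub("\n$", "", body)
    writeLines(c(paste0(">", hdr), body), con, sep = "\n")
  }
  invisible(path)
}

#' Read a Newick tree with support values
#'
#' Internal-node labels that parse as numbers are interpreted as node
#' support. Supports are normalized to the 0-100 scale: `support_scale =
#' "fraction"` declares that the file stores supports in [0, 1] and rescales
#' them by 100.
#'
#' @param path Path to a file holding a single Newick string.
#' @param support_scale Either `"percent"` (default; values already 0-100)
#'   or `"fraction"` (values in 0-1, rescaled).
#' @return An [ape::read.tree()] `phylo` object; `node.label` holds the
#'   normalized supports as character (empty where absent).
#' @export
read_newick <- function(path, support_scale = c("percent", "fraction")) {
  support_scale <- match.arg(support_scale)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  read_newick_text(txt, support_scale)
}

read_newick_text <- function(txt, support_scale = "percent") {
  open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (open != close)
    stop("unbalanced parentheses in Newick string (", open, " '(' vs ",
         close, " ')')")
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("failed to parse Newick string")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$node.label) && support_scale == "fraction") {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label <- ifelse(is.na(sup), tree$node.label,
                              format(sup * 100, trim = TRUE))
  }
  tree
}

#' Numeric node supports of a tree
#'
#' @param tree A `phylo` object.
#' @return Numeric vector over internal nodes (in `ape` node order,
#'   root first); `NA` where no numeric label is present.
#' @export
node_support <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object (node labels are written as-is).
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read genomic intervals from BED or SAM
#'
#' All intervals are 0-based half-open (BED convention); SAM alignments are
#' converted at the boundary using the reference-consuming CIGAR operations
#' (M, D, N, =, X). Unmapped SAM records (FLAG bit 0x4) are skipped and
#' their count is reported via `message()` and the `"n_unmapped"` attribute.
#' Strand is ignored throughout.
#'
#' @param path Input path.
#' @param format `"bed"` (3- or 4-column) or `"sam"`.
#' @return A data.frame with columns `contig`, `start`, `end`, `label`.
#' @export
read_intervals <- function(path, format = c("bed", "sam")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "bed") {
    keep <- which(nzchar(lines) & !startsWith(lines, "#") &
                    !startsWith(lines, "track"))
    out <- lapply(keep, function(ln) {
      f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L) stop("BED line ", ln, ": fewer than 3 fields")
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end) || start < 0L || start >= end)
        stop("BED line ", ln, ": invalid coordinates (need 0 <= start < end)")
      data.frame(contig = f[1], start = start, end = end,
                 label = if (length(f) >= 4L) f[4] else "",
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out) %||%
      data.frame(contig = character(), start = integer(), end = integer(),
                 label = character(), stringsAsFactors = FALSE)
    attr(res, "n_unmapped") <- 0L
    return(res)
  }
  # SAM subset: QNAME FLAG RNAME POS MAPQ CIGAR ...
  keep <- which(nzchar(lines) & !startsWith(lines, "@"))
  n_unmapped <- 0L
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) stop("SAM line ", ln, ": fewer than 6 fields")
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) stop("SAM line ", ln, ": bad FLAG")
    if (bitwAnd(flag, 4L) != 0L) { n_unmapped <- n_unmapped + 1L; next }
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(pos) || pos < 1L) stop("SAM line ", ln, ": bad POS")
    ref_len <- cigar_reference_width(f[6])
    if (ref_len <= 0L) stop("SAM line ", ln, ": CIGAR consumes no reference")
    out[[k]] <- data.frame(contig = f[3], start = pos - 1L,
                           end = pos - 1L + ref_len, label = f[1],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (n_unmapped > 0L)
    message("read_intervals: skipped ", n_unmapped, " unmapped SAM record(s)")
  res <- do.call(rbind, out) %||%
    data.frame(contig = character(), start = integer(), end = integer(),
               label = character(), stringsAsFactors = FALSE)
  attr(res, "n_unmapped") <- n_unmapped
  res
}

# Reference-consuming width of a CIGAR string (ops M, D, N, =, X).
cigar_reference_width <- function(cigar) {
  if (cigar == "*") return(0L)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(ops)) != nchar(cigar)) stop("malformed CIGAR: ", cigar)
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

#' Write intervals to a 4-column BED file
#'
#' @param intervals Data.frame with `contig`, `start`, `end`, `label`
#'   (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(intervals)))
  lab <- intervals$label %||% rep(".", nrow(intervals))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(intervals$contig, intervals$start, intervals$end, lab,
                   sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read an OrthoFinder-style orthogroup table
#'
#' The file has a header row of species names (first column names the
#' family), one row per family, and cells holding comma-separated gene ids
#' (empty cell = family absent from that species). Families present in zero
#' species are dropped with a warning; a gene id occurring in two families
#' is an error.
#'
#' @param path Path to the TSV file.
#' @return A `family_matrix` object; see [family_matrix()].
#' @export
read_ogf_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  species <- colnames(tab)[-1]
  fam_ids <- tab[[1]]
  gene_map <- lapply(seq_len(nrow(tab)), function(i) {
    cells <- as.character(tab[i, -1])
    g <- lapply(cells, function(x) {
      if (is.na(x) || !nzchar(x)) character(0)
      else trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    })
    names(g) <- species
    g
  })
  names(gene_map) <- fam_ids
  family_matrix(gene_map)
}

#' Construct a family presence/absence matrix from a gene map
#'
#' @param gene_map Named list (one element per family) of named lists (one
#'   element per species) of character vectors of gene ids; an empty vector
#'   means the family is absent from that species.
#' @return Object of class `family_matrix` with elements `presence`
#'   (logical families x species matrix), `gene_map`, `families`, `species`,
#'   and `gene2family` (named character vector).
#' @export
family_matrix <- function(gene_map) {
  stopifnot(length(gene_map) > 0L)
  species <- names(gene_map[[1]])
  presence <- t(vapply(gene_map, function(g) {
    lengths(g[species]) > 0L
  }, logical(length(species))))
  colnames(presence) <- species
  empty <- rowSums(presence) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty),
            " family(ies) present in zero species: ",
            paste(head(names(gene_map)[empty], 5), collapse = ", "))
    gene_map <- gene_map[!empty]
    presence <- presence[!empty, , drop = FALSE]
  }
  all_genes <- unlist(lapply(gene_map, unlist), use.names = FALSE)
  fam_of_gene <- rep(names(gene_map),
                     vapply(gene_map, function(g) length(unlist(g)), integer(1)))
  if (anyDuplicated(all_genes)) {
    dup <- all_genes[duplicated(all_genes)][1]
    stop("gene '", dup, "' appears in more than one family: ",
         paste(unique(fam_of_gene[all_genes == dup]), collapse = ", "))
  }
  structure(list(presence = presence, gene_map = gene_map,
                 families = rownames(presence), species = species,
                 gene2family = setNames(fam_of_gene, all_genes)),
            class = "family_matrix")
}

#' @export
print.family_matrix <- function(x, ...) {
  cat("family_matrix:", length(x$families), "families x",
      length(x$species), "species;",
      length(x$gene2family), "genes\n")
  invisible(x)
}

#' Write a family matrix as an orthogroup TSV
#'
#' @param fm A `family_matrix`.
#' @param path Output path.
#' @export
write_ogf_table <- function(fm, path) {
  rows <- vapply(fm$gene_map, function(g) {
    paste(vapply(g[fm$species], paste, "", collapse = ","), collapse = "\t")
  }, "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(c("family", fm$species), collapse = "\t"),
               paste(names(rows), rows, sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read a replicated time-course count table
#'
#' Expects a TSV with a `gene` column and one column per sample named
#' `<condition>_t<hours>_r<replicate>` (e.g. `ctrl_t6_r2`).
#'
#' @param path Path to the TSV.
#' @return List with `values` (numeric genes x samples matrix) and
#'   `samples` (data.frame: `condition`, `timepoint_h`, `replicate`).
#' @export
read_counts <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- genes
  parse_sample_names(colnames(vals))  # validates
  list(values = vals, samples = parse_sample_names(colnames(vals)))
}

parse_sample_names <- function(nm) {
  m <- regmatches(nm, regexec("^(.+)_t([0-9.]+)_r([0-9]+)$", nm))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("sample name(s) not of the form <condition>_t<hours>_r<rep>: ",
         paste(nm[bad], collapse = ", "))
  data.frame(sample = nm,
             condition = vapply(m, `[`, "", 2),
             timepoint_h = as.numeric(vapply(m, `[`, "", 3)),
             replicate = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Write a count matrix with sample metadata encoded in column names
#'
#' @param values Numeric genes x samples matrix.
#' @param samples Data.frame with `condition`, `timepoint_h`, `replicate`
#'   (rows parallel to columns of `values`).
#' @param path Output path.
#' @export
write_counts <- function(values, samples, path) {
  cn <- sprintf("%s_t%g_r%d", samples$condition, samples$timepoint_h,
                samples$replicate)
  df <- data.frame(gene = rownames(values), values, check.names = FALSE)
  colnames(df) <- c("gene", cn)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}
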