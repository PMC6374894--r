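#' @useDynLib reodeg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats p.adjust pbinom dhyper phyper rlnorm rnbinom quantile median
#' @importFrom utils read.table write.table
NULL

## ---- expression matrix container -------------------------------------------

## An expression matrix is a plain numeric matrix, genes in rows (unique
## rownames) and samples in columns (unique colnames), all values finite
## and >= 0.  Helper validates and normalises.
validate_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must carry gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene id: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample id: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(x) | x < 0)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop("negative or non-finite value at gene '", rownames(x)[i],
         "', sample '", colnames(x)[j], "'", call. = FALSE)
  }
  x
}

#' Read a gene-by-sample expression matrix from delimited text
#'
#' Expects the first column to hold gene identifiers and the header row to
#' hold sample identifiers.  All remaining cells must be finite, non-negative
#' numbers (raw counts for RNA-seq, normalized intensities for arrays).
#'
#' @param path Path to the file.
#' @param fmt Either `"tsv"` (default) or `"csv"`.
#' @return A numeric matrix with gene rownames and sample colnames, in file
#'   order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_expression_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path, fmt = c("tsv", "csv")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (fmt == "tsv") "\t" else ","
  raw <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "")
  if (ncol(raw) < 2L) stop("no sample columns in ", path, call. = FALSE)
  gene_ids <- raw[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  sample_ids <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop("non-numeric cell '", col[bad[1L]], "' at gene '",
           gene_ids[bad[1L]], "', sample '", sample_ids[j], "'",
           call. = FALSE)
    vals[, j] <- num
  }
  validate_expression_matrix(vals)
}

#' Write an expression matrix as delimited text
#'
#' Values are written with full double precision (`%.17g`) so that a
#' write/read round trip reproduces the matrix bit-for-bit.
#'
#' @param x Numeric gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @param fmt `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, fmt = c("tsv", "csv")) {
  fmt <- match.arg(fmt)
  x <- validate_expression_matrix(x)
  sep <- if (fmt == "tsv") "\t" else ","
  chr <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  lines <- c(paste(c("gene_id", colnames(x)), collapse = sep),
             paste(rownames(x), apply(chr, 1L, paste, collapse = sep),
                   sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene transcript lengths
#'
#' Two-column tab-separated file: gene identifier and transcript length in
#' base pairs.
#'
#' @param path Path to the file.
#' @return Named integer vector of lengths (bp).
#' @export
read_gene_lengths <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, check.names = FALSE,
                    colClasses = c("character", "numeric"))
  lens <- tab[[2L]]
  names(lens) <- tab[[1L]]
  if (anyDuplicated(names(lens)))
    stop("duplicate gene id in lengths file: ",
         names(lens)[duplicated(names(lens))][1L], call. = FALSE)
  if (any(!is.finite(lens) | lens <= 0))
    stop("transcript lengths must be positive", call. = FALSE)
  lens
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' RPKM for gene g in sample k is
#' `count / ((column total / 1e6) * (length_bp / 1e3))`.  Optionally
#' log2-transformed after adding a pseudocount.  The log2 map is strictly
#' monotone for any positive pseudocount, so within-sample orderings (and
#' hence all REO-based results) are unaffected by `pseudocount`.
#'
#' @param counts Raw count matrix (genes x samples).
#' @param lengths Named vector of transcript lengths in bp covering every
#'   gene in `counts` (see [read_gene_lengths()]).
#' @param log2_transform If `TRUE`, return `log2(RPKM + pseudocount)`.
#' @param pseudocount Positive offset used by the log2 transform.
#' @return Matrix of (log2) RPKM values with the same dimnames as `counts`.
#' @export
compute_rpkm <- function(counts, lengths, log2_transform = FALSE,
                         pseudocount = 1) {
  counts <- validate_expression_matrix(counts, "counts")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop("missing transcript length for gene '", missing[1L], "'",
         call. = FALSE)
  len <- lengths[rownames(counts)]
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample '", colnames(counts)[which(totals == 0)[1L]],
         "' has zero total count", call. = FALSE)
  rpkm <- sweep(counts, 2L, totals / 1e6, "/") / (len / 1e3)
  if (log2_transform) {
    if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
    rpkm <- log2(rpkm + pseudocount)
  }
  rpkm
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the per-rank cross-sample mean.  Tied values within a column receive the
#' mean of the rank-values they span.
#'
#' @param x Numeric matrix with at least two samples.
#' @return Quantile-normalized matrix with unchanged dimnames.
#' @export
quantile_normalize <- function(x) {
  x <- validate_expression_matrix(x)
  if (ncol(x) < 2L)
    stop("quantile normalization needs at least two samples", call. = FALSE)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Drop genes observed in too few samples
#'
#' A gene is removed when its count is zero in strictly more than
#' `max_zero_fraction` of the samples; a gene at exactly the threshold is
#' retained.  Retained genes keep their original order.
#'
#' @param counts Count matrix (genes x samples).
#' @param max_zero_fraction Maximum tolerated fraction of zero-count
#'   samples (default 0.75).
#' @return The filtered matrix (possibly with zero rows).
#' @export
filter_low_expression <- function(counts, max_zero_fraction = 0.75) {
  counts <- validate_expression_matrix(counts, "counts")
  zero_frac <- rowMeans(counts == 0)
  counts[zero_frac <= max_zero_fraction, , drop = FALSE]
}

## ---- gene sets --------------------------------------------------------------

#' Read a gene-set collection from a GMT file
#'
#' Standard tab-separated GMT: set id, description, then member genes.
#' Duplicate members within a set are dropped with a warning; empty sets are
#' an error.
#'
#' @param path Path to the `.gmt` file.
#' @return A named list of character vectors (members per set) with a
#'   `"description"` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate set id in GMT: ", ids[duplicated(ids)][1L], call. = FALSE)
  desc <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "",
                 character(1L))
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members))
      stop("gene set '", f[[1L]], "' has no members", call. = FALSE)
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", f[[1L]], "' dropped",
              call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- ids
  names(desc) <- ids
  attr(sets, "description") <- desc
  sets
}
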