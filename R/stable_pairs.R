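## Stable REO pairs: gene pairs whose within-sample ordering recurs in
## significantly more samples of a phenotype than chance.

#' Upper-tail binomial probability for a REO pattern
#'
#' Probability of observing the majority ordering in at least `s` of `n`
#' informative samples under the null that either ordering is equally likely:
#' `P(X >= s)` for `X ~ Binomial(n, p0)`, computed by exact summation.
#'
#' @param s Number of samples supporting the ordering (0 <= s <= n).
#' @param n Number of informative (non-tied) samples; must be positive.
#' @param p0 Null probability of the ordering (default 0.5).
#' @return The upper-tail probability; vectorized over `s` and `n`.
#' @examples
#' binomial_reo_pvalue(10, 10)   # 2^-10
#' binomial_reo_pvalue(7, 10)    # 176/1024
#' @export
binomial_reo_pvalue <- function(s, n, p0 = 0.5) {
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must lie in (0, 1)", call. = FALSE)
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(s < 0 | s > n)) stop("s must satisfy 0 <= s <= n", call. = FALSE)
  pbinom(s - 1, n, p0, lower.tail = FALSE)
}

## canonical (lexicographic) gene order plus upper-triangle index vectors
pair_index_vectors <- function(g) {
  i <- rep.int(seq_len(g - 1L), (g - 1L):1L)
  j <- sequence((g - 1L):1L, from = 2:g)
  list(i = i, j = j)
}

#' Per-pair ordering support counts
#'
#' For every unordered gene pair, counts the samples in which the first gene
#' (lexicographically smaller id) is strictly above the second (`s_ij`), the
#' reverse (`s_ji`), and their sum `n_eff`.  Samples where the two values tie
#' exactly support neither ordering and are excluded from both counts.
#'
#' @param x Expression matrix (genes x samples), at least 2 genes and 1
#'   sample.
#' @return A data frame with one row per unordered pair: `gene_i`, `gene_j`
#'   (with `gene_i < gene_j` lexicographically), `s_ij`, `s_ji`, `n_eff`.
#' @export
pair_support_counts <- function(x) {
  x <- validate_expression_matrix(x)
  if (nrow(x) < 2L) stop("need at least two genes", call. = FALSE)
  if (ncol(x) < 1L) stop("need at least one sample", call. = FALSE)
  x <- x[order(rownames(x)), , drop = FALSE]
  cnt <- pair_counts_cpp(x)
  idx <- pair_index_vectors(nrow(x))
  data.frame(gene_i = rownames(x)[idx$i],
             gene_j = rownames(x)[idx$j],
             s_ij = cnt$s_ij,
             s_ji = cnt$n_eff - cnt$s_ij,
             n_eff = cnt$n_eff,
             stringsAsFactors = FALSE)
}

#' Identify significantly stable REO gene pairs in one phenotype
#'
#' For each unordered gene pair the majority ordering is tested with the
#' exact binomial upper tail ([binomial_reo_pvalue()]); p-values are
#' Benjamini-Hochberg adjusted across all pairs with at least one
#' informative sample, and pairs with adjusted value at most `fdr` are kept
#' in their majority direction.  Pairs split exactly evenly between the two
#' orderings are never stable.
#'
#' @param x Expression matrix (genes x samples).
#' @param fdr FDR threshold for stable pairs (default 0.05).
#' @param p0 Null ordering probability (default 0.5).
#' @param phenotype Optional label stored in the result.
#' @return An object of class `"StablePairSet"`: a list with `pairs` (data
#'   frame `winner`, `loser`, `s`, `n_eff`, `p`, `q`, ordered
#'   lexicographically), `genes` (sorted universe), `phenotype`, `fdr`,
#'   `n_samples` and `n_tested` (pairs entering the BH family).
#' @export
identify_stable_pairs <- function(x, fdr = 0.05, p0 = 0.5,
                                  phenotype = NA_character_) {
  x <- validate_expression_matrix(x)
  if (nrow(x) < 2L) stop("need at least two genes", call. = FALSE)
  if (fdr <= 0 || fdr > 1) stop("fdr must lie in (0, 1]", call. = FALSE)
  if (ncol(x) < 3L)
    warning("fewer than 3 samples: stable-pair calls will have little power",
            call. = FALSE)
  x <- x[order(rownames(x)), , drop = FALSE]
  genes <- rownames(x)
  cnt <- pair_counts_cpp(x)
  s_ij <- cnt$s_ij
  n_eff <- cnt$n_eff
  usable <- n_eff > 0L
  if (!any(usable))
    stop("no gene pair has an informative (non-tied) ordering", call. = FALSE)
  s_maj <- pmax(s_ij, n_eff - s_ij)
  p <- rep(NA_real_, length(s_ij))
  p[usable] <- pbinom(s_maj[usable] - 1, n_eff[usable], p0,
                      lower.tail = FALSE)
  q <- rep(NA_real_, length(s_ij))
  q[usable] <- p.adjust(p[usable], method = "BH")
  tie <- 2L * s_maj == n_eff
  keep <- usable & !tie & q <= fdr
  idx <- pair_index_vectors(nrow(x))
  i <- idx$i[keep]
  j <- idx$j[keep]
  i_wins <- s_ij[keep] >= n_eff[keep] - s_ij[keep]
  pairs <- data.frame(
    winner = ifelse(i_wins, genes[i], genes[j]),
    loser  = ifelse(i_wins, genes[j], genes[i]),
    s = s_maj[keep],
    n_eff = n_eff[keep],
    p = p[keep],
    q = q[keep],
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 genes = genes,
                 phenotype = phenotype,
                 fdr = fdr,
                 n_samples = ncol(x),
                 n_tested = sum(usable)),
            class = "StablePairSet")
}

#' @export
print.StablePairSet <- function(x, ...) {
  cat("StablePairSet:", nrow(x$pairs), "stable pairs among",
      length(x$genes), "genes\n")
  cat("  phenotype:", x$phenotype, " samples:", x$n_samples,
      " FDR:", x$fdr, " pairs tested:", x$n_tested, "\n")
  invisible(x)
}

#' Write / read a stable-pair set as tab-separated text
#'
#' Columns: winner, loser, s, n_eff, p, q.  A `.gz` suffix triggers gzip
#' compression (pair files can be large).
#'
#' @param sps A `StablePairSet`.
#' @param path Output path.
#' @return `path` (write) or a `StablePairSet` with minimal metadata (read).
#' @export
write_stable_pairs <- function(sps, path) {
  stopifnot(inherits(sps, "StablePairSet"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  df <- sps$pairs
  df$p <- sprintf("%.17g", df$p)
  df$q <- sprintf("%.17g", df$q)
  writeLines(c(paste(colnames(df), collapse = "\t"),
               do.call(paste, c(unname(df), sep = "\t"))), con)
  invisible(path)
}

#' @rdname write_stable_pairs
#' @param phenotype,fdr Metadata restored onto the read object.
#' @export
read_stable_pairs <- function(path, phenotype = NA_character_, fdr = NA_real_) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  genes <- sort(unique(c(df$winner, df$loser)))
  structure(list(pairs = df, genes = genes, phenotype = phenotype,
                 fdr = fdr, n_samples = NA_integer_,
                 n_tested = NA_integer_),
            class = "StablePairSet")
}
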