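## The REO-based DEG caller: overlap of the two phenotypes' stable pairs,
## per-gene 2x2 tables of consistent vs reversed orderings, Fisher exact
## tests, and iterative exclusion of candidate DEGs as ranking partners.

#' Pairs stably ordered in both phenotypes
#'
#' Intersects two stable-pair sets on unordered pairs and annotates each
#' shared pair with its per-phenotype winning gene and a reversal flag
#' (the two phenotypes disagree on the direction).
#'
#' @param normal,disease `StablePairSet` objects over the same gene
#'   universe.
#' @return An object of class `"OverlapPairs"`: a data frame with columns
#'   `gene_lo`, `gene_hi` (lexicographic pair), `winner_normal`,
#'   `winner_disease`, `reversed`; the sorted gene universe is kept in the
#'   `"genes"` attribute.
#' @export
overlap_pairs <- function(normal, disease) {
  stopifnot(inherits(normal, "StablePairSet"),
            inherits(disease, "StablePairSet"))
  if (!setequal(normal$genes, disease$genes))
    stop("stable-pair sets come from different gene universes", call. = FALSE)
  uni <- sort(normal$genes)
  pair_idx <- function(sps) {
    wi <- match(sps$pairs$winner, uni)
    li <- match(sps$pairs$loser, uni)
    list(lo = pmin(wi, li), hi = pmax(wi, li))
  }
  pn <- pair_idx(normal)
  pd <- pair_idx(disease)
  # numeric keys stay exact well beyond any realistic gene universe
  kn <- (pn$lo - 1) * length(uni) + pn$hi
  kd <- (pd$lo - 1) * length(uni) + pd$hi
  m <- match(kn, kd)
  hit <- which(!is.na(m))
  if (!length(hit))
    stop("phenotypes share no stable background", call. = FALSE)
  wn <- normal$pairs$winner[hit]
  wd <- disease$pairs$winner[m[hit]]
  out <- data.frame(gene_lo = uni[pn$lo[hit]],
                    gene_hi = uni[pn$hi[hit]],
                    winner_normal = wn,
                    winner_disease = wd,
                    reversed = wn != wd,
                    stringsAsFactors = FALSE)
  ord <- order(pn$lo[hit], pn$hi[hit])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genes") <- uni
  class(out) <- c("OverlapPairs", class(out))
  out
}

## Vectorized two-sided Fisher exact p for 2x2 tables (a b / c d):
## sum of hypergeometric point probabilities (margins fixed) not exceeding
## the observed one, with the same relative tolerance as stats::fisher.test.
fisher_p_vec <- function(a, b, cc, d) {
  m <- a + b          # first-row total
  n2 <- cc + d        # second-row total
  k <- a + cc         # first-column total
  lo <- pmax(0L, k - n2)
  hi <- pmin(k, m)
  len <- hi - lo + 1L
  gi <- rep.int(seq_along(a), len)
  xs <- sequence(len, from = lo)
  dens <- dhyper(xs, m[gi], n2[gi], k[gi])
  dobs <- dhyper(a, m, n2, k)
  p <- rowsum(dens * (dens <= dobs[gi] * (1 + 1e-7)), gi, reorder = FALSE)
  pmin(as.vector(p), 1)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `rbind(c(a, b), c(c, d))` with all
#' margins fixed: the sum of hypergeometric probabilities of every table at
#' least as extreme (point probability not exceeding the observed one, to
#' relative tolerance 1e-7).  The degenerate all-zero table returns 1.
#'
#' @param a,b,c,d Non-negative cell counts (first row `a`, `b`; second row
#'   `c`, `d`).
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(1, 1, 1, 1)  # 1
#' fisher_exact_two_sided(5, 0, 0, 5)  # 2/252
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (length(cells) != 4L || any(cells < 0) || any(cells != round(cells)))
    stop("a, b, c, d must be non-negative integer counts", call. = FALSE)
  if (all(cells == 0)) return(1)
  fisher_p_vec(a, b, c, d)
}

#' Per-gene contingency table over overlap pairs
#'
#' For gene `G`, counts among overlap pairs whose partner is not excluded:
#' `a` = pairs with `G` above its partner in the normal phenotype, `b` =
#' below; `c`, `d` likewise in the disease phenotype.  Because every overlap
#' pair is stably ordered in both phenotypes, `a + b = c + d`.
#'
#' @param gene Gene identifier.
#' @param overlaps An [overlap_pairs()] result.
#' @param excluded Character vector of partner genes to exclude (candidate
#'   DEGs); must not contain `gene`.
#' @return Named integer vector `c(a =, b =, c =, d =)` (all zero when the
#'   gene has no usable pairs).
#' @export
gene_table <- function(gene, overlaps, excluded = character()) {
  stopifnot(inherits(overlaps, "OverlapPairs"))
  if (gene %in% excluded)
    stop("the gene under test cannot be excluded", call. = FALSE)
  sel_lo <- overlaps$gene_lo == gene & !(overlaps$gene_hi %in% excluded)
  sel_hi <- overlaps$gene_hi == gene & !(overlaps$gene_lo %in% excluded)
  sel <- sel_lo | sel_hi
  a <- sum(overlaps$winner_normal[sel] == gene)
  cc <- sum(overlaps$winner_disease[sel] == gene)
  n <- sum(sel)
  c(a = a, b = n - a, c = cc, d = n - cc)
}

#' Call differentially expressed genes by REO reversal
#'
#' The full caller: identifies stable pairs in each phenotype, intersects
#' them, builds per-gene contingency tables of normal-vs-disease ordering
#' directions, applies the two-sided Fisher exact test with BH correction,
#' and iterates — excluding current candidate DEGs as ranking partners —
#' until the candidate count is unchanged between successive iterations.
#'
#' @param normal,disease Expression matrices over the same gene universe
#'   (genes x samples); each phenotype should have at least 3 samples.
#' @param stable_fdr FDR for stable-pair identification (default 0.05).
#' @param deg_fdr FDR for DEG calls (default 0.05).
#' @param max_iter Safety cap on filtering iterations (default 100).
#' @param p0 Null REO probability for the binomial test (default 0.5).
#' @param verbose Print per-iteration candidate counts.
#' @return Object of class `"RankCompResult"`: list with `table` (data frame
#'   of called DEGs: `gene`, `direction`, `p`, `q`, `a`, `b`, `c`, `d`),
#'   `iterations`, `converged`, `candidate_counts` (per iteration),
#'   `n_overlap_pairs`, `n_reversed_pairs`, `genes` and the thresholds used.
#' @export
call_degs <- function(normal, disease, stable_fdr = 0.05, deg_fdr = 0.05,
                      max_iter = 100L, p0 = 0.5, verbose = FALSE) {
  normal <- validate_expression_matrix(normal, "normal matrix")
  disease <- validate_expression_matrix(disease, "disease matrix")
  if (!setequal(rownames(normal), rownames(disease)))
    stop("normal and disease matrices must share the gene universe",
         call. = FALSE)
  if (ncol(normal) < 3L || ncol(disease) < 3L)
    warning("fewer than 3 samples in a phenotype: low power", call. = FALSE)
  sp_n <- identify_stable_pairs(normal, fdr = stable_fdr, p0 = p0,
                                phenotype = "normal")
  sp_d <- identify_stable_pairs(disease, fdr = stable_fdr, p0 = p0,
                                phenotype = "disease")
  ov <- overlap_pairs(sp_n, sp_d)
  uni <- attr(ov, "genes")
  G <- length(uni)
  u <- match(ov$gene_lo, uni)
  v <- match(ov$gene_hi, uni)
  wN_u <- ov$winner_normal == ov$gene_lo
  wD_u <- ov$winner_disease == ov$gene_lo

  cand <- rep(FALSE, G)
  counts_hist <- integer(0)
  converged <- FALSE
  membership_note <- FALSE
  prev_count <- -1L
  prev_which <- integer(0)
  a <- b <- cc <- d <- integer(G)
  p <- q <- rep(1, G)

  for (it in seq_len(max_iter)) {
    keep_u <- !cand[v]   # pair usable for its lo gene iff hi gene not a candidate
    keep_v <- !cand[u]
    a  <- tabulate(u[keep_u & wN_u], G) + tabulate(v[keep_v & !wN_u], G)
    nn <- tabulate(u[keep_u], G)        + tabulate(v[keep_v], G)
    b  <- nn - a
    cc <- tabulate(u[keep_u & wD_u], G) + tabulate(v[keep_v & !wD_u], G)
    d  <- nn - cc
    nz <- nn > 0L
    p <- rep(1, G)
    p[nz] <- fisher_p_vec(a[nz], b[nz], cc[nz], d[nz])
    q <- rep(1, G)
    q[nz] <- p.adjust(p[nz], method = "BH")
    sig <- nz & q <= deg_fdr
    no_dir <- sig & cc == a
    if (any(no_dir)) {
      warning(sum(no_dir), " significant gene(s) without a defensible ",
              "direction dropped", call. = FALSE)
      sig[no_dir] <- FALSE
    }
    counts_hist <- c(counts_hist, sum(sig))
    if (verbose)
      message("iteration ", it, ": ", sum(sig), " candidate DEGs")
    if (sum(sig) == prev_count) {
      converged <- TRUE
      if (!identical(which(sig), prev_which))
        membership_note <- TRUE
      cand <- sig
      break
    }
    prev_count <- sum(sig)
    prev_which <- which(sig)
    cand <- sig
  }
  if (!converged)
    warning("candidate count did not stabilise within ", max_iter,
            " iterations; returning the last iteration", call. = FALSE)
  if (membership_note)
    warning("DEG count converged but membership differs between the final ",
            "two iterations", call. = FALSE)

  sel <- which(cand)
  tab <- data.frame(gene = uni[sel],
                    direction = as.character(ifelse(cc[sel] > a[sel],
                                                    "up", "down")),
                    p = p[sel], q = q[sel],
                    a = a[sel], b = b[sel], c = cc[sel], d = d[sel],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$q, tab$p, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 iterations = length(counts_hist),
                 converged = converged,
                 candidate_counts = counts_hist,
                 n_overlap_pairs = nrow(ov),
                 n_reversed_pairs = sum(ov$reversed),
                 genes = uni,
                 stable_fdr = stable_fdr,
                 deg_fdr = deg_fdr),
            class = "RankCompResult")
}

#' @export
print.RankCompResult <- function(x, ...) {
  cat("RankComp REO-based DEG call\n")
  cat("  overlap pairs:", x$n_overlap_pairs,
      " (", x$n_reversed_pairs, "reversed )\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  DEGs at FDR", x$deg_fdr, ":", nrow(x$table),
      "(", sum(x$table$direction == "up"), "up /",
      sum(x$table$direction == "down"), "down )\n")
  invisible(x)
}

#' Write a DEG table as tab-separated text
#'
#' @param res A `RankCompResult` (or a compatible data frame with at least
#'   `gene` and `direction` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_degs <- function(res, path) {
  df <- if (inherits(res, "RankCompResult")) {
    out <- res$table
    out$n_iterations <- rep(res$iterations, nrow(out))
    out
  } else as.data.frame(res)
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  writeLines(c(paste(colnames(df), collapse = "\t"),
               if (nrow(df)) do.call(paste, c(unname(df), sep = "\t"))),
             path)
  invisible(path)
}

#' Read a DEG table written by [write_degs()]
#'
#' @param path Path to the TSV file.
#' @return A data frame with at least `gene` and `direction` columns.
#' @export
read_degs <- function(path) {
  read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE,
             colClasses = c(gene = "character", direction = "character"))
}
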