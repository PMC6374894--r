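## Hypergeometric gene-set over-representation.

#' Hypergeometric gene-set enrichment
#'
#' For each gene set, tests whether the query list (e.g. the up- or
#' down-regulated DEGs) overlaps the set more than expected when drawing
#' `n` genes from a universe of `N`: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`, where `K` is the set size within the
#' universe and `k` the observed overlap.  P-values are BH-adjusted across
#' all sets with at least one universe member.  The universe should be the
#' genes actually tested by the DEG caller, not the genome.
#'
#' @param query Character vector of query genes; members outside the
#'   universe are dropped (with a message giving the count).
#' @param sets A gene-set collection (named list of character vectors, e.g.
#'   from [read_gmt()]).
#' @param universe Character vector of background genes.
#' @param fdr Significance threshold recorded in the `significant` column
#'   (default 0.05).
#' @return Data frame sorted by `p`: `set_id`, `N`, `K`, `n`, `k`, `p`,
#'   `q`, `significant`.  Sets without universe members are omitted.
#' @examples
#' hypergeom_enrich(c("a", "b"), list(s1 = c("a", "b", "c")),
#'                  universe = letters[1:10])
#' @export
hypergeom_enrich <- function(query, sets, universe, fdr = 0.05) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  dropped <- sum(!query %in% universe)
  if (dropped > 0)
    message(dropped, " query gene(s) outside the universe dropped")
  query <- unique(intersect(query, universe))
  if (!length(query))
    stop("no query gene lies in the universe", call. = FALSE)
  N <- length(universe)
  n <- length(query)
  K <- vapply(sets, function(m) length(intersect(m, universe)), integer(1L))
  k <- vapply(sets, function(m) length(intersect(m, query)), integer(1L))
  keep <- K >= 1L
  p <- phyper(k[keep] - 1, K[keep], N - K[keep], n, lower.tail = FALSE)
  out <- data.frame(set_id = names(sets)[keep],
                    N = N, K = K[keep], n = n, k = k[keep],
                    p = p, q = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$q <= fdr
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
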