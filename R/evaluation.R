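## Scoring DEG calls against simulation truth, and comparing DEG lists
## across datasets (POG / concordance).

#' Harmonic mean of sensitivity and specificity
#'
#' `2 * sen * spe / (sen + spe)`, with 0 when both rates are 0.
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @return The F-score.
#' @export
f_score <- function(sensitivity, specificity) {
  s <- sensitivity + specificity
  ifelse(s > 0, 2 * sensitivity * specificity / s, 0)
}

## normalise a DEG argument (RankCompResult, data frame, or gene/direction
## vectors) to a data frame with gene + direction
as_deg_list <- function(x) {
  if (inherits(x, "RankCompResult")) x <- x$table
  x <- as.data.frame(x)
  if (!all(c("gene", "direction") %in% colnames(x)))
    stop("a DEG list needs 'gene' and 'direction' columns", call. = FALSE)
  if (!all(x$direction %in% c("up", "down")))
    stop("directions must be 'up' or 'down'", call. = FALSE)
  x[, c("gene", "direction")]
}

#' Confusion-matrix metrics for a DEG call against simulation truth
#'
#' Sensitivity is the fraction of true DEGs correctly identified;
#' specificity the fraction of true non-DEGs not called; the F-score their
#' harmonic mean; the empirical FDR the fraction of calls that are false.
#' With `require_direction = TRUE` (default) a true DEG called in the wrong
#' direction counts as a false positive, not a true positive.
#'
#' @param called A `RankCompResult` or data frame with `gene` and
#'   `direction` columns; called genes must all appear in the truth.
#' @param truth A [assign_fc_groups()] result (or data frame `gene`, `fc`).
#' @param require_direction Whether the called direction must match the
#'   sign of the true fold change.
#' @return One-row data frame: `sensitivity`, `specificity`, `f_score`,
#'   `fdr`, `tp`, `fp`, `tn`, `fn` (rates are `NA` when their denominator
#'   is empty, except `fdr` which is 0 for an empty call set).
#' @export
confusion_metrics <- function(called, truth, require_direction = TRUE) {
  called <- as_deg_list(called)
  truth <- as.data.frame(truth)
  if (!all(called$gene %in% truth$gene))
    stop("called genes outside the truth universe", call. = FALSE)
  fc <- truth$fc[match(called$gene, truth$gene)]
  true_dir <- ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none"))
  correct <- fc != 1 & (!require_direction | called$direction == true_dir)
  tp <- sum(correct)
  fp <- nrow(called) - tp
  n_true <- sum(truth$fc != 1)
  n_null <- sum(truth$fc == 1)
  called_null <- sum(fc == 1)
  tn <- n_null - called_null
  fn <- n_true - tp
  sen <- if (n_true > 0) tp / n_true else NA_real_
  spe <- if (n_null > 0) tn / n_null else NA_real_
  data.frame(sensitivity = sen,
             specificity = spe,
             f_score = if (is.na(sen) || is.na(spe)) NA_real_
                       else f_score(sen, spe),
             fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
             tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Percentage-of-overlapping-genes and concordance scores
#'
#' For two directed DEG lists of lengths `L1` and `L2` sharing `n` genes of
#' which `s` agree in direction: `POG12 = s / L1`, `POG21 = s / L2`,
#' `concordance = s / n`.  The concordance p-value is the binomial upper
#' tail `P(X >= s)` with `X ~ Binomial(n, p0)` — the chance of seeing at
#' least `s` direction agreements among the `n` shared genes.
#'
#' @param list1,list2 DEG lists (data frames with `gene`, `direction`, or
#'   `RankCompResult` objects); both non-empty.
#' @param p0 Null probability of direction agreement (default 0.5).
#' @return One-row data frame: `L1`, `L2`, `n`, `s`, `pog12`, `pog21`,
#'   `concordance` (`NA` when the lists share no gene, with
#'   `concordance_p = 1`) and `concordance_p`.
#' @export
pog_scores <- function(list1, list2, p0 = 0.5) {
  l1 <- as_deg_list(list1)
  l2 <- as_deg_list(list2)
  if (!nrow(l1) || !nrow(l2))
    stop("DEG lists must be non-empty", call. = FALSE)
  shared <- intersect(l1$gene, l2$gene)
  n <- length(shared)
  s <- sum(l1$direction[match(shared, l1$gene)] ==
           l2$direction[match(shared, l2$gene)])
  data.frame(L1 = nrow(l1), L2 = nrow(l2), n = n, s = s,
             pog12 = s / nrow(l1),
             pog21 = s / nrow(l2),
             concordance = if (n > 0) s / n else NA_real_,
             concordance_p = if (n > 0) binomial_reo_pvalue(s, n, p0) else 1)
}

#' Average metric reports across simulation repeats
#'
#' Arithmetic mean of each rate across repeats (missing rates are dropped
#' from their mean); the raw confusion counts are summed for reference.
#'
#' @param reports A list of [confusion_metrics()] rows (or a data frame of
#'   stacked rows).
#' @return A one-row data frame in the same layout.
#' @export
aggregate_repeats <- function(reports) {
  if (is.data.frame(reports)) reports <- split(reports, seq_len(nrow(reports)))
  if (!length(reports)) stop("no reports to aggregate", call. = FALSE)
  all <- do.call(rbind, lapply(reports, as.data.frame))
  rates <- c("sensitivity", "specificity", "f_score", "fdr")
  counts <- c("tp", "fp", "tn", "fn")
  out <- as.data.frame(c(lapply(all[rates], mean, na.rm = TRUE),
                         lapply(all[counts], sum)))
  out[rates][vapply(out[rates], is.nan, logical(1L))] <- NA_real_
  out
}
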