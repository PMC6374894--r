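## Experiment orchestration: simulation sweeps over spike-in designs,
## null-split false-discovery experiments, and the optional count-based
## comparator.

#' Describe one spike-in design for a sweep
#'
#' @param n_up,n_down Numbers of up-/down-regulated genes.
#' @param scheme `"four_group"` or `"uniform"` (see [assign_fc_groups()]).
#' @param fc Fold change for the uniform scheme.
#' @return A design list usable in [sweep_config()].
#' @export
sweep_design <- function(n_up, n_down, scheme = "four_group", fc = NULL) {
  list(n_up = n_up, n_down = n_down, scheme = scheme, fc = fc)
}

#' Build a sweep configuration
#'
#' @param designs List of [sweep_design()] entries.
#' @param n_genes,n_samples Cohort size per phenotype; disease samples are
#'   the baseline samples with fold changes applied and the cohort rescaled
#'   to the baseline sequencing mass.
#' @param repeats Simulation repeats per design.
#' @param base_seed Base seed; repeat `r` of design `d` uses baseline seed
#'   `base_seed + r - 1` and fold-change assignment seed
#'   `base_seed + r - 1 + 70001 * d`.
#' @param stable_fdr,deg_fdr Caller thresholds.
#' @param comparator Also run the count-based comparator ([wrap_count_comparator()]).
#' @param baseline_params Extra arguments to [generate_baseline()]
#'   (`mean_log`, `sd_log`, `dispersion`).
#' @return A validated configuration list of class `"sweep_config"`.
#' @export
sweep_config <- function(designs, n_genes = 2000L, n_samples = 20L,
                         repeats = 5L, base_seed = 1L,
                         stable_fdr = 0.05, deg_fdr = 0.05,
                         comparator = FALSE, baseline_params = list()) {
  stopifnot(length(designs) >= 1L, repeats >= 1L)
  for (d in designs)
    stopifnot(is.list(d), all(c("n_up", "n_down", "scheme") %in% names(d)))
  structure(list(designs = designs, n_genes = n_genes,
                 n_samples = n_samples, repeats = repeats,
                 base_seed = base_seed, stable_fdr = stable_fdr,
                 deg_fdr = deg_fdr, comparator = comparator,
                 baseline_params = baseline_params),
            class = "sweep_config")
}

#' Read a sweep configuration from YAML
#'
#' Top-level keys mirror the [sweep_config()] arguments; `designs` is a
#' sequence of mappings with `n_up`, `n_down`, `scheme` and optional `fc`.
#'
#' @param path Path to the YAML file.
#' @return A `"sweep_config"` object.
#' @export
read_sweep_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read sweep configs",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  designs <- lapply(cfg$designs, function(d)
    sweep_design(d$n_up, d$n_down,
                 scheme = d$scheme %||% "four_group", fc = d$fc))
  args <- cfg[setdiff(names(cfg), "designs")]
  do.call(sweep_config, c(list(designs = designs), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

design_label <- function(d) {
  if (d$scheme == "uniform")
    sprintf("up%d_down%d_fc%g", d$n_up, d$n_down, d$fc)
  else
    sprintf("up%d_down%d_%s", d$n_up, d$n_down, d$scheme)
}

#' Run a simulation sweep
#'
#' For every design and repeat: generate a baseline cohort, assign fold
#' changes, spike them in, rescale the spiked cohort to the baseline
#' sequencing mass, call DEGs by REO reversal (and optionally with the
#' count-based comparator) and score the calls against the truth.  Counts
#' entering the REO caller are used directly as the rank input: with equal
#' nominal transcript lengths, RPKM is a per-sample monotone map of the
#' counts and leaves every within-sample ordering unchanged.
#'
#' @param config A [sweep_config()] (or a path to a YAML config).
#' @return Object of class `"SweepReport"`: list with `table` (one row per
#'   design x method: mean `factor`, `sensitivity`, `specificity`,
#'   `f_score`, `fdr` over repeats, plus summed confusion counts),
#'   `per_repeat` (all individual rows) and `config`.  Comparator rows are
#'   `NA` when the comparator is unavailable; `comparator_missing` records
#'   that.
#' @export
run_sweep <- function(config) {
  if (is.character(config)) config <- read_sweep_config(config)
  stopifnot(inherits(config, "sweep_config"))
  per <- list()
  comparator_missing <- FALSE
  for (d_idx in seq_along(config$designs)) {
    d <- config$designs[[d_idx]]
    for (r in seq_len(config$repeats)) {
      seed_r <- config$base_seed + r - 1L
      baseline <- do.call(generate_baseline,
                          c(list(n_genes = config$n_genes,
                                 n_samples = config$n_samples,
                                 seed = seed_r),
                            config$baseline_params))
      truth <- assign_fc_groups(rownames(baseline), d$n_up, d$n_down,
                                scheme = d$scheme, fc = d$fc,
                                seed = seed_r + 70001L * d_idx)
      spiked <- apply_fc(baseline, truth)
      resc <- rescale_to_common_total(baseline, spiked)
      disease <- resc$matrix
      colnames(disease) <- paste0("d_", colnames(disease))
      res <- call_degs(baseline, disease,
                       stable_fdr = config$stable_fdr,
                       deg_fdr = config$deg_fdr)
      row <- confusion_metrics(res, truth)
      row <- cbind(design = design_label(d), method = "rankcomp",
                   repeat_idx = r, factor = resc$factor, row,
                   n_degs = nrow(res$table))
      per[[length(per) + 1L]] <- row
      if (isTRUE(config$comparator)) {
        cmp <- tryCatch(
          wrap_count_comparator(baseline, disease, fdr = config$deg_fdr),
          error = function(e) e)
        if (inherits(cmp, "error")) {
          comparator_missing <- TRUE
        } else {
          crow <- confusion_metrics(cmp, truth)
          per[[length(per) + 1L]] <-
            cbind(design = design_label(d), method = "comparator",
                  repeat_idx = r, factor = resc$factor, crow,
                  n_degs = nrow(cmp))
        }
      }
    }
  }
  per_repeat <- do.call(rbind, per)
  rownames(per_repeat) <- NULL
  groups <- split(per_repeat, list(per_repeat$design, per_repeat$method),
                  drop = TRUE)
  table <- do.call(rbind, lapply(groups, function(g) {
    agg <- aggregate_repeats(g[, c("sensitivity", "specificity", "f_score",
                                   "fdr", "tp", "fp", "tn", "fn")])
    cbind(design = g$design[1L], method = g$method[1L],
          factor = mean(g$factor), agg,
          mean_n_degs = mean(g$n_degs), repeats = nrow(g))
  }))
  # stable ordering: designs in config order, then method
  lbl <- vapply(config$designs, design_label, character(1L))
  table <- table[order(match(table$design, lbl), table$method), , drop = FALSE]
  rownames(table) <- NULL
  structure(list(table = table, per_repeat = per_repeat, config = config,
                 comparator_missing = comparator_missing),
            class = "SweepReport")
}

#' @export
print.SweepReport <- function(x, digits = 4, ...) {
  cat("Simulation sweep:", length(x$config$designs), "design(s) x",
      x$config$repeats, "repeat(s),", x$config$n_genes, "genes,",
      x$config$n_samples, "+", x$config$n_samples, "samples\n")
  df <- x$table
  for (col in c("factor", "sensitivity", "specificity", "f_score", "fdr"))
    df[[col]] <- round(df[[col]], digits)
  print(df[, c("design", "method", "factor", "sensitivity", "specificity",
               "f_score", "fdr", "mean_n_degs")], row.names = FALSE)
  if (x$comparator_missing)
    cat("note: comparator unavailable for some runs\n")
  invisible(x)
}

#' Null-split false-discovery experiment
#'
#' Repeatedly splits a single-phenotype cohort into two random halves and
#' counts the DEGs called between them; with no real signal the counts
#' measure false discoveries under the default thresholds.
#'
#' @param normal Expression matrix with at least 6 samples.
#' @param repeats Number of random splits.
#' @param seed Base seed; split `r` uses `seed + r`.
#' @param stable_fdr,deg_fdr Caller thresholds.
#' @return List with `counts` (DEGs per repeat), `median`, `q95` (95th
#'   percentile) and `repeats`.
#' @export
run_null_experiment <- function(normal, repeats = 20L, seed = 1L,
                                stable_fdr = 0.05, deg_fdr = 0.05) {
  stopifnot(repeats >= 1L)
  counts <- integer(repeats)
  for (r in seq_len(repeats)) {
    halves <- make_null_split(normal, seed = seed + r)
    res <- call_degs(halves$a, halves$b,
                     stable_fdr = stable_fdr, deg_fdr = deg_fdr)
    counts[r] <- nrow(res$table)
  }
  list(counts = counts,
       median = median(counts),
       q95 = unname(quantile(counts, 0.95, type = 1)),
       repeats = repeats)
}

#' Count-based comparator DEG call
#'
#' Runs the conventional count-based pipeline (edgeR: TMM normalization,
#' common/tagwise dispersion, exact test, BH) on the two cohorts and
#' normalises its calls into the package's directed DEG format.  The
#' comparator is called as an external dependency, never reimplemented;
#' when edgeR is not installed an explicit "comparator unavailable" error
#' is raised.
#'
#' @param baseline,disease Count matrices over the same gene universe
#'   (fractional rescaled counts are rounded to integers for the
#'   comparator when `round_counts = TRUE`).
#' @param fdr FDR threshold applied to the comparator's adjusted p-values.
#' @param round_counts Round counts to integers first (default `TRUE`).
#' @return Data frame `gene`, `direction`, `p`, `q` (the comparator's
#'   calls at `fdr`).
#' @export
wrap_count_comparator <- function(baseline, disease, fdr = 0.05,
                                  round_counts = TRUE) {
  if (!requireNamespace("edgeR", quietly = TRUE))
    stop("comparator unavailable: the 'edgeR' package is not installed",
         call. = FALSE)
  baseline <- validate_expression_matrix(baseline, "baseline")
  disease <- validate_expression_matrix(disease, "disease")
  if (!setequal(rownames(baseline), rownames(disease)))
    stop("cohorts must share the gene universe", call. = FALSE)
  disease <- disease[rownames(baseline), , drop = FALSE]
  counts <- cbind(baseline, disease)
  if (round_counts) counts <- round(counts)
  colnames(counts) <- make.unique(colnames(counts))
  group <- factor(rep(c("normal", "disease"),
                      c(ncol(baseline), ncol(disease))),
                  levels = c("normal", "disease"))
  y <- edgeR::DGEList(counts = counts, group = group)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y, pair = c("normal", "disease"))
  tt <- edgeR::topTags(et, n = Inf, sort.by = "none")$table
  q <- tt$FDR
  keep <- q <= fdr
  out <- data.frame(gene = rownames(tt)[keep],
                    direction = ifelse(tt$logFC[keep] > 0, "up", "down"),
                    p = tt$PValue[keep], q = q[keep],
                    stringsAsFactors = FALSE)
  out[order(out$q, out$p, out$gene), , drop = FALSE]
}
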