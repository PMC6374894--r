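## Synthetic RNA-seq cohorts with spike-in fold changes and
## transcriptome-size rescaling.
##
## The size-factor mechanism: profiling extracts the same RNA amount S from
## each sample, so a sample from cells with total per-cell transcript count
## T_k contributes n_k = S / T_k cells, and the measured level of gene i is
## proportional to its per-cell concentration N_ki / T_k.  Spiking fold
## changes into a baseline inflates (or deflates) the disease transcriptome;
## multiplying the spiked counts by factor = baseline total / spiked total
## restores equal sequencing mass, exactly as equal-RNA-input profiling
## would.  The rescaling is a single positive scalar per cohort, hence
## strictly monotone within every sample: all within-sample orderings are
## untouched while count magnitudes shift globally.

#' Generate a negative-binomial baseline cohort
#'
#' One mean per gene is drawn from a log-normal distribution and shared
#' across samples, which induces the stable within-cohort REO structure the
#' rank-based caller assumes; counts are then negative-binomial around that
#' mean with a common dispersion.
#'
#' @param n_genes,n_samples Cohort dimensions.
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @param mean_log,sd_log Location and scale (natural-log) of the per-gene
#'   mean distribution; defaults `log(60)` and 2 give means spanning roughly
#'   0.1 to 1e4 counts, a typical filtered bulk RNA-seq dynamic range.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   default 0.1 is a moderate bulk-tissue value.
#' @return Integer count matrix with genes `g0001, ...` and samples
#'   `s01, ...`.
#' @export
generate_baseline <- function(n_genes = 2000L, n_samples = 27L, seed = 1L,
                              mean_log = log(60), sd_log = 2,
                              dispersion = 0.1) {
  stopifnot(n_genes >= 2L, n_samples >= 1L, sd_log > 0, dispersion > 0)
  set.seed(seed)
  mu <- rlnorm(n_genes, meanlog = mean_log, sdlog = sd_log)
  counts <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = 1 / dispersion),
                   nrow = n_genes, ncol = n_samples)
  gw <- max(4L, nchar(as.character(n_genes)))
  sw <- max(2L, nchar(as.character(n_samples)))
  dimnames(counts) <- list(sprintf(paste0("g%0", gw, "d"), seq_len(n_genes)),
                           sprintf(paste0("s%0", sw, "d"), seq_len(n_samples)))
  attr(counts, "true_mean") <- stats::setNames(mu, rownames(counts))
  counts
}

#' Assign true fold changes to a random gene subset
#'
#' Two spike-in designs.  `"four_group"` splits the up-regulated genes into
#' four (near-)equal groups with fold changes 2, 3, 4 and 5 and the
#' down-regulated genes likewise with 1/2, 1/3, 1/4 and 1/5; a remainder
#' not divisible by four is distributed round-robin.  `"uniform"` gives all
#' up-regulated genes a single fold change `fc` and all down-regulated genes
#' `1/fc`.  Genes are selected without replacement under `seed`.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param n_up,n_down Numbers of up- and down-regulated genes.
#' @param scheme `"four_group"` or `"uniform"`.
#' @param fc Fold change for the `"uniform"` scheme (> 1).
#' @param seed Integer seed for the gene selection.
#' @return Object of class `"SimulationTruth"`: data frame `gene`, `fc`
#'   (1 for unchanged genes) in `gene_ids` order, with design metadata in
#'   attributes.
#' @export
assign_fc_groups <- function(gene_ids, n_up, n_down,
                             scheme = c("four_group", "uniform"),
                             fc = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(n_up >= 0, n_down >= 0, n_up + n_down <= length(gene_ids))
  if (scheme == "uniform") {
    if (is.null(fc) || fc <= 1)
      stop("the uniform scheme needs a fold change fc > 1", call. = FALSE)
  } else if (!is.null(fc)) {
    stop("fc applies only to the uniform scheme", call. = FALSE)
  }
  set.seed(seed)
  chosen <- sample(gene_ids, n_up + n_down)
  ups <- chosen[seq_len(n_up)]
  downs <- chosen[n_up + seq_len(n_down)]
  group_fcs <- function(n, levels) {
    if (n == 0L) return(numeric(0))
    base <- n %/% 4L
    extra <- n %% 4L
    sizes <- rep(base, 4L) + (seq_len(4L) <= extra)
    if (extra > 0L)
      message("group size ", n, " not divisible by 4; ",
              "remainder distributed round-robin")
    rep(levels, times = sizes)
  }
  fcs <- rep(1, length(gene_ids))
  names(fcs) <- gene_ids
  if (scheme == "four_group") {
    fcs[ups] <- group_fcs(n_up, c(2, 3, 4, 5))
    fcs[downs] <- group_fcs(n_down, c(1 / 2, 1 / 3, 1 / 4, 1 / 5))
  } else {
    fcs[ups] <- fc
    fcs[downs] <- 1 / fc
  }
  truth <- data.frame(gene = gene_ids, fc = unname(fcs),
                      stringsAsFactors = FALSE)
  attr(truth, "n_up") <- n_up
  attr(truth, "n_down") <- n_down
  attr(truth, "scheme") <- scheme
  attr(truth, "fc_level") <- if (scheme == "uniform") fc else NA_real_
  attr(truth, "seed") <- seed
  class(truth) <- c("SimulationTruth", class(truth))
  truth
}

#' Apply true fold changes to a baseline cohort
#'
#' Each gene's counts are multiplied by its fold change in every sample;
#' unchanged genes are returned bit-identical.
#'
#' @param baseline Count matrix.
#' @param truth A [assign_fc_groups()] result covering every baseline gene.
#' @return The spiked (pre-rescaling) matrix.
#' @export
apply_fc <- function(baseline, truth) {
  baseline <- validate_expression_matrix(baseline, "baseline")
  fc <- truth$fc[match(rownames(baseline), truth$gene)]
  if (anyNA(fc))
    stop("truth does not cover gene '",
         rownames(baseline)[which(is.na(fc))[1L]], "'", call. = FALSE)
  baseline * fc
}

#' Rescale a spiked cohort to the baseline sequencing mass
#'
#' Multiplies every count of the spiked cohort by the transcriptome size
#' factor `sum(baseline) / sum(modified)` so both cohorts carry the same
#' total counts — the in-silico equivalent of extracting equal RNA amounts
#' from cells whose total transcriptome differs.  Being a single positive
#' scalar, the rescaling preserves every within-sample ordering.
#'
#' @param baseline,modified Count matrices (the spiked matrix may hold
#'   fractional values).
#' @param per_sample If `TRUE`, equalise each sample's column total
#'   separately instead of the pooled grand total.
#' @param round_counts `"none"` (default) keeps fractional rescaled counts;
#'   `"nearest"` rounds them to integers.
#' @return List with `matrix` (the rescaled cohort) and `factor` (scalar, or
#'   per-sample vector when `per_sample = TRUE`).
#' @export
rescale_to_common_total <- function(baseline, modified, per_sample = FALSE,
                                    round_counts = c("none", "nearest")) {
  round_counts <- match.arg(round_counts)
  baseline <- validate_expression_matrix(baseline, "baseline")
  modified <- validate_expression_matrix(modified, "modified")
  if (per_sample) {
    tot <- colSums(modified)
    if (any(tot == 0)) stop("modified sample with zero total", call. = FALSE)
    factor <- colSums(baseline) / tot
    out <- sweep(modified, 2L, factor, "*")
  } else {
    tot <- sum(modified)
    if (tot == 0) stop("modified matrix has zero total count", call. = FALSE)
    factor <- sum(baseline) / tot
    out <- modified * factor
  }
  if (round_counts == "nearest") out <- round(out)
  list(matrix = out, factor = factor)
}

#' Split a cohort into two random halves (null experiment)
#'
#' Seeded partition of the samples into two disjoint groups of sizes
#' `ceiling(n/2)` and `floor(n/2)`; used to measure false discoveries when
#' no real phenotype difference exists.
#'
#' @param x Expression matrix with at least 6 samples.
#' @param seed Integer seed.
#' @return List with matrices `a` and `b`.
#' @export
make_null_split <- function(x, seed = 1L) {
  x <- validate_expression_matrix(x)
  n <- ncol(x)
  if (n < 6L) stop("null split needs at least 6 samples", call. = FALSE)
  set.seed(seed)
  na <- ceiling(n / 2)
  pick <- sample(n, na)
  list(a = x[, sort(pick), drop = FALSE],
       b = x[, sort(setdiff(seq_len(n), pick)), drop = FALSE])
}
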