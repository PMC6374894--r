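# Independent oracles used to validate the exact tests, plus small fixture
# builders shared across test files.

# Binomial upper tail by direct term-by-term summation (no pbinom).
binom_tail_sum <- function(s, n, p0 = 0.5) {
  if (s == 0) return(1)
  k <- s:n
  sum(choose(n, k) * p0^k * (1 - p0)^(n - k))
}

# Binomial upper tail by exhaustive enumeration of all 2^n outcomes at
# p0 = 0.5: count outcomes with at least s successes.
binom_tail_enum <- function(s, n) {
  stopifnot(n <= 20)
  v <- 0:(2^n - 1)
  pc <- integer(length(v))
  for (b in seq_len(n)) {
    pc <- pc + v %% 2L
    v <- v %/% 2L
  }
  sum(pc >= s) / 2^n
}

# Exact table probability under fixed margins, from binomial coefficients.
table_prob <- function(a, r1, r2, c1) {
  choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
}

# Two-sided Fisher p by enumeration of every table with the given margins.
fisher_two_sided_enum <- function(a, b, cc, d) {
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  if (r1 + r2 == 0) return(1)
  xs <- max(0, c1 - r2):min(c1, r1)
  probs <- table_prob(xs, r1, r2, c1)
  p_obs <- table_prob(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hypergeometric upper tail P(X >= k) by direct summation.
hyper_tail_sum <- function(k, N, K, n) {
  if (k <= max(0, n - (N - K))) return(1)
  xs <- k:min(K, n)
  if (!length(xs)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Tiny expression matrix with named dims.
emat <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples), byrow = TRUE,
         dimnames = list(genes, samples))
}

# Construct a StablePairSet by hand for overlap tests.
make_sps <- function(winner, loser, genes, phenotype = "x", fdr = 0.05) {
  structure(list(pairs = data.frame(winner = winner, loser = loser,
                                    s = rep(10L, length(winner)),
                                    n_eff = rep(10L, length(winner)),
                                    p = rep(1e-3, length(winner)),
                                    q = rep(1e-3, length(winner)),
                                    stringsAsFactors = FALSE),
                 genes = sort(genes), phenotype = phenotype, fdr = fdr,
                 n_samples = 10L, n_tested = length(winner)),
            class = "StablePairSet")
}

# A small spiked cohort: baseline + disease (fold changes applied and
# rescaled) + truth, as one bundle.
make_spiked_cohort <- function(n_genes = 300, n_samples = 20, n_up = 30,
                               n_down = 30, scheme = "four_group", fc = NULL,
                               seed = 42) {
  baseline <- generate_baseline(n_genes, n_samples, seed = seed)
  truth <- suppressMessages(
    assign_fc_groups(rownames(baseline), n_up, n_down, scheme = scheme,
                     fc = fc, seed = seed + 1))
  resc <- rescale_to_common_total(baseline, apply_fc(baseline, truth))
  disease <- resc$matrix
  colnames(disease) <- paste0("d_", colnames(disease))
  list(baseline = baseline, disease = disease, truth = truth,
       factor = resc$factor)
}
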