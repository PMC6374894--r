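test_that("expression matrices round-trip through TSV and CSV bit-faithfully", {
  x <- emat(c(1.5, 2.25, 1/3, 0, 1e-7, 123456.789), c("gA", "gB", "gC"),
            c("s1", "s2"))
  for (fmt in c("tsv", "csv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_expression_matrix(x, path, fmt = fmt)
    y <- read_expression_matrix(path, fmt = fmt)
    expect_identical(dimnames(y), dimnames(x))
    expect_identical(y, x)   # full-precision writer: exact round trip
  }
})

test_that("malformed matrices are rejected with informative errors", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "A\t1\t2", "A\t3\t4"), path)
  expect_error(read_expression_matrix(path), "A")
  writeLines(c("gene_id\ts1\ts2", "A\t1\t2", "B\t-1.0\t4"), path)
  expect_error(read_expression_matrix(path), "gene 'B'.*sample 's1'")
  writeLines(c("gene_id\ts1\ts2", "A\t1\t2", "B\tfoo\t4"), path)
  expect_error(read_expression_matrix(path), "non-numeric.*'foo'")
})

test_that("RPKM follows count / ((column total/1e6) * (length/1e3))", {
  counts <- emat(c(10, 1e6 - 10), c("g1", "g2"), "s1")
  lens <- c(g1 = 1000, g2 = 1000)
  expect_equal(compute_rpkm(counts, lens)["g1", "s1"], 10)
  # count 5, length 500 bp, column total 2e6 -> 5 / (2 * 0.5) = 5
  counts2 <- emat(c(5, 2e6 - 5), c("g1", "g2"), "s1")
  lens2 <- c(g1 = 500, g2 = 1000)
  expect_equal(compute_rpkm(counts2, lens2)["g1", "s1"], 5)
  # zero count stays zero; log2 with pseudocount 1 gives 0
  counts3 <- emat(c(0, 100), c("g1", "g2"), "s1")
  expect_equal(compute_rpkm(counts3, lens)["g1", "s1"], 0)
  expect_equal(compute_rpkm(counts3, lens, log2_transform = TRUE,
                            pseudocount = 1)["g1", "s1"], 0)
  expect_error(compute_rpkm(counts, lens[1]), "g2")
  zero <- emat(c(0, 0), c("g1", "g2"), "s1")
  expect_error(compute_rpkm(zero, lens), "zero total")
})

test_that("log2 RPKM preserves within-sample orderings for any pseudocount", {
  set.seed(7)
  counts <- matrix(rpois(40 * 6, 50), 40, 6,
                   dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:6)))
  lens <- stats::setNames(rep(1000L, 40), rownames(counts))
  base_ranks <- apply(counts, 2, rank, ties.method = "average")
  for (pc in c(0.5, 1, 2)) {
    lr <- compute_rpkm(counts, lens, log2_transform = TRUE, pseudocount = pc)
    expect_equal(apply(lr, 2, rank, ties.method = "average"), base_ranks)
  }
})

test_that("quantile normalization matches the rank-mean construction", {
  x <- emat(c(1, 6, 2, 4, 3, 5), c("g1", "g2", "g3"), c("s1", "s2"))
  qn <- quantile_normalize(x)
  expect_equal(unname(qn[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "s2"]), c(4.5, 2.5, 3.5))
  # fixed point when all columns are identical
  y <- emat(rep(c(3, 1, 2), 2), c("g1", "g2", "g3"), c("s1", "s2"))
  y[, 2] <- y[, 1]
  expect_equal(quantile_normalize(y), y)
  # idempotence
  set.seed(11)
  z <- matrix(runif(60), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:3)))
  expect_equal(quantile_normalize(quantile_normalize(z)),
               quantile_normalize(z), tolerance = 1e-9)
  # tied values receive the mean of the rank-values they span
  w <- emat(c(1, 1, 1, 2, 2, 3), c("g1", "g2", "g3"), c("s1", "s2"))
  qw <- quantile_normalize(w)
  ref <- rowMeans(cbind(sort(w[, 1]), sort(w[, 2])))
  expect_equal(unname(qw[1:2, "s1"]), rep(mean(ref[1:2]), 2))
  expect_error(quantile_normalize(w[, 1, drop = FALSE]), "two samples")
})

test_that("low-expression filter removes genes zero in MORE than the threshold", {
  n <- 20
  x <- rbind(all_zero = rep(0, n),
             at_threshold = c(rep(0, 15), rep(5, 5)),  # exactly 75% zeros
             over_threshold = c(rep(0, 16), rep(5, 4)),
             no_zero = rep(3, n))
  colnames(x) <- sprintf("s%02d", 1:n)
  kept <- filter_low_expression(x)
  expect_identical(rownames(kept), c("at_threshold", "no_zero"))
  # never reorders retained genes
  y <- x[c("no_zero", "at_threshold", "all_zero"), ]
  expect_identical(rownames(filter_low_expression(y)),
                   c("no_zero", "at_threshold"))
})

test_that("GMT collections read back with descriptions and deduped members", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tfirst set\tg1\tg2\tg3",
               "setB\t\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(attr(sets, "description")[["setA"]], "first set")
  writeLines("setC\tdesc\tg1\tg1\tg2", path)
  expect_warning(sets2 <- read_gmt(path), "duplicate")
  expect_identical(sets2$setC, c("g1", "g2"))
  writeLines("setD\tdesc", path)
  expect_error(read_gmt(path), "no members")
})
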