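# preprocess: log2 transform, quantile normalization, ComBat-style batch
# adjustment.  The batch-adjustment reference fixture was produced by an
# independent published implementation of the parametric empirical-Bayes
# algorithm on the deterministically regenerated input below.

test_that("log2_transform applies the offset convention and advances scale", {
  m <- make_expr(matrix(c(8, 2, 1000, 3), 2, 2), scale = "raw")
  out <- log2_transform(m, offset = 0)
  expect_equal(unclass(out)[1, 1], 3)
  expect_equal(unclass(out)[1, 2], log2(1000))
  expect_equal(round(unclass(out)[1, 2], 4), 9.9658)
  expect_equal(expr_scale(out), "log2")

  withzero <- make_expr(matrix(c(0, 1, 2, 3), 2, 2), scale = "raw")
  expect_error(log2_transform(withzero, offset = 0), "nonpositive")
  out0 <- log2_transform(withzero, offset = 1)
  expect_equal(unclass(out0)[1, 1], 0)
  expect_error(log2_transform(out0), "raw-scale")
})

test_that("quantile normalization equalizes distributions and is idempotent", {
  m <- make_expr(cbind(c(1, 2, 3), c(4, 5, 6)))
  qn <- quantile_normalize(m)
  expect_equal(unname(unclass(qn)[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(unclass(qn)[, 2]), c(2.5, 3.5, 4.5))

  # fixed point: identical columns are unchanged
  same <- make_expr(cbind(c(1, 5, 2), c(1, 5, 2)))
  expect_equal(unclass(quantile_normalize(same)), unclass(same),
               ignore_attr = TRUE)

  # permuted columns end up permutations of the same multiset
  set.seed(41)
  x <- rnorm(50)
  pm <- make_expr(cbind(x, sample(x), rnorm(50)))
  qn2 <- unclass(quantile_normalize(pm))
  expect_equal(unname(sort(qn2[, 1])), unname(sort(qn2[, 2])))
  expect_equal(unname(sort(qn2[, 1])), unname(sort(qn2[, 3])))

  # idempotence on continuous data
  set.seed(42)
  big <- make_expr(matrix(rnorm(600), 100, 6))
  once <- quantile_normalize(big)
  twice <- quantile_normalize(specdeconv:::set_scale(once, "log2_quantile"))
  expect_equal(unclass(twice), unclass(once), tolerance = 1e-12)

  # within-column ranks preserved
  expect_equal(order(unclass(once)[, 3]), order(unclass(big)[, 3]))

  expect_error(quantile_normalize(make_expr(matrix(1:3, 3, 1))), "at least 2")
})

test_that("quantile normalization gives ties the mean of spanned quantiles", {
  m <- make_expr(cbind(c(1, 1, 4), c(1, 2, 3)))
  qn <- unclass(quantile_normalize(m))
  ref <- rowMeans(cbind(sort(c(1, 1, 4)), sort(c(1, 2, 3))))
  expect_equal(unname(qn[, 1]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("batch_adjust removes a pure additive shift and validates input", {
  # noise-free location-only case: each gene constant within batch, batch B
  # shifted by +1; the batch means must be equalized exactly
  set.seed(7)
  mu <- rnorm(40, 8)
  batch <- rep(c("A", "B"), each = 4)
  shifted <- cbind(matrix(mu, 40, 4), matrix(mu + 1, 40, 4))
  dimnames(shifted) <- list(sprintf("g%02d", 1:40), sprintf("s%d", 1:8))
  adj <- suppressMessages(
    batch_adjust(make_expr(shifted, scale = "log2_quantile"), batch)
  )
  mean_a <- rowMeans(unclass(adj)[, batch == "A"])
  mean_b <- rowMeans(unclass(adj)[, batch == "B"])
  expect_lt(max(abs(mean_a - mean_b)), 1e-6)
  expect_equal(expr_scale(adj), "log2_quantile_batchadj")
  # gene and sample order unchanged
  expect_equal(dimnames(adj), dimnames(shifted))

  base <- shifted + matrix(rnorm(320, sd = 0.3), 40, 8)
  expect_error(batch_adjust(make_expr(base), rep("A", 8)), "at least 2 batches")
  expect_error(batch_adjust(make_expr(base), c("A", rep("B", 7))),
               "fewer than 2 samples")
  expect_error(
    batch_adjust(make_expr(base), batch, covariate_groups = batch),
    "confounded"
  )
})

test_that("batch_adjust location part is a no-op on a two-equal-batch split", {
  # duplicating a batch-free dataset into two identical "batches" gives
  # zero estimated batch locations: per-gene means must be preserved (the
  # empirical-Bayes scale pooling may still rescale residuals slightly)
  set.seed(8)
  half <- matrix(rnorm(30 * 5, 8), 30, 5)
  dup <- cbind(half, half)
  dimnames(dup) <- list(sprintf("g%02d", 1:30), sprintf("s%d", 1:10))
  adj <- batch_adjust(make_expr(dup, scale = "log2_quantile"),
                      rep(c("A", "B"), each = 5))
  expect_equal(rowMeans(unclass(adj)), rowMeans(dup), tolerance = 1e-8)
  expect_equal(rowMeans(unclass(adj)[, 1:5]), rowMeans(unclass(adj)[, 6:10]),
               tolerance = 1e-8)
})

test_that("batch_adjust matches the reference parametric implementation", {
  # regenerate the 50-gene fixture input deterministically
  set.seed(20260909)
  n_g <- 50; n_s <- 10
  vals <- matrix(rnorm(n_g * n_s, mean = 8, sd = 1.5), n_g, n_s,
                 dimnames = list(sprintf("g%02d", 1:n_g), sprintf("s%02d", 1:n_s)))
  batch <- rep(c("A", "B"), each = 5)
  vals[, batch == "B"] <- vals[, batch == "B"] + 0.7 + rnorm(n_g) * 0.2
  mine <- batch_adjust(make_expr(vals, scale = "log2_quantile"), batch)
  ref <- read_expression_tsv(test_path("combat-reference-fixture.tsv"))
  expect_equal(unclass(mine), unclass(ref), tolerance = 1e-6,
               ignore_attr = TRUE)
  # pooled per-gene mean and variance agree tightly with the reference
  expect_lt(max(abs(rowMeans(unclass(mine)) - rowMeans(unclass(ref)))), 1e-6)
  expect_lt(max(abs(apply(unclass(mine), 1, var) - apply(unclass(ref), 1, var))),
            1e-6)
})
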