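# cell_deconvolution: signature derivation, per-sample ranking, the
# running-sum enrichment score (checked against an explicit step-by-step
# oracle), sample scoring, and the association/longitudinal tests.

test_that("derive_signature recovers planted markers and breaks ties by id", {
  ref <- make_ref(seed = 3, n_genes = 300, n_markers = 10)
  sig <- derive_signature(ref, "TPH", n_top = 10, min_fc = 1.5)
  expect_setequal(sig$genes, ref$marker_map$TPH)

  # n_top = 1 returns the single argmax gene
  one <- derive_signature(ref, "TPH", n_top = 1, min_fc = 1.5)
  expect_length(one$genes, 1)
  expect_true(one$genes %in% ref$marker_map$TPH)

  # tie at the cutoff: lexicographically smaller id wins
  means <- cbind(T1 = c(5, 3, 3, 1), T2 = c(1, 1, 1, 1))
  rownames(means) <- c("gz", "gb", "ga", "gc")
  tied_ref <- structure(
    list(cell_types = c("T1", "T2"), genes = rownames(means),
         mean_log2 = means, marker_map = list(), marker_effect = 2),
    class = "ReferenceProfiles"
  )
  two <- derive_signature(tied_ref, "T1", n_top = 2, min_fc = 1.2)
  expect_equal(two$genes, c("gz", "ga"))

  expect_error(derive_signature(ref, "nosuch"), "unknown cell type")
  flat <- tied_ref
  flat$mean_log2[] <- 1
  expect_error(derive_signature(flat, "T1"), "no gene exceeds")
})

test_that("derive_signature works from a labelled reference matrix", {
  ref <- make_ref(seed = 9, n_genes = 200, n_markers = 8)
  # expand profile means into 2 noise-free replicate columns per type
  cols <- do.call(cbind, rep(lapply(seq_along(ref$cell_types), function(i) {
    ref$mean_log2[, i]
  }), each = 2))
  labels <- rep(ref$cell_types, each = 2)
  colnames(cols) <- sprintf("r%02d", seq_len(ncol(cols)))
  m <- expression_matrix(cols, "log2")
  sig <- derive_signature(m, "TPH", n_top = 8, min_fc = 1.5,
                          type_labels = labels)
  expect_setequal(sig$genes, ref$marker_map$TPH)
})

test_that("rank_genes sorts by expression with deterministic tie-breaks", {
  m <- make_expr(matrix(c(3, 1, 2), 3, 1), genes = c("A", "B", "C"),
                 samples = "s1")
  expect_equal(rank_genes(m, "s1"), c("A", "C", "B"))
  tie <- make_expr(matrix(c(2, 2), 2, 1), genes = c("B", "A"), samples = "s1")
  expect_equal(rank_genes(tie, "s1"), c("A", "B"))
  # permuting row order leaves the ranking unchanged
  perm <- make_expr(matrix(c(2, 2), 2, 1), genes = c("A", "B"), samples = "s1")
  expect_equal(rank_genes(perm, "s1"), rank_genes(tie, "s1"))
  expect_error(rank_genes(m, "nope"), "unknown sample")
})

test_that("enrichment_score reproduces hand-enumerated extremes", {
  ranked <- sprintf("g%02d", 1:10)
  expect_equal(enrichment_score(ranked, gene_signature("s", ranked[1:2])), 1)
  expect_equal(enrichment_score(ranked, gene_signature("s", ranked[9:10])), -1)
  # hand enumeration for hits at ranks 1-2: 0.5, 1.0, then -0.125 steps
  es <- enrichment_score(ranked, gene_signature("s", ranked[1:2]))
  expect_equal(es, es_oracle(ranked, ranked[1:2]))
  expect_error(enrichment_score(ranked, gene_signature("s", "absent")),
               "no genes")
  expect_error(enrichment_score(ranked, gene_signature("s", ranked)),
               "entire ranked list")
})

test_that("enrichment_score equals the step-by-step oracle on random instances", {
  set.seed(17)
  for (i in 1:300) {
    n <- sample(5:60, 1)
    s <- sample(1:(n - 1), 1)
    ranked <- sample(sprintf("g%03d", 1:n))
    sig <- sample(ranked, s)
    expect_identical(enrichment_score(ranked, gene_signature("x", sig)),
                     es_oracle(ranked, sig))
  }
})

test_that("moving a signature gene up in rank never decreases a positive ES", {
  # exhaustive over all placements for N <= 12, |S| = 2
  for (n in c(6, 9, 12)) {
    ranked <- sprintf("g%02d", 1:n)
    combos <- utils::combn(n, 2)
    for (j in seq_len(ncol(combos))) {
      pos <- combos[, j]
      es <- enrichment_score(ranked, gene_signature("x", ranked[pos]))
      if (pos[1] > 1 && es > 0) {
        up <- c(pos[1] - 1, pos[2])
        if (up[1] != up[2]) {
          es_up <- enrichment_score(ranked, gene_signature("x", ranked[up]))
          expect_gte(es_up, es - 1e-12)
        }
      }
    }
  }
})

test_that("ES is invariant to positive affine transforms of a sample", {
  set.seed(23)
  vals <- matrix(rnorm(200, 7), 100, 2)
  m <- make_expr(vals)
  sig <- gene_signature("x", rownames(m)[sample(100, 12)])
  base <- suppressMessages(score_samples(m, sig))
  shifted <- vals
  shifted[, 1] <- 1.7 * shifted[, 1] + 3.2
  m2 <- make_expr(shifted)
  after <- suppressMessages(score_samples(m2, sig))
  expect_identical(unclass(base), unclass(after))
})

test_that("score_samples drops missing genes with a message and validates", {
  set.seed(29)
  m <- make_expr(matrix(rnorm(300, 7), 100, 3))
  sig_ok <- gene_signature("ok", c(rownames(m)[1:10], "ghost"))
  expect_message(es <- score_samples(m, sig_ok), "dropped 1")
  expect_equal(attr(es, "dropped_genes")[["ok"]], 1)
  expect_true(all(abs(es) <= 1))
  expect_equal(dim(es), c(3L, 1L))

  # duplicate signature gives identical columns
  es2 <- suppressMessages(score_samples(m, list(sig_ok, sig_ok)))
  expect_equal(unname(es2[, 1]), unname(es2[, 2]))

  expect_error(score_samples(m, gene_signature("bad", "ghost")),
               "no genes on the matrix")
})

test_that("pure single-type samples score in the top decile for their signature", {
  ref <- make_ref(seed = 31, n_genes = 500, n_markers = 15)
  n <- 20
  co <- generate_cohort(ref, n_responders = n / 2, n_nonresponders = n / 2,
                        noise_sd = 0.3, n_de_genes = 0,
                        batches = c(b = 0),
                        tph_fractions = c(1, rep(0.05, n - 1)),
                        seed = 31)
  sig <- derive_signature(ref, "TPH", n_top = 15)
  es <- score_samples(co$matrix, sig)
  pure <- es[co$sheet$sample_id[co$sheet$patient_id == "P01"], 1]
  expect_true(all(pure >= quantile(es[, 1], 0.9)))
})

test_that("associate_with_response labels direction and is symmetric", {
  sheet <- sample_sheet(make_sheet(3, 3))
  es <- matrix(c(0.1, 0.1, 0.2, 0.15, 0.12, 0.14,
                 0.5, 0.45, 0.55, 0.52, 0.48, 0.51),
               12, 1, dimnames = list(sheet$sample_id, "SIG"))
  class(es) <- c("EnrichmentScoreMatrix", "matrix", "array")
  res <- associate_with_response(es, sheet, "week0")
  expect_equal(res$direction, "lower_in_responders")
  expect_lt(res$p_value, 0.05)

  # flipping the group labels flips direction, keeps p
  flipped <- sheet
  flipped$response <- rev(flipped$response)
  flipped$responder_flag <- rev(flipped$responder_flag)
  res2 <- associate_with_response(es, flipped, "week0")
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(res2$direction, "higher_in_responders")

  # constant scores: p = 1, direction none
  es_const <- es; es_const[] <- 0.3
  res3 <- associate_with_response(es_const, sheet, "week0")
  expect_equal(res3$p_value, 1)
  expect_equal(res3$direction, "none")
})

test_that("compare_longitudinal pairs by patient and detects planted shifts", {
  sheet <- sample_sheet(make_sheet(3, 2))
  base <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  es <- matrix(NA_real_, 10, 1, dimnames = list(sheet$sample_id, "SIG"))
  for (i in seq_along(base)) {
    es[sheet$sample_id[sheet$patient_id == sprintf("P%02d", i)], 1] <- base[i]
  }
  class(es) <- c("EnrichmentScoreMatrix", "matrix", "array")
  # identical week0/week20 per patient: paired p = 1
  out <- compare_longitudinal(es, sheet, "SIG")
  expect_equal(out$within_group$p_value, c(1, 1))

  # constant +delta shift on responders' week20: mean change = delta exactly
  delta <- 0.07
  shifted <- es
  rows <- sheet$sample_id[sheet$timepoint == "week20" & sheet$responder_flag]
  shifted[rows, 1] <- shifted[rows, 1] + delta
  out2 <- compare_longitudinal(shifted, sheet, "SIG")
  expect_equal(out2$within_group$mean_change[out2$within_group$group == "responder"],
               delta)
  expect_error(compare_longitudinal(es, sheet, "nope"), "unknown signature")
})
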