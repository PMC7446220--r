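# synthetic_data: generator contracts — determinism, planted structure,
# exact mixture arithmetic.

test_that("reference profiles plant disjoint elevated markers deterministically", {
  ref <- generate_reference_profiles(100, paste0("T", 1:4), 10, 2.0, seed = 1)
  all_markers <- unlist(ref$marker_map)
  expect_length(all_markers, 40)
  expect_false(anyDuplicated(all_markers) > 0)
  for (tp in ref$cell_types) {
    own <- ref$mean_log2[ref$marker_map[[tp]], tp]
    others <- ref$mean_log2[ref$marker_map[[tp]],
                            setdiff(ref$cell_types, tp), drop = FALSE]
    expect_true(all(own - apply(others, 1, max) >= 2.0 - 1e-9))
  }
  expect_true(all(is.finite(ref$mean_log2)))

  # bit-identical under the same seed; different under another
  ref2 <- generate_reference_profiles(100, paste0("T", 1:4), 10, 2.0, seed = 1)
  expect_identical(ref, ref2)
  ref3 <- generate_reference_profiles(100, paste0("T", 1:4), 10, 2.0, seed = 2)
  expect_false(identical(ref$mean_log2, ref3$mean_log2))

  # degenerate: zero markers
  none <- generate_reference_profiles(50, c("A", "B"), 0, 2.0, seed = 1)
  expect_true(all(lengths(none$marker_map) == 0))
  expect_error(generate_reference_profiles(10, paste0("T", 1:4), 5, 2.0, 1),
               "infeasible")
})

test_that("cohort mixtures are exact on the linear scale", {
  ref <- generate_reference_profiles(60, c("TPH", "F1"), 5, 2.0, seed = 2)
  co <- generate_cohort(ref, n_responders = 2, n_nonresponders = 2,
                        noise_sd = 0, n_de_genes = 0, batches = c(b = 0),
                        jitter_concentration = Inf,
                        tph_fraction_resp = 0.2, tph_fraction_nonresp = 0.2,
                        seed = 2)
  lin_expected <- 2^ref$mean_log2 %*% t(co$truth$fractions)
  expect_equal(2^unclass(co$matrix), lin_expected, tolerance = 1e-9,
               ignore_attr = TRUE)

  # identity mixture: single cell type with weight 1 reproduces its profile
  solo <- generate_reference_profiles(40, "TPH", 0, 2.0, seed = 3)
  co1 <- generate_cohort(solo, n_responders = 2, n_nonresponders = 2,
                         noise_sd = 0, n_de_genes = 0, batches = c(b = 0),
                         tph_fraction_resp = 1, tph_fraction_nonresp = 1,
                         jitter_concentration = Inf, seed = 3)
  for (s in co1$sheet$sample_id) {
    expect_equal(unname(unclass(co1$matrix)[, s]),
                 unname(solo$mean_log2[, "TPH"]))
  }
})

test_that("cohort structure: pairing, groups, batches, planted DE", {
  ref <- make_ref(seed = 4, n_genes = 300, n_markers = 10)
  co <- generate_cohort(ref, seed = 4)
  sheet <- co$sheet
  expect_equal(nrow(sheet), 22)
  expect_equal(sum(sheet$responder_flag), 16)  # 8 patients x 2 timepoints
  expect_true(all(table(sheet$patient_id) == 2))
  # both timepoints of a patient share a batch; batches round-robin
  by_pat <- tapply(sheet$batch, sheet$patient_id, unique)
  expect_true(all(lengths(by_pat) == 1))
  expect_equal(sort(unique(sheet$batch)), c("batch1", "batch2"))

  # fractions sum to 1 and the planted DE sets are disjoint non-markers
  expect_equal(unname(rowSums(co$truth$fractions)), rep(1, 22),
               tolerance = 1e-9)
  expect_length(intersect(co$truth$de_genes_up_resp,
                          co$truth$de_genes_up_nonresp), 0)
  expect_length(intersect(unlist(ref$marker_map),
                          c(co$truth$de_genes_up_resp,
                            co$truth$de_genes_up_nonresp)), 0)

  # exact group separation with jitter disabled
  co0 <- generate_cohort(ref, tph_fraction_resp = 0.05,
                         tph_fraction_nonresp = 0.15,
                         jitter_concentration = Inf, seed = 4)
  fr <- co0$truth$fractions[co0$sheet$sample_id, "TPH"]
  expect_equal(mean(fr[!co0$sheet$responder_flag]) -
                 mean(fr[co0$sheet$responder_flag]), 0.10)

  # determinism
  expect_identical(generate_cohort(ref, seed = 4)$matrix, co$matrix)
  expect_error(generate_cohort(ref, noise_sd = -1, seed = 1), "nonnegative")
  expect_error(generate_cohort(ref, tph_fraction_resp = 1.2, seed = 1),
               "\\[0, 1\\]")
})

test_that("planted GO terms overlap their DE set by the stated count", {
  genes <- sprintf("g%05d", 1:500)
  de <- genes[1:20]
  go <- generate_go_annotation(genes, n_terms = 10,
                               planted_terms = list(de = de),
                               planted_size = 10, planted_overlap = 0.8,
                               seed = 5)
  planted <- go$annotation[[go$truth]]
  expect_length(planted$genes, 10)
  expect_length(intersect(planted$genes, de), 8)

  # empty annotation propagates cleanly
  empty <- generate_go_annotation(genes, n_terms = 0, seed = 5)
  expect_length(empty$annotation, 0)

  expect_identical(generate_go_annotation(genes, 10, seed = 6)$annotation,
                   generate_go_annotation(genes, 10, seed = 6)$annotation)
  expect_error(generate_go_annotation(genes[1:5], n_terms = 2,
                                      term_size_range = c(10, 20), seed = 1),
               "universe")
})

test_that("qPCR generator is a seeded linear map of expression", {
  m <- make_expr(matrix(c(10, 5, 8, 5), 2, 2), genes = c("T", "E"))
  tab <- generate_qpcr(m, "T", "E", slope = -1, intercept = 30,
                       noise_sd = 0, seed = 7)
  expect_equal(tab$ct[tab$gene_id == "T" & tab$sample_id == "s01"], 20)
  expect_equal(tab$ct[tab$gene_id == "T" & tab$sample_id == "s02"], 22)
  expect_identical(generate_qpcr(m, "T", "E", noise_sd = 0.2, seed = 8),
                   generate_qpcr(m, "T", "E", noise_sd = 0.2, seed = 8))
  expect_error(generate_qpcr(m, "ghost", "E", seed = 1), "absent")
  expect_error(generate_qpcr(m, "T", "E", slope = 1, seed = 1), "negative")
})

test_that("generator streams are independent across operation tags", {
  ref <- generate_reference_profiles(100, c("TPH", "F1"), 5, 2, seed = 10)
  co_a <- generate_cohort(ref, n_de_genes = 0, seed = 10)
  # an interleaved unrelated generator call must not change the cohort
  invisible(generate_go_annotation(sprintf("g%05d", 1:100), 5, seed = 10))
  co_b <- generate_cohort(ref, n_de_genes = 0, seed = 10)
  expect_identical(co_a$matrix, co_b$matrix)
})
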