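## Pipeline orchestration: one config drives preprocess -> differential
## expression -> GO over-representation -> enrichment-score deconvolution
## -> optional qPCR validation, writing all tabular outputs as TSV plus a
## machine-readable JSON summary.  Given the same config and seed, a run is
## byte-identical (timings go to stderr only, never into outputs).

#' Default pipeline configuration
#'
#' A fully synthetic configuration exercising every stage with the
#' package's stated-world defaults: 2,000 genes, four cell types (a
#' T_PH-like type plus three synovial fibroblast subtypes), 54 planted
#' markers per type at +2 log2, 8 responders vs 3 non-responders sampled at
#' week0/week20, T_PH fractions 0.05 vs 0.15, noise sd 0.3, 20 planted DE
#' genes at +1 log2, two batches shifted by 0.3 log2, 50 random GO terms
#' plus planted ones.
#'
#' @param seed integer seed.
#' @return a config list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    thresholds = list(p_nominal = 0.05, fc_threshold = 1.2, alpha = 0.05),
    contrasts = c("baseline", "week20", "longitudinal-responders"),
    synthetic = list(
      n_genes = 2000,
      cell_types = c("TPH", "CD34pos", "CD34neg_THY1pos", "CD34neg_THY1neg"),
      n_markers_per_type = 54,
      marker_effect = 2.0,
      n_responders = 8, n_nonresponders = 3,
      tph_fraction_resp = 0.05, tph_fraction_nonresp = 0.15,
      noise_sd = 0.3, n_de_genes = 20, de_effect = 1.0,
      batches = c(batch1 = 0, batch2 = 0.3),
      n_go_terms = 50,
      qpcr = TRUE
    )
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  has_synth <- !is.null(config$synthetic)
  has_real <- !is.null(config$inputs)
  if (has_synth == has_real) {
    stop("config must contain exactly one of 'synthetic' or 'inputs'")
  }
  th <- config$thresholds
  if (is.null(th)) th <- list()
  defaults <- list(p_nominal = 0.05, fc_threshold = 1.2, alpha = 0.05)
  for (nm in names(defaults)) if (is.null(th[[nm]])) th[[nm]] <- defaults[[nm]]
  if (th$p_nominal <= 0 || th$p_nominal > 1 || th$fc_threshold < 1 ||
      th$alpha <= 0 || th$alpha > 1) {
    stop("thresholds out of range")
  }
  config$thresholds <- th
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$contrasts)) {
    config$contrasts <- c("baseline", "week20", "longitudinal-responders")
  }
  config
}

write_tsv_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  for (j in which(num)) df[[j]] <- format_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.2fs", stage,
                  as.numeric(proc.time()[["elapsed"]]) - t0))
}

#' Run the full analysis pipeline
#'
#' Sequences preprocessing (quantile normalization and, with >= 2 batches,
#' empirical-Bayes batch adjustment), the configured differential
#' expression contrasts, GO over-representation on the selected gene lists,
#' enrichment-score deconvolution with response association and
#' longitudinal comparison, and (if a Ct table is available) delta-delta-Ct
#' qPCR validation.  All tables are written under `out_dir` along with
#' `summary.json`.
#'
#' @param config config list or JSON path; see [default_config()].  A real
#'   data run uses `config$inputs` with paths `matrix`, `sample_sheet`,
#'   `signatures` (GMT), `annotation`, and optionally `qpcr_table` +
#'   `qpcr_endogenous`; a synthetic run uses `config$synthetic`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  t0 <- as.numeric(proc.time()[["elapsed"]])

  ## ---- stage 1: acquire inputs -------------------------------------
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    ref <- generate_reference_profiles(
      n_genes = sy$n_genes, cell_types = sy$cell_types,
      n_markers_per_type = sy$n_markers_per_type,
      marker_effect = sy$marker_effect, seed = seed
    )
    cohort <- generate_cohort(
      ref,
      n_responders = sy$n_responders, n_nonresponders = sy$n_nonresponders,
      tph_fraction_resp = sy$tph_fraction_resp,
      tph_fraction_nonresp = sy$tph_fraction_nonresp,
      noise_sd = sy$noise_sd, n_de_genes = sy$n_de_genes,
      de_effect = sy$de_effect, batches = unlist(sy$batches), seed = seed
    )
    mat <- cohort$matrix
    sheet <- cohort$sheet
    go <- generate_go_annotation(
      rownames(mat), n_terms = sy$n_go_terms,
      planted_terms = list(
        up_resp = cohort$truth$de_genes_up_resp,
        up_nonresp = cohort$truth$de_genes_up_nonresp
      ),
      seed = seed
    )
    annotation <- go$annotation
    signatures <- lapply(ref$cell_types, function(tp) {
      derive_signature(ref, tp, n_top = 100, min_fc = 1.5)
    })
    qpcr_tab <- NULL
    if (isTRUE(sy$qpcr)) {
      targets <- utils::head(cohort$truth$de_genes_up_resp, 2L)
      endo <- setdiff(rownames(mat), unlist(ref$marker_map))[1L]
      qpcr_tab <- generate_qpcr(mat, targets, endo, noise_sd = 0, seed = seed)
    }
  } else {
    inp <- config$inputs
    mat <- read_expression_tsv(inp$matrix,
                               scale = if (is.null(inp$scale)) "log2" else inp$scale)
    sheet <- read_sample_sheet(inp$sample_sheet)
    signatures <- read_gmt(inp$signatures)
    annotation <- read_go_annotation(inp$annotation)
    qpcr_tab <- if (!is.null(inp$qpcr_table)) {
      read_qpcr_table(inp$qpcr_table, inp$qpcr_endogenous)
    }
  }
  stage_msg("acquire", t0); t0 <- as.numeric(proc.time()[["elapsed"]])

  ## ---- stage 2: preprocess -----------------------------------------
  if (expr_scale(mat) == "raw") mat <- log2_transform(mat)
  mat <- quantile_normalize(mat)
  batch <- stats::setNames(sheet$batch, sheet$sample_id)
  if (length(unique(batch)) >= 2L) {
    mat <- batch_adjust(mat, batch)
  }
  write_expression_tsv(mat, file.path(out_dir, "expression_preprocessed.tsv"))
  stage_msg("preprocess", t0); t0 <- as.numeric(proc.time()[["elapsed"]])

  ## ---- stage 3: differential expression ----------------------------
  resp <- sheet$sample_id[sheet$responder_flag]
  nonresp <- sheet$sample_id[!sheet$responder_flag]
  de_results <- list()
  for (ct in config$contrasts) {
    de_results[[ct]] <- switch(
      ct,
      "baseline" = de_contrast(
        mat,
        intersect(resp, sheet$sample_id[sheet$timepoint == "week0"]),
        intersect(nonresp, sheet$sample_id[sheet$timepoint == "week0"])
      ),
      "week20" = de_contrast(
        mat,
        intersect(resp, sheet$sample_id[sheet$timepoint == "week20"]),
        intersect(nonresp, sheet$sample_id[sheet$timepoint == "week20"])
      ),
      "longitudinal-responders" = {
        rsub <- sheet[sheet$responder_flag, , drop = FALSE]
        pats <- intersect(rsub$patient_id[rsub$timepoint == "week0"],
                          rsub$patient_id[rsub$timepoint == "week20"])
        w0 <- rsub$sample_id[match(paste(pats, "week0"),
                                   paste(rsub$patient_id, rsub$timepoint))]
        w20 <- rsub$sample_id[match(paste(pats, "week20"),
                                    paste(rsub$patient_id, rsub$timepoint))]
        de_contrast(mat, w20, w0, paired = TRUE)
      },
      stop("unknown contrast: ", ct)
    )
    write_tsv_table(de_results[[ct]],
                    file.path(out_dir, paste0("de_", gsub("[^a-z0-9]+", "_", ct), ".tsv")))
  }
  stage_msg("diffexpr", t0); t0 <- as.numeric(proc.time()[["elapsed"]])

  ## ---- stage 4: GO over-representation -----------------------------
  annotated <- unique(unlist(lapply(annotation, `[[`, "genes")))
  universe <- intersect(rownames(mat), annotated)
  group_labels <- list(
    "baseline" = c("Response", "Non-response"),
    "week20" = c("Response", "Non-response"),
    "longitudinal-responders" = c("Upregulated", "Downregulated")
  )
  enrich_results <- list()
  for (ct in names(de_results)) {
    sel <- select_de_genes(de_results[[ct]],
                           p_nominal = config$thresholds$p_nominal,
                           fc_threshold = config$thresholds$fc_threshold)
    labels <- group_labels[[ct]]
    lists <- list(intersect(sel$genes_up_in_A, universe),
                  intersect(sel$genes_up_in_B, universe))
    for (k in 1:2) {
      if (length(universe) == 0L || length(lists[[k]]) == 0L) next
      key <- paste0(ct, ":", labels[k])
      enrich_results[[key]] <- enrich(lists[[k]], annotation, universe,
                                      group_label = labels[k])
    }
  }
  if (length(enrich_results)) {
    all_enrich <- do.call(rbind, c(enrich_results, make.row.names = FALSE))
    all_enrich <- cbind(contrast = rep(sub(":.*$", "", names(enrich_results)),
                                       vapply(enrich_results, nrow, integer(1L))),
                        all_enrich)
    write_tsv_table(all_enrich, file.path(out_dir, "go_enrichment.tsv"))
  }
  stage_msg("enrich", t0); t0 <- as.numeric(proc.time()[["elapsed"]])

  ## ---- stage 5: deconvolution --------------------------------------
  scores <- suppressMessages(score_samples(mat, signatures))
  es_df <- data.frame(sample_id = rownames(scores),
                      as.data.frame(unclass(scores)),
                      check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(es_df, file.path(out_dir, "enrichment_scores.tsv"))
  assoc <- rbind(
    associate_with_response(scores, sheet, timepoint = "week0"),
    associate_with_response(scores, sheet, timepoint = "week20")
  )
  write_tsv_table(assoc, file.path(out_dir, "es_association.tsv"))
  longit <- lapply(colnames(scores), function(sig) {
    compare_longitudinal(scores, sheet, sig)$within_group
  })
  longit_df <- do.call(rbind, lapply(seq_along(longit), function(i) {
    cbind(signature = colnames(scores)[i], longit[[i]])
  }))
  write_tsv_table(longit_df, file.path(out_dir, "es_longitudinal.tsv"))
  stage_msg("deconvolution", t0); t0 <- as.numeric(proc.time()[["elapsed"]])

  ## ---- stage 6: qPCR validation ------------------------------------
  qpcr_summary <- NULL
  if (!is.null(qpcr_tab)) {
    targets <- setdiff(unique(qpcr_tab$gene_id), endogenous_gene(qpcr_tab))
    qrows <- lapply(targets, function(g) {
      out <- qpcr_array_correlation(qpcr_tab, mat, g)
      data.frame(gene_id = g, r = out$correlation$r,
                 r_squared = out$correlation$r_squared,
                 p_value = out$correlation$p_value, stringsAsFactors = FALSE)
    })
    qpcr_summary <- do.call(rbind, qrows)
    write_tsv_table(qpcr_summary, file.path(out_dir, "qpcr_correlation.tsv"))
  }
  stage_msg("qpcr", t0)

  ## ---- summary ------------------------------------------------------
  tph_sig <- colnames(scores)[1L]
  assoc0 <- assoc[assoc$contrast == "responder_vs_non@week0", , drop = FALSE]
  summary <- list(
    package_version = as.character(utils::packageVersion("specdeconv")),
    seed = seed,
    config_hash = content_hash(as.character(
      jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
    )),
    thresholds = config$thresholds,
    n_genes = nrow(mat),
    n_samples = ncol(mat),
    final_scale = expr_scale(mat),
    signature_sizes = stats::setNames(
      lapply(signatures, function(s) length(s$genes)),
      vapply(signatures, `[[`, character(1L), "name")
    ),
    signature_dropped_genes = as.list(attr(scores, "dropped_genes")),
    de_selected = lapply(de_results, function(r) {
      sel <- select_de_genes(r, config$thresholds$p_nominal,
                             config$thresholds$fc_threshold)
      list(n_up_in_A = length(sel$genes_up_in_A),
           n_up_in_B = length(sel$genes_up_in_B),
           n_bonferroni_significant =
             sum(r$p_bonferroni < config$thresholds$alpha))
    }),
    go_significant = lapply(enrich_results, function(r) {
      sum(r$p_adjusted < config$thresholds$alpha)
    }),
    association_week0 = stats::setNames(
      lapply(seq_len(nrow(assoc0)), function(i) {
        list(p_value = assoc0$p_value[i], direction = assoc0$direction[i])
      }), assoc0$signature
    ),
    tph_signature = tph_sig,
    qpcr = if (!is.null(qpcr_summary)) {
      stats::setNames(
        lapply(seq_len(nrow(qpcr_summary)), function(i) {
          list(r = qpcr_summary$r[i], r_squared = qpcr_summary$r_squared[i],
               p_value = qpcr_summary$p_value[i])
        }), qpcr_summary$gene_id
      )
    }
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
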