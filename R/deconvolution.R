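## Per-sample enrichment-score deconvolution of cell subsets.
##
## The estimator follows the SPEC (Subset Prediction from Enrichment
## Correlation) idea: a cell subset's contribution to a bulk sample is
## summarized by how high the subset's signature genes sit in that sample's
## ranked expression profile, measured with the classic unweighted
## (Kolmogorov-Smirnov) GSEA running-sum statistic.  Walking down the
## ranked list, the running sum gains 1/|S| at each signature gene and
## loses 1/(N - |S|) at each other gene; the enrichment score (ES) is the
## signed maximum deviation from zero, which lies in [-1, 1].  The ES
## depends only on within-sample ranks, so it is invariant to any positive
## affine transform of a sample's expression values.

#' Derive a cell-type marker signature from reference profiles
#'
#' Ranks genes by their one-vs-rest log2 fold change (target-type mean
#' minus the maximum of all other types' means) and keeps the top `n_top`
#' genes whose fold change strictly exceeds `min_fc` (a linear-scale
#' ratio).  Ties in fold change are broken ascending by gene id, making the
#' selection deterministic.
#'
#' @param ref a `ReferenceProfiles` object (see
#'   [generate_reference_profiles()]) or an `ExpressionMatrix` of reference
#'   samples together with `type_labels`.
#' @param target_type cell type whose signature is derived.
#' @param n_top maximum signature size (default 100, a common size for
#'   subset marker panels).
#' @param min_fc minimum one-vs-rest linear fold change (default 1.5).
#' @param type_labels per-column cell-type labels, required when `ref` is
#'   an `ExpressionMatrix` of profiled reference samples.
#' @return a [gene_signature()] named after `target_type`.
#' @export
derive_signature <- function(ref, target_type, n_top = 100, min_fc = 1.5,
                             type_labels = NULL) {
  if (inherits(ref, "ReferenceProfiles")) {
    means <- ref$mean_log2
  } else if (inherits(ref, "ExpressionMatrix")) {
    if (is.null(type_labels) || length(type_labels) != ncol(ref)) {
      stop("type_labels (one per reference column) required for an ExpressionMatrix")
    }
    types <- unique(as.character(type_labels))
    means <- vapply(types, function(tp) {
      rowMeans(unclass(ref)[, type_labels == tp, drop = FALSE])
    }, numeric(nrow(ref)))
  } else {
    stop("ref must be ReferenceProfiles or an ExpressionMatrix")
  }
  if (ncol(means) < 2L) stop("need at least 2 cell types")
  if (!target_type %in% colnames(means)) {
    stop("unknown cell type: ", target_type)
  }
  other <- means[, setdiff(colnames(means), target_type), drop = FALSE]
  lfc <- means[, target_type] - apply(other, 1L, max)
  keep <- lfc > log2(min_fc)
  if (!any(keep)) {
    stop("no gene exceeds min_fc = ", min_fc, " for type '", target_type, "'")
  }
  ids <- rownames(means)[keep]
  lfc <- lfc[keep]
  ord <- order_radix(-lfc, ids)
  ids <- ids[ord][seq_len(min(n_top, length(ids)))]
  gene_signature(target_type, ids,
                 description = sprintf("top %d one-vs-rest markers", length(ids)))
}

#' Rank the genes of one sample
#'
#' Genes sorted by descending expression in the given sample; ties are
#' broken ascending by gene id so the order is a deterministic total order
#' independent of the matrix's row order.
#'
#' @param matrix `ExpressionMatrix`.
#' @param sample_id sample to rank.
#' @return character vector of gene ids, highest expression first.
#' @export
rank_genes <- function(matrix, sample_id) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!sample_id %in% colnames(matrix)) {
    stop("unknown sample: ", sample_id)
  }
  x <- unclass(matrix)[, sample_id]
  rownames(matrix)[order_radix(-x, rownames(matrix))]
}

#' Running-sum enrichment score of a signature in a ranked list
#'
#' The classic unweighted GSEA statistic: walking down the ranking, add
#' 1/|S| at each signature gene and subtract 1/(N-|S|) at each other gene;
#' the ES is the running-sum value of maximal absolute magnitude, keeping
#' its sign (ties in |deviation| resolve to the earliest position).  A
#' signature occupying the top |S| ranks gives ES = +1; the bottom |S|
#' ranks give ES = -1.
#'
#' @param ranked character vector: the full ranked gene list (length N).
#' @param signature a [gene_signature()]; genes absent from `ranked` are
#'   ignored by the caller's contract (see [score_samples()]).
#' @param weights optional non-negative per-gene hit weights (same length
#'   as `ranked`, e.g. |expression|^p for a weighted variant).  `NULL`
#'   (default) is the unweighted statistic.
#' @return ES in [-1, 1].
#' @export
enrichment_score <- function(ranked, signature, weights = NULL) {
  sig_genes <- if (inherits(signature, "GeneSignature")) signature$genes else signature
  n <- length(ranked)
  hit <- ranked %in% sig_genes
  s <- sum(hit)
  if (s == 0L) stop("signature has no genes in the ranked list")
  if (s == n) stop("signature covers the entire ranked list")
  if (is.null(weights)) {
    steps <- ifelse(hit, 1 / s, -1 / (n - s))
  } else {
    if (length(weights) != n || any(weights < 0)) {
      stop("weights must be non-negative, one per ranked gene")
    }
    wsum <- sum(weights[hit])
    if (wsum == 0) stop("all signature-gene weights are zero")
    steps <- ifelse(hit, weights / wsum, -1 / (n - s))
  }
  ## single double-precision pass (not cumsum, which accumulates in long
  ## double): the statistic is defined as the literal step-by-step walk,
  ## and tests hold it to bit-exact agreement with that definition
  rs <- 0
  best <- 0
  for (step in steps) {
    rs <- rs + step
    if (abs(rs) > abs(best)) best <- rs
  }
  ## the statistic lies in [-1, 1] by construction; clamp the last-ulp
  ## accumulation error so the analytic extremes are hit exactly
  max(-1, min(1, best))
}

#' Score all samples against a set of signatures
#'
#' Computes the per-sample ES of each signature via [rank_genes()] +
#' [enrichment_score()].  Signature genes absent from the matrix are
#' dropped; the dropped count per signature is recorded in the
#' `dropped_genes` attribute and reported via `message()`.
#'
#' @param matrix `ExpressionMatrix`.
#' @param signatures list of [gene_signature()] objects (a single signature
#'   is accepted).
#' @return `EnrichmentScoreMatrix`: numeric matrix samples x signatures
#'   with a `dropped_genes` attribute (named integer vector).
#' @export
score_samples <- function(matrix, signatures) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (inherits(signatures, "GeneSignature")) signatures <- list(signatures)
  sig_names <- vapply(signatures, `[[`, character(1L), "name")
  genes <- rownames(matrix)
  dropped <- integer(length(signatures))
  names(dropped) <- sig_names
  kept <- vector("list", length(signatures))
  for (i in seq_along(signatures)) {
    inside <- signatures[[i]]$genes %in% genes
    dropped[i] <- sum(!inside)
    if (!any(inside)) {
      stop("signature '", sig_names[i], "' has no genes on the matrix")
    }
    if (dropped[i] > 0L) {
      message(sprintf("signature '%s': dropped %d gene(s) absent from the matrix",
                      sig_names[i], dropped[i]))
    }
    kept[[i]] <- signatures[[i]]$genes[inside]
  }
  es <- matrix(NA_real_, ncol(matrix), length(signatures),
               dimnames = list(colnames(matrix), sig_names))
  for (sample in colnames(matrix)) {
    ranked <- rank_genes(matrix, sample)
    for (i in seq_along(kept)) {
      es[sample, i] <- enrichment_score(ranked, kept[[i]])
    }
  }
  structure(es, dropped_genes = dropped,
            class = c("EnrichmentScoreMatrix", "matrix", "array"))
}

#' Test association of enrichment scores with clinical response
#'
#' Two-sided Welch t-test of each signature's ES between response groups at
#' one timepoint.  `grouping = "responder_vs_non"` contrasts EULAR
#' good+moderate vs none; `"good_vs_rest"` contrasts good vs
#' moderate+none.
#'
#' @param scores an `EnrichmentScoreMatrix` from [score_samples()].
#' @param sheet a [sample_sheet()] covering the scored samples.
#' @param timepoint `"week0"` or `"week20"`.
#' @param grouping group definition (see above).
#' @return `AssociationResult` data.frame: `signature`, `contrast`,
#'   `mean_responder`, `mean_nonresponder`, `t_statistic`, `p_value`,
#'   `direction` (`lower_in_responders` / `higher_in_responders` / `none`).
#' @export
associate_with_response <- function(scores, sheet, timepoint = "week0",
                                    grouping = c("responder_vs_non",
                                                 "good_vs_rest")) {
  grouping <- match.arg(grouping)
  timepoint <- match.arg(timepoint, c("week0", "week20"))
  sub <- sheet[sheet$timepoint == timepoint &
                 sheet$sample_id %in% rownames(scores), , drop = FALSE]
  in_a <- if (grouping == "responder_vs_non") sub$responder_flag
          else sub$response == "good"
  a_ids <- sub$sample_id[in_a]
  b_ids <- sub$sample_id[!in_a]
  if (length(a_ids) < 2L || length(b_ids) < 2L) {
    stop("need at least 2 samples per group at ", timepoint)
  }
  res <- do.call(rbind, lapply(colnames(scores), function(sig) {
    wt <- welch_scalar(scores[a_ids, sig], scores[b_ids, sig])
    md <- mean(scores[a_ids, sig]) - mean(scores[b_ids, sig])
    data.frame(
      signature = sig,
      contrast = paste0(grouping, "@", timepoint),
      mean_responder = mean(scores[a_ids, sig]),
      mean_nonresponder = mean(scores[b_ids, sig]),
      t_statistic = wt$t,
      p_value = wt$p,
      direction = if (md < 0) "lower_in_responders"
                  else if (md > 0) "higher_in_responders" else "none",
      stringsAsFactors = FALSE
    )
  }))
  rownames(res) <- NULL
  class(res) <- c("AssociationResult", "data.frame")
  res
}

## Scalar Welch t-test with the package's degenerate-variance conventions.
welch_scalar <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  d <- mean(x) - mean(y)
  if (se2 == 0) {
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0))
  }
  t <- d / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

## Scalar paired t-test on differences.
paired_scalar <- function(d) {
  n <- length(d)
  m <- mean(d)
  v <- stats::var(d)
  if (v == 0) {
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                p = if (m == 0) 1 else 0, mean_diff = m, n = n))
  }
  t <- m / sqrt(v / n)
  list(t = t, p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
       mean_diff = m, n = n)
}

#' Longitudinal comparison of enrichment scores
#'
#' Within each response group, a paired t-test of week20 - week0 ES across
#' patients with both timepoints; plus the cross-sectional
#' responder-vs-non-responder test at week 20.
#'
#' @param scores an `EnrichmentScoreMatrix`.
#' @param sheet a [sample_sheet()].
#' @param signature signature (column) name to compare.
#' @return list with `within_group` (data.frame: `group`, `n_pairs`,
#'   `mean_change`, `t_statistic`, `p_value`) and `week20_cross_sectional`
#'   (one-row `AssociationResult`).
#' @export
compare_longitudinal <- function(scores, sheet, signature) {
  if (!signature %in% colnames(scores)) {
    stop("unknown signature: ", signature)
  }
  groups <- list(responder = sheet$responder_flag,
                 nonresponder = !sheet$responder_flag)
  rows <- lapply(names(groups), function(g) {
    sub <- sheet[groups[[g]], , drop = FALSE]
    w0 <- sub[sub$timepoint == "week0", c("patient_id", "sample_id")]
    w20 <- sub[sub$timepoint == "week20", c("patient_id", "sample_id")]
    common <- intersect(w0$patient_id, w20$patient_id)
    common <- common[w0$sample_id[match(common, w0$patient_id)] %in% rownames(scores) &
                       w20$sample_id[match(common, w20$patient_id)] %in% rownames(scores)]
    if (length(common) < 2L) {
      return(data.frame(group = g, n_pairs = length(common),
                        mean_change = NA_real_, t_statistic = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    d <- scores[w20$sample_id[match(common, w20$patient_id)], signature] -
      scores[w0$sample_id[match(common, w0$patient_id)], signature]
    pt <- paired_scalar(d)
    data.frame(group = g, n_pairs = pt$n, mean_change = pt$mean_diff,
               t_statistic = pt$t, p_value = pt$p, stringsAsFactors = FALSE)
  })
  within <- do.call(rbind, rows)
  if (all(within$n_pairs == 0)) stop("no complete week0/week20 pairs")
  cross <- associate_with_response(scores, sheet, timepoint = "week20",
                                   grouping = "responder_vs_non")
  list(within_group = within,
       week20_cross_sectional = cross[cross$signature == signature, ,
                                      drop = FALSE])
}
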