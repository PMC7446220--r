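## Relative qPCR quantification (delta-delta-Ct) and its correlation with
## array-derived expression, mirroring the usual technical-validation step:
## delta-Ct normalizes each sample's target Ct by the endogenous control,
## delta-delta-Ct references a calibrator, and fold change = 2^(-ddCt).

#' Delta-delta-Ct fold change
#'
#' Per sample: `dCt = Ct(target) - Ct(endogenous)`; `ddCt = dCt -
#' dCt(calibrator)`; `fold = 2^(-ddCt)`.  Technical replicates (repeated
#' sample/gene rows) are averaged on the Ct scale before dCt.  The
#' calibrator is one sample id or a vector of sample ids whose mean dCt is
#' the reference; it defaults to all samples (fold changes relative to the
#' cohort mean).
#'
#' @param table a [qpcr_table()].
#' @param target_gene gene to quantify.
#' @param calibrator sample id(s); default all samples in the table.
#' @return `DdctResult` data.frame: `sample_id`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`.
#' @export
ddct_fold_change <- function(table, target_gene, calibrator = NULL) {
  stopifnot(inherits(table, "QpcrTable"))
  endo <- endogenous_gene(table)
  ct_of <- function(gene) {
    sub <- table[table$gene_id == gene, , drop = FALSE]
    tapply(sub$ct, sub$sample_id, mean)
  }
  ct_t <- ct_of(target_gene)
  ct_e <- ct_of(endo)
  samples <- names(ct_e)
  missing <- setdiff(samples, names(ct_t))
  if (length(missing)) {
    stop("target gene '", target_gene, "' not measured for sample(s): ",
         paste(missing, collapse = ", "))
  }
  d_ct <- ct_t[samples] - ct_e[samples]
  if (is.null(calibrator)) calibrator <- samples
  unknown <- setdiff(calibrator, samples)
  if (length(unknown)) {
    stop("calibrator sample(s) not in table: ", paste(unknown, collapse = ", "))
  }
  dd_ct <- d_ct - mean(d_ct[calibrator])
  res <- data.frame(
    sample_id = samples,
    delta_ct = unname(d_ct),
    delta_delta_ct = unname(dd_ct),
    fold_change = unname(2^(-dd_ct)),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("DdctResult", "data.frame")
  res
}

#' Pearson product-moment correlation with t-based p value
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r`, `r_squared`, `p_value` (two-sided, from the t
#'   transform with n - 2 degrees of freedom).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sqrt(sum(dx^2))
  sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) stop("correlation undefined for a constant vector")
  r <- sum(dx * dy) / (sx * sy)
  r <- min(1, max(-1, r))
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  list(r = r, r_squared = r * r, p_value = p)
}

#' Correlate qPCR fold changes with array expression
#'
#' Computes per-sample -2^ddCt-style quantification for a target gene and
#' correlates log2 fold change (equivalently, -ddCt) with the gene's array
#' log2 expression across samples.
#'
#' @param table a [qpcr_table()].
#' @param expr `ExpressionMatrix` on a log2 scale covering the same
#'   samples.
#' @param target_gene gene id.
#' @param calibrator passed to [ddct_fold_change()].
#' @return list with the `DdctResult` and the [pearson_correlation()]
#'   result against the array values.
#' @export
qpcr_array_correlation <- function(table, expr, target_gene,
                                   calibrator = NULL) {
  dd <- ddct_fold_change(table, target_gene, calibrator = calibrator)
  missing <- setdiff(dd$sample_id, colnames(expr))
  if (length(missing)) {
    stop("array matrix lacks sample(s): ", paste(missing, collapse = ", "))
  }
  array_vals <- unclass(expr)[target_gene, dd$sample_id]
  corr <- pearson_correlation(log2(dd$fold_change), array_vals)
  list(ddct = dd, correlation = corr)
}
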