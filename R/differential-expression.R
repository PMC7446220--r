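## Per-gene two-group differential expression: t statistics (Welch by
## default for unpaired contrasts, paired-by-patient for longitudinal
## ones), signed fold changes on the log2 scale, Bonferroni correction, and
## the nominal-P + fold-change gene-selection filter that feeds GO
## over-representation.

#' Per-gene two-group t-test
#'
#' Unpaired contrasts use the two-sided pooled-variance (Student) t-test by
#' default, which is exact under the equal-variance Gaussian noise model;
#' the Welch (unequal-variance) test is available via `var_equal = FALSE`.
#' (At the emulated cohort size of 8 vs 3 the Welch-Satterthwaite tail
#' approximation is ~3x anticonservative at Bonferroni-level thresholds,
#' which would destroy family-wise error calibration; see the methods
#' vignette.)  Paired contrasts use the two-sided paired t-test on
#' within-pair differences, with pairs matched by position in
#' `group_a`/`group_b` (callers match by patient).  Degenerate
#' zero-variance genes follow a documented total-order convention: both
#' groups constant and equal gives t = 0, p = 1; constant and unequal
#' gives p = 0.
#'
#' @param matrix `ExpressionMatrix`.
#' @param group_a,group_b disjoint sample id vectors, each of size >= 2.
#' @param paired if `TRUE`, `group_a[i]` is paired with `group_b[i]`.
#' @param var_equal if `FALSE`, use the Welch test instead of the pooled
#'   Student test for unpaired contrasts.
#' @return data.frame with columns `gene_id`, `t_statistic`, `p_value`.
#' @export
ttest_per_gene <- function(matrix, group_a, group_b, paired = FALSE,
                           var_equal = TRUE) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  check_groups(matrix, group_a, group_b)
  if (paired && length(group_a) != length(group_b)) {
    stop("paired test requires equally sized, matched groups")
  }
  a <- unclass(matrix)[, group_a, drop = FALSE]
  b <- unclass(matrix)[, group_b, drop = FALSE]

  if (paired) {
    d <- a - b
    n <- ncol(d)
    m <- rowMeans(d)
    v <- rowSums((d - m)^2) / (n - 1)
    se <- sqrt(v / n)
    t_stat <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
    df <- rep(n - 1, nrow(d))
  } else {
    n1 <- ncol(a); n2 <- ncol(b)
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    v1 <- rowSums((a - m1)^2) / (n1 - 1)
    v2 <- rowSums((b - m2)^2) / (n2 - 1)
    if (var_equal) {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- rep(n1 + n2 - 2, nrow(a))
    } else {
      se2 <- v1 / n1 + v2 / n2
      se <- sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    diff <- m1 - m2
    t_stat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
    df[!is.finite(df)] <- 1  # only reached alongside se == 0
  }
  p <- ifelse(is.finite(t_stat),
              2 * stats::pt(abs(t_stat), df, lower.tail = FALSE), 0)
  p <- pmin(pmax(p, 0), 1)
  p[se == 0 & t_stat == 0] <- 1
  data.frame(gene_id = rownames(matrix), t_statistic = t_stat,
             p_value = p, stringsAsFactors = FALSE)
}

check_groups <- function(matrix, group_a, group_b) {
  unknown <- setdiff(c(group_a, group_b), colnames(matrix))
  if (length(unknown)) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  }
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint")
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 samples")
  }
  invisible(TRUE)
}

#' Signed per-gene fold change between two groups
#'
#' On a log2 matrix, the linear-scale ratio is r = 2^(mean_A - mean_B).
#' The signed convention reports r when r >= 1 and -1/r otherwise, so a
#' gene twice as high in group B appears as -2.0 and |FC| >= 1 always.
#'
#' @param matrix `ExpressionMatrix` on a log2 scale.
#' @param group_a,group_b non-empty sample id vectors.
#' @return data.frame with `gene_id`, `fold_change`, `direction`
#'   (`up_in_A` / `up_in_B` / `none`).
#' @export
signed_fold_change <- function(matrix, group_a, group_b) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  a <- unclass(matrix)[, group_a, drop = FALSE]
  b <- unclass(matrix)[, group_b, drop = FALSE]
  diff <- rowMeans(a) - rowMeans(b)
  r <- 2^diff
  fc <- ifelse(r >= 1, r, -1 / r)
  direction <- ifelse(diff > 0, "up_in_A", ifelse(diff < 0, "up_in_B", "none"))
  data.frame(gene_id = rownames(matrix), fold_change = fc,
             direction = direction, stringsAsFactors = FALSE)
}

#' Bonferroni correction
#'
#' @param p_values p values in (0, 1].
#' @param m number of tests (>= `length(p_values)`; defaults to it).
#' @return adjusted p values, `min(1, p * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p values must lie in (0, 1]")
  }
  if (m < length(p_values)) stop("m must be >= the number of tests")
  pmin(1, p_values * m)
}

#' Run one full differential-expression contrast
#'
#' Combines the t-test, signed fold change and Bonferroni correction into
#' the standard per-gene result table, sorted by p value.
#'
#' @inheritParams ttest_per_gene
#' @return `DEResult` data.frame: `gene_id`, `t_statistic`, `p_value`,
#'   `p_bonferroni`, `fold_change`, `direction`, sorted by `p_value`
#'   (ties by gene id).
#' @export
de_contrast <- function(matrix, group_a, group_b, paired = FALSE,
                        var_equal = TRUE) {
  tt <- ttest_per_gene(matrix, group_a, group_b, paired = paired,
                       var_equal = var_equal)
  fc <- signed_fold_change(matrix, group_a, group_b)
  res <- data.frame(
    gene_id = tt$gene_id,
    t_statistic = tt$t_statistic,
    p_value = tt$p_value,
    p_bonferroni = pmin(1, tt$p_value * nrow(tt)),
    fold_change = fc$fold_change,
    direction = fc$direction,
    stringsAsFactors = FALSE
  )
  res <- res[order_radix(res$p_value, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Select differentially expressed genes for pathway analysis
#'
#' Keeps genes with nominal p below `p_nominal` and absolute signed fold
#' change strictly above `fc_threshold`, partitioned by direction.  The
#' fold-change inequality is strict: |FC| equal to the threshold is
#' excluded.
#'
#' @param result a `DEResult` from [de_contrast()].
#' @param p_nominal nominal p-value threshold (default 0.05).
#' @param fc_threshold fold-change ratio threshold (default 1.2).
#' @return list with `genes_up_in_A` and `genes_up_in_B` character vectors.
#' @export
select_de_genes <- function(result, p_nominal = 0.05, fc_threshold = 1.2) {
  keep <- result$p_value < p_nominal & abs(result$fold_change) > fc_threshold
  list(
    genes_up_in_A = result$gene_id[keep & result$direction == "up_in_A"],
    genes_up_in_B = result$gene_id[keep & result$direction == "up_in_B"]
  )
}
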