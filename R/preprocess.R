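## Preprocessing: raw intensities -> analysis-ready log2 matrix.
## The three stages mirror standard single-color microarray practice:
## log2 transform, quantile normalization across all samples, and
## empirical-Bayes location-scale batch adjustment (the ComBat algorithm).
## Gene and sample order is never changed by any stage.

#' Log2-transform a raw-intensity expression matrix
#'
#' @param matrix `ExpressionMatrix` on the raw scale.
#' @param offset nonnegative constant added before taking logs; the default
#'   1 guards zero intensities without distorting mid-range values.
#' @return `ExpressionMatrix` on the log2 scale.
#' @export
log2_transform <- function(matrix, offset = 1) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (expr_scale(matrix) != "raw") {
    stop("log2_transform expects a raw-scale matrix, got '", expr_scale(matrix), "'")
  }
  if (offset < 0) stop("offset must be nonnegative")
  if (any(matrix + offset <= 0)) {
    stop("nonpositive intensity after offset; increase the offset")
  }
  out <- log2(unclass(matrix) + offset)
  set_scale(expression_matrix(out, "raw"), "log2")
}

#' Quantile-normalize a log2 expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the across-sample mean of the order statistics.  Within-column ranks are
#' preserved.  Ties within a column receive the mean of the reference
#' quantiles they span, so the result is independent of input row order.
#'
#' @param matrix `ExpressionMatrix` on the log2 scale.
#' @return `ExpressionMatrix` on the log2_quantile scale.
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  x <- unclass(matrix)
  if (ncol(x) < 2L) stop("quantile normalization requires at least 2 samples")
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    ord <- order(col)
    r <- ref
    ## tie groups: runs of equal values share the mean of the reference
    ## quantiles their ranks span
    sorted <- col[ord]
    grp <- cumsum(c(TRUE, sorted[-1L] != sorted[-length(sorted)]))
    r <- stats::ave(ref, grp, FUN = mean)
    out[ord, j] <- r
  }
  dimnames(out) <- dimnames(x)
  set_scale(expression_matrix(out, "raw"), "log2_quantile")
}

#' Empirical-Bayes batch adjustment (ComBat algorithm)
#'
#' Parametric location-scale adjustment: each gene is standardized using
#' pooled mean and variance, per-batch gene-wise locations and scales are
#' estimated, shrunk toward batch-level priors (normal prior on location,
#' inverse-gamma on scale, moment-matched, solved by the standard iterative
#' conditional scheme), removed, and the pooled location/scale restored.
#' With no covariates and a pure additive batch shift, per-gene batch means
#' are equalized.
#'
#' @param matrix `ExpressionMatrix` (log2_quantile scale expected; log2
#'   accepted).
#' @param batches character/factor of batch labels, one per sample (in
#'   column order), or a named vector matched by sample id.
#' @param covariate_groups optional labels per sample for a biological
#'   grouping whose effect must be preserved during standardization.
#' @param conv convergence tolerance of the iterative prior solution.
#' @return `ExpressionMatrix` on the log2_quantile_batchadj scale.
#' @export
batch_adjust <- function(matrix, batches, covariate_groups = NULL,
                         conv = 1e-4) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  dat <- unclass(matrix)
  n_array <- ncol(dat)
  if (!is.null(names(batches))) {
    missing <- setdiff(colnames(dat), names(batches))
    if (length(missing)) {
      stop("no batch label for sample(s): ", paste(missing, collapse = ", "))
    }
    batches <- batches[colnames(dat)]
  }
  if (length(batches) != n_array) {
    stop("need one batch label per sample")
  }
  batch <- factor(as.character(batches), levels = unique(as.character(batches)))
  if (nlevels(batch) < 2L) stop("batch adjustment requires at least 2 batches")
  n_per <- table(batch)
  if (any(n_per < 2L)) {
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "))
  }

  batch_design <- stats::model.matrix(~ -1 + batch)
  design <- batch_design
  if (!is.null(covariate_groups)) {
    grp <- factor(as.character(covariate_groups))
    if (nlevels(grp) > 1L) {
      mm <- stats::model.matrix(~grp)[, -1L, drop = FALSE]
      design <- cbind(batch_design, mm)
      if (qr(design)$rank < ncol(design)) {
        stop("batch is confounded with the covariate grouping")
      }
    }
  }
  n_batch <- nlevels(batch)
  n_batches <- as.numeric(table(batch))

  ## Genes without usable residual variance (uniform expression, rank-pinned
  ## rows after quantile normalization, or a batch in which the gene is
  ## constant) cannot be location-scale standardized -- the empirical-Bayes
  ## machinery would divide by zero.  For these the noise->0 limit of the
  ## algorithm applies: a location-only adjustment that removes the fitted
  ## per-batch offset exactly (equalizing per-gene batch means) and leaves
  ## the scale untouched.
  full <- dat
  B0 <- solve(crossprod(design), t(design) %*% t(dat))
  vp0 <- as.vector(((dat - t(design %*% B0))^2) %*% rep(1 / n_array, n_array))
  min_batch_var <- apply(dat, 1L, function(row) {
    min(tapply(row, batch, stats::var))
  })
  flat <- vp0 <= 0 | min_batch_var <= 0
  if (any(flat)) {
    message(sprintf(
      "batch_adjust: %d gene(s) without within-batch variance adjusted location-only",
      sum(flat)))
    gamma0 <- B0[seq_len(n_batch), flat, drop = FALSE]
    offset0 <- sweep(gamma0, 2L,
                     as.vector(crossprod(n_batches / n_array, gamma0)))
    full[flat, ] <- dat[flat, , drop = FALSE] -
      t(batch_design %*% offset0)
    if (all(flat)) {
      dimnames(full) <- dimnames(unclass(matrix))
      return(set_scale(expression_matrix(full, "raw"),
                       "log2_quantile_batchadj"))
    }
    dat <- dat[!flat, , drop = FALSE]
  }

  ## standardize genes, preserving covariate effects
  B_hat <- solve(crossprod(design), t(design) %*% t(dat))
  grand_mean <- crossprod(n_batches / n_array, B_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- ((dat - t(design %*% B_hat))^2) %*% rep(1 / n_array, n_array)
  stand_mean <- t(grand_mean) %*% t(rep(1, n_array))
  if (ncol(design) > n_batch) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (dat - stand_mean) / (sqrt(var_pooled) %*% t(rep(1, n_array)))

  ## batch effect estimates and empirical-Bayes priors
  gamma_hat <- solve(crossprod(batch_design), t(batch_design) %*% t(s_data))
  delta_hat <- t(vapply(levels(batch), function(b) {
    apply(s_data[, batch == b, drop = FALSE], 1L, stats::var)
  }, numeric(nrow(dat))))
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, stats::var)
  a_prior <- apply(delta_hat, 1L, function(d) {
    m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 1L, function(d) {
    m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- delta_star <- matrix(NA_real_, n_batch, nrow(dat))
  for (i in seq_len(n_batch)) {
    sdat <- s_data[, batch == levels(batch)[i], drop = FALSE]
    n <- rowSums(!is.na(sdat))
    g_old <- gamma_hat[i, ]
    d_old <- delta_hat[i, ]
    ## Degenerate prior: if the scale estimates are identical across genes
    ## the inverse-gamma moments blow up (a, b -> Inf); the prior then
    ## concentrates at the common value, so the posterior equals it and
    ## only the location update remains.
    if (!is.finite(a_prior[i]) || !is.finite(b_prior[i])) {
      gamma_star[i, ] <- (t2[i] * n * gamma_hat[i, ] + d_old * gamma_bar[i]) /
        (t2[i] * n + d_old)
      delta_star[i, ] <- d_old
      next
    }
    change <- 1
    while (change > conv) {
      g_new <- (t2[i] * n * gamma_hat[i, ] + d_old * gamma_bar[i]) /
        (t2[i] * n + d_old)
      sum2 <- rowSums((sdat - g_new %*% t(rep(1, ncol(sdat))))^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (n / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
  }

  ## remove shrunken batch effects and restore pooled location/scale
  bayes <- s_data
  for (i in seq_len(n_batch)) {
    idx <- batch == levels(batch)[i]
    bayes[, idx] <- (bayes[, idx, drop = FALSE] -
                       t(batch_design[idx, , drop = FALSE] %*% gamma_star)) /
      (sqrt(delta_star[i, ]) %*% t(rep(1, sum(idx))))
  }
  out <- bayes * (sqrt(var_pooled) %*% t(rep(1, n_array))) + stand_mean
  full[!flat, ] <- out
  dimnames(full) <- dimnames(unclass(matrix))
  set_scale(expression_matrix(full, "raw"), "log2_quantile_batchadj")
}
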