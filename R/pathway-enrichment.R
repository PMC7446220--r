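## Hypergeometric GO over-representation analysis with Bonferroni control.
## The upper-tail probability is computed from first principles as an exact
## log-space sum over binomial coefficients, so it stays stable for large
## universes; enrichment is one-sided (over-representation only).

#' Hypergeometric over-representation p value
#'
#' Exact upper tail P(X >= overlap) for X ~ Hypergeometric(universe_size,
#' term_size, list_size): the probability of drawing at least `overlap`
#' term genes when `list_size` genes are drawn without replacement from a
#' universe containing `term_size` term genes.  Computed as a log-space sum
#' of binomial-coefficient terms (numerically stable for large counts).
#'
#' @param overlap observed overlap count.
#' @param list_size number of selected genes.
#' @param term_size number of universe genes annotated to the term.
#' @param universe_size total universe size.
#' @return p value in (0, 1].
#' @export
hypergeometric_overrep <- function(overlap, list_size, term_size,
                                   universe_size) {
  if (any(c(overlap, list_size, term_size, universe_size) < 0) ||
      overlap > min(list_size, term_size) ||
      term_size > universe_size || list_size > universe_size) {
    stop("inconsistent hypergeometric counts")
  }
  if (overlap == 0) return(1)
  k <- seq.int(overlap, min(list_size, term_size))
  ## also respect the lower support bound: k >= list + term - universe
  k <- k[k >= list_size + term_size - universe_size]
  log_terms <- lchoose(term_size, k) +
    lchoose(universe_size - term_size, list_size - k) -
    lchoose(universe_size, list_size)
  m <- max(log_terms)
  p <- exp(m + log(sum(exp(log_terms - m))))
  min(1, p)
}

#' GO over-representation analysis of a gene list
#'
#' Tests every annotation term (intersected with the universe; terms with
#' no universe gene are dropped) for over-representation in `gene_list`
#' with the one-sided hypergeometric tail, and applies Bonferroni
#' correction over the number of terms actually tested.
#'
#' @param gene_list character vector of selected genes (must be a subset of
#'   `universe`).
#' @param annotation a [go_annotation()].
#' @param universe character vector of background genes.
#' @param group_label label recorded in the `gene_group` column (e.g.
#'   `"Non-response"`, `"Downregulated"`).
#' @return `EnrichmentResult` data.frame, one row per tested term, sorted
#'   by p value (ties by term id): `term_id`, `term_name`, `overlap_count`,
#'   `term_size`, `list_size`, `universe_size`, `p_value`, `p_adjusted`,
#'   `gene_group`.
#' @export
enrich <- function(gene_list, annotation, universe, group_label = "") {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    stop("gene list contains genes outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  }
  empty_result <- data.frame(
    term_id = character(), term_name = character(),
    overlap_count = integer(), term_size = integer(),
    list_size = integer(), universe_size = integer(),
    p_value = numeric(), p_adjusted = numeric(),
    gene_group = character(), stringsAsFactors = FALSE
  )
  if (length(gene_list) == 0L) {
    warning("empty gene list; returning no enrichment results")
    return(structure(empty_result, class = c("EnrichmentResult", "data.frame")))
  }
  rows <- lapply(names(annotation), function(id) {
    term_genes <- intersect(annotation[[id]]$genes, universe)
    if (length(term_genes) == 0L) return(NULL)
    ov <- length(intersect(term_genes, gene_list))
    data.frame(
      term_id = id,
      term_name = annotation[[id]]$term_name,
      overlap_count = ov,
      term_size = length(term_genes),
      list_size = length(gene_list),
      universe_size = length(universe),
      p_value = hypergeometric_overrep(ov, length(gene_list),
                                       length(term_genes), length(universe)),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(structure(empty_result, class = c("EnrichmentResult", "data.frame")))
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- pmin(1, res$p_value * nrow(res))
  res$gene_group <- group_label
  res <- res[order_radix(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}
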