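## Independent oracles used across tests.  These deliberately re-derive the
## quantities being checked by a different route (explicit loops, exact
## binomial-coefficient arithmetic, base-R reference functions) and must
## stay independent of the package implementation.

## Step-by-step running-sum enrichment score: walk the ranked list keeping
## the signed deviation of maximal absolute magnitude (first position wins
## ties).  Optional per-position hit weights mirror the weighted variant.
es_oracle <- function(ranked, sig_genes) {
  n <- length(ranked)
  s <- sum(ranked %in% sig_genes)
  rs <- 0
  best <- 0
  for (g in ranked) {
    rs <- rs + if (g %in% sig_genes) 1 / s else -1 / (n - s)
    if (abs(rs) > abs(best)) best <- rs
  }
  max(-1, min(1, best))  # ES lies in [-1, 1] by definition
}

## Exact hypergeometric upper tail from integer binomial coefficients
## (safe for universe <= 25 where choose() is exact).
hyper_oracle <- function(overlap, list_size, term_size, universe_size) {
  if (overlap == 0) return(1)
  ks <- overlap:min(list_size, term_size)
  ks <- ks[ks >= list_size + term_size - universe_size]
  sum(choose(term_size, ks) * choose(universe_size - term_size, list_size - ks)) /
    choose(universe_size, list_size)
}

## Small expression matrix builder for hand-constructed cases.
make_expr <- function(values, genes = NULL, samples = NULL, scale = "log2") {
  m <- as.matrix(values)
  usable <- function(nm) {
    !is.null(nm) && all(nzchar(nm)) && !anyDuplicated(nm)
  }
  if (is.null(genes)) {
    genes <- if (usable(rownames(m))) rownames(m)
             else sprintf("g%02d", seq_len(nrow(m)))
  }
  if (is.null(samples)) {
    samples <- if (usable(colnames(m))) colnames(m)
               else sprintf("s%02d", seq_len(ncol(m)))
  }
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, scale = scale)
}

## Minimal valid sample-sheet data.frame for n patients, two timepoints.
make_sheet <- function(n_resp = 2, n_nonresp = 2, batch = "b1") {
  n <- n_resp + n_nonresp
  pats <- sprintf("P%02d", seq_len(n))
  data.frame(
    sample_id = paste0(rep(pats, each = 2), c("_w0", "_w20")),
    patient_id = rep(pats, each = 2),
    timepoint = rep(c("week0", "week20"), n),
    response = rep(c(rep("good", n_resp), rep("none", n_nonresp)), each = 2),
    batch = batch,
    stringsAsFactors = FALSE
  )
}

## Default small reference profiles shared by several tests.
make_ref <- function(seed = 1, n_genes = 600, n_markers = 20) {
  generate_reference_profiles(
    n_genes, c("TPH", "CD34pos", "CD34neg_THY1pos", "CD34neg_THY1neg"),
    n_markers_per_type = n_markers, marker_effect = 2.0, seed = seed
  )
}
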