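#' @keywords internal
"_PACKAGE"

## Expression scales form a one-way ladder: raw -> log2 -> log2_quantile ->
## log2_quantile_batchadj.  Preprocessing operations refuse to move backwards.
EXPRESSION_SCALES <- c("raw", "log2", "log2_quantile", "log2_quantile_batchadj")

#' Construct an expression matrix container
#'
#' A gene-by-sample numeric matrix carrying its scale provenance.  Rows are
#' genes (unique, ordered ids), columns are samples (unique, ordered ids).
#' Gene identifiers are opaque case-sensitive strings; no symbol
#' normalization is attempted and missing values are rejected.
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample ids); all values must be finite.
#' @param scale one of `"raw"`, `"log2"`, `"log2_quantile"`,
#'   `"log2_quantile_batchadj"`.
#' @return an object of class `ExpressionMatrix` (a numeric matrix with a
#'   `scale` attribute).
#' @export
expression_matrix <- function(values, scale = "raw") {
  scale <- match.arg(scale, EXPRESSION_SCALES)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix requires gene rownames and sample colnames")
  }
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g)) {
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  }
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  }
  if (!all(is.finite(values))) {
    stop("expression matrix contains non-finite values; missing data are not supported")
  }
  structure(values, scale = scale, class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
    nrow(x), ncol(x), expr_scale(x)
  ))
  invisible(x)
}

#' Scale provenance of an expression matrix
#' @param x an `ExpressionMatrix`.
#' @return scale string.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "raw" else s
}

## Rebuild the container after an operation, advancing the scale.  The
## forward-only invariant is enforced here.
set_scale <- function(x, new_scale) {
  new_scale <- match.arg(new_scale, EXPRESSION_SCALES)
  old <- match(expr_scale(x), EXPRESSION_SCALES)
  new <- match(new_scale, EXPRESSION_SCALES)
  if (new < old) {
    stop(sprintf(
      "scale may only advance: cannot move from '%s' back to '%s'",
      expr_scale(x), new_scale
    ))
  }
  attr(x, "scale") <- new_scale
  x
}

#' Construct a sample sheet
#'
#' Per-sample clinical and technical annotations.  The `responder_flag`
#' column is always derived (EULAR good or moderate response counts as
#' responder), never read from file.
#'
#' @param df data.frame with columns `sample_id`, `patient_id`,
#'   `timepoint` (`week0`/`week20`), `response` (`good`/`moderate`/`none`)
#'   and `batch`.
#' @return a validated `SampleSheet` data.frame with derived
#'   `responder_flag`.
#' @export
sample_sheet <- function(df) {
  required <- c("sample_id", "patient_id", "timepoint", "response", "batch")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in required) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad_tp <- setdiff(unique(df$timepoint), c("week0", "week20"))
  if (length(bad_tp)) {
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "))
  }
  bad_resp <- setdiff(unique(df$response), c("good", "moderate", "none"))
  if (length(bad_resp)) {
    stop("unknown response label(s): ", paste(bad_resp, collapse = ", "))
  }
  key <- paste(df$patient_id, df$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("patient_id", "timepoint"), drop = FALSE]
    stop("patient has more than one sample at a timepoint: ",
         paste(unique(paste(dup$patient_id, dup$timepoint)), collapse = ", "))
  }
  df$responder_flag <- df$response %in% c("good", "moderate")
  rownames(df) <- df$sample_id
  class(df) <- c("SampleSheet", "data.frame")
  df
}

#' Construct a gene signature
#'
#' A named, non-empty set of genes marking one cell subset (for instance the
#' 54-gene peripheral-helper-T-cell overexpression signature or a synovial
#' fibroblast subtype marker set).
#'
#' @param name signature name.
#' @param genes character vector of gene ids (deduplicated, order kept).
#' @param description free-text description (kept on GMT round-trips).
#' @return a `GeneSignature` object.
#' @export
gene_signature <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("signature name must be a non-empty string")
  }
  genes <- as.character(genes)
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0L) stop("gene signature '", name, "' is empty")
  structure(
    list(name = name, genes = genes, description = description),
    class = "GeneSignature"
  )
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Construct a GO annotation
#'
#' @param terms named list: term id -> list(term_name =, genes = character
#'   vector).  Every term must be non-empty; term ids must be unique.
#' @return a `GOAnnotation` object.
#' @export
go_annotation <- function(terms) {
  if (anyDuplicated(names(terms))) {
    stop("duplicate GO term id(s): ",
         paste(unique(names(terms)[duplicated(names(terms))]), collapse = ", "))
  }
  for (id in names(terms)) {
    t <- terms[[id]]
    if (is.null(t$genes) || length(t$genes) == 0L) {
      stop("GO term '", id, "' has no genes")
    }
    terms[[id]]$genes <- unique(as.character(t$genes))
    if (is.null(t$term_name)) terms[[id]]$term_name <- id
  }
  structure(terms, class = "GOAnnotation")
}

#' @export
print.GOAnnotation <- function(x, ...) {
  cat(sprintf("GOAnnotation: %d terms\n", length(x)))
  invisible(x)
}

#' Construct a qPCR Ct table
#'
#' Long-format table of raw cycle-threshold values with a designated
#' endogenous control gene (the normalizer for delta-Ct).  Technical
#' replicates (repeated sample/gene rows) are permitted and averaged on the
#' Ct scale by downstream quantification.
#'
#' @param df data.frame with columns `sample_id`, `gene_id`, `ct`.
#' @param endogenous_gene gene id of the endogenous control; must be
#'   measured for every sample in the table.
#' @return a `QpcrTable` data.frame.
#' @export
qpcr_table <- function(df, endogenous_gene) {
  required <- c("sample_id", "gene_id", "ct")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("qPCR table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$gene_id <- as.character(df$gene_id)
  df$ct <- as.numeric(df$ct)
  if (!all(is.finite(df$ct)) || any(df$ct <= 0)) {
    stop("Ct values must be finite and positive")
  }
  samples <- unique(df$sample_id)
  with_endo <- unique(df$sample_id[df$gene_id == endogenous_gene])
  lacking <- setdiff(samples, with_endo)
  if (length(lacking)) {
    stop("endogenous gene '", endogenous_gene,
         "' not measured for sample(s): ", paste(lacking, collapse = ", "))
  }
  attr(df, "endogenous_gene") <- endogenous_gene
  class(df) <- c("QpcrTable", "data.frame")
  df
}

#' Endogenous control gene of a qPCR table
#' @param x a `QpcrTable`.
#' @return gene id string.
#' @export
endogenous_gene <- function(x) attr(x, "endogenous_gene")
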