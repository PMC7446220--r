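## Readers and writers for the plain-text formats the pipeline touches:
## TSV expression matrices, TSV sample sheets, GMT gene sets, GO annotations
## (long TSV or GMT) and TSV Ct tables.  All readers reject malformed input
## rather than silently coercing; all round-trips are lossless at the
## printed precision (values are written with 15 significant digits).

TSV_DIGITS <- 15L

## Read a tab-delimited file into a character matrix, checking for ragged
## rows.  Base scan() keeps full control over coercion errors.
read_tsv_cells <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty file: ", path)
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read an expression matrix from TSV
#'
#' Expected layout: header row of sample ids, first column gene ids,
#' tab-delimited numeric cells.
#'
#' @param path file path.
#' @param scale scale provenance to stamp on the matrix (the file format
#'   itself carries none).
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, scale = "log2") {
  cells <- read_tsv_cells(path)
  header <- cells[[1L]]
  n_samp <- length(header) - 1L
  if (n_samp < 1L) stop("expression TSV has no sample columns: ", path)
  samples <- header[-1L]
  body <- cells[-1L]
  widths <- lengths(body)
  if (any(widths != n_samp + 1L)) {
    stop("ragged row(s) in expression TSV at line(s): ",
         paste(which(widths != n_samp + 1L) + 1L, collapse = ", "))
  }
  genes <- vapply(body, `[[`, character(1L), 1L)
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1L]), numeric(n_samp))
  )
  vals <- if (n_samp == 1L) matrix(vals, nrow = 1L) else t(vals)
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)
    stop("non-numeric expression value(s) for gene(s): ",
         paste(genes[bad], collapse = ", "))
  }
  dimnames(vals) <- list(genes, samples)
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix to TSV
#' @param matrix an `ExpressionMatrix`.
#' @param path output path.
#' @export
write_expression_tsv <- function(matrix, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(matrix, 2L, format_num)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(matrix))
  writeLines(paste(rownames(matrix),
                   apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

format_num <- function(x) {
  formatC(x, digits = TSV_DIGITS, format = "g")
}

#' Read gene signatures from a GMT file
#'
#' GMT dialect: one set per line, `name TAB description TAB gene TAB gene...`.
#'
#' @param path file path.
#' @return named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  rows <- read_tsv_cells(path)
  sigs <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    if (length(r) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields (name, description, >=1 gene)")
    }
    gene_signature(r[[1L]], r[-(1:2)], description = r[[2L]])
  })
  names(sigs) <- vapply(sigs, `[[`, character(1L), "name")
  if (anyDuplicated(names(sigs))) {
    stop("duplicate signature name(s) in GMT: ",
         paste(unique(names(sigs)[duplicated(names(sigs))]), collapse = ", "))
  }
  sigs
}

#' Write gene signatures to a GMT file
#' @param signatures list of `GeneSignature` objects.
#' @param path output path.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "GeneSignature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Required columns: `sample_id`, `patient_id`, `timepoint`, `response`,
#' `batch`.  `responder_flag` is derived (good/moderate = responder), never
#' read from the file.
#'
#' @param path file path.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  sample_sheet(df)
}

#' Write a sample sheet to TSV
#' @param sheet a `SampleSheet`.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(
    sheet[, c("sample_id", "patient_id", "timepoint", "response", "batch")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a GO annotation
#'
#' Two on-disk dialects are accepted: long TSV with columns
#' `term_id`, `term_name`, `gene_id` (one row per term/gene pair), or GMT
#' (term id as set name, term name as description).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"gmt"`.
#' @return a [go_annotation()].
#' @export
read_go_annotation <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    sigs <- read_gmt(path)
    terms <- lapply(sigs, function(s) list(term_name = s$description, genes = s$genes))
    names(terms) <- names(sigs)
    return(go_annotation(terms))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("term_id", "term_name", "gene_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("GO annotation TSV is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ids <- unique(df$term_id)
  terms <- lapply(ids, function(id) {
    sub <- df[df$term_id == id, , drop = FALSE]
    list(term_name = sub$term_name[[1L]], genes = unique(sub$gene_id))
  })
  names(terms) <- ids
  go_annotation(terms)
}

#' Write a GO annotation as long TSV
#' @param annotation a `GOAnnotation`.
#' @param path output path.
#' @export
write_go_annotation <- function(annotation, path) {
  rows <- do.call(rbind, lapply(names(annotation), function(id) {
    t <- annotation[[id]]
    data.frame(term_id = id, term_name = t$term_name, gene_id = t$genes,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table from TSV
#'
#' Required columns: `sample_id`, `gene_id`, `ct`.
#'
#' @param path file path.
#' @param endogenous_gene id of the endogenous control gene; must be present
#'   for every sample.
#' @return a [qpcr_table()].
#' @export
read_qpcr_table <- function(path, endogenous_gene) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  qpcr_table(df, endogenous_gene = endogenous_gene)
}

#' Write a qPCR Ct table to TSV
#' @param table a `QpcrTable`.
#' @param path output path.
#' @export
write_qpcr_table <- function(table, path) {
  df <- as.data.frame(table)
  df$ct <- format_num(df$ct)
  utils::write.table(df[, c("sample_id", "gene_id", "ct")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
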