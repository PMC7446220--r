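## Synthetic ground-truth data emulating a two-timepoint anti-TNF synovial
## cohort: bulk log2-intensity profiles formed as convex mixtures (on the
## linear scale) of cell-type reference profiles, Gaussian measurement
## noise, additive batch shifts, two response groups differing in their
## T_PH mixing fraction, planted responder-vs-non-responder DE genes, and a
## GO annotation with planted enriched terms.  Every generator draws from
## its own RNG stream seeded by (seed, operation tag), so outputs are
## fully reproducible and independent of one another.

#' Generate cell-type reference profiles with planted markers
#'
#' Background expression for each gene is a baseline drawn from
#' Normal(mean 7, sd 1) on the log2 scale, shared across cell types;
#' each type's marker genes get `+marker_effect` added in that type only.
#' Marker sets are pairwise disjoint by construction, so every marker
#' exceeds all other types by exactly `marker_effect` log2 units.
#'
#' @param n_genes number of genes.
#' @param cell_types character vector of type names (first-class citizens:
#'   e.g. `c("TPH", "CD34pos", "CD34neg_THY1pos", "CD34neg_THY1neg")`).
#' @param n_markers_per_type planted markers per type.
#' @param marker_effect log2 elevation of a marker in its own type (> 0).
#' @param seed integer seed.
#' @param baseline_mean,baseline_sd baseline log2 distribution parameters.
#' @return `ReferenceProfiles`: list with `cell_types`, `genes`,
#'   `mean_log2` (gene x type matrix), `marker_map` (type -> gene ids) and
#'   `marker_effect`.
#' @export
generate_reference_profiles <- function(n_genes, cell_types,
                                        n_markers_per_type,
                                        marker_effect = 2.0, seed = 1,
                                        baseline_mean = 7, baseline_sd = 1) {
  cell_types <- as.character(cell_types)
  if (anyDuplicated(cell_types)) stop("duplicate cell type names")
  if (marker_effect <= 0 && n_markers_per_type > 0) {
    stop("marker_effect must be positive")
  }
  if (n_markers_per_type * length(cell_types) > n_genes) {
    stop("infeasible marker allocation: ",
         n_markers_per_type * length(cell_types), " markers > ",
         n_genes, " genes")
  }
  genes <- sprintf("g%05d", seq_len(n_genes))
  out <- with_op_seed(seed, "reference_profiles", {
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    mean_log2 <- matrix(baseline, n_genes, length(cell_types),
                        dimnames = list(genes, cell_types))
    marker_pool <- sample(genes, n_markers_per_type * length(cell_types))
    marker_map <- stats::setNames(vector("list", length(cell_types)), cell_types)
    for (i in seq_along(cell_types)) {
      mk <- if (n_markers_per_type > 0) {
        marker_pool[seq.int((i - 1L) * n_markers_per_type + 1L,
                            i * n_markers_per_type)]
      } else character()
      marker_map[[i]] <- mk
      mean_log2[mk, i] <- mean_log2[mk, i] + marker_effect
    }
    list(mean_log2 = mean_log2, marker_map = marker_map)
  })
  structure(
    list(cell_types = cell_types, genes = genes, mean_log2 = out$mean_log2,
         marker_map = out$marker_map, marker_effect = marker_effect),
    class = "ReferenceProfiles"
  )
}

#' @export
print.ReferenceProfiles <- function(x, ...) {
  cat(sprintf("ReferenceProfiles: %d genes, %d cell types (%s)\n",
              length(x$genes), length(x$cell_types),
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

#' Generate a paired two-timepoint synthetic cohort
#'
#' Each patient contributes one week0 and one week20 sample.  A sample's
#' expected log2 expression is the log2 of the convex mixture, on the
#' linear (2^x) scale, of the reference profiles weighted by the patient's
#' cell fractions (intensities, not logs, are additive across cells); an
#' additive batch shift, planted DE effects and Normal(0, noise_sd)
#' measurement noise are added on the log2 scale.  The T_PH fraction is
#' Beta-distributed around the group mean (concentration
#' `jitter_concentration`; `Inf` disables jitter) and the residual mass is
#' spread over the remaining types by a uniform Dirichlet draw.  Fractions
#' are stable over time within a patient.  Planted DE genes are chosen
#' among non-marker genes and get `+de_effect` in one response group at
#' both timepoints (half up in responders, half up in non-responders).
#' Patients are assigned to batches round-robin, both timepoints together.
#'
#' @param ref a [generate_reference_profiles()] result; the first cell type
#'   whose name matches `tph_type` plays the T_PH role.
#' @param n_responders,n_nonresponders patient counts (default 8 vs 3,
#'   mirroring a small longitudinal arthroscopy cohort).  Responders
#'   alternate EULAR `good`/`moderate`; non-responders are `none`.
#' @param tph_fraction_resp,tph_fraction_nonresp mean T_PH mixing fraction
#'   per group (defaults 0.05 vs 0.15; synthetic conventions, not
#'   estimates).
#' @param noise_sd log2 measurement noise sd (default 0.3).
#' @param n_de_genes number of planted DE genes (default 20).
#' @param de_effect planted log2 effect size (default 1.0).
#' @param batches named numeric vector of additive log2 batch shifts
#'   (default two batches, shifts 0 and 0.3).
#' @param jitter_concentration Beta concentration of the T_PH fraction
#'   jitter (default 50; `Inf` = exact group mean).
#' @param tph_fractions optional explicit per-patient T_PH fractions
#'   (length `n_responders + n_nonresponders`, responders first); overrides
#'   the group means and jitter, e.g. to plant a fraction grid.
#' @param tph_type name of the T_PH-like type in `ref`.
#' @param seed integer seed.
#' @return list with `matrix` (`ExpressionMatrix`, log2 scale), `sheet`
#'   (a [sample_sheet()]) and `truth` (`SyntheticTruth`: `fractions`
#'   sample x type matrix, `de_genes_up_resp`, `de_genes_up_nonresp`,
#'   `batch_shifts`, `tph_type`, `seed`).
#' @export
generate_cohort <- function(ref, n_responders = 8, n_nonresponders = 3,
                            tph_fraction_resp = 0.05,
                            tph_fraction_nonresp = 0.15,
                            noise_sd = 0.3, n_de_genes = 20, de_effect = 1.0,
                            batches = c(batch1 = 0, batch2 = 0.3),
                            jitter_concentration = 50,
                            tph_fractions = NULL,
                            tph_type = "TPH", seed = 1) {
  stopifnot(inherits(ref, "ReferenceProfiles"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  for (f in c(tph_fraction_resp, tph_fraction_nonresp)) {
    if (f < 0 || f > 1) stop("T_PH fraction must lie in [0, 1]")
  }
  if (!tph_type %in% ref$cell_types) {
    stop("reference profiles lack the T_PH-like type '", tph_type, "'")
  }
  if (is.null(names(batches))) {
    names(batches) <- paste0("batch", seq_along(batches))
  }
  n_pat <- n_responders + n_nonresponders
  patients <- sprintf("P%02d", seq_len(n_pat))
  response <- c(rep_len(c("good", "moderate"), n_responders),
                rep("none", n_nonresponders))
  batch_of_patient <- rep_len(names(batches), n_pat)

  sheet <- sample_sheet(data.frame(
    sample_id = paste0(rep(patients, each = 2L), c("_w0", "_w20")),
    patient_id = rep(patients, each = 2L),
    timepoint = rep(c("week0", "week20"), n_pat),
    response = rep(response, each = 2L),
    batch = rep(batch_of_patient, each = 2L),
    stringsAsFactors = FALSE
  ))

  other_types <- setdiff(ref$cell_types, tph_type)
  n_genes <- length(ref$genes)
  marker_genes <- unlist(ref$marker_map, use.names = FALSE)

  gen <- with_op_seed(seed, "cohort", {
    ## per-patient cell fractions (time-stable)
    mu <- ifelse(response %in% c("good", "moderate"),
                 tph_fraction_resp, tph_fraction_nonresp)
    tph <- if (!is.null(tph_fractions)) {
      if (length(tph_fractions) != n_pat ||
          any(tph_fractions < 0 | tph_fractions > 1)) {
        stop("tph_fractions must give one value in [0, 1] per patient")
      }
      as.numeric(tph_fractions)
    } else if (is.infinite(jitter_concentration)) mu else {
      vapply(mu, function(m) {
        if (m == 0 || m == 1) m
        else stats::rbeta(1L, m * jitter_concentration,
                          (1 - m) * jitter_concentration)
      }, numeric(1L))
    }
    tph <- pmin(pmax(tph, 0), 1)
    rest <- if (length(other_types)) {
      g <- matrix(stats::rgamma(n_pat * length(other_types), shape = 1),
                  n_pat, length(other_types))
      g / rowSums(g) * (1 - tph)
    } else matrix(0, n_pat, 0L)
    frac_pat <- cbind(tph, rest)
    colnames(frac_pat) <- c(tph_type, other_types)
    frac_pat <- frac_pat[, ref$cell_types, drop = FALSE]
    rownames(frac_pat) <- patients

    ## planted DE genes among non-markers
    pool <- setdiff(ref$genes, marker_genes)
    if (n_de_genes > length(pool)) {
      stop("not enough non-marker genes for ", n_de_genes, " DE genes")
    }
    de <- if (n_de_genes > 0) sample(pool, n_de_genes) else character()
    up_resp <- de[seq_len(ceiling(n_de_genes / 2))]
    up_nonresp <- setdiff(de, up_resp)

    ## expected log2 expression per sample
    fractions <- frac_pat[sheet$patient_id, , drop = FALSE]
    rownames(fractions) <- sheet$sample_id
    lin_ref <- 2^ref$mean_log2
    expected <- log2(lin_ref %*% t(fractions))
    shift <- batches[sheet$batch]
    expected <- expected + matrix(shift, n_genes, nrow(sheet), byrow = TRUE)
    is_resp <- sheet$responder_flag
    expected[up_resp, is_resp] <- expected[up_resp, is_resp] + de_effect
    expected[up_nonresp, !is_resp] <- expected[up_nonresp, !is_resp] + de_effect
    noise <- matrix(stats::rnorm(length(expected), 0, noise_sd),
                    nrow(expected), ncol(expected))
    vals <- expected + noise
    dimnames(vals) <- list(ref$genes, sheet$sample_id)
    list(vals = vals, fractions = fractions,
         up_resp = up_resp, up_nonresp = up_nonresp)
  })

  truth <- structure(
    list(fractions = gen$fractions,
         de_genes_up_resp = gen$up_resp,
         de_genes_up_nonresp = gen$up_nonresp,
         batch_shifts = batches,
         tph_type = tph_type,
         seed = seed),
    class = "SyntheticTruth"
  )
  list(matrix = expression_matrix(gen$vals, scale = "log2"),
       sheet = sheet, truth = truth)
}

#' Generate a synthetic GO annotation with planted enriched terms
#'
#' Random terms draw their members uniformly from the gene universe.  Each
#' planted term is constructed so that `round(planted_overlap * size)` of
#' its members come from the supplied planted gene set (e.g. a set of
#' planted DE genes) and the remainder from outside it.
#'
#' @param genes gene universe (character).
#' @param n_terms number of random (non-planted) terms.
#' @param term_size_range integer range of random term sizes (default
#'   10--50).
#' @param planted_terms named list of gene-id vectors to plant enrichment
#'   for; each yields one term named `PLANTED_<name>`.
#' @param planted_size size of each planted term (default 10).
#' @param planted_overlap fraction of a planted term drawn from its gene
#'   set (default 0.8).
#' @param seed integer seed.
#' @return list with `annotation` (a [go_annotation()]) and `truth`
#'   (character vector of planted term ids).
#' @export
generate_go_annotation <- function(genes, n_terms = 50,
                                   term_size_range = c(10, 50),
                                   planted_terms = list(),
                                   planted_size = 10,
                                   planted_overlap = 0.8, seed = 1) {
  genes <- as.character(genes)
  if (max(term_size_range) > length(genes)) {
    stop("term sizes exceed the universe size")
  }
  terms <- with_op_seed(seed, "go_annotation", {
    out <- list()
    if (n_terms > 0) {
      sizes <- sample(seq.int(term_size_range[1], term_size_range[2]),
                      n_terms, replace = TRUE)
      for (i in seq_len(n_terms)) {
        id <- sprintf("GO:%07d", i)
        out[[id]] <- list(term_name = sprintf("random process %d", i),
                          genes = sample(genes, sizes[i]))
      }
    }
    for (nm in names(planted_terms)) {
      inset <- intersect(planted_terms[[nm]], genes)
      k <- round(planted_overlap * planted_size)
      outside_pool <- setdiff(genes, inset)
      if (k > length(inset) || (planted_size - k) > length(outside_pool)) {
        stop("planted overlap infeasible for term '", nm, "'")
      }
      id <- paste0("PLANTED_", nm)
      out[[id]] <- list(
        term_name = sprintf("planted process %s", nm),
        genes = c(sample(inset, k), sample(outside_pool, planted_size - k))
      )
    }
    out
  })
  if (length(terms) == 0L) {
    return(list(annotation = go_annotation(list()), truth = character()))
  }
  list(annotation = go_annotation(terms),
       truth = grep("^PLANTED_", names(terms), value = TRUE))
}

#' Generate a synthetic qPCR Ct table from an expression matrix
#'
#' Each measured gene's Ct follows the linear amplification model
#' `Ct = intercept + slope * log2_expression + Normal(0, noise_sd)`,
#' with a negative slope (higher expression amplifies earlier, giving a
#' lower Ct).  The endogenous control gene is measured for every sample.
#'
#' @param expr `ExpressionMatrix` on a log2 scale.
#' @param target_genes genes to assay.
#' @param endogenous_gene endogenous control gene id.
#' @param slope Ct change per log2 unit (must be negative; default -1).
#' @param intercept Ct at zero log2 expression (default 38).
#' @param noise_sd Ct measurement noise sd (default 0.2).
#' @param seed integer seed.
#' @return a [qpcr_table()].
#' @export
generate_qpcr <- function(expr, target_genes, endogenous_gene,
                          slope = -1, intercept = 38, noise_sd = 0.2,
                          seed = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  genes <- unique(c(target_genes, endogenous_gene))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("gene(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  }
  if (slope >= 0) stop("slope must be negative (higher expression -> lower Ct)")
  samples <- colnames(expr)
  df <- with_op_seed(seed, "qpcr", {
    rows <- expand.grid(gene_id = genes, sample_id = samples,
                        stringsAsFactors = FALSE)
    log2e <- unclass(expr)[cbind(rows$gene_id, rows$sample_id)]
    rows$ct <- intercept + slope * log2e +
      stats::rnorm(nrow(rows), 0, noise_sd)
    rows[, c("sample_id", "gene_id", "ct")]
  })
  qpcr_table(df, endogenous_gene = endogenous_gene)
}
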