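# specdeconv

Multilevel analysis of bulk synovial-membrane transcriptomes for anti-TNF
response studies in rheumatoid arthritis, built around a per-sample
enrichment-score deconvolution of pathogenic cell subsets — peripheral
helper T cells (T<sub>PH</sub>, PD-1<sup>hi</sup>CXCR5<sup>−</sup>CD4<sup>+</sup>)
and the CD34/THY1-defined synovial fibroblast subtypes — plus the
surrounding pipeline: quantile normalization, empirical-Bayes (ComBat-style)
batch adjustment, per-gene t-test differential expression with Bonferroni
control, hypergeometric GO over-representation, and ΔΔCt qPCR validation.
A synthetic-data generator plants known ground truth (cell mixing
fractions, DE genes, enriched GO terms) so the entire pipeline is testable
end to end without any external download.

## The statistic at the core

For a sample's ranked gene list of length *N* and a cell-subset signature
of *|S|* genes, walk the list from the most to the least expressed gene,
adding 1/|S| at every signature gene and subtracting 1/(N−|S|) at every
other gene. The **enrichment score (ES)** is the running-sum value of
maximal absolute magnitude, signed, in [−1, 1] — the classic unweighted
Kolmogorov–Smirnov GSEA statistic, used here per sample (the SPEC approach:
Subset Prediction from Enrichment Correlation). The ES depends only on
within-sample ranks, so it is exactly invariant to positive affine
transforms of a sample's expression. Group association is a Welch t-test
on ES between EULAR responders (good+moderate) and non-responders;
longitudinal change is a paired t-test of week20 − week0 ES within
patients.

## Worked example

```r
library(specdeconv)

ref <- generate_reference_profiles(
  n_genes = 2000,
  cell_types = c("TPH", "CD34pos", "CD34neg_THY1pos", "CD34neg_THY1neg"),
  n_markers_per_type = 54, marker_effect = 2.0, seed = 42
)
cohort <- generate_cohort(ref, seed = 42)   # 8 responders vs 3 non-responders,
                                            # week0 + week20, TPH 0.05 vs 0.15
mat <- quantile_normalize(cohort$matrix)
mat <- batch_adjust(mat, setNames(cohort$sheet$batch, cohort$sheet$sample_id))

tph <- derive_signature(ref, "TPH")         # 54-gene marker signature
es  <- score_samples(mat, tph)
round(head(es[, 1], 4), 3)
#>  P01_w0 P01_w20  P02_w0 P02_w20
#>   0.094   0.096   0.099   0.105

cor(es[, 1], cohort$truth$fractions[rownames(es), "TPH"], method = "spearman")
#> 0.911      # ES recovers the planted mixing fractions

associate_with_response(es, cohort$sheet, timepoint = "week0")
#>   signature               contrast mean_responder mean_nonresponder t_statistic
#> 1       TPH responder_vs_non@week0        -0.0105             0.201       -5.18
#>    p_value           direction
#> 1 0.000958 lower_in_responders
```

The planted world has responders carrying fewer T<sub>PH</sub> cells
(5% vs 15% of the mixture); the ES-based test recovers exactly that:
lower scores in responders at baseline, p ≈ 1e-3.

`run_pipeline(default_config(seed = 1), "out/")` runs every stage from one
config (preprocessing → DE contrasts → GO enrichment → deconvolution →
qPCR validation) and writes TSV tables plus a byte-reproducible
`summary.json`. The same machinery is scriptable via `exec/specdeconv`
subcommands (`pipeline`, `preprocess`, `diffexpr`, `enrich`, `score`,
`associate`, `qpcr`).

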