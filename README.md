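# immunosig

Immunosignature analysis of random-peptide microarrays in R.

An immunosignature is the binding pattern of a serum antibody repertoire
across a large library of random-sequence peptides (here: 12-mers, scanned in
two channels — IgG at 532 nm, IgM at 635 nm). Individual peptides are
mimotopes, not natural antigens, but the joint reactivity pattern can
separate cases from controls. `immunosig` is aimed at analysts working with
such arrays (or evaluating the method) and implements the full chain as
tested, composable functions:

* **Simulation** — a generative model for two-channel array scans with a
  planted discriminative motif, engineered sub-background peptides, replicate
  spots/samples and sporadic dropout, so every downstream stage can be
  validated against known ground truth (`simulate_ims_dataset()`).
* **I/O** — a minimal GenePix-GPR-style dialect for spot tables, TSV
  matrices and design tables (`read_gpr()`, `write_matrix_tsv()`, ...).
* **Preprocessing** — background subtraction; exclusion of peptides negative
  in >50% of samples in either channel; within-array median normalization of
  the log-ratios `M = log2(IgM/IgG)`; between-array Aquantile normalization
  of the mean log-intensities `A` (via limma); replicate averaging; exclusion
  of peptides >25% missing in either cohort (`preprocess_scans()`).
* **Signature reduction** — progressive random-forest feature elimination:
  5,000-tree forests with `mtry = round(0.5 * sqrt(N))`, bootstrap
  resampling with out-of-bag (OOB) evaluation and class upweighting; keep
  the top 30%, then the top 40%, then iteratively shed the least important
  features until the OOB score stops improving (`stepwise_reduce()`), with a
  Table-style metric panel (`confusion_metrics()`).
* **Homology post-processing** — BLAST traceback (btop) parsing, exclusion
  of hits lacking an ungapped block with ≥5 identities or <34% query
  coverage, distinct-peptide aggregation per protein, and ranking by the
  size-adjusted metric `Adj = protein length / peptide count`
  (`parse_btop()`, `filter_hits()`, `aggregate_by_protein()`).
* **Motif discovery** — exhaustive k-mer consensus search with Hamming
  mismatches and shift-merging (`find_consensus_motifs()`).

Fitted signatures support `tidy()`, `glance()` and `autoplot()`.

## Worked example

A small end-to-end run on simulated data — 1,000 peptides of which 12 carry
the planted `GVALSG` motif, 12 cases vs 12 controls:

```r
library(immunosig)

params <- ims_params(n_peptides = 1000, n_cases = 12, n_controls = 12,
                     n_carriers = 12, n_trees = 300)
run <- run_ims_pipeline(params, seed = 42)
run
#> Immunosignature run (seed 42)
#>   peptides simulated: 1000 (carriers: 12)
#>   analysis matrix: 948 peptides x 24 subjects x 2 channels
#>   signature: 168 features, OOB overall 100.00%
#>   carrier recovery: 100.0%
#>   top motif: PVAL (support 14 of 145)
```

Reading this: 52 of the 1,000 peptides were removed by the two QC filters
(the engineered sub-background peptides among them); the stepwise reduction
stopped at a 168-feature signature that classifies every subject correctly
out of bag; all 12 planted carrier peptides are inside the signature; and
the consensus search over the 145 signature peptides ranks a merged shift
variant of the planted motif first (its `merged_variants` column contains
`GVAL`, `GVALS` and `GVALSG` itself), with support 14 — the 12 planted
carriers plus chance matches at one mismatch.

The metric panel applied to an external confusion table (counts: controls
41/1, cases 3/39, control = positive class):

```r
m <- matrix(c(41, 3, 1, 39), 2,
            dimnames = list(c("control", "case"), c("control", "case")))
confusion_metrics(m)[, c("overall_pct", "sensitivity_pct",
                         "specificity_pct", "precision_pct", "f1_pct")]
#>   overall_pct sensitivity_pct specificity_pct precision_pct   f1_pct
#> 1     95.2381        97.61905        92.85714      93.18182 95.34884
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/synthetic-data.R` | library/design/scan generators |
| `R/array-io.R` | GPR dialect, TSV matrices and designs |
| `R/preprocess.R` | QC filters, M/A normalization, averaging |
| `R/signature.R` | random-forest reduction, metrics, plots |
| `R/homology.R` | btop parsing, hit filtering, Adj ranking, BLAST wrapper |
| `R/motif.R` | consensus-motif search, FASTA I/O |
| `R/pipeline.R` | `run_ims_pipeline()` orchestration |
| `vignettes/immunosignature-analysis.Rmd` | methods notes and design choices |
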