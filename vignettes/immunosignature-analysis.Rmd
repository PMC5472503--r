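---
title: "Immunosignature analysis: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunosignature analysis: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

An immunosignature is the binding profile of a serum's antibody repertoire
across a large library of random-sequence peptides. The peptides are not
natural antigens; they act as mimotopes, and the joint pattern of reactivity
over the library can separate disease states even when no individual peptide
is interpretable on its own. `immunosig` implements a complete analysis chain
for two-channel (IgG / IgM) random 12-mer peptide arrays in a case/control
design: simulation, quality control and normalization, classifier-driven
signature reduction, homology post-processing of the signature peptides, and
consensus-motif discovery.

Because raw scans of this kind are rarely public, the package treats its
synthetic-data generator as a first-class module: every downstream stage is
specified, tested and benchmarked against data with known ground truth.

# The generative model

`simulate_scans()` draws, for peptide $p$, sample $i$, channel $c$ and spot
replicate $r$:

$$\log_2 F_{picr} = \mu + \beta_{pc} + u_{ic}
  + \delta\,\mathbf{1}[\text{case}_i \wedge \text{carrier}_p]
  + \varepsilon_{picr},$$

with baseline $\mu$ (default 10), per-peptide per-channel reactivity
$\beta_{pc} \sim N(0, 1)$, per-array per-channel offset
$u_{ic} \sim N(0, 0.3)$, spot noise $\varepsilon \sim N(0, 1)$ and a planted
disease effect $\delta$ (default 2.0, i.e. two noise standard deviations)
confined to carrier peptides — peptides into which the consensus motif
(default `GVALSG`) has been embedded — in case samples. Backgrounds are
log-normal ($\log_2 B \sim N(6.6, 0.3)$, a few hundred AU under a foreground
of roughly a thousand). Two engineered failure modes exercise the QC filters:
a fraction of non-carrier peptides (default 5%) is persistently
sub-background (foreground re-drawn around $\log_2 B - 0.7$, so it is
negative in roughly three quarters of samples), and sporadic dropouts
(default 2% of remaining spots) create scattered missing values at the log
step.

Deliberate simplifications: no spatial artifacts (streaks, bubbles,
print-tip effects), no isotype cross-talk between the two dyes, no
saturation at the scanner's dynamic-range ceiling, and noise that is
Gaussian on the log scale with a variance that does not depend on intensity.
Passing the package's recovery benchmarks therefore demonstrates that the
pipeline's logic is correct and well calibrated — not that real arrays,
whose artifacts are exactly the excluded ones, would classify equally well.
Cohort defaults mirror a 21-case / 21-control two-site study; the published
site description of that design is internally inconsistent (its control
counts sum to 22), so the package splits controls 11/10 across sites.

# Preprocessing

The chain runs in a fixed order, each step a public function:

1. **Background subtraction** (`subtract_background()`): `fg - bg` per spot.
   Negative values are kept — they are data for the next step.
2. **Negative-incidence filter** (`filter_negative_incidence()`): a peptide
   is dropped when *strictly more than* 50% of samples have a negative
   corrected value in *either* channel (spot replicates averaged per sample
   first). A peptide negative in exactly half the samples is retained; the
   rule is "more than", applied to fractions, not counts.
3. **M/A transform** (`compute_ma()`): per spot,
   $M = \log_2(\mathrm{IgM}_{635}/\mathrm{IgG}_{532})$ and
   $A = \tfrac12(\log_2 \mathrm{IgM}_{635} + \log_2 \mathrm{IgG}_{532})$.
   The log is undefined for non-positive corrected values, so those spots
   become missing here — never clipped to a floor. The dye mapping (IgG on
   the 532 nm scan, IgM on 635 nm) follows the secondary-antibody
   conjugates; it is a naming convention, not an algorithmic assumption.
4. **Within-array median normalization**
   (`normalize_within_array_median()`): $M' = M - \mathrm{median}(M)$ per
   array, A untouched. Delegated to `limma::normalizeWithinArrays()`.
5. **Between-array Aquantile normalization**
   (`normalize_between_arrays_aquantile()`): A-values quantile-normalized
   across arrays (sorted A replaced by across-array order-statistic means,
   interpolated ranks where arrays have missing spots, ties receiving the
   mean of their tied reference values), M untouched. Delegated to
   `limma::normalizeBetweenArrays(method = "Aquantile")` — the same package
   a two-channel array analysis would use directly. One A per spot is shared
   by both channels; channels are reconstructed exactly as
   $A \mp M/2$.
6. **Replicate averaging** (`average_replicates()`): mean over available
   values, spot level before sample level; missing only if all replicates
   are missing.
7. **Cohort missingness filter** (`filter_missing_by_cohort()`): a peptide
   is dropped when strictly more than 25% of its values are missing within
   the case cohort or within the control cohort, evaluated per channel; a
   failure anywhere removes the peptide from the final set, keeping one
   peptide universe across channels.

Both filters are idempotent. Note that with sporadic dropout no array is
ever complete, so the textbook Aquantile invariant — identical sorted A
across arrays — is only exact on dropout-free data; the test suite checks it
there, and checks the weaker per-array median and M-invariance properties on
realistic data.

# Signature reduction

Both channels enter the classifier together, as `peptide|channel` features.
Each forest (`fit_rf()`, backed by \pkg{ranger}) uses:

* 5,000 trees by default (the synthetic benchmark uses 500 for speed, which
  is already past the OOB-stability plateau at these problem sizes);
* `mtry_rule(N)` = half the square root of the *current* feature count,
  rounded half away from zero — recomputed at every reduction step;
* nodes split while they hold at least two samples (trees grown essentially
  to purity);
* the smaller class upweighted to the size of the larger via per-sample
  weights;
* bootstrap resampling with replacement, evaluated by out-of-bag (OOB)
  prediction: overall percent correct over samples while out of bag;
* mean-decrease-in-impurity importance (deterministic given the fitted
  forest; permutation importance available via `rf_config(importance =
  "permutation")`), ties broken by feature id.

`stepwise_reduce()` applies the progressive schedule: keep the top 30% of
features and refit; keep the top 40% of those and refit; then repeatedly
drop the least-important 10% (at least one feature) until the OOB score has
not improved for 3 consecutive iterations. Retention counts are
`ceiling(fraction * N)`. The returned signature is the smallest feature set
that achieved the best OOB score anywhere in the trace. The 10% removal rate
and patience of 3 are this package's defaults (both configurable): gentle
enough that an informative feature is unlikely to ride out with a bulk
removal, aggressive enough to shrink a few-hundred-feature set within a
handful of refits.

Residual missing values are imputed with the feature's within-cohort median
before fitting — the least informative single-value choice that respects the
cohort structure the classifier is asked to find.

Two calibration facts the tests rely on: on label-permuted data the OOB
score centres near chance but runs a few points *below* 50% at these cohort
sizes — when a sample is out of bag its own class is slightly
underrepresented in the bag, a known small-sample pessimism of OOB
evaluation — and on the default benchmark (5,000 peptides, 30 carriers at
effect 2.0, 20 vs 20) the reduction recovers the full carrier set with an
OOB score of 100%.

Metric reporting (`confusion_metrics()`) treats **control** as the positive
class by default: that is the convention under which a published
41/1-versus-3/39 confusion table yields its stated specificity (92.86),
recall (97.62), precision (93.18) and F1 (95.35) simultaneously. A flag
switches the convention.

# Homology post-processing

Signature peptides are searched against protein databases with BLASTP tuned
for 12-mer queries (word size 2, window 15, threshold 16, PAM30, gap open
9 / extend 1, E-value 1000, one HSP per query/subject pair, HSP query
coverage at least 34%); `run_blastp()` wraps the external binary and
`read_blast_tab()` consumes pre-computed tabular output when BLAST is run
elsewhere. Database construction is out of scope: the functions accept any
FASTA plus a flat accession metadata table, and a flat `taxid -> species,
genus` table replaces a taxonomy service.

The post-processing itself:

* `parse_btop()` losslessly decodes the BLAST traceback string
  (identity-run lengths, mismatch pairs, gap pairs with `-`), rejecting
  malformed input with the offending position.
* `max_block_identities()` sums identities within each gap-free block and
  takes the maximum. A hit is discarded unless some block reaches 5
  identities (`filter_hits()`). Counting per *block* — mismatches allowed
  between the identities, gaps not — rather than per consecutive run is
  deliberate: antibody-contact residues need not be contiguous. The
  strict-consecutive interpretation is available as `mode = "run"`.
* `aggregate_by_protein()` counts *distinct* query peptides per subject
  accession (consistent with one HSP per pair) and applies the reporting
  threshold — 4 for the human table, 2 for the endogenous-retrovirus table,
  3 for the viral/bacterial table in the published analysis.
* `adjusted_metric()` divides protein length by that peptide count; tables
  rank ascending in it (`rank_table()`, ties by accession). Low values mean
  hits concentrated on a short protein, which is what makes a homology
  plausible rather than a base-rate artifact of protein length.

Display values round half away from zero to one decimal; machine output
keeps full precision. Of the 50 published table rows bundled as a fixture,
46 are arithmetically consistent with their printed length and peptide
count at that precision; the four flagged anomalies (two obvious misprints,
one truncated-instead-of-rounded value, one row whose printed adjusted value
implies a different peptide count) are excluded from exact checks and
marked in the fixture's `note` column.

# Consensus motifs

`find_consensus_motifs()` replaces a progressive multiple alignment with an
exhaustive, deterministic search: every k-mer (k = 4–8) occurring in the
peptide set is a candidate; its support is the number of peptides matching
it within one Hamming mismatch (hashed position-masked lookup, exact for
the 0- and 1-mismatch cases); candidates above the support floor are ranked
by support, then length, then alphabetically; and shifted variants are
merged into the highest-ranked representative. Two motifs merge when one is
a substring of the other, when some ungapped offset aligns them with at
least `min(k) - 1` matching positions, or when a prefix of one equals a
suffix of the other over at least 3 residues. The last clause is essential:
frame-shifted windows of one underlying consensus (the relation between
shifted 6-mers such as `LSGVLS` and `GVALSG`) agree only on their
prefix/suffix overlap and would otherwise never merge.

The mismatch tolerance and window range used to call motif membership in
the source analysis are not stated, so planted-motif counts are checked as
properties (the planted motif, or a merged variant of it, ranks first with
at least its planted support) rather than as exact reproductions.

# Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data:
libraries of 100–5,000 peptides, cohorts of 12–40 subjects, forests of
60–500 trees, 1,000 fuzzed traceback strings, and a 233-peptide / 40-carrier
motif benchmark matching the scale of the published signature. These sizes
put every property comfortably in its asymptotic regime while keeping a full
run in minutes on one core. All randomness flows through explicit seeds; a
rerun with the same parameters and seed is byte-identical, and generator
functions restore the caller's RNG state.

# Known limitations

* The classification benchmark is synthetic by necessity; the published
  cohort's sera are not available, so its real-data accuracy cannot be
  reproduced, only the pipeline that produced it.
* OOB evaluation is the only internal validation, as in the source design —
  there is no external test set, and OOB at n = 40 carries the small-sample
  pessimism noted above.
* The homology stage requires the caller to supply databases; the published
  human/retroviral/microbial database subsets are not reconstructible
  bit-for-bit.
* The motif finder models ungapped motifs only; an indel within a motif
  splits its support between variants.
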