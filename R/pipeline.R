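#' Resolved parameter set for an end-to-end run
#'
#' Collects every stage's tunables in one nested list so a run is fully
#' described by (params, seed). Defaults are the package's standard synthetic
#' benchmark: 5,000 peptides with 30 planted GVALSG carriers at a 2.0 log2
#' effect, 20 cases / 20 controls, 2 spot replicates, 500 trees per forest.
#' A full-scale array corresponds to `n_peptides = 125000`,
#' `n_cases = n_controls = 21`, `n_carriers = 40`, `n_trees = 5000`.
#'
#' @param n_peptides,peptide_length,n_cases,n_controls,n_carriers,n_spot_replicates,n_sample_replicates
#'   Simulation scale.
#' @param model [binding_model()] parameters.
#' @param negative_threshold,missing_threshold Preprocessing filters.
#' @param n_trees,min_samples_split Forest hyperparameters ([rf_config()]).
#' @param keep_fractions,drop_fraction,patience Reduction schedule
#'   ([stepwise_reduce()]).
#' @param motif_k_range,motif_max_mismatch,motif_min_support Consensus-motif
#'   search ([find_consensus_motifs()]).
#' @return A named list of class `ims_params`.
#' @export
ims_params <- function(n_peptides = 5000, peptide_length = 12,
                       n_cases = 20, n_controls = 20, n_carriers = 30,
                       n_spot_replicates = 2, n_sample_replicates = 1,
                       model = binding_model(),
                       negative_threshold = 0.5, missing_threshold = 0.25,
                       n_trees = 500, min_samples_split = 2,
                       keep_fractions = c(0.30, 0.40),
                       drop_fraction = 0.10, patience = 3,
                       motif_k_range = 4:8, motif_max_mismatch = 1,
                       motif_min_support = 2) {
  structure(
    list(
      n_peptides = n_peptides, peptide_length = peptide_length,
      n_cases = n_cases, n_controls = n_controls, n_carriers = n_carriers,
      n_spot_replicates = n_spot_replicates,
      n_sample_replicates = n_sample_replicates,
      model = model,
      negative_threshold = negative_threshold,
      missing_threshold = missing_threshold,
      n_trees = n_trees, min_samples_split = min_samples_split,
      keep_fractions = keep_fractions, drop_fraction = drop_fraction,
      patience = patience,
      motif_k_range = motif_k_range,
      motif_max_mismatch = motif_max_mismatch,
      motif_min_support = motif_min_support
    ),
    class = "ims_params"
  )
}

#' Run the full immunosignature pipeline on synthetic data
#'
#' Orchestrates simulate -> preprocess -> stepwise random-forest reduction ->
#' metrics -> consensus-motif discovery from a single seed. When `out_dir` is
#' given, the stage outputs (analysis matrix TSV, design TSV, signature and
#' OOB tables, metrics, motif report and the resolved parameters) are written
#' there as TSV/JSON.
#'
#' @param params An [ims_params()] list.
#' @param seed Integer seed driving every random stage.
#' @param out_dir Optional output directory.
#' @return A list of class `ims_run`: `dataset` (see [simulate_ims_dataset()]),
#'   `matrix` (preprocessed intensities), `signature` ([stepwise_reduce()]
#'   result), `metrics`, `motifs`, `carrier_recovery` (fraction of planted
#'   carriers present in the final signature), `params`, `seed`.
#' @export
run_ims_pipeline <- function(params = ims_params(), seed = 1, out_dir = NULL) {
  stopifnot(inherits(params, "ims_params"))
  ds <- simulate_ims_dataset(
    n_peptides = params$n_peptides, peptide_length = params$peptide_length,
    n_cases = params$n_cases, n_controls = params$n_controls,
    n_carriers = params$n_carriers, model = params$model,
    n_spot_replicates = params$n_spot_replicates,
    n_sample_replicates = params$n_sample_replicates, seed = seed
  )
  mat <- preprocess_scans(ds$spots, ds$design,
                          negative_threshold = params$negative_threshold,
                          missing_threshold = params$missing_threshold)
  cfg <- rf_config(n_trees = params$n_trees,
                   min_samples_split = params$min_samples_split,
                   seed = seed + 100L)
  sig <- stepwise_reduce(mat, ds$design, cfg,
                         keep_fractions = params$keep_fractions,
                         drop_fraction = params$drop_fraction,
                         patience = params$patience)
  sig_peptides <- unique(sig$selected$peptide_id)
  recovery <- mean(ds$carrier_ids %in% sig_peptides)
  motifs <- find_consensus_motifs(
    ds$library |> filter(.data$peptide_id %in% sig_peptides),
    k_range = params$motif_k_range,
    max_mismatch = params$motif_max_mismatch,
    min_support = params$motif_min_support
  )
  run <- structure(
    list(dataset = ds, matrix = mat, signature = sig, metrics = sig$metrics,
         motifs = motifs, carrier_recovery = recovery,
         params = params, seed = seed),
    class = "ims_run"
  )
  if (!is.null(out_dir)) {
    write_ims_run(run, out_dir)
  }
  run
}

#' @export
print.ims_run <- function(x, ...) {
  cat(sprintf("Immunosignature run (seed %d)\n", x$seed))
  cat(sprintf("  peptides simulated: %d (carriers: %d)\n",
              x$params$n_peptides, x$params$n_carriers))
  cat(sprintf("  analysis matrix: %d peptides x %d subjects x 2 channels\n",
              length(unique(x$matrix$peptide_id)),
              length(unique(x$matrix$sample_id))))
  cat(sprintf("  signature: %d features, OOB overall %.2f%%\n",
              nrow(x$signature$selected), x$signature$oob_score))
  cat(sprintf("  carrier recovery: %.1f%%\n", 100 * x$carrier_recovery))
  if (nrow(x$motifs) > 0) {
    cat(sprintf("  top motif: %s (support %d of %d)\n",
                x$motifs$motif[1], x$motifs$support[1], x$motifs$n_scanned[1]))
  }
  invisible(x)
}

# Serialise an ims_run's tables and resolved parameters
write_ims_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(run$matrix, file.path(out_dir, "matrix.tsv"))
  write_design_tsv(run$dataset$design, file.path(out_dir, "design.tsv"))
  readr::write_tsv(run$signature$selected, file.path(out_dir, "signature.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$signature$oob, file.path(out_dir, "oob_predictions.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$signature$trace, file.path(out_dir, "trace.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    run$metrics |> select(-"per_class_pct"),
    file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  jsonlite::write_json(
    run$motifs |> mutate(merged_variants = purrr::map(.data$merged_variants, I)),
    file.path(out_dir, "motifs.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  p <- run$params
  p$model <- unclass(p$model)
  jsonlite::write_json(
    list(seed = run$seed, params = unclass(p)),
    file.path(out_dir, "run_config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
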