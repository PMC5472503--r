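#' Background subtraction
#'
#' Simple background subtraction: `value = foreground - background` per spot,
#' in both channels. Negative values are retained deliberately — they drive the
#' negative-incidence QC filter — and only become missing later, at the log
#' step of normalization.
#'
#' @param spots Raw spot tibble ([simulate_scans()] / [read_gpr()]).
#' @return The spot tibble with a `value` column, `stage = "background_corrected"`.
#' @export
subtract_background <- function(spots) {
  stopifnot(is.data.frame(spots), all(c("fg", "bg") %in% names(spots)))
  out <- spots |> mutate(value = .data$fg - .data$bg)
  attr(out, "negative_peptides") <- attr(spots, "negative_peptides", exact = TRUE)
  set_stage(out, "background_corrected")
}

#' Filter peptides with a high incidence of negative corrected values
#'
#' A peptide is excluded when, in at least one channel, strictly more than
#' `threshold` of the samples have a negative background-corrected value
#' (spot replicates are averaged per sample first). Exclusion at exactly the
#' threshold does not occur: the rule is "more than".
#'
#' @param corrected Output of [subtract_background()] covering all samples.
#' @param threshold Maximum tolerated fraction of negative samples (default 0.5).
#' @return The corrected table restricted to retained peptides; the exclusion
#'   report (peptide, channel, negative fraction) is attached as attribute
#'   `exclusion_report`.
#' @export
filter_negative_incidence <- function(corrected, threshold = 0.5) {
  stopifnot(is.data.frame(corrected), "value" %in% names(corrected))
  if (length(unique(corrected$sample_id)) == 0) {
    abort("no samples present; cannot compute negative incidence.")
  }
  incidence <- corrected |>
    summarise(value = mean(.data$value),
              .by = c("peptide_id", "channel", "sample_id")) |>
    summarise(frac_negative = mean(.data$value < 0),
              .by = c("peptide_id", "channel"))
  excluded <- incidence |>
    filter(.data$frac_negative > threshold) |>
    arrange(.data$peptide_id)
  out <- corrected |> filter(!.data$peptide_id %in% excluded$peptide_id)
  attr(out, "exclusion_report") <- excluded
  set_stage(out, ims_stage(corrected) %||% "background_corrected")
}

#' M/A transform of a two-channel array
#'
#' Computes the per-spot log-ratio `M = log2(IgM_635 / IgG_532)` and average
#' log-intensity `A = (log2(IgM_635) + log2(IgG_532)) / 2` from background-
#' corrected values. The log transform is undefined for non-positive values,
#' so a spot with a non-positive corrected value in either channel gets
#' missing M and A — never a clipped value.
#'
#' @param corrected Output of [subtract_background()] (optionally after
#'   [filter_negative_incidence()]).
#' @return A tibble `sample_id`, `peptide_id`, `spot_rep`, `M`, `A`.
#' @export
compute_ma <- function(corrected) {
  stopifnot(is.data.frame(corrected), "value" %in% names(corrected))
  wide <- corrected |>
    select("sample_id", "peptide_id", "spot_rep", "channel", "value") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value")
  if (!all(CHANNELS %in% names(wide))) {
    abort("both channels (IgG_532, IgM_635) are required for the M/A transform.")
  }
  safe_log2 <- function(x) {
    out <- rep(NA_real_, length(x))
    pos <- !is.na(x) & x > 0
    out[pos] <- log2(x[pos])
    out
  }
  l_g <- safe_log2(wide$IgG_532)
  l_m <- safe_log2(wide$IgM_635)
  wide |>
    transmute(.data$sample_id, .data$peptide_id, .data$spot_rep,
              M = l_m - l_g, A = (l_m + l_g) / 2)
}

# ma tibble <-> limma MAList matrices (rows = peptide x spot, cols = arrays)
ma_to_malist <- function(ma) {
  key <- paste(ma$peptide_id, ma$spot_rep, sep = "\r")
  ukey <- unique(key)
  usmp <- unique(ma$sample_id)
  ri <- match(key, ukey)
  ci <- match(ma$sample_id, usmp)
  M <- A <- matrix(NA_real_, length(ukey), length(usmp),
                   dimnames = list(ukey, usmp))
  M[cbind(ri, ci)] <- ma$M
  A[cbind(ri, ci)] <- ma$A
  methods::new(methods::getClass("MAList", where = asNamespace("limma")),
               list(M = M, A = A))
}

malist_to_ma <- function(mal) {
  key <- rownames(mal$M)
  parts <- strsplit(key, "\r", fixed = TRUE)
  tibble(
    sample_id = rep(colnames(mal$M), each = length(key)),
    peptide_id = rep(vapply(parts, `[`, "", 1L), ncol(mal$M)),
    spot_rep = rep(as.integer(vapply(parts, `[`, "", 2L)), ncol(mal$M)),
    M = as.vector(mal$M),
    A = as.vector(mal$A)
  )
}

#' Within-array median normalization
#'
#' Centres each array's log-ratios: `M' = M - median(M)` over the array's
#' non-missing spots; A is untouched. Delegates to
#' `limma::normalizeWithinArrays(method = "median")`.
#'
#' @param ma M/A tibble from [compute_ma()].
#' @return The tibble with normalized `M`.
#' @export
normalize_within_array_median <- function(ma) {
  stopifnot(is.data.frame(ma), all(c("sample_id", "M", "A") %in% names(ma)))
  all_missing <- ma |>
    summarise(none = all(is.na(.data$M)), .by = "sample_id") |>
    filter(.data$none)
  if (nrow(all_missing) > 0) {
    abort(sprintf("array(s) with all spots missing: %s",
                  paste(all_missing$sample_id, collapse = ", ")))
  }
  mal <- ma_to_malist(ma)
  norm <- limma::normalizeWithinArrays(mal, method = "median")
  out <- malist_to_ma(norm) |>
    semi_join(ma, by = c("sample_id", "peptide_id", "spot_rep"))
  out[order(match(paste(out$sample_id, out$peptide_id, out$spot_rep),
                  paste(ma$sample_id, ma$peptide_id, ma$spot_rep))), ]
}

#' Between-array Aquantile normalization
#'
#' Quantile-normalizes the A-values across arrays (each array's sorted A is
#' replaced by the across-array mean of order statistics; ranks of missing
#' values are interpolated), leaving M untouched. Delegates to
#' `limma::normalizeBetweenArrays(method = "Aquantile")`. With a single array
#' this is the identity, with a warning.
#'
#' @param ma M/A tibble, typically after [normalize_within_array_median()].
#' @return The tibble with normalized `A`.
#' @export
normalize_between_arrays_aquantile <- function(ma) {
  stopifnot(is.data.frame(ma), all(c("sample_id", "M", "A") %in% names(ma)))
  n_arrays <- length(unique(ma$sample_id))
  if (n_arrays < 2) {
    warn("only one array: Aquantile normalization is the identity.")
    return(ma)
  }
  mal <- ma_to_malist(ma)
  norm <- limma::normalizeBetweenArrays(mal, method = "Aquantile")
  out <- malist_to_ma(norm) |>
    semi_join(ma, by = c("sample_id", "peptide_id", "spot_rep"))
  out[order(match(paste(out$sample_id, out$peptide_id, out$spot_rep),
                  paste(ma$sample_id, ma$peptide_id, ma$spot_rep))), ]
}

#' Reconstruct per-channel log2 intensities from M/A values
#'
#' Inverts the M/A transform: `log2(IgG_532) = A - M/2`,
#' `log2(IgM_635) = A + M/2`.
#'
#' @param ma M/A tibble.
#' @return Long tibble `sample_id`, `peptide_id`, `spot_rep`, `channel`,
#'   `value` (log2 scale), `stage = "normalized"`.
#' @export
channels_from_ma <- function(ma) {
  out <- bind_rows(
    ma |> transmute(.data$sample_id, .data$peptide_id, .data$spot_rep,
                    channel = "IgG_532", value = .data$A - .data$M / 2),
    ma |> transmute(.data$sample_id, .data$peptide_id, .data$spot_rep,
                    channel = "IgM_635", value = .data$A + .data$M / 2)
  )
  set_stage(out, "normalized")
}

#' Average replicated spots, then replicated samples
#'
#' Arithmetic mean over non-missing replicate values, spot level first and
#' technical sample replicates (the design's `replicate_group`) second; a cell
#' is missing only when all its replicates are missing. The returned
#' `sample_id` is the replicate group (one row set per subject).
#'
#' @param values Long normalized tibble from [channels_from_ma()].
#' @param design Cohort design mapping `sample_id` to `replicate_group`.
#' @return Tibble `peptide_id`, `channel`, `sample_id`, `value`,
#'   `stage = "averaged"`.
#' @export
average_replicates <- function(values, design) {
  stopifnot(is.data.frame(values), is.data.frame(design))
  mean_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  out <- values |>
    summarise(value = mean_na(.data$value),
              .by = c("peptide_id", "channel", "sample_id")) |>
    inner_join(design |> select("sample_id", "replicate_group"), by = "sample_id") |>
    summarise(value = mean_na(.data$value),
              .by = c("peptide_id", "channel", "replicate_group")) |>
    rename(sample_id = "replicate_group")
  set_stage(out, "averaged")
}

# subject-level design (one row per replicate group)
subject_design <- function(design) {
  design |>
    distinct(.data$replicate_group, .data$class_label) |>
    rename(sample_id = "replicate_group")
}

#' Filter peptides by per-cohort missingness
#'
#' A peptide is excluded when strictly more than `threshold` of its values are
#' missing within the case cohort or within the control cohort (evaluated in
#' each channel; failure anywhere excludes the peptide from the final set).
#'
#' @param averaged Averaged tibble from [average_replicates()].
#' @param design Cohort design; its subject level (`replicate_group`) must match
#'   the averaged `sample_id`s.
#' @param threshold Maximum tolerated missing fraction (default 0.25).
#' @return Filtered tibble, `stage = "filtered"`, with attribute
#'   `exclusion_report`.
#' @export
filter_missing_by_cohort <- function(averaged, design, threshold = 0.25) {
  sdesign <- subject_design(design)
  cohort_n <- sdesign |> count(.data$class_label)
  if (nrow(cohort_n) < 2 || any(cohort_n$n == 0)) {
    abort("both cohorts (case, control) must be nonempty.")
  }
  report <- averaged |>
    inner_join(sdesign, by = "sample_id") |>
    summarise(frac_missing = mean(is.na(.data$value)),
              .by = c("peptide_id", "channel", "class_label"))
  excluded <- report |>
    filter(.data$frac_missing > threshold) |>
    arrange(.data$peptide_id)
  out <- averaged |> filter(!.data$peptide_id %in% excluded$peptide_id)
  attr(out, "exclusion_report") <- excluded
  set_stage(out, "filtered")
}

#' Full preprocessing chain for immunosignature scans
#'
#' Applies, in fixed order: background subtraction; negative-incidence filter
#' (> `negative_threshold` of samples negative in either channel); within-array
#' median normalization of M; between-array Aquantile normalization of A;
#' channel reconstruction; averaging over replicated spots then replicated
#' samples; per-cohort missingness filter (> `missing_threshold` missing in
#' either cohort).
#'
#' @param spots Raw spot tibble covering all samples.
#' @param design Cohort design.
#' @param negative_threshold,missing_threshold Filter thresholds.
#' @return Analysis-ready long tibble `peptide_id`, `channel`, `sample_id`,
#'   `value` (log2), `stage = "filtered"`, carrying a `qc` attribute (counts of
#'   peptides removed per filter, per-array raw M medians); see [qc_report()].
#' @export
preprocess_scans <- function(spots, design,
                             negative_threshold = 0.5,
                             missing_threshold = 0.25) {
  corrected <- subtract_background(spots)
  kept <- filter_negative_incidence(corrected, threshold = negative_threshold)
  neg_report <- attr(kept, "exclusion_report", exact = TRUE)
  ma <- compute_ma(kept)
  raw_medians <- ma |>
    summarise(m_median = median(.data$M, na.rm = TRUE), .by = "sample_id")
  ma <- normalize_within_array_median(ma)
  ma <- normalize_between_arrays_aquantile(ma)
  values <- channels_from_ma(ma)
  averaged <- average_replicates(values, design)
  out <- filter_missing_by_cohort(averaged, design, threshold = missing_threshold)
  miss_report <- attr(out, "exclusion_report", exact = TRUE)
  attr(out, "qc") <- list(
    n_peptides_in = length(unique(spots$peptide_id)),
    n_samples = length(unique(spots$sample_id)),
    n_subjects = length(unique(design$replicate_group)),
    excluded_negative_incidence = unique(neg_report$peptide_id),
    excluded_missingness = unique(miss_report$peptide_id),
    n_peptides_final = length(unique(out$peptide_id)),
    raw_m_medians = raw_medians
  )
  out
}

#' Retrieve the QC report attached by [preprocess_scans()]
#'
#' @param x Result of [preprocess_scans()].
#' @return A list with per-filter exclusions and per-array raw M medians.
#' @export
qc_report <- function(x) attr(x, "qc", exact = TRUE)
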