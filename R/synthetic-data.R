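#' Generate a random-peptide library
#'
#' Draws `n_peptides` amino-acid sequences of fixed length, i.i.d. uniform over
#' `alphabet`, emulating the random 12-mer libraries printed on immunosignature
#' microarrays.
#'
#' @param n_peptides Number of peptides (the physical arrays carry 125,000).
#' @param length Sequence length in residues; immunosignature arrays use 12-mers.
#' @param alphabet Character vector of residues to draw from. Defaults to the 20
#'   standard amino acids; pass a subset (e.g. without cysteine) for libraries
#'   synthesised with a restricted chemistry.
#' @param seed Integer seed; identical seeds give byte-identical libraries.
#'
#' @return A tibble with columns `peptide_id` and `sequence`.
#' @examples
#' peptide_library(5, length = 12, seed = 1)
#' @export
peptide_library <- function(n_peptides, length = 12, alphabet = AA_STANDARD,
                            seed = NULL) {
  if (!is.numeric(n_peptides) || n_peptides < 1) {
    abort("`n_peptides` must be a positive integer.")
  }
  if (!is.numeric(length) || length < 1) {
    abort("`length` must be a positive integer.")
  }
  alphabet <- as.character(alphabet)
  if (base::length(alphabet) < 1 || any(nchar(alphabet) != 1L)) {
    abort("`alphabet` must be a nonempty vector of single characters.")
  }
  n_peptides <- as.integer(n_peptides)
  length <- as.integer(length)
  seqs <- with_seed(seed, {
    chars <- sample(alphabet, n_peptides * length, replace = TRUE)
    apply(matrix(chars, nrow = n_peptides), 1L, paste0, collapse = "")
  })
  tibble(
    peptide_id = sprintf("pep_%0*d", nchar(as.character(n_peptides)), seq_len(n_peptides)),
    sequence = seqs
  )
}

#' Plant a motif into a subset of library peptides
#'
#' Overwrites a window at a random offset of `n_carriers` randomly chosen
#' peptides with `motif`, so downstream motif-recovery analyses have a known
#' ground truth. Peptides already containing the motif by chance keep it; the
#' `motif_carrier` column marks only the engineered carriers.
#'
#' @param library A tibble from [peptide_library()].
#' @param motif Amino-acid string to embed (default the GVALSG consensus).
#' @param n_carriers Number of peptides to overwrite.
#' @param seed Integer seed.
#'
#' @return The library with a logical `motif_carrier` column.
#' @export
plant_motif <- function(library, motif = "GVALSG", n_carriers, seed = NULL) {
  stopifnot(is.data.frame(library), all(c("peptide_id", "sequence") %in% names(library)))
  len <- nchar(library$sequence[1] %||% "")
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 1) {
    abort("`motif` must be a single nonempty string.")
  }
  if (nchar(motif) > len) {
    abort(sprintf("`motif` (length %d) does not fit in peptides of length %d.",
                  nchar(motif), len))
  }
  if (n_carriers > nrow(library)) {
    abort("`n_carriers` exceeds the number of peptides.")
  }
  library$motif_carrier <- FALSE
  if (n_carriers == 0) {
    return(as_tibble(library))
  }
  with_seed(seed, {
    idx <- sample(nrow(library), n_carriers)
    offs <- sample(len - nchar(motif) + 1L, n_carriers, replace = TRUE)
    seqs <- library$sequence
    for (j in seq_along(idx)) {
      s <- seqs[idx[j]]
      substr(s, offs[j], offs[j] + nchar(motif) - 1L) <- motif
      seqs[idx[j]] <- s
    }
    library$sequence <- seqs
    library$motif_carrier[idx] <- TRUE
  })
  as_tibble(library)
}

#' Case/control cohort design
#'
#' Builds the sample sheet for a two-cohort study. Defaults mirror a 21-case /
#' 21-control design recruited at US and European sites (11+10 cases, 12+10
#' controls). `replicate_group` identifies technical replicates of one subject;
#' with `n_sample_replicates = 1` each sample is its own group.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param case_sites,control_sites Named integer vectors of per-site counts that
#'   must sum to the cohort size; `NULL` gives an 11/10 US/EU split at the
#'   default size 21 and an even split otherwise.
#' @param n_sample_replicates Technical replicates per subject.
#'
#' @return A tibble with columns `sample_id`, `class_label` (`case`/`control`),
#'   `site`, `replicate_group`.
#' @export
cohort_design <- function(n_cases = 21, n_controls = 21,
                          case_sites = NULL, control_sites = NULL,
                          n_sample_replicates = 1) {
  if (n_cases < 1 || n_controls < 1) abort("both cohorts must be nonempty.")
  if (is.null(case_sites)) {
    case_sites <- if (n_cases == 21) c(US = 11, EU = 10) else site_split(n_cases)
  }
  if (is.null(control_sites)) {
    control_sites <- if (n_controls == 21) c(US = 11, EU = 10) else site_split(n_controls)
  }
  if (sum(case_sites) != n_cases || sum(control_sites) != n_controls) {
    abort("site counts must sum to the cohort size.")
  }
  subj <- bind_rows(
    tibble(
      subject_id = sprintf("case_%02d", seq_len(n_cases)),
      class_label = "case",
      site = rep(names(case_sites), case_sites)
    ),
    tibble(
      subject_id = sprintf("ctrl_%02d", seq_len(n_controls)),
      class_label = "control",
      site = rep(names(control_sites), control_sites)
    )
  )
  out <- tidyr::crossing(subj, rep = seq_len(n_sample_replicates)) |>
    mutate(
      sample_id = if (n_sample_replicates > 1) {
        sprintf("%s_r%d", .data$subject_id, .data$rep)
      } else {
        .data$subject_id
      },
      replicate_group = .data$subject_id
    ) |>
    select("sample_id", "class_label", "site", "replicate_group") |>
    arrange(.data$replicate_group, .data$sample_id)
  out
}

site_split <- function(n) c(US = ceiling(n / 2), EU = floor(n / 2))

#' Antibody-binding model for scan simulation
#'
#' Parameters of the generative model behind [simulate_scans()]. Foreground
#' spot intensities are generated on the log2 scale as
#' `baseline + peptide effect + sample effect + motif effect (cases x carriers)
#' + noise`; backgrounds are log-normal. A `negative_fraction` of non-carrier
#' peptides is engineered to fall below background in most samples (these are
#' the peptides the negative-incidence QC filter must catch), and a small
#' `missing_fraction` of remaining spots is also pushed below background to
#' create sporadic missing values at the log step.
#'
#' @param baseline_log2 Mean log2 foreground intensity (arbitrary units).
#' @param peptide_effect_sd SD of the per-peptide, per-channel reactivity level.
#' @param sample_effect_sd SD of the per-array, per-channel offset (serum
#'   concentration / scanner gain).
#' @param noise_sd Per-spot log2 noise SD.
#' @param motif Discriminative motif carried by responder peptides.
#' @param motif_effect_log2 Log2 intensity shift added to carrier peptides in
#'   case samples only (both channels).
#' @param n_carrier_peptides Number of engineered carrier peptides.
#' @param background_meanlog2,background_sdlog2 Log2 mean/SD of spot background.
#' @param negative_fraction Fraction of non-carrier peptides made persistently
#'   sub-background.
#' @param negative_shift_log2 Mean log2(foreground/background) for engineered
#'   negative peptides; must be < 0 so they are negative in most samples.
#' @param missing_fraction Per-spot probability of a sporadic sub-background
#'   dropout on otherwise normal peptides.
#'
#' @return A list of class `binding_model`.
#' @export
binding_model <- function(baseline_log2 = 10,
                          peptide_effect_sd = 1,
                          sample_effect_sd = 0.3,
                          noise_sd = 1,
                          motif = "GVALSG",
                          motif_effect_log2 = 2,
                          n_carrier_peptides = 40,
                          background_meanlog2 = 6.6,
                          background_sdlog2 = 0.3,
                          negative_fraction = 0.05,
                          negative_shift_log2 = -0.7,
                          missing_fraction = 0.02) {
  sds <- c(peptide_effect_sd, sample_effect_sd, noise_sd, background_sdlog2)
  if (any(sds < 0)) abort("standard deviations must be >= 0.")
  fracs <- c(negative_fraction, missing_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1].")
  structure(
    list(
      baseline_log2 = baseline_log2,
      peptide_effect_sd = peptide_effect_sd,
      sample_effect_sd = sample_effect_sd,
      noise_sd = noise_sd,
      motif = motif,
      motif_effect_log2 = motif_effect_log2,
      n_carrier_peptides = n_carrier_peptides,
      background_meanlog2 = background_meanlog2,
      background_sdlog2 = background_sdlog2,
      negative_fraction = negative_fraction,
      negative_shift_log2 = negative_shift_log2,
      missing_fraction = missing_fraction
    ),
    class = "binding_model"
  )
}

#' Simulate two-channel array scans
#'
#' Emits one spot table per sample covering both detection channels (IgG at
#' 532 nm, IgM at 635 nm), with replicated spots laid out on a deterministic
#' grid. See [binding_model()] for the generative model.
#'
#' @param library Peptide library, typically after [plant_motif()]; its
#'   `motif_carrier` column (if present) selects the responder peptides.
#' @param design Cohort design from [cohort_design()].
#' @param model A [binding_model()].
#' @param n_spot_replicates Printed spots per peptide per array.
#' @param seed Integer seed.
#'
#' @return A tibble of spots: `sample_id`, `channel`, `block`, `row`, `column`,
#'   `spot_rep`, `peptide_id`, `fg` and `bg` (median foreground/background,
#'   raw arbitrary units), with attributes `negative_peptides` (engineered
#'   sub-background peptide ids) and `stage = "raw"`.
#' @export
simulate_scans <- function(library, design, model = binding_model(),
                           n_spot_replicates = 2, seed = NULL) {
  stopifnot(inherits(model, "binding_model"), is.data.frame(library),
            is.data.frame(design), nrow(design) > 0)
  if (n_spot_replicates < 1) abort("`n_spot_replicates` must be >= 1.")
  n_pep <- nrow(library)
  n_smp <- nrow(design)
  carriers <- if ("motif_carrier" %in% names(library)) library$motif_carrier else rep(FALSE, n_pep)
  is_case <- design$class_label == "case"

  # fixed grid layout: replicate r of peptide p sits in block r
  grid_cols <- max(1L, ceiling(sqrt(n_pep)))
  layout <- tibble(
    peptide_id = rep(library$peptide_id, n_spot_replicates),
    spot_rep = rep(seq_len(n_spot_replicates), each = n_pep),
    block = rep(seq_len(n_spot_replicates), each = n_pep),
    row = rep((seq_len(n_pep) - 1L) %/% grid_cols + 1L, n_spot_replicates),
    column = rep((seq_len(n_pep) - 1L) %% grid_cols + 1L, n_spot_replicates)
  )

  with_seed(seed, {
    non_carrier <- which(!carriers)
    n_neg <- floor(model$negative_fraction * length(non_carrier))
    neg_idx <- if (n_neg > 0) sort(sample(non_carrier, n_neg)) else integer(0)
    is_neg <- seq_len(n_pep) %in% neg_idx

    per_channel <- function(channel) {
      pep_eff <- rnorm(n_pep, 0, model$peptide_effect_sd)
      smp_eff <- rnorm(n_smp, 0, model$sample_effect_sd)
      n_cells <- n_pep * n_smp * n_spot_replicates
      # index order: peptide fastest, then sample, then spot replicate
      pep_i <- rep(seq_len(n_pep), times = n_smp * n_spot_replicates)
      smp_i <- rep(rep(seq_len(n_smp), each = n_pep), times = n_spot_replicates)
      rep_i <- rep(seq_len(n_spot_replicates), each = n_pep * n_smp)

      log_bg <- rnorm(n_cells, model$background_meanlog2, model$background_sdlog2)
      log_fg <- model$baseline_log2 + pep_eff[pep_i] + smp_eff[smp_i] +
        model$motif_effect_log2 * (carriers[pep_i] & is_case[smp_i]) +
        rnorm(n_cells, 0, model$noise_sd)

      # engineered negatives and sporadic dropouts: foreground re-drawn around
      # background shifted down, so fg < bg with probability pnorm(-shift/sd)
      drop <- is_neg[pep_i] |
        (!carriers[pep_i] & runif(n_cells) < model$missing_fraction)
      n_drop <- sum(drop)
      if (n_drop > 0) {
        log_fg[drop] <- log_bg[drop] + model$negative_shift_log2 +
          rnorm(n_drop, 0, model$noise_sd)
      }

      tibble(
        sample_id = design$sample_id[smp_i],
        channel = channel,
        peptide_id = library$peptide_id[pep_i],
        spot_rep = rep_i,
        fg = 2^log_fg,
        bg = 2^log_bg
      )
    }

    spots <- bind_rows(lapply(CHANNELS, per_channel)) |>
      left_join(layout, by = c("peptide_id", "spot_rep")) |>
      select("sample_id", "channel", "block", "row", "column", "spot_rep",
             "peptide_id", "fg", "bg") |>
      arrange(.data$sample_id, .data$channel, .data$spot_rep, .data$row, .data$column)
    attr(spots, "negative_peptides") <- library$peptide_id[neg_idx]
    set_stage(spots, "raw")
  })
}

#' Simulate a complete immunosignature dataset
#'
#' Convenience wrapper chaining [peptide_library()], [plant_motif()],
#' [cohort_design()] and [simulate_scans()] from a single seed. The default
#' scale (5,000 peptides, 30 carriers, 20 cases / 20 controls, 2 spot
#' replicates) is the package's standard synthetic benchmark; pass
#' `n_peptides = 125000`, `n_cases = n_controls = 21` for a full-scale array.
#'
#' @param n_peptides,peptide_length,alphabet Library parameters.
#' @param n_cases,n_controls Cohort sizes.
#' @param n_carriers Planted motif carriers.
#' @param model A [binding_model()]; its `n_carrier_peptides` is overridden by
#'   `n_carriers`.
#' @param n_spot_replicates,n_sample_replicates Replication structure.
#' @param seed Single integer seed for the whole dataset.
#'
#' @return A list with elements `library`, `design`, `spots`, `model`,
#'   `carrier_ids`.
#' @export
simulate_ims_dataset <- function(n_peptides = 5000, peptide_length = 12,
                                 alphabet = AA_STANDARD,
                                 n_cases = 20, n_controls = 20,
                                 n_carriers = 30,
                                 model = binding_model(),
                                 n_spot_replicates = 2,
                                 n_sample_replicates = 1,
                                 seed = 1) {
  model$n_carrier_peptides <- n_carriers
  lib <- peptide_library(n_peptides, peptide_length, alphabet, seed = seed)
  lib <- plant_motif(lib, model$motif, n_carriers, seed = seed + 1L)
  design <- cohort_design(n_cases, n_controls,
                          n_sample_replicates = n_sample_replicates)
  spots <- simulate_scans(lib, design, model,
                          n_spot_replicates = n_spot_replicates,
                          seed = seed + 2L)
  list(
    library = lib,
    design = design,
    spots = spots,
    model = model,
    carrier_ids = lib$peptide_id[lib$motif_carrier]
  )
}
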