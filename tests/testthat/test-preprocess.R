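make_corrected <- function(values_by_sample, channel = "IgG_532",
                           peptide_ids = NULL) {
  # values_by_sample: named list sample_id -> numeric vector over peptides
  n <- length(values_by_sample[[1]])
  if (is.null(peptide_ids)) peptide_ids <- sprintf("pep_%02d", seq_len(n))
  dplyr::bind_rows(lapply(names(values_by_sample), function(s) {
    tibble::tibble(sample_id = s, channel = channel, spot_rep = 1L,
                   peptide_id = peptide_ids,
                   value = values_by_sample[[s]])
  }))
}

test_that("background subtraction is plain fg - bg with negatives retained", {
  spots <- tibble::tibble(
    sample_id = "s1", channel = "IgG_532", block = 1, row = 1, column = 1:3,
    spot_rep = 1L, peptide_id = c("a", "b", "c"),
    fg = c(500, 100, 50), bg = c(100, 100, 100)
  )
  corr <- subtract_background(spots)
  expect_equal(corr$value, c(400, 0, -50))
  expect_equal(attr(corr, "stage"), "background_corrected")
})

test_that("negative-incidence filter excludes strictly above 50% in either channel", {
  n_smp <- 10
  mk <- function(n_neg_igg, n_neg_igm) {
    igg <- c(rep(-1, n_neg_igg), rep(1, n_smp - n_neg_igg))
    igm <- c(rep(-1, n_neg_igm), rep(1, n_smp - n_neg_igm))
    dplyr::bind_rows(
      make_corrected(setNames(as.list(igg), sprintf("s%02d", 1:n_smp)),
                     channel = "IgG_532", peptide_ids = "pep"),
      make_corrected(setNames(as.list(igm), sprintf("s%02d", 1:n_smp)),
                     channel = "IgM_635", peptide_ids = "pep")
    )
  }
  # 6/10 negative in IgG -> excluded
  expect_equal(nrow(filter_negative_incidence(mk(6, 0))), 0)
  # 5/10 in each channel -> boundary, retained ("more than" is strict)
  expect_equal(length(unique(filter_negative_incidence(mk(5, 5))$peptide_id)), 1)
  # negative only in IgM -> still excluded (either-channel rule)
  expect_equal(nrow(filter_negative_incidence(mk(0, 6))), 0)
})

test_that("negative-incidence filter is idempotent and reports exclusions", {
  ds <- tiny_dataset(n_peptides = 200, seed = 13)
  corr <- subtract_background(ds$spots)
  once <- filter_negative_incidence(corr)
  report <- attr(once, "exclusion_report")
  expect_true(all(report$frac_negative > 0.5))
  twice <- filter_negative_incidence(once)
  expect_equal(nrow(attr(twice, "exclusion_report")), 0)
  expect_equal(nrow(twice), nrow(once))
})

test_that("M/A transform masks non-positive values and reconstructs exactly", {
  corr <- dplyr::bind_rows(
    tibble::tibble(sample_id = "s1", channel = "IgG_532", spot_rep = 1L,
                   peptide_id = c("a", "b"), value = c(4, -2)),
    tibble::tibble(sample_id = "s1", channel = "IgM_635", spot_rep = 1L,
                   peptide_id = c("a", "b"), value = c(16, 8))
  )
  ma <- compute_ma(corr)
  a_row <- ma[ma$peptide_id == "a", ]
  expect_equal(a_row$M, 2)   # log2(16) - log2(4)
  expect_equal(a_row$A, 3)   # (4 + 2) / 2
  expect_true(is.na(ma$M[ma$peptide_id == "b"]))

  ch <- channels_from_ma(ma)
  expect_equal(ch$value[ch$peptide_id == "a" & ch$channel == "IgG_532"], 2)
  expect_equal(ch$value[ch$peptide_id == "a" & ch$channel == "IgM_635"], 4)
})

test_that("within-array median normalization centres each array's M", {
  ma <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    peptide_id = rep(c("a", "b", "c"), 2), spot_rep = 1L,
    M = c(1, 2, 3, 5, 5, 8), A = c(1, 2, 3, 4, 5, 6)
  )
  norm <- normalize_within_array_median(ma)
  expect_equal(norm$M[norm$sample_id == "s1"], c(-1, 0, 1))
  expect_equal(norm$A, ma$A) # A untouched
  # idempotent on already-centred arrays
  again <- normalize_within_array_median(norm)
  expect_equal(again$M, norm$M)
  # post hoc invariant on a random array
  set.seed(2)
  r <- tibble::tibble(sample_id = "s1", peptide_id = sprintf("p%d", 1:21),
                      spot_rep = 1L, M = rnorm(21), A = rnorm(21))
  expect_equal(median(normalize_within_array_median(r)$M), 0)
  # all-missing array is an error
  bad <- ma
  bad$M[bad$sample_id == "s2"] <- NA
  expect_error(normalize_within_array_median(bad), "all spots missing")
})

test_that("Aquantile replaces sorted A by order-statistic means, M untouched", {
  ma <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 2),
    peptide_id = rep(c("a", "b"), 2), spot_rep = 1L,
    M = c(0.5, -0.5, 1, 2), A = c(1, 3, 2, 4)
  )
  norm <- normalize_between_arrays_aquantile(ma)
  expect_equal(norm$A, c(1.5, 3.5, 1.5, 3.5))
  expect_equal(norm$M, ma$M)

  # identical A multisets are a fixed point
  fixed <- ma
  fixed$A <- c(1, 3, 3, 1)
  norm2 <- normalize_between_arrays_aquantile(fixed)
  expect_equal(sort(norm2$A[1:2]), c(1, 3))
  expect_equal(norm2$A, fixed$A)

  # single array: identity with a warning
  single <- ma[ma$sample_id == "s1", ]
  expect_warning(out <- normalize_between_arrays_aquantile(single), "one array")
  expect_equal(out$A, single$A)
})

test_that("after Aquantile all complete arrays share the same sorted A", {
  corr <- positive_corrected(n_pep = 120, n_arr = 6, seed = 17)
  ma <- normalize_between_arrays_aquantile(
    normalize_within_array_median(compute_ma(corr))
  )
  by_arr <- split(ma$A, ma$sample_id)
  expect_true(all(!vapply(by_arr, anyNA, logical(1))))
  ref <- sort(by_arr[[1]])
  for (a in by_arr[-1]) expect_equal(sort(a), ref)
})

test_that("replicate averaging is mean-over-available, spot level first", {
  values <- tibble::tibble(
    sample_id = c("s1a", "s1a", "s1b", "s1b"),
    peptide_id = "pep", channel = "IgG_532", spot_rep = c(1L, 2L, 1L, 2L),
    value = c(2, 4, NA, 10)
  )
  design <- tibble::tibble(sample_id = c("s1a", "s1b"),
                           class_label = "case", site = "US",
                           replicate_group = "subj1")
  avg <- average_replicates(values, design)
  # spot mean per sample: s1a -> 3, s1b -> 10; then subject mean -> 6.5.
  # (a flat mean of the four values would give 16/3, not 6.5)
  expect_equal(avg$value, 6.5)
  expect_equal(avg$sample_id, "subj1")

  # all replicates missing -> missing
  values$value <- NA_real_
  expect_true(is.na(average_replicates(values, design)$value))
})

test_that("cohort missingness filter applies a strict 25% rule per cohort", {
  n_per <- 21
  design <- cohort_design(n_per, n_per)
  subj <- unique(design$replicate_group)
  mk_avg <- function(n_missing_case) {
    miss <- subj[design$class_label[match(subj, design$replicate_group)] == "case"][
      seq_len(n_missing_case)]
    tibble::tibble(peptide_id = "pep", channel = "IgG_532", sample_id = subj,
                   value = ifelse(subj %in% miss, NA_real_, 1))
  }
  # 6/21 = 28.6% missing in the case cohort -> excluded
  expect_equal(nrow(filter_missing_by_cohort(mk_avg(6), design)), 0)
  # 5/21 = 23.8% -> retained
  expect_equal(nrow(filter_missing_by_cohort(mk_avg(5), design)), n_per * 2)
  # no missingness -> identity
  full <- mk_avg(0)
  expect_equal(nrow(filter_missing_by_cohort(full, design)), nrow(full))
  # empty cohort is an error
  bad_design <- design[design$class_label == "case", ]
  expect_error(filter_missing_by_cohort(mk_avg(0), bad_design), "cohort")
})

test_that("the full preprocessing chain runs in order and reports QC", {
  ds <- tiny_dataset(n_peptides = 150, seed = 23)
  mat <- preprocess_scans(ds$spots, ds$design)
  qc <- qc_report(mat)
  expect_equal(qc$n_peptides_in, 150)
  expect_equal(qc$n_peptides_final, length(unique(mat$peptide_id)))
  expect_true(all(attr(ds$spots, "negative_peptides") %in%
                    qc$excluded_negative_incidence))
  expect_false(any(qc$excluded_negative_incidence %in% mat$peptide_id))
  expect_equal(attr(mat, "stage"), "filtered")
  # both channels survive with one row per subject
  expect_setequal(unique(mat$channel), c("IgG_532", "IgM_635"))
  expect_setequal(unique(mat$sample_id), unique(ds$design$replicate_group))
})
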