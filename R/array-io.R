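GPR_COLUMNS <- c("Block", "Column", "Row", "Name", "ID",
                 "F532 Median", "B532 Median", "F635 Median", "B635 Median")

#' Write one sample's scan as a GPR-dialect file
#'
#' Serialises the spot table of a single sample (both channels) in a minimal
#' GenePix Results (ATF) dialect: an `ATF 1.0` preamble, quoted header records,
#' then a tab-separated table with columns Block, Column, Row, Name, ID,
#' F532/B532/F635/B635 Median. One file carries both wavelengths, as GenePix
#' writes them.
#'
#' @param spots Spot tibble as produced by [simulate_scans()], restricted to
#'   one `sample_id`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gpr <- function(spots, path) {
  stopifnot(is.data.frame(spots))
  ids <- unique(spots$sample_id)
  if (length(ids) != 1L) {
    abort("`spots` must contain exactly one sample_id; split before writing.")
  }
  wide <- spots |>
    select("channel", "block", "row", "column", "spot_rep", "peptide_id", "fg", "bg") |>
    tidyr::pivot_wider(names_from = "channel", values_from = c("fg", "bg"))
  need <- c("fg_IgG_532", "bg_IgG_532", "fg_IgM_635", "bg_IgM_635")
  missing_ch <- setdiff(need, names(wide))
  if (length(missing_ch) > 0) {
    abort(paste0("both channels are required to write a GPR file; missing: ",
                 paste(missing_ch, collapse = ", ")))
  }
  tbl <- tibble(
    Block = wide$block, Column = wide$column, Row = wide$row,
    Name = wide$peptide_id, ID = wide$peptide_id,
    `F532 Median` = wide$fg_IgG_532, `B532 Median` = wide$bg_IgG_532,
    `F635 Median` = wide$fg_IgM_635, `B635 Median` = wide$bg_IgM_635
  )
  writeLines(c(
    "ATF\t1.0",
    sprintf("%d\t%d", 2L, ncol(tbl)),
    "\"Type=GenePix Results 3\"",
    sprintf("\"SampleID=%s\"", ids),
    paste(sprintf('"%s"', names(tbl)), collapse = "\t")
  ), path)
  readr::write_tsv(tbl, path, col_names = FALSE, progress = FALSE,
                   append = TRUE)
  invisible(path)
}

#' Read a GPR-dialect scan file
#'
#' Parses the dialect written by [write_gpr()] (a subset of the GenePix GPR
#' format: only the median foreground/background statistics are used; mean
#' columns, flags and wavelength metadata are ignored). The single file is
#' split into the two channel scans.
#'
#' @param path GPR file path.
#' @param sample_id Sample identifier; defaults to the `SampleID` header record
#'   if present, else the file name.
#' @return A spot tibble in the layout of [simulate_scans()] (long over the two
#'   channels), `stage = "raw"`.
#' @export
read_gpr <- function(path, sample_id = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  hdr_idx <- grep("^\"?Block\"?\t", lines)
  if (length(hdr_idx) == 0) {
    abort("not a GPR-dialect file: no 'Block' column-header line found.")
  }
  hdr_idx <- hdr_idx[1]
  if (is.null(sample_id)) {
    sid_line <- grep("SampleID=", lines[seq_len(hdr_idx - 1L)], value = TRUE)
    sample_id <- if (length(sid_line) > 0) {
      sub(".*SampleID=([^\"]*)\".*", "\\1", sid_line[1])
    } else {
      sub("\\.gpr$", "", basename(path), ignore.case = TRUE)
    }
  }
  cols <- gsub('^"|"$', "", strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]])
  absent <- setdiff(GPR_COLUMNS, cols)
  if (length(absent) > 0) {
    abort(sprintf("GPR file is missing mandatory column(s): %s",
                  paste(sprintf('"%s"', absent), collapse = ", ")))
  }
  body <- lines[-seq_len(hdr_idx)]
  body <- body[nzchar(body)]
  tbl <- readr::read_tsv(I(body), col_names = cols, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  num_cols <- c("Block", "Column", "Row",
                "F532 Median", "B532 Median", "F635 Median", "B635 Median")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(tbl[[cc]]))
    bad <- which(is.na(v) & !is.na(tbl[[cc]]) & nzchar(tbl[[cc]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' in column \"%s\" at line %d of %s",
                    tbl[[cc]][bad[1]], cc, hdr_idx + bad[1], path))
    }
    tbl[[cc]] <- v
  }
  spot_rep <- stats::ave(seq_len(nrow(tbl)), tbl$ID, FUN = seq_along)
  base <- tibble(
    sample_id = sample_id,
    block = as.integer(tbl$Block), row = as.integer(tbl$Row),
    column = as.integer(tbl$Column),
    spot_rep = as.integer(spot_rep), peptide_id = tbl$ID
  )
  out <- bind_rows(
    base |> mutate(channel = "IgG_532", fg = tbl$`F532 Median`, bg = tbl$`B532 Median`),
    base |> mutate(channel = "IgM_635", fg = tbl$`F635 Median`, bg = tbl$`B635 Median`)
  ) |>
    select("sample_id", "channel", "block", "row", "column", "spot_rep",
           "peptide_id", "fg", "bg")
  set_stage(out, "raw")
}

#' Write / read an intensity matrix as TSV
#'
#' The on-disk layout is wide: one row per feature (`peptide_id`, plus a
#' `channel` column when the matrix holds both channels), one column per
#' sample, missing values encoded as `NA` (empty cells are also accepted on
#' read). Values round-trip to at least 10 significant digits.
#'
#' @param matrix Long intensity tibble with columns `peptide_id`, optionally
#'   `channel`, `sample_id`, `value`.
#' @param path File path.
#' @return `write_matrix_tsv()` returns `path` invisibly; `read_matrix_tsv()`
#'   returns the long tibble (ordered by feature, then sample column order).
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(is.data.frame(matrix),
            all(c("peptide_id", "sample_id", "value") %in% names(matrix)))
  keys <- intersect(c("peptide_id", "channel"), names(matrix))
  wide <- matrix |>
    select(all_of(c(keys, "sample_id", "value"))) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
  readr::write_tsv(wide, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  wide <- readr::read_tsv(path, na = c("NA", ""), progress = FALSE,
                          show_col_types = FALSE)
  if (!"peptide_id" %in% names(wide)) {
    abort("matrix TSV must have a `peptide_id` column.")
  }
  keys <- intersect(c("peptide_id", "channel"), names(wide))
  dup <- wide |> count(across(all_of(keys))) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate peptide_id in matrix TSV: %s",
                  paste(head(dup$peptide_id, 5), collapse = ", ")))
  }
  sample_cols <- setdiff(names(wide), keys)
  for (sc in sample_cols) {
    if (!is.numeric(wide[[sc]])) {
      abort(sprintf("non-numeric values in sample column \"%s\".", sc))
    }
  }
  if (length(sample_cols) == 0 || nrow(wide) == 0) {
    out <- tibble(peptide_id = character(0), sample_id = character(0),
                  value = double(0))
    if ("channel" %in% keys) out$channel <- character(0)
    return(out[, c(keys, "sample_id", "value")])
  }
  wide |>
    tidyr::pivot_longer(all_of(sample_cols), names_to = "sample_id",
                        values_to = "value") |>
    select(all_of(keys), "sample_id", "value")
}

#' Write / read a cohort design table as TSV
#'
#' @param design Design tibble from [cohort_design()].
#' @param path File path.
#' @export
write_design_tsv <- function(design, path) {
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "class_label")
  absent <- setdiff(need, names(d))
  if (length(absent) > 0) {
    abort(sprintf("design TSV is missing column(s): %s",
                  paste(absent, collapse = ", ")))
  }
  if (!"replicate_group" %in% names(d)) d$replicate_group <- d$sample_id
  d
}
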