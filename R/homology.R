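#' Parse a BLAST traceback (btop) string
#'
#' btop encodes an alignment as a concatenation of identity-run lengths
#' (digits), mismatch pairs (query character, subject character) and gap pairs
#' (one side `-`). The parse is lossless: operations are returned in order,
#' together with the gap-free block each belongs to (blocks split at gap
#' operations).
#'
#' @param btop A single btop string.
#' @return A tibble of operations: `op` (`identity`/`mismatch`/`gap`),
#'   `length` (identity-run length, 1 otherwise), `q`, `s` (characters for
#'   mismatch/gap ops), `block` (gap-free block index).
#' @examples
#' parse_btop("5AG7")  # 5 identities, A->G mismatch, 7 identities
#' @export
parse_btop <- function(btop) {
  if (!is.character(btop) || length(btop) != 1L || is.na(btop)) {
    abort("`btop` must be a single string.")
  }
  if (!nzchar(btop)) abort("`btop` is empty: not a valid alignment encoding.")
  chars <- strsplit(btop, "", fixed = TRUE)[[1]]
  is_digit <- chars %in% as.character(0:9)
  n <- length(chars)
  ops <- vector("list", n)
  n_ops <- 0L
  block <- 1L
  i <- 1L
  while (i <= n) {
    if (is_digit[i]) {
      j <- i
      while (j < n && is_digit[j + 1L]) j <- j + 1L
      run <- as.integer(paste(chars[i:j], collapse = ""))
      if (run > 0) {
        n_ops <- n_ops + 1L
        ops[[n_ops]] <- list(op = "identity", length = run,
                             q = NA_character_, s = NA_character_, block = block)
      }
      i <- j + 1L
    } else {
      if (i + 1L > n || is_digit[i + 1L]) {
        abort(sprintf("malformed btop at position %d: unpaired character '%s'.",
                      i, chars[i]))
      }
      q <- chars[i]
      s <- chars[i + 1L]
      if (q == "-" && s == "-") {
        abort(sprintf("malformed btop at position %d: '-' paired with '-'.", i))
      }
      if (q == "-" || s == "-") {
        n_ops <- n_ops + 1L
        ops[[n_ops]] <- list(op = "gap", length = 1L, q = q, s = s, block = block)
        block <- block + 1L
      } else {
        n_ops <- n_ops + 1L
        ops[[n_ops]] <- list(op = "mismatch", length = 1L, q = q, s = s,
                             block = block)
      }
      i <- i + 2L
    }
  }
  out <- bind_rows(lapply(ops[seq_len(n_ops)], as_tibble))
  if (n_ops == 0L) {
    out <- tibble(op = character(0), length = integer(0), q = character(0),
                  s = character(0), block = integer(0))
  }
  # gap ops separate blocks but belong to neither; renumber blocks of
  # non-gap ops consecutively
  out
}

#' Most identities in any single gap-free block
#'
#' For each gap-free block of the alignment (mismatches allowed within a
#' block, gaps split blocks) the identities are summed; the maximum over
#' blocks is returned. `mode = "run"` instead returns the longest single
#' consecutive identity run (the strict-contiguity variant).
#'
#' @param btop Character vector of btop strings.
#' @param mode `"block"` (sum identities per gap-free block, the default) or
#'   `"run"` (longest consecutive identity run).
#' @return Integer vector.
#' @examples
#' max_block_identities("2AB2CD1") # 5: one gap-free block, 2 + 2 + 1
#' max_block_identities("4A-4")   # 4: the gap splits the alignment
#' @export
max_block_identities <- function(btop, mode = c("block", "run")) {
  mode <- match.arg(mode)
  vapply(btop, function(b) {
    ops <- parse_btop(b)
    ids <- ops[ops$op == "identity", ]
    if (nrow(ids) == 0) {
      return(0L)
    }
    if (mode == "run") {
      return(max(ids$length))
    }
    as.integer(max(tapply(ids$length, ids$block, sum)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Read BLASTP tabular output with btop and taxid columns
#'
#' Reads tab-separated BLAST output (outfmt 6 or 7; `#` comment lines are
#' skipped) with the package's canonical column set, the one produced by
#' [blastp_command()]:
#' `qseqid sseqid slen evalue qcovhsp btop staxids stitle`.
#'
#' @param path Tabular hits file.
#' @param col_names Column names, in file order.
#' @return A tibble of hits with those columns.
#' @export
read_blast_tab <- function(path,
                           col_names = c("qseqid", "sseqid", "slen", "evalue",
                                         "qcovhsp", "btop", "staxids",
                                         "stitle")) {
  tbl <- readr::read_tsv(path, col_names = col_names, comment = "#",
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  for (cc in intersect(c("slen", "evalue", "qcovhsp"), names(tbl))) {
    v <- suppressWarnings(as.numeric(tbl[[cc]]))
    if (anyNA(v) && !all(is.na(tbl[[cc]][is.na(v)]))) {
      abort(sprintf("non-numeric values in BLAST column '%s'.", cc))
    }
    tbl[[cc]] <- v
  }
  tbl
}

#' Filter hits on identity-block and query-coverage thresholds
#'
#' Retains a hit iff its best gap-free block carries at least
#' `min_block_identities` amino-acid identities (see
#' [max_block_identities()]) and its HSP covers at least `min_qcov` percent of
#' the query. Excluded hits, with the rule(s) they failed, are attached as
#' attribute `exclusion_report`.
#'
#' @param hits Tibble with at least `btop` and `qcovhsp` columns.
#' @param min_block_identities Minimum identities in one gap-free block.
#' @param min_qcov Minimum query coverage percent.
#' @param mode Identity counting mode, see [max_block_identities()].
#' @return The retained hits, with a `block_identities` column added.
#' @export
filter_hits <- function(hits, min_block_identities = 5, min_qcov = 34,
                        mode = c("block", "run")) {
  stopifnot(is.data.frame(hits), all(c("btop", "qcovhsp") %in% names(hits)))
  mode <- match.arg(mode)
  hits <- hits |>
    mutate(block_identities = max_block_identities(.data$btop, mode = mode))
  keep <- hits$block_identities >= min_block_identities &
    hits$qcovhsp >= min_qcov
  excl <- hits[!keep, , drop = FALSE] |>
    mutate(reason = paste0(
      ifelse(.data$block_identities < min_block_identities,
             sprintf("block_identities<%g", min_block_identities), ""),
      ifelse(.data$block_identities < min_block_identities &
               .data$qcovhsp < min_qcov, ";", ""),
      ifelse(.data$qcovhsp < min_qcov, sprintf("qcov<%g", min_qcov), "")
    ))
  out <- hits[keep, , drop = FALSE]
  attr(out, "exclusion_report") <- excl
  out
}

#' Size-adjusted homology metric
#'
#' Protein length in amino acids divided by the number of distinct peptides
#' homologous to the protein. Low values flag short proteins densely covered
#' by signature peptides.
#'
#' @param length_aa Protein length(s), amino acids.
#' @param peptide_count Distinct homologous peptides per protein.
#' @return `length_aa / peptide_count` (unrounded; display tables round to one
#'   decimal, half away from zero).
#' @examples
#' adjusted_metric(617, 10) # 61.7
#' @export
adjusted_metric <- function(length_aa, peptide_count) {
  if (any(peptide_count < 1)) abort("`peptide_count` must be >= 1.")
  if (any(length_aa < 1)) abort("`length_aa` must be >= 1.")
  length_aa / peptide_count
}

#' Aggregate filtered hits per protein
#'
#' Groups hits by subject accession, counts distinct query peptides (one HSP
#' per query/subject pair is assumed upstream, `max_hsps 1`), drops proteins
#' seen by fewer than `min_peptides` peptides and computes the size-adjusted
#' metric. Reporting thresholds used for published tables: 4 (human), 2
#' (endogenous retroviral), 3 (viral/bacterial).
#'
#' @param hits Filtered hits ([filter_hits()]).
#' @param min_peptides Minimum distinct peptides per protein.
#' @param metadata Optional tibble keyed by `accession` adding `symbol`,
#'   `description`, `taxid` and (overriding `slen`) `length`.
#' @return A tibble of homology records: `peptides`, `accession`, `symbol`,
#'   `description`, `length`, `adj` (unrounded), `adj_rounded` (one decimal,
#'   half away from zero).
#' @export
aggregate_by_protein <- function(hits, min_peptides = 1, metadata = NULL) {
  stopifnot(is.data.frame(hits), all(c("qseqid", "sseqid") %in% names(hits)))
  rec <- hits |>
    summarise(
      peptides = n_distinct(.data$qseqid),
      length = if ("slen" %in% names(hits)) first(.data$slen) else NA_real_,
      description = if ("stitle" %in% names(hits)) first(.data$stitle) else NA_character_,
      .by = "sseqid"
    ) |>
    rename(accession = "sseqid") |>
    mutate(symbol = NA_character_)
  if (!is.null(metadata)) {
    stopifnot("accession" %in% names(metadata))
    meta <- metadata |> distinct(.data$accession, .keep_all = TRUE)
    rec <- rec |> left_join(meta, by = "accession", suffix = c("", ".meta"))
    for (col in c("length", "symbol", "description")) {
      meta_col <- paste0(col, ".meta")
      if (meta_col %in% names(rec)) {
        rec[[col]] <- coalesce(rec[[meta_col]], rec[[col]])
      }
    }
    rec <- rec |> select(-ends_with(".meta"))
  }
  rec |>
    filter(.data$peptides >= min_peptides) |>
    mutate(adj = adjusted_metric(.data$length, .data$peptides),
           adj_rounded = round_half_away(.data$adj, 1)) |>
    select("peptides", "accession", "symbol", "description", "length",
           "adj", "adj_rounded")
}

#' Rank homology records by the size-adjusted metric
#'
#' Ascending in `adj` — smaller values mean more peptide hits per residue and
#' rank first — with ties broken by accession for determinism.
#'
#' @param records Output of [aggregate_by_protein()].
#' @return The records, ordered.
#' @export
rank_table <- function(records) {
  stopifnot(is.data.frame(records), all(c("adj", "accession") %in% names(records)))
  records |> arrange(.data$adj, .data$accession)
}

#' Map taxids to species/genus labels
#'
#' Joins a flat `taxid -> (species, genus)` table onto hits; a plain-file
#' replacement for a full taxonomy service.
#'
#' @param hits Hits with a `staxids` column.
#' @param taxon_map Tibble or TSV path with columns `taxid`, `species`,
#'   `genus`.
#' @return Hits with `species` and `genus` columns.
#' @export
add_taxa <- function(hits, taxon_map) {
  if (is.character(taxon_map)) {
    taxon_map <- readr::read_tsv(taxon_map, show_col_types = FALSE,
                                 progress = FALSE)
  }
  stopifnot(all(c("taxid", "species", "genus") %in% names(taxon_map)))
  hits |>
    mutate(.taxid = as.character(.data$staxids)) |>
    left_join(taxon_map |> mutate(taxid = as.character(.data$taxid)),
              by = c(".taxid" = "taxid")) |>
    select(-".taxid")
}

#' BLASTP parameter set for short random peptides
#'
#' The search is tuned for 12-mer queries: word size 2, window 15, threshold
#' 16, PAM30 matrix, gap open 9 / extend 1, E-value cutoff 1000, one HSP per
#' query/subject pair, and a minimum HSP query coverage of 34 percent. The
#' output format records btop and subject taxids for the downstream filters.
#'
#' @param evalue,word_size,window_size,threshold,matrix,gapopen,gapextend,max_hsps,qcov_hsp_perc
#'   BLASTP parameters.
#' @return A named list of class `blast_params`.
#' @export
blast_params <- function(evalue = 1000, word_size = 2, window_size = 15,
                         threshold = 16, matrix = "PAM30", gapopen = 9,
                         gapextend = 1, max_hsps = 1, qcov_hsp_perc = 34) {
  structure(
    list(evalue = evalue, word_size = word_size, window_size = window_size,
         threshold = threshold, matrix = matrix, gapopen = gapopen,
         gapextend = gapextend, max_hsps = max_hsps,
         qcov_hsp_perc = qcov_hsp_perc,
         outfmt = "6 qseqid sseqid slen evalue qcovhsp btop staxids stitle"),
    class = "blast_params"
  )
}

#' Assemble the blastp invocation
#'
#' @param query_fasta Peptide FASTA query file.
#' @param db BLAST protein database path.
#' @param out Output file for tabular hits.
#' @param params A [blast_params()].
#' @return The full command line as a single string.
#' @export
blastp_command <- function(query_fasta, db, out, params = blast_params()) {
  stopifnot(inherits(params, "blast_params"))
  paste(
    "blastp",
    "-query", shQuote(query_fasta),
    "-db", shQuote(db),
    "-out", shQuote(out),
    "-evalue", params$evalue,
    "-word_size", params$word_size,
    "-window_size", params$window_size,
    "-threshold", params$threshold,
    "-matrix", params$matrix,
    "-gapopen", params$gapopen,
    "-gapextend", params$gapextend,
    "-max_hsps", params$max_hsps,
    "-qcov_hsp_perc", params$qcov_hsp_perc,
    "-outfmt", shQuote(params$outfmt)
  )
}

#' Run blastp (external tool) and read its hits
#'
#' Requires the NCBI BLAST+ `blastp` binary on the PATH; without it the
#' pipeline consumes pre-computed tabular files via [read_blast_tab()]
#' instead, and this function raises an explicit error saying so. The
#' invocation is logged via `message()` before it runs.
#'
#' @inheritParams blastp_command
#' @return The hits tibble ([read_blast_tab()]), with the command attached as
#'   attribute `command`.
#' @export
run_blastp <- function(query_fasta, db, out = tempfile(fileext = ".tsv"),
                       params = blast_params()) {
  if (!nzchar(Sys.which("blastp"))) {
    abort(paste(
      "external tool unavailable: `blastp` not found on PATH.",
      "Run BLAST elsewhere and load its tabular output with read_blast_tab()."
    ), class = "immunosig_external_tool")
  }
  cmd <- blastp_command(query_fasta, db, out, params)
  message("running: ", cmd)
  status <- system(cmd)
  if (status != 0) abort(sprintf("blastp exited with status %d.", status))
  hits <- read_blast_tab(out)
  attr(hits, "command") <- cmd
  hits
}
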