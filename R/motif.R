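# Extract the sequence vector (and ids) from a character vector or a tibble
# with a `sequence` column.
peptide_sequences <- function(peptides) {
  if (is.character(peptides)) {
    ids <- names(peptides) %||% sprintf("pep_%d", seq_along(peptides))
    return(list(id = ids, seq = unname(peptides)))
  }
  stopifnot(is.data.frame(peptides), "sequence" %in% names(peptides))
  ids <- if ("peptide_id" %in% names(peptides)) {
    peptides$peptide_id
  } else {
    sprintf("pep_%d", seq_len(nrow(peptides)))
  }
  list(id = ids, seq = peptides$sequence)
}

# minimum Hamming distance of `motif` over all offsets of each sequence
min_hamming <- function(seqs, motif) {
  k <- nchar(motif)
  mchars <- strsplit(motif, "", fixed = TRUE)[[1]]
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) {
      return(k)
    }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    best <- k
    for (off in 0:(n - k)) {
      d <- sum(chars[(off + 1):(off + k)] != mchars)
      if (d < best) best <- d
    }
    best
  }, integer(1), USE.NAMES = FALSE)
}

#' Count peptides carrying a motif
#'
#' A peptide carries the motif when some ungapped offset aligns the motif with
#' at most `max_mismatch` Hamming mismatches (no indels).
#'
#' @param peptides Character vector of sequences, or a tibble with a
#'   `sequence` (and optionally `peptide_id`) column.
#' @param motif Motif string.
#' @param max_mismatch Mismatches tolerated.
#' @return A one-row tibble: `motif`, `k`, `max_mismatch`, `support`
#'   (number of carriers), `n_scanned`, and `carrier_ids` (list column).
#' @examples
#' count_motif_carriers(c("AAGVALSGAAAA", "AAAAAAAAAAAA"), "GVALSG")
#' @export
count_motif_carriers <- function(peptides, motif, max_mismatch = 0) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif)) {
    abort("`motif` must be a single nonempty string.")
  }
  p <- peptide_sequences(peptides)
  if (any(nchar(p$seq) < nchar(motif))) {
    abort("`motif` is longer than some peptides.")
  }
  hits <- min_hamming(p$seq, motif) <= max_mismatch
  tibble(
    motif = motif, k = nchar(motif), max_mismatch = as.integer(max_mismatch),
    support = sum(hits), n_scanned = length(p$seq),
    carrier_ids = list(p$id[hits])
  )
}

# support of every candidate k-mer at <= max_mismatch, computed by hashed
# lookup of position-masked windows (exact for max_mismatch <= 1; a direct
# scan handles larger tolerances).
kmer_support <- function(seqs, k, max_mismatch) {
  wins <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) {
      return(character(0))
    }
    substring(s, 1:(n - k + 1), k:n)
  })
  pep_of_win <- rep(seq_along(seqs), lengths(wins))
  wins <- unlist(wins, use.names = FALSE)
  cand <- unique(wins)
  if (length(cand) == 0) {
    return(tibble(motif = character(0), support = integer(0)))
  }
  if (max_mismatch == 0) {
    grp <- split(pep_of_win, wins)
    support <- vapply(grp, function(p) length(unique(p)), integer(1))
    return(tibble(motif = names(support), support = unname(support)))
  }
  if (max_mismatch == 1) {
    # windows within Hamming distance 1 share a masked variant (one position
    # blanked out); union over mask positions, counting distinct peptides
    mask_at <- function(x, j) {
      substr(x, j, j) <- "."
      x
    }
    carriers <- vector("list", length(cand))
    names(carriers) <- cand
    for (j in seq_len(k)) {
      wm <- mask_at(wins, j)
      cm <- mask_at(cand, j)
      grp <- split(pep_of_win, wm)
      idx <- match(cm, names(grp))
      hit <- !is.na(idx)
      if (any(hit)) {
        carriers[hit] <- Map(c, carriers[hit], grp[idx[hit]])
      }
    }
    support <- vapply(carriers, function(p) length(unique(p)), integer(1))
    return(tibble(motif = cand, support = unname(support)))
  }
  support <- vapply(cand, function(m) {
    sum(vapply(split(wins, pep_of_win), function(w) {
      any(colSums(matrix(unlist(strsplit(w, "")), nrow = k) !=
                    strsplit(m, "")[[1]]) <= max_mismatch)
    }, logical(1)))
  }, integer(1))
  tibble(motif = cand, support = unname(support))
}

# Two motifs are shifted variants of one signal when (a) one is a substring
# of the other, (b) some ungapped offset aligns them with >= min(k) - 1
# matching positions, or (c) a prefix of one equals a suffix of the other
# over at least `min_overlap` residues (a perfect shift, the relation between
# frame-shifted windows of one underlying consensus).
motifs_mergeable <- function(a, b, min_overlap = 3L) {
  if (grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE)) {
    return(TRUE)
  }
  ka <- nchar(a)
  kb <- nchar(b)
  need <- min(ka, kb) - 1L
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  for (off in (-kb + 1):(ka - 1)) {
    ia <- max(1, 1 + off):min(ka, kb + off)
    ib <- ia - off
    n_match <- sum(ac[ia] == bc[ib])
    if (length(ia) >= need && n_match >= need) {
      return(TRUE)
    }
    # perfect shift: the overlapping window agrees everywhere and reaches an
    # end of both motifs (always true for any offset), with enough overlap
    if (length(ia) >= min_overlap && n_match == length(ia)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Discover consensus motifs by exhaustive k-mer counting
#'
#' Enumerates every k-mer occurring in the peptides for each window size in
#' `k_range`, counts its carriers at up to `max_mismatch` Hamming mismatches,
#' keeps those with support at least `min_support`, orders them by support
#' (then longer k, then alphabetically) and merges overlapping/shifted
#' variants into the highest-ranked representative. This replaces a
#' progressive multiple alignment with a deterministic, exhaustive search —
#' feasible because signature peptide sets are small (hundreds of 12-mers).
#'
#' @param peptides Sequences (character vector or tibble with `sequence`).
#' @param k_range Window sizes to scan.
#' @param max_mismatch Mismatches tolerated when counting carriers.
#' @param min_support Minimum carriers for a motif to be reported.
#' @return A tibble of motif reports: `motif`, `k`, `max_mismatch`, `support`,
#'   `n_scanned`, `merged_variants` (list column of absorbed motifs), ordered
#'   by rank.
#' @export
find_consensus_motifs <- function(peptides, k_range = 4:8, max_mismatch = 1,
                                  min_support = 2) {
  p <- peptide_sequences(peptides)
  if (length(p$seq) == 0) abort("`peptides` is empty.")
  cands <- bind_rows(lapply(k_range, function(k) {
    kmer_support(p$seq, k, max_mismatch) |> mutate(k = as.integer(k))
  })) |>
    filter(.data$support >= min_support) |>
    arrange(desc(.data$support), desc(.data$k), .data$motif)
  if (nrow(cands) == 0) {
    return(tibble(motif = character(0), k = integer(0),
                  max_mismatch = integer(0), support = integer(0),
                  n_scanned = integer(0), merged_variants = list()))
  }
  kept <- integer(0)
  absorbed <- list()
  for (i in seq_len(nrow(cands))) {
    merged <- FALSE
    for (j in seq_along(kept)) {
      if (motifs_mergeable(cands$motif[kept[j]], cands$motif[i])) {
        absorbed[[j]] <- c(absorbed[[j]], cands$motif[i])
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      kept <- c(kept, i)
      absorbed[[length(kept)]] <- character(0)
    }
  }
  cands[kept, ] |>
    mutate(max_mismatch = as.integer(max_mismatch),
           n_scanned = length(p$seq),
           merged_variants = absorbed) |>
    select("motif", "k", "max_mismatch", "support", "n_scanned",
           "merged_variants")
}

#' Write peptides to FASTA
#'
#' Plain-text FASTA export of a peptide set, e.g. for external alignment or as
#' a BLAST query.
#'
#' @param peptides Tibble with `peptide_id` and `sequence`, or a named
#'   character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(peptides, path) {
  p <- peptide_sequences(peptides)
  writeLines(paste0(">", p$id, "\n", p$seq), path)
  invisible(path)
}

#' Read a peptide FASTA file
#'
#' @param path FASTA file.
#' @return Tibble with `peptide_id` and `sequence`.
#' @export
read_peptide_fasta <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("no FASTA headers found.")
  id <- sub("^>(\\S+).*", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  tibble(peptide_id = id, sequence = unname(seqs))
}
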