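# Shared small fixtures, built in code.

# quick synthetic dataset: small library, planted carriers, scans simulated
tiny_dataset <- function(n_peptides = 300, n_cases = 10, n_controls = 10,
                         n_carriers = 8, seed = 42, ...) {
  simulate_ims_dataset(
    n_peptides = n_peptides, n_cases = n_cases, n_controls = n_controls,
    n_carriers = n_carriers, seed = seed, ...
  )
}

quick_config <- function(n_trees = 150, seed = 7) {
  rf_config(n_trees = n_trees, seed = seed)
}

# long intensity tibble from an explicit peptides x samples matrix
matrix_to_long <- function(m, channel = NULL) {
  df <- tibble::as_tibble(m, rownames = "peptide_id") |>
    tidyr::pivot_longer(-peptide_id, names_to = "sample_id",
                        values_to = "value")
  if (!is.null(channel)) df$channel <- channel
  df
}

# brute-force oracle for motif carrier counting: nested loops, no shared code
# with the implementation
brute_force_carriers <- function(seqs, motif, max_mismatch) {
  k <- nchar(motif)
  sapply(seqs, function(s) {
    if (nchar(s) < k) return(FALSE)
    for (off in 0:(nchar(s) - k)) {
      mm <- 0
      for (j in 1:k) {
        if (substr(s, off + j, off + j) != substr(motif, j, j)) mm <- mm + 1
      }
      if (mm <= max_mismatch) return(TRUE)
    }
    FALSE
  }, USE.NAMES = FALSE)
}

# random alignment generator for btop fuzzing: emits the btop string plus the
# explicit per-column operation list it encodes
random_alignment <- function(n_ops = 8) {
  alpha <- setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
  ops <- character(0)
  btop <- ""
  last_digit <- FALSE
  for (i in seq_len(sample(2:n_ops, 1))) {
    kind <- sample(c("id", "mm", "gap"), 1, prob = c(0.5, 0.3, 0.2))
    if (kind == "id") {
      run <- sample(1:9, 1)
      # merge consecutive runs in the expected op list, but keep the btop
      # string as two adjacent numbers only if not ambiguous (digits would
      # concatenate); force a separator op instead
      if (last_digit) {
        q <- sample(alpha, 1); s <- sample(setdiff(alpha, q), 1)
        ops <- c(ops, paste0("M", q, s))
        btop <- paste0(btop, q, s)
      }
      ops <- c(ops, rep("I", run))
      btop <- paste0(btop, run)
      last_digit <- TRUE
    } else if (kind == "mm") {
      q <- sample(alpha, 1); s <- sample(setdiff(alpha, q), 1)
      ops <- c(ops, paste0("M", q, s))
      btop <- paste0(btop, q, s)
      last_digit <- FALSE
    } else {
      if (runif(1) < 0.5) {
        s <- sample(alpha, 1)
        ops <- c(ops, "G")
        btop <- paste0(btop, "-", s)
      } else {
        q <- sample(alpha, 1)
        ops <- c(ops, "G")
        btop <- paste0(btop, q, "-")
      }
      last_digit <- FALSE
    }
  }
  list(btop = btop, ops = ops)
}

# independent computation of the best gap-free block identity count from the
# explicit op list
oracle_max_block <- function(ops) {
  best <- 0L
  cur <- 0L
  for (op in ops) {
    if (op == "I") {
      cur <- cur + 1L
    } else if (op == "G") {
      best <- max(best, cur)
      cur <- 0L
    }
    # mismatches neither add identities nor close the block
  }
  max(best, cur)
}

# fully positive background-corrected values (no dropout), so every array is
# complete after the log step
positive_corrected <- function(n_pep = 200, n_arr = 8, n_rep = 2, seed = 1) {
  set.seed(seed)
  grid <- tidyr::crossing(
    sample_id = sprintf("s%02d", seq_len(n_arr)),
    peptide_id = sprintf("p%03d", seq_len(n_pep)),
    spot_rep = seq_len(n_rep),
    channel = c("IgG_532", "IgM_635")
  )
  grid$value <- 2^rnorm(nrow(grid), 10, 1.5)
  grid
}
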