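test_that("btop parsing matches hand-derived op lists", {
  p <- parse_btop("12")
  expect_equal(nrow(p), 1)
  expect_equal(p$op, "identity")
  expect_equal(p$length, 12L)

  p <- parse_btop("5AG7")
  expect_equal(p$op, c("identity", "mismatch", "identity"))
  expect_equal(p$length[c(1, 3)], c(5L, 7L))
  expect_equal(p$q[2], "A")
  expect_equal(p$s[2], "G")
  expect_equal(unique(p$block), 1L)

  p <- parse_btop("4A-4")
  expect_equal(p$op, c("identity", "gap", "identity"))
  expect_equal(p$block, c(1L, 1L, 2L))

  # gaps on the query side too, and multi-digit runs
  p <- parse_btop("10-G3")
  expect_equal(p$length[1], 10L)
  expect_equal(p$op[2], "gap")
  expect_equal(p$q[2], "-")
})

test_that("malformed btop strings raise positioned parse errors", {
  expect_error(parse_btop("5A"), "position 2")
  expect_error(parse_btop("3--2"), "'-' paired with '-'")
  expect_error(parse_btop(""), "empty")
  expect_error(parse_btop(c("1", "2")), "single string")
})

test_that("max_block_identities sums identities within gap-free blocks", {
  expect_equal(max_block_identities("2AB2CD1"), 5L)
  expect_equal(max_block_identities("4A-4"), 4L)
  expect_equal(max_block_identities("12"), 12L)
  expect_equal(max_block_identities(c("12", "4A-4")), c(12L, 4L))
  # strict-consecutive-run mode
  expect_equal(max_block_identities("2AB2CD1", mode = "run"), 2L)
  expect_equal(max_block_identities("12", mode = "run"), 12L)
})

test_that("btop block counting agrees with a brute-force reconstruction", {
  set.seed(97)
  for (i in 1:300) {
    al <- random_alignment()
    expect_equal(max_block_identities(al$btop), oracle_max_block(al$ops),
                 info = al$btop)
  }
})

toy_hits <- function() {
  tibble::tibble(
    qseqid = c("q1", "q1", "q2", "q3", "q3", "q4"),
    sseqid = c("protA", "protB", "protA", "protA", "protC", "protC"),
    slen = c(200, 400, 200, 200, 90, 90),
    evalue = 1,
    qcovhsp = c(50, 42, 100, 33, 40, 80),
    btop = c("12", "5AG7", "2AB2CD1", "6", "4A-4", "3AB3"),
    staxids = c("9606", "9606", "9606", "9606", "11676", "11676"),
    stitle = c("protein A", "protein B", "protein A", "protein A",
               "protein C", "protein C")
  )
}

test_that("hit filtering applies both thresholds and logs exclusions", {
  hits <- toy_hits()
  kept <- filter_hits(hits)
  # q3/protA fails qcov (33 < 34); q3/protC fails identities (4 < 5)
  expect_equal(nrow(kept), 4)
  excl <- attr(kept, "exclusion_report")
  expect_equal(nrow(excl), 2)
  expect_true(any(grepl("qcov", excl$reason)))
  expect_true(any(grepl("block_identities", excl$reason)))

  single <- tibble::tibble(qseqid = "q", sseqid = "s", slen = 10,
                           qcovhsp = 50, btop = "4A-4", stitle = "x")
  expect_equal(nrow(filter_hits(single)), 0)
  single$qcovhsp <- 33
  single$btop <- "5"
  expect_equal(nrow(filter_hits(single)), 0)
  single$qcovhsp <- 42
  single$btop <- "5AG7"
  expect_equal(nrow(filter_hits(single)), 1)
})

test_that("filtering is monotone in both thresholds", {
  set.seed(13)
  hits <- tibble::tibble(
    qseqid = sprintf("q%d", 1:80),
    sseqid = sprintf("s%d", sample(1:20, 80, TRUE)),
    slen = sample(50:900, 80, TRUE),
    qcovhsp = sample(20:100, 80, TRUE),
    btop = vapply(1:80, function(i) random_alignment()$btop, ""),
    stitle = "t"
  )
  prev <- nrow(filter_hits(hits, 1, 0))
  for (th in list(c(3, 20), c(5, 34), c(7, 50), c(9, 80))) {
    cur <- nrow(filter_hits(hits, th[1], th[2]))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("per-protein aggregation counts distinct peptides and applies thresholds", {
  hits <- filter_hits(toy_hits())
  rec <- aggregate_by_protein(hits, min_peptides = 1)
  protA <- rec[rec$accession == "protA", ]
  expect_equal(protA$peptides, 2) # q1 and q2, distinct queries
  expect_equal(protA$adj, 100)
  expect_equal(nrow(aggregate_by_protein(hits, min_peptides = 2)), 1)
  # metadata join overrides length and adds symbols
  meta <- tibble::tibble(accession = "protA", symbol = "PRTA",
                         description = "protein A full", length = 150L)
  rec2 <- aggregate_by_protein(hits, min_peptides = 2, metadata = meta)
  expect_equal(rec2$symbol, "PRTA")
  expect_equal(rec2$adj, 75)
})

test_that("the size-adjusted metric reproduces published table rows", {
  expect_equal(round_half_away(adjusted_metric(617, 10), 1), 61.7)
  expect_equal(round_half_away(adjusted_metric(588, 3), 1), 196)
  expect_equal(adjusted_metric(423, 1), 423)
  expect_error(adjusted_metric(100, 0), "peptide_count")
})

test_that("ranking ascends in adj with deterministic tie-breaks", {
  rec <- tibble::tibble(
    accession = c("x", "b", "a", "z"),
    adj = c(58.8, 40.8, 61.7, 40.8)
  )
  ranked <- rank_table(rec)
  expect_equal(ranked$adj, c(40.8, 40.8, 58.8, 61.7))
  expect_equal(ranked$accession[1:2], c("b", "z"))
  expect_equal(rank_table(rec[1, ])$accession, "x")
})

test_that("taxid mapping joins a flat lineage table", {
  hits <- toy_hits()
  taxa <- tibble::tibble(taxid = c("9606", "11676"),
                         species = c("Homo sapiens", "HIV-1"),
                         genus = c("Homo", "Lentivirus"))
  out <- add_taxa(hits, taxa)
  expect_equal(out$species[out$staxids == "9606"][1], "Homo sapiens")
  expect_equal(out$genus[out$staxids == "11676"][1], "Lentivirus")
})

test_that("the blastp invocation serialises the short-peptide parameter set", {
  cmd <- blastp_command("q.fasta", "db/human", "hits.tsv")
  expect_match(cmd, "-matrix PAM30 -gapopen 9 -gapextend 1", fixed = TRUE)
  expect_match(cmd, "-evalue 1000", fixed = TRUE)
  expect_match(cmd, "-word_size 2", fixed = TRUE)
  expect_match(cmd, "-window_size 15", fixed = TRUE)
  expect_match(cmd, "-threshold 16", fixed = TRUE)
  expect_match(cmd, "-max_hsps 1", fixed = TRUE)
  expect_match(cmd, "-qcov_hsp_perc 34", fixed = TRUE)
  expect_match(cmd, "btop", fixed = TRUE)
  expect_match(cmd, "staxids", fixed = TRUE)
})

test_that("run_blastp errors cleanly when the binary is absent", {
  withr::local_envvar(PATH = tempdir())
  expect_error(run_blastp("q.fasta", "db"), class = "immunosig_external_tool")
})

test_that("a self-alignment through blastp yields full coverage and a pure-identity btop", {
  skip_if(!nzchar(Sys.which("blastp")) || !nzchar(Sys.which("makeblastdb")),
          "BLAST+ not on PATH")
  dir <- withr::local_tempdir()
  db_fa <- file.path(dir, "db.fasta")
  writeLines(c(">target", "GVALSGKLMNPQ", ">decoy", "WWWWYYYYHHHH"), db_fa)
  system2("makeblastdb",
          c("-in", db_fa, "-dbtype", "prot", "-out", file.path(dir, "db")),
          stdout = FALSE, stderr = FALSE)
  q_fa <- file.path(dir, "q.fasta")
  writeLines(c(">query", "GVALSGKLMNPQ"), q_fa)
  hits <- suppressMessages(
    run_blastp(q_fa, file.path(dir, "db"), file.path(dir, "hits.tsv"))
  )
  top <- hits[hits$sseqid == "target", ][1, ]
  expect_equal(top$qcovhsp, 100)
  expect_equal(top$btop, "12")
  expect_equal(max_block_identities(top$btop), 12L)
})
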