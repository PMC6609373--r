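mk_mirna <- function(seq, id = "miR-x") list(id = id, sequence = seq)
mk_tx <- function(seq, topology = "linear", id = "tx") {
  list(id = id, sequence = seq, topology = topology)
}

## let-7-like miRNA used throughout; its 8mer site is revcomp(pos 2-8) + A
mir <- "TGAGGTAGTAGGTTGTATAGTT"              # seed GAGGTAG

test_that("no match is possible when the seed complement is absent", {
  t_allA <- mk_tx(strrep("A", 60))
  res <- find_seed_sites(t_allA, mk_mirna(mir))
  expect_equal(nrow(res), 0)
})

test_that("a planted 8mer is found once, at its offset, with the right type", {
  core8 <- paste0(oracle_revcomp(substr(mir, 2, 8)), "A")
  bg <- strrep("C", 40)
  seq <- paste0(bg, core8, strrep("C", 30))   # 8mer at 0-based offset 40
  res <- find_seed_sites(mk_tx(seq), mk_mirna(mir))
  expect_equal(nrow(res), 1)
  expect_equal(res$start, 40L)
  expect_equal(res$site_type, "8mer")

  # same core without the flanking A is a 7mer-m8; without m8 pairing, 7mer-A1
  seq_m8 <- paste0(bg, oracle_revcomp(substr(mir, 2, 8)), "C", strrep("C", 29))
  res_m8 <- find_seed_sites(mk_tx(seq_m8), mk_mirna(mir))
  expect_equal(res_m8$site_type, "7mer-m8")
  expect_equal(res_m8$start, 40L)
  # preceding base must differ from the m8 complement to stay a 7mer-A1
  seq_a1 <- paste0(bg, "T", oracle_revcomp(substr(mir, 2, 7)), "A",
                   strrep("C", 29))
  res_a1 <- find_seed_sites(mk_tx(seq_a1), mk_mirna(mir))
  expect_equal(res_a1$site_type, "7mer-A1")
  expect_equal(res_a1$start, 41L)
})

test_that("junction-spanning sites exist only under circular topology", {
  core8 <- paste0(oracle_revcomp(substr(mir, 2, 8)), "A")
  L <- 50
  start <- L - 3                               # 3 bases before the junction
  head_len <- 8 - 3                            # 5 bases wrap to the front
  seq <- paste0(substr(core8, 4, 8), strrep("C", L - 8), substr(core8, 1, 3))
  circ <- find_seed_sites(mk_tx(seq, "circular"), mk_mirna(mir))
  expect_equal(circ$start, start)
  expect_equal(circ$site_type, "8mer")
  lin <- find_seed_sites(mk_tx(seq, "linear"), mk_mirna(mir))
  expect_equal(nrow(lin), 0)
  expect_equal(head_len, 5)                    # geometry sanity
})

test_that("find_seed_sites equals the brute-force window oracle on random pairs", {
  set.seed(99)
  for (i in 1:100) {
    L <- sample(50:500, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    mseq <- paste(sample(c("A", "C", "G", "T"), sample(18:25, 1), TRUE),
                  collapse = "")
    circular <- i %% 2 == 0
    got <- find_seed_sites(mk_tx(seq, if (circular) "circular" else "linear"),
                           mk_mirna(mseq))
    want <- oracle_seed_sites(seq, mseq, circular)
    expect_equal(got$start, want$start, info = paste("pair", i))
    expect_equal(got$site_type, want$site_type, info = paste("pair", i))
  }
})

test_that("circular scanning finds a superset of linear sites", {
  set.seed(7)
  for (i in 1:30) {
    seq <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    mseq <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
    lin <- find_seed_sites(mk_tx(seq, "linear"), mk_mirna(mseq))
    circ <- find_seed_sites(mk_tx(seq, "circular"), mk_mirna(mseq))
    expect_true(all(lin$start %in% circ$start))
  }
})

test_that("build_target_map is complete, order-invariant and duplicate-safe", {
  set.seed(5)
  txs <- transcript_set(paste0("t", 1:3),
                        replicate(3, paste(sample(c("A", "C", "G", "T"), 80,
                                                  TRUE), collapse = "")))
  mirs <- mirna_set(paste0("m", 1:2),
                    replicate(2, paste(sample(c("A", "C", "G", "T"), 22,
                                              TRUE), collapse = "")))
  map <- build_target_map(txs, mirs)
  per_pair <- sum(vapply(1:3, function(i) sum(vapply(1:2, function(j)
    nrow(find_seed_sites(txs[i, ], mirs[j, ])), numeric(1))), numeric(1)))
  expect_equal(nrow(map), per_pair)

  map2 <- build_target_map(txs[3:1, ], mirs[2:1, ])
  expect_equal(as.data.frame(map2), as.data.frame(map))

  dup <- txs; dup$id <- c("t1", "t1", "t3")
  expect_error(build_target_map(dup, mirs), "duplicate transcript")
  empty_map <- build_target_map(txs, mirs[0, ])
  expect_equal(nrow(empty_map), 0)
})

test_that("site tables round-trip through TSV with validation", {
  set.seed(6)
  txs <- transcript_set("t1",
                        paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                              collapse = ""))
  mirs <- mirna_set("m1", "TGAGGTAGTAGGTTGTATAGTT")
  map <- build_target_map(txs, mirs)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(map, tf)
  back <- load_site_table(tf, attr(map, "transcript_lengths"))
  expect_equal(as.data.frame(back), as.data.frame(map))

  writeLines("mirna\ttranscript\tstart\tsite_type", tf)
  expect_equal(nrow(load_site_table(tf)), 0)
  writeLines(c("mirna\ttranscript\tstart\tsite_type",
               "m1\tt1\t10\t9mer"), tf)
  expect_error(load_site_table(tf), "unknown site_type")
  writeLines(c("mirna\ttranscript\tstart\tsite_type",
               "m1\tt1\t500\t8mer"), tf)
  expect_error(load_site_table(tf, c(t1 = 200)), "beyond transcript length")
})

test_that("record constructors validate their domain invariants", {
  expect_error(mirna_set("m", "ACGT"), "18-25")
  expect_error(transcript_set("t", "ACGTACG"), "shorter than 8")
  expect_error(transcript_set(c("t", "t"), c(strrep("A", 10), strrep("C", 10))),
               "duplicate")
  # U/T and case normalization at parse time
  m <- mirna_set("m", "ugagguaguagguuguauaguu")
  expect_equal(m$sequence, "TGAGGTAGTAGGTTGTATAGTT")
})

test_that("FASTA round-trips preserve ids, topology and class tags", {
  set.seed(8)
  txs <- transcript_set(c("tx1", "cx1"),
                        replicate(2, paste(sample(c("A", "C", "G", "T"), 60,
                                                  TRUE), collapse = "")),
                        topology = c("linear", "circular"),
                        rna_class = c("lncrna", "circrna"))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_transcript_fasta(txs, fa)
  back <- read_transcript_fasta(fa)
  expect_equal(as.data.frame(back), as.data.frame(txs))

  mirs <- mirna_set("m1", "TGAGGTAGTAGGTTGTATAGTT")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_mirna_fasta(mirs, fa2)
  expect_equal(as.data.frame(read_mirna_fasta(fa2)), as.data.frame(mirs))
})
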