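small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_mrna = 30, n_lncrna = 12, n_circrna = 10, n_mirna = 4,
         n_planted_triples = 6, utr_len = 120, lnc_len = 150,
         circ_len = 140, n_gene_sets = 4, set_size = 5, module_size = 4),
    list(...))
  do.call(sim_config, args)
}

test_that("configuration invariants are enforced with the field named", {
  expect_error(sim_config(n_per_group = 0), "n_per_group")
  expect_error(sim_config(frac_de_contrast1 = 1.2), "frac_de_contrast1")
  expect_error(sim_config(effect_log2fc = -1), "effect_log2fc")
  expect_error(sim_config(effect_log2fc = 0.3), "effect_log2fc")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(utr_len = 0.5), "utr_len")
})

test_that("expression generation is deterministic and honors empty planting", {
  cfg <- small_cfg()
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr$mrna$values, b$expr$mrna$values)
  expect_identical(a$truth$de_status, b$truth$de_status)

  none <- small_cfg(frac_de_contrast1 = 0, n_planted_triples = 0)
  t0 <- simulate_expression(none)$truth
  expect_equal(sum(t0$de_status$status_contrast1 != "not_de"), 0)
  expect_equal(nrow(t0$planted_triples), 0)
  expect_true(all(a$expr$mrna$values > 0))
})

test_that("planted shifts realize the configured effect size", {
  cfg <- sim_config(n_mrna = 1500, n_lncrna = 1, n_circrna = 1,
                    frac_de_contrast1 = 0.4, effect_log2fc = 1.5,
                    noise_sd = 0.4, n_planted_triples = 0, rng_seed = 3)
  sim <- simulate_expression(cfg)
  de <- sim$truth$de_status
  up <- de$feature[de$rna_class == "mrna" & de$status_contrast1 == "up"]
  expect_gte(length(up), 200)
  lg <- log2(sim$expr$mrna$values)
  g <- sim$expr$mrna$groups
  diff1 <- rowMeans(lg[up, g == "MCD"]) - rowMeans(lg[up, g == "normal"])
  expect_lt(abs(mean(diff1) - 1.5), 0.15)
  # reversal features carry equal-magnitude opposite shifts in contrast 2
  rev_up <- de$feature[de$rna_class == "mrna" & de$pattern %in% "reversed-up"]
  diff2 <- rowMeans(lg[rev_up, g == "QG"]) - rowMeans(lg[rev_up, g == "MCD"])
  expect_lt(abs(mean(diff2) + 1.5), 0.2)
})

test_that("sequence planting is exclusive: a full scan finds exactly the planted sites", {
  cfg <- small_cfg()
  sim <- simulate_expression(cfg)
  seqs <- simulate_sequences(cfg, sim$truth)
  map <- build_target_map(seqs$transcripts, seqs$mirnas)
  got <- paste(map$mirna, map$transcript, map$start, map$site_type)
  want <- with(seqs$truth$planted_sites,
               paste(mirna, transcript, start, site_type))
  expect_setequal(got, want)
  # every planted triple's sponge and mRNA carry a site for its miRNA
  tri <- seqs$truth$planted_triples
  for (i in seq_len(nrow(tri))) {
    expect_true(any(map$mirna == tri$mirna[i] &
                    map$transcript == tri$sponge[i]))
    expect_true(any(map$mirna == tri$mirna[i] &
                    map$transcript == tri$mrna[i]))
  }
})

test_that("zero planted triples means zero canonical sites anywhere", {
  cfg <- small_cfg(n_planted_triples = 0)
  sim <- simulate_expression(cfg)
  seqs <- simulate_sequences(cfg, sim$truth)
  map <- build_target_map(seqs$transcripts, seqs$mirnas)
  expect_equal(nrow(map), 0)
  expect_error(simulate_sequences(small_cfg(utr_len = 6), sim$truth),
               "configuration error")
})

test_that("junction-spanning circRNA sites vanish under forced linear scanning", {
  cfg <- small_cfg(circ_junction_frac = 1, n_planted_triples = 8,
                   rng_seed = 21)
  sim <- simulate_expression(cfg)
  seqs <- simulate_sequences(cfg, sim$truth)
  sites <- seqs$truth$planted_sites
  tx <- seqs$transcripts
  circ_ids <- tx$id[tx$topology == "circular"]
  junc <- sites[sites$transcript %in% circ_ids, , drop = FALSE]
  junc <- junc[junc$start > nchar(tx$sequence[match(junc$transcript, tx$id)]) - 8, ,
               drop = FALSE]
  expect_gt(nrow(junc), 0)
  for (i in seq_len(nrow(junc))) {
    row <- tx[tx$id == junc$transcript[i], ]
    mir <- seqs$mirnas[seqs$mirnas$id == junc$mirna[i], ]
    as_circ <- find_seed_sites(row, mir)
    expect_true(junc$start[i] %in% as_circ$start)
    row$topology <- "linear"
    as_lin <- find_seed_sites(row, mir)
    expect_false(junc$start[i] %in% as_lin$start)
  }
})

test_that("gene-set fixtures: enrichment plant, byte determinism, size guard", {
  cfg <- small_cfg()
  sim <- simulate_expression(cfg)
  gs <- simulate_gene_sets(cfg, sim$truth)
  expect_equal(gs$truth$enriched_set_id, names(gs$sets)[1])
  rev_mrna <- with(sim$truth$de_status,
                   feature[rna_class == "mrna" & !is.na(pattern)])
  overlap <- length(intersect(gs$sets[[1]], rev_mrna)) / cfg$set_size
  expect_equal(overlap, gs$truth$enriched_overlap)
  expect_error(simulate_gene_sets(small_cfg(set_size = 31), sim$truth),
               "set_size")

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(simulate_gene_sets(cfg, sim$truth)$sets, f1)
  write_gmt(simulate_gene_sets(cfg, sim$truth)$sets, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(read_gmt(f1), gs$sets)
})

test_that("interaction fixtures: planted clique, p=0 background, determinism", {
  cfg <- small_cfg()
  sim <- simulate_expression(cfg)
  ints <- simulate_interactions(cfg, sim$truth)
  ints2 <- simulate_interactions(cfg, sim$truth)
  expect_identical(ints$edges, ints2$edges)
  expect_equal(length(ints$truth$module_members), cfg$module_size)

  bare <- simulate_interactions(cfg, sim$truth, background_p = 0)
  members <- bare$truth$module_members
  expect_equal(nrow(bare$edges), choose(cfg$module_size, 2))
  expect_setequal(unique(c(bare$edges$node_a, bare$edges$node_b)), members)
  expect_error(simulate_interactions(small_cfg(module_size = 2), sim$truth),
               "module_size")
})
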