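#' Configuration for the synthetic three-group ceRNA study
#'
#' Defines the simulated study conditions: three groups (control, disease,
#' treatment) of `n_per_group` samples each; a fraction of features planted
#' as differentially expressed in the disease contrast, of which a sub-fraction
#' is reversed by treatment (equal-magnitude opposite shift in the second
#' contrast); transcript and miRNA sequences with planted canonical seed-match
#' sites shared between sponges and mRNAs; one enriched gene set; and one
#' dense interaction module in a sparse background.
#'
#' Baseline log2 intensities are drawn from N(8, 1.5) per feature and sample
#' noise is additive in log2 space, keeping linear intensities positive and
#' microarray-like in range.
#'
#' @param n_per_group samples per group (default 12).
#' @param n_mrna,n_lncrna,n_circrna feature counts per RNA class.
#' @param frac_de_contrast1 fraction of features planted DE in the disease
#'   contrast.
#' @param frac_reversed fraction of contrast-1 DE features also planted DE in
#'   contrast 2 with opposite sign.
#' @param effect_log2fc mean planted |log2 fold change| (must be >=
#'   log2(1.5)); default 1.5.
#' @param noise_sd sd of log2 intensity noise; default 0.4.
#' @param utr_len,lnc_len,circ_len sequence lengths (nt).
#' @param n_mirna number of miRNAs.
#' @param n_planted_triples number of planted sponge-miRNA-mRNA triples.
#' @param n_gene_sets,set_size enrichment fixture sizes.
#' @param overlap_frac fraction of the enriched set drawn from planted
#'   reversal mRNAs.
#' @param module_size planted clique size in the interaction fixture.
#' @param circ_junction_frac fraction of planted circRNA sites placed across
#'   the back-splice junction.
#' @param rng_seed integer seed (Mersenne-Twister).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 12,
                       n_mrna = 300, n_lncrna = 100, n_circrna = 80,
                       frac_de_contrast1 = 0.3, frac_reversed = 0.5,
                       effect_log2fc = 1.5, noise_sd = 0.4,
                       utr_len = 300, lnc_len = 400, circ_len = 350,
                       n_mirna = 10, n_planted_triples = 25,
                       n_gene_sets = 10, set_size = 20, overlap_frac = 0.8,
                       module_size = 6, circ_junction_frac = 0.5,
                       rng_seed = 1L) {
  cfg <- list(n_per_group = n_per_group, n_mrna = n_mrna,
              n_lncrna = n_lncrna, n_circrna = n_circrna,
              frac_de_contrast1 = frac_de_contrast1,
              frac_reversed = frac_reversed,
              effect_log2fc = effect_log2fc, noise_sd = noise_sd,
              utr_len = utr_len, lnc_len = lnc_len, circ_len = circ_len,
              n_mirna = n_mirna, n_planted_triples = n_planted_triples,
              n_gene_sets = n_gene_sets, set_size = set_size,
              overlap_frac = overlap_frac, module_size = module_size,
              circ_junction_frac = circ_junction_frac,
              rng_seed = as.integer(rng_seed))
  counts <- c("n_per_group", "n_mrna", "n_lncrna", "n_circrna", "utr_len",
              "lnc_len", "circ_len", "n_mirna", "n_gene_sets", "set_size",
              "module_size")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]]))
      stop("invalid configuration field '", f, "': must be a positive count")
  if (cfg$n_planted_triples < 0 ||
      cfg$n_planted_triples != round(cfg$n_planted_triples))
    stop("invalid configuration field 'n_planted_triples'")
  for (f in c("frac_de_contrast1", "frac_reversed", "overlap_frac",
              "circ_junction_frac"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid configuration field '", f, "': must be in [0, 1]")
  if (!is.numeric(cfg$effect_log2fc) || cfg$effect_log2fc <= 0)
    stop("invalid configuration field 'effect_log2fc': must be > 0")
  if (cfg$effect_log2fc < log2(1.5))
    stop("invalid configuration field 'effect_log2fc': must be >= log2(1.5)")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("invalid configuration field 'noise_sd': must be > 0")
  structure(cfg, class = "sim_config")
}

## deterministic sub-seeds per generator so each stage is a pure function of
## (config, seed) regardless of call order; kept below 2^31
.sub_seed <- function(cfg, stage) {
  (cfg$rng_seed %% 1000000L) * 1000L +
    c(expression = 1L, sequences = 2L, gene_sets = 3L, interactions = 4L)[[stage]]
}

.group_labels <- c("normal", "MCD", "QG")

#' Simulate three-group expression matrices with planted, recorded structure
#'
#' Plants DE features in the disease contrast (group 2 vs group 1) with
#' random sign and magnitude `effect_log2fc`; a `frac_reversed` subset is
#' reversed by treatment (group 3 returns to baseline, giving an
#' equal-magnitude opposite shift in contrast 2), the remainder stays at the
#' disease level (not DE in contrast 2). Also selects the planted
#' sponge-miRNA-mRNA triples among reversed features with matching direction,
#' so they survive the ceRNA direction-concordance filter.
#'
#' @param config a [sim_config].
#' @param group_labels labels for (control, disease, treatment).
#' @return list with `expr` (named list of [expr_matrix]: `mrna`, `lncrna`,
#'   `circrna`) and `truth` (a `planted_truth` list: `de_status` data.frame
#'   with per-contrast planted status, `reversal` data.frame,
#'   `planted_triples`, `mirna_ids`, and rng metadata).
#' @export
simulate_expression <- function(config, group_labels = .group_labels) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config, "expression"), kind = "Mersenne-Twister")
  n <- config$n_per_group
  samples <- paste0(rep(group_labels, each = n), "_",
                    sprintf("%02d", rep(seq_len(n), 3)))
  groups <- stats::setNames(rep(group_labels, each = n), samples)
  class_sizes <- c(mrna = config$n_mrna, lncrna = config$n_lncrna,
                   circrna = config$n_circrna)
  prefixes <- c(mrna = "mRNA", lncrna = "lnc", circrna = "circ")

  expr <- list()
  status_rows <- list()
  for (cl in names(class_sizes)) {
    nf <- class_sizes[[cl]]
    ids <- sprintf("%s_%04d", prefixes[[cl]], seq_len(nf))
    n_de <- round(config$frac_de_contrast1 * nf)
    n_rev <- round(config$frac_reversed * n_de)
    de_idx <- if (n_de > 0) sort(sample.int(nf, n_de)) else integer()
    rev_idx <- if (n_rev > 0) sort(sample(de_idx, n_rev)) else integer()
    dir <- stats::setNames(rep(0L, nf), ids)
    dir[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)

    baseline <- stats::rnorm(nf, mean = 8, sd = 1.5)
    logx <- matrix(stats::rnorm(nf * 3 * n, sd = config$noise_sd),
                   nrow = nf, dimnames = list(ids, samples)) + baseline
    is_disease <- groups == group_labels[2]
    is_treat <- groups == group_labels[3]
    shift <- dir * config$effect_log2fc
    # disease group carries the planted contrast-1 shift
    logx[, is_disease] <- logx[, is_disease] + shift
    # treatment group: reversed features return to baseline (opposite shift
    # in contrast 2); non-reversed DE features keep the disease level
    keep_shift <- shift
    keep_shift[rev_idx] <- 0
    logx[, is_treat] <- logx[, is_treat] + keep_shift

    s1 <- ifelse(dir == 1L, "up", ifelse(dir == -1L, "down", "not_de"))
    s2 <- rep("not_de", nf)
    s2[rev_idx] <- ifelse(dir[rev_idx] == 1L, "down", "up")
    pattern <- rep(NA_character_, nf)
    pattern[rev_idx] <- ifelse(dir[rev_idx] == 1L, "reversed-up",
                               "reversed-down")
    status_rows[[cl]] <- data.frame(
      feature = ids, rna_class = cl,
      status_contrast1 = s1, status_contrast2 = s2,
      direction = as.integer(dir), pattern = pattern,
      stringsAsFactors = FALSE)
    expr[[cl]] <- expr_matrix(2^logx, groups)
  }
  de_status <- do.call(rbind, status_rows)
  rownames(de_status) <- NULL

  mirna_ids <- sprintf("sim-miR-%02d", seq_len(config$n_mirna))
  triples <- .plan_triples(de_status, mirna_ids, config$n_planted_triples)

  truth <- structure(list(
    de_status = de_status,
    reversal = de_status[!is.na(de_status$pattern),
                         c("feature", "rna_class", "pattern")],
    planted_triples = triples,
    mirna_ids = mirna_ids,
    planted_sites = NULL,
    enriched_set_id = NULL,
    module_members = NULL,
    rng = list(algorithm = "Mersenne-Twister", seed = config$rng_seed)),
    class = "planted_truth")
  list(expr = expr, truth = truth)
}

## pair reversed sponges with reversed mRNAs of the same planted direction so
## triples pass the concordance filter by construction
.plan_triples <- function(de_status, mirna_ids, n_triples) {
  empty <- data.frame(sponge = character(), mirna = character(),
                      mrna = character(), stringsAsFactors = FALSE)
  if (n_triples == 0) return(empty)
  rev <- de_status[!is.na(de_status$pattern), ]
  out <- list()
  k <- 0L
  for (d in c(1L, -1L)) {
    sponges <- rev$feature[rev$rna_class != "mrna" & rev$direction == d]
    mrnas <- rev$feature[rev$rna_class == "mrna" & rev$direction == d]
    if (!length(sponges) || !length(mrnas)) next
    want <- if (d == 1L) ceiling(n_triples / 2) else floor(n_triples / 2)
    for (i in seq_len(want)) {
      k <- k + 1L
      out[[k]] <- data.frame(
        sponge = sponges[((i - 1) %% length(sponges)) + 1],
        mirna = mirna_ids[((k - 1) %% length(mirna_ids)) + 1],
        mrna = mrnas[((i - 1) %% length(mrnas)) + 1],
        stringsAsFactors = FALSE)
    }
  }
  if (!k) return(empty)
  triples <- unique(do.call(rbind, out))
  rownames(triples) <- NULL
  triples
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted_truth:", sum(x$de_status$status_contrast1 != "not_de"),
      "contrast-1 DE features,", nrow(x$reversal), "reversed,",
      nrow(x$planted_triples), "planted triples\n")
  invisible(x)
}
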