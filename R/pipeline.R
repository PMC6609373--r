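#' Validate a pipeline configuration
#'
#' A configuration is a YAML (or JSON) file, or an equivalent named list,
#' with either a `simulate:` block (fields of [sim_config]) or an `inputs:`
#' block of file paths (`mrna`, `lncrna`, `circrna` expression TSVs,
#' `design`, `transcripts` FASTA, `mirnas` FASTA, `gene_sets` GMT, `edges`
#' TSV), plus `groups` (control, disease, treatment labels in order),
#' `thresholds` and an `outdir`. Missing thresholds are filled with the
#' package defaults (fold change 1.5, p 0.05, hub degree 5, MCODE score 4,
#' kappa 0.4, `require_reversal` off).
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @return A validated list of class `pipeline_config` with defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a file path")
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs)
    stop("config must have exactly one of 'simulate' or 'inputs'")
  if (is.null(config$groups))
    stop("config missing field 'groups' (control, disease, treatment labels)")
  if (length(config$groups) != 3)
    stop("'groups' must list exactly three labels")
  th <- config$thresholds
  if (is.null(th)) th <- list()
  defaults <- list(fold_change_min = 1.5, p_max = 0.05, min_degree = 5,
                   score_min = 4, kappa_min = 0.4, require_reversal = FALSE,
                   top_n = 30)
  for (f in names(defaults)) if (is.null(th[[f]])) th[[f]] <- defaults[[f]]
  # de_thresholds() enforces the fold-change/p invariants
  de_thresholds(th$fold_change_min, th$p_max)
  if (th$min_degree < 1) stop("'min_degree' must be >= 1")
  if (th$score_min <= 0) stop("'score_min' must be > 0")
  config$thresholds <- th
  if (is.null(config$rng_seed)) config$rng_seed <- 1L
  if (has_sim) {
    sim_args <- config$simulate
    if (!is.list(sim_args)) sim_args <- list()
    if (is.null(sim_args$rng_seed)) sim_args$rng_seed <- config$rng_seed
    config$simulate <- do.call(sim_config, sim_args)
  }
  if (is.null(config$outdir)) config$outdir <- "cernarev_output"
  structure(config, class = "pipeline_config")
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full drug-reversal ceRNA analysis
#'
#' Stages, in order: simulate or load inputs; quantile-normalize each
#' expression matrix; compute the two contrasts (disease vs control,
#' treatment vs disease) per RNA class; intersect DE calls and classify
#' reversal patterns; predict miRNA seed-match sites; assemble lncRNA- and
#' circRNA-sponge ceRNA networks and their merge; run gene-set enrichment and
#' the kappa term network on the overlapping mRNAs; induce the interaction
#' subnetwork, call hubs and detect MCODE modules. Every stage's tables and
#' networks are written under `outdir` along with a JSON manifest of counts
#' and parameters.
#'
#' @param config a `pipeline_config`, a list, or a path (see
#'   [validate_config]).
#' @return Invisibly, an object of class `cerna_pipeline` holding every
#'   stage's in-memory result plus the manifest.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  th <- config$thresholds
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  groups <- unlist(config$groups)

  log_lines <- c(sprintf("groups: %s", paste(groups, collapse = ", ")),
                 sprintf("thresholds: fold_change_min=%g p_max=%g min_degree=%d score_min=%g kappa_min=%g require_reversal=%s",
                         th$fold_change_min, th$p_max, th$min_degree,
                         th$score_min, th$kappa_min, th$require_reversal))

  ## ---- stage: inputs -------------------------------------------------
  if (!is.null(config$simulate)) {
    cfg <- config$simulate
    sim <- simulate_expression(cfg, group_labels = groups)
    seqs <- simulate_sequences(cfg, sim$truth)
    gs <- simulate_gene_sets(cfg, seqs$truth)
    ints <- simulate_interactions(cfg, gs$truth)
    truth <- ints$truth
    expr <- sim$expr
    transcripts <- seqs$transcripts
    mirnas <- seqs$mirnas
    sets <- gs$sets
    edges <- ints$edges
    write_truth_json(truth, file.path(outdir, "planted_truth.json"))
    log_lines <- c(log_lines, sprintf("simulate: seed=%d", cfg$rng_seed))
  } else {
    inp <- config$inputs
    expr <- list(mrna = read_expression(inp$mrna, inp$design),
                 lncrna = read_expression(inp$lncrna, inp$design),
                 circrna = read_expression(inp$circrna, inp$design))
    transcripts <- read_transcript_fasta(inp$transcripts)
    mirnas <- read_mirna_fasta(inp$mirnas)
    sets <- read_gmt(inp$gene_sets)
    edges <- read_edge_table(inp$edges, min_confidence = inp$min_confidence)
    truth <- NULL
  }

  ## ---- stage: normalize + contrasts ----------------------------------
  thr <- de_thresholds(th$fold_change_min, th$p_max)
  contrasts <- list()
  overlaps <- list()
  reversals <- list()
  for (cl in names(expr)) {
    norm <- quantile_normalize(expr[[cl]])
    c1 <- compute_contrast(norm, groups[2], groups[1], thr)
    c2 <- compute_contrast(norm, groups[3], groups[2], thr)
    ov <- intersect_contrasts(c1, c2)
    rv <- if (length(ov)) classify_reversal(c1, c2, ov) else
      data.frame(feature = character(), pattern = character())
    contrasts[[cl]] <- list(contrast1 = c1, contrast2 = c2)
    overlaps[[cl]] <- ov
    reversals[[cl]] <- rv
    .write_tsv(as.data.frame(c1), file.path(outdir, paste0(cl, "_contrast1.tsv")))
    .write_tsv(as.data.frame(c2), file.path(outdir, paste0(cl, "_contrast2.tsv")))
    .write_tsv(data.frame(feature = ov), file.path(outdir, paste0(cl, "_overlap.tsv")))
    .write_tsv(rv, file.path(outdir, paste0(cl, "_reversal.tsv")))
  }

  ## ---- stage: target prediction --------------------------------------
  de_features <- unlist(overlaps, use.names = FALSE)
  scan_set <- transcripts[transcripts$id %in% de_features, , drop = FALSE]
  class(scan_set) <- class(transcripts)
  target_map <- build_target_map(scan_set, mirnas)
  write_site_table(target_map, file.path(outdir, "target_sites.tsv"))

  ## ---- stage: ceRNA networks -----------------------------------------
  nets <- list()
  for (cl in c("lncrna", "circrna")) {
    nets[[cl]] <- build_cerna_network(
      sponges = overlaps[[cl]], mrnas = overlaps$mrna,
      target_map = target_map,
      contrast1 = .stack_contrasts(contrasts, "contrast1"),
      contrast2 = .stack_contrasts(contrasts, "contrast2"),
      require_reversal = isTRUE(th$require_reversal))
    .write_tsv(nets[[cl]]$triples,
               file.path(outdir, paste0(cl, "_cerna_triples.tsv")))
    write_cerna_network(nets[[cl]],
                        sif_path = file.path(outdir, paste0(cl, "_cerna.sif")),
                        graphml_path = file.path(outdir, paste0(cl, "_cerna.graphml")))
  }
  merged <- merge_networks(nets)
  write_cerna_network(merged, sif_path = file.path(outdir, "merged_cerna.sif"),
                      graphml_path = file.path(outdir, "merged_cerna.graphml"))

  ## ---- stage: enrichment ---------------------------------------------
  background <- rownames(expr$mrna$values)
  enr <- enrich(overlaps$mrna, sets, background, top_n = th$top_n)
  .write_tsv(as.data.frame(enr), file.path(outdir, "enrichment.tsv"))
  tnet <- if (nrow(enr)) term_network(enr, sets, background, th$kappa_min)
          else NULL
  if (!is.null(tnet)) {
    .write_tsv(tnet$nodes, file.path(outdir, "term_network_nodes.tsv"))
    .write_tsv(tnet$edges, file.path(outdir, "term_network_edges.tsv"))
  }

  ## ---- stage: PPI ----------------------------------------------------
  ppi <- induce_subnetwork(edges, overlaps$mrna)
  hubs <- find_hubs(ppi, th$min_degree)
  modules <- mcode(ppi, mcode_params(score_min = th$score_min))
  .write_tsv(hubs, file.path(outdir, "hubs.tsv"))
  write_modules(modules, file.path(outdir, "mcode_modules.tsv"))
  igraph::write_graph(ppi, file.path(outdir, "ppi.graphml"),
                      format = "graphml")

  ## ---- manifest ------------------------------------------------------
  writeLines(log_lines, file.path(outdir, "pipeline.log"))
  summ <- network_summary(ppi)
  manifest <- list(
    parameters = th,
    rng_seed = config$rng_seed,
    groups = as.list(stats::setNames(groups, c("control", "disease",
                                               "treatment"))),
    counts = list(
      de_contrast1 = lapply(contrasts, function(x)
        sum(x$contrast1$status != "not_de")),
      de_contrast2 = lapply(contrasts, function(x)
        sum(x$contrast2$status != "not_de")),
      overlap = lapply(overlaps, length),
      reversed = lapply(reversals, function(r)
        sum(grepl("^reversed", r$pattern))),
      target_sites = nrow(target_map),
      cerna_triples = lapply(nets, function(n) nrow(n$triples)),
      merged_nodes = nrow(merged$nodes),
      enriched_terms = nrow(enr),
      ppi_nodes = summ$n_nodes, ppi_edges = summ$n_edges,
      ppi_avg_neighbors = summ$avg_neighbors,
      hubs = nrow(hubs),
      mcode_modules = length(modules)),
    outputs = sort(list.files(outdir)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  res <- structure(list(config = config, truth = truth,
                        contrasts = contrasts, overlaps = overlaps,
                        reversals = reversals, target_map = target_map,
                        networks = nets, merged = merged,
                        enrichment = enr, term_network = tnet,
                        ppi = ppi, hubs = hubs, modules = modules,
                        manifest = manifest),
                   class = "cerna_pipeline")
  invisible(res)
}

## bind the per-class contrast tables into one lookup table
.stack_contrasts <- function(contrasts, which) {
  out <- do.call(rbind, lapply(unname(contrasts), function(x)
    as.data.frame(x[[which]])))
  rownames(out) <- NULL
  out
}

#' @export
print.cerna_pipeline <- function(x, ...) {
  cat("cerna_pipeline run\n")
  cat("  DE overlap: ",
      paste(sprintf("%s=%d", names(x$overlaps),
                    lengths(x$overlaps)), collapse = ", "), "\n", sep = "")
  cat("  ceRNA triples: lncrna=", nrow(x$networks$lncrna$triples),
      ", circrna=", nrow(x$networks$circrna$triples), "\n", sep = "")
  cat("  PPI: ", x$manifest$counts$ppi_nodes, " nodes, ",
      x$manifest$counts$hubs, " hubs, ", x$manifest$counts$mcode_modules,
      " MCODE modules\n", sep = "")
  invisible(x)
}

#' @export
#' @method summary cerna_pipeline
summary.cerna_pipeline <- function(object, ...) object$manifest$counts
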