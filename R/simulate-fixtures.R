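## Sequence, gene-set and interaction fixtures with planted, recorded truth.

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## TRUE if seq (linear, or circularized) contains none of the hexamer cores
.clean_background <- function(seq, cores, circular) {
  scan_seq <- if (circular) paste0(seq, substr(seq, 1, 5)) else seq
  !any(vapply(cores, grepl, logical(1), x = scan_seq, fixed = TRUE))
}

## overwrite 8 characters at 0-based offset, wrapping modulo length
.plant_window <- function(seq, site8, offset) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  idx <- ((offset + 0:7) %% L) + 1L
  chars[idx] <- strsplit(site8, "")[[1]]
  paste(chars, collapse = "")
}

#' Simulate transcript and miRNA sequences with planted seed-match sites
#'
#' Generates a unique-seed miRNA per id recorded in the truth, then for every
#' transcript a random A/C/G/T background that is rejection-sampled (up to
#' 1000 attempts) so that the only canonical sites present are the planted
#' ones: each planted sponge-miRNA-mRNA triple gets one perfect 8mer site on
#' the sponge and one on the mRNA at recorded offsets. A `circ_junction_frac`
#' subset of circRNA sites is placed across the back-splice junction
#' (offset > length - 8), so it is only found under circular-topology
#' scanning.
#'
#' @param config a [sim_config].
#' @param truth the `planted_truth` from [simulate_expression].
#' @return list with `transcripts` (a [transcript_set] covering every
#'   feature), `mirnas` (a [mirna_set]) and `truth` updated with
#'   `planted_sites` (`mirna`, `transcript`, `start`, `site_type`).
#' @export
simulate_sequences <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "planted_truth"))
  lens <- c(mrna = config$utr_len, lncrna = config$lnc_len,
            circrna = config$circ_len)
  if (any(lens < 8))
    stop("configuration error: sequence length shorter than site length (8)")
  set.seed(.sub_seed(config, "sequences"), kind = "Mersenne-Twister")

  ## miRNAs with pairwise-distinct seed cores (rc of positions 2-7). A core
  ## must also never occur inside any miRNA's planted 8mer string except as
  ## that miRNA's own single anchor, otherwise planting one site would
  ## unavoidably create a site for another miRNA and rejection sampling
  ## could never terminate.
  # overlapping occurrence count (periodic cores like AAAAAA overlap)
  n_occ <- function(hay, needle) {
    hit <- gregexpr(paste0("(?=", needle, ")"), hay, perl = TRUE)[[1]]
    if (hit[1] == -1) 0L else length(hit)
  }
  mirseq <- character(length(truth$mirna_ids))
  cores <- character(0)
  sites <- character(0)
  for (i in seq_along(mirseq)) {
    ok <- FALSE
    for (attempt in seq_len(1000)) {
      s <- .rand_dna(22)
      core <- .revcomp(substr(s, 2, 7))
      own_site <- paste0(.revcomp(substr(s, 2, 8)), "A")
      if (core %in% cores) next
      if (n_occ(own_site, core) != 1) next                 # periodic core
      if (any(vapply(sites, n_occ, 0L, needle = core) > 0)) next
      if (any(vapply(cores, function(cc) n_occ(own_site, cc), 0L) > 0)) next
      ok <- TRUE
      break
    }
    if (!ok) stop("could not draw mutually compatible miRNA seeds")
    mirseq[i] <- s
    cores <- c(cores, core)
    sites <- c(sites, own_site)
  }
  mirnas <- mirna_set(truth$mirna_ids, mirseq)
  site8 <- stats::setNames(sites, mirnas$id)

  ## planted (transcript, mirna) pairs: one site per unique pair
  tri <- truth$planted_triples
  pairs <- unique(rbind(
    data.frame(transcript = tri$sponge, mirna = tri$mirna,
               stringsAsFactors = FALSE),
    data.frame(transcript = tri$mrna, mirna = tri$mirna,
               stringsAsFactors = FALSE)))

  de <- truth$de_status
  topo <- ifelse(de$rna_class == "circrna", "circular", "linear")
  cls <- ifelse(de$rna_class == "mrna", "mrna_utr", de$rna_class)
  L_of <- lens[de$rna_class]

  site_rows <- list()
  seqs <- character(nrow(de))
  for (i in seq_len(nrow(de))) {
    id <- de$feature[i]
    L <- L_of[[i]]
    circular <- topo[i] == "circular"
    my_pairs <- pairs[pairs$transcript == id, , drop = FALSE]
    n_sites <- nrow(my_pairs)
    # interior 12-nt blocks; ends are reserved for junction-spanning sites
    avail_blocks <- if (L >= 36) seq(12L, L - 24L, by = 12L) else integer()
    if (n_sites > length(avail_blocks))
      stop("configuration error: transcript '", id, "' too short (", L,
           " nt) for ", n_sites, " planted sites")
    planted <- NULL
    ok <- FALSE
    for (attempt in seq_len(1000)) {
      s <- .rand_dna(L)
      if (!.clean_background(s, cores, circular)) next
      planted <- NULL
      if (n_sites > 0) {
        offs <- sample(avail_blocks, n_sites)
        if (circular) {
          # at most one junction-spanning site per circRNA (windows near the
          # back-splice junction would otherwise overlap); offsets L-6..L-1
          # put the seed-match core itself across the junction, so the site
          # is invisible to linear scanning
          junc <- stats::runif(n_sites) < config$circ_junction_frac
          if (any(junc)) offs[which(junc)[1]] <- L - sample(1:6, 1)
        }
        for (j in seq_len(n_sites))
          s <- .plant_window(s, site8[[my_pairs$mirna[j]]], offs[j])
        planted <- data.frame(mirna = my_pairs$mirna, transcript = id,
                              start = as.integer(offs), site_type = "8mer",
                              stringsAsFactors = FALSE)
      }
      # accept only if a full scan finds exactly the planted sites
      found <- do.call(rbind, lapply(seq_len(nrow(mirnas)), function(j)
        find_seed_sites(list(id = id, sequence = s,
                             topology = topo[i]), mirnas[j, ])))
      n_found <- if (is.null(found)) 0L else nrow(found)
      if (is.null(planted)) {
        if (n_found == 0) { ok <- TRUE; break }
      } else if (n_found == nrow(planted)) {
        key_f <- paste(found$mirna, found$start, found$site_type)
        key_p <- paste(planted$mirna, planted$start, planted$site_type)
        if (setequal(key_f, key_p)) { ok <- TRUE; break }
      }
    }
    if (!ok)
      stop("rejection sampling failed for transcript '", id,
           "' after 1000 attempts")
    seqs[i] <- s
    if (!is.null(planted)) site_rows[[length(site_rows) + 1L]] <- planted
  }
  transcripts <- transcript_set(de$feature, seqs, topo, cls)
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(mirna = character(), transcript = character(),
               start = integer(), site_type = character(),
               stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  truth$planted_sites <- sites
  truth$planting_plan <- truth$planted_triples
  truth$planted_triples <- .triple_closure(sites, de)
  list(transcripts = transcripts, mirnas = mirnas, truth = truth)
}

## all triples implied by the planted sites: a sponge and an mRNA carrying a
## site for the same miRNA, planted in the same direction (reversal planting
## makes same direction in contrast 1 imply same direction in contrast 2)
.triple_closure <- function(sites, de_status) {
  dir_of <- stats::setNames(de_status$direction, de_status$feature)
  is_mrna <- stats::setNames(de_status$rna_class == "mrna", de_status$feature)
  out <- list()
  for (mir in unique(sites$mirna)) {
    tr <- unique(sites$transcript[sites$mirna == mir])
    sp <- tr[!is_mrna[tr]]
    mr <- tr[is_mrna[tr]]
    for (s in sp) for (m in mr)
      if (dir_of[[s]] == dir_of[[m]])
        out[[length(out) + 1L]] <- data.frame(
          sponge = s, mirna = mir, mrna = m, stringsAsFactors = FALSE)
  }
  triples <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(sponge = character(), mirna = character(),
               mrna = character(), stringsAsFactors = FALSE)
  triples <- triples[order(triples$sponge, triples$mirna, triples$mrna), ,
                     drop = FALSE]
  rownames(triples) <- NULL
  triples
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' The first set (`gene_set_01`) draws an `overlap_frac` share of its members
#' from the planted reversal mRNAs; all other sets are uniform draws from the
#' background (all simulated mRNAs).
#'
#' @param config a [sim_config].
#' @param truth the `planted_truth` from [simulate_expression].
#' @return list with `sets` (named list), `background` (character vector) and
#'   `truth` updated with `enriched_set_id` and `enriched_overlap`.
#' @export
simulate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "planted_truth"))
  set.seed(.sub_seed(config, "gene_sets"), kind = "Mersenne-Twister")
  de <- truth$de_status
  background <- de$feature[de$rna_class == "mrna"]
  if (config$set_size > length(background))
    stop("configuration error: set_size exceeds background size")
  rev_mrna <- de$feature[de$rna_class == "mrna" & !is.na(de$pattern)]
  n_overlap <- min(round(config$overlap_frac * config$set_size),
                   length(rev_mrna))
  enriched <- c(sample(rev_mrna, n_overlap),
                sample(setdiff(background, rev_mrna),
                       config$set_size - n_overlap))
  sets <- list(sort(enriched))
  for (i in seq_len(config$n_gene_sets - 1))
    sets[[i + 1]] <- sort(sample(background, config$set_size))
  names(sets) <- sprintf("gene_set_%02d", seq_along(sets))
  truth$enriched_set_id <- names(sets)[1]
  truth$enriched_overlap <- n_overlap / config$set_size
  list(sets = sets, background = background, truth = truth)
}

#' Simulate an interaction edge table with one planted dense module
#'
#' An Erdos-Renyi background over all simulated mRNAs with edge probability
#' chosen so the mean degree is about 2.7, plus one planted clique of
#' `module_size` on recorded reversal mRNAs.
#'
#' @param config a [sim_config].
#' @param truth the `planted_truth` from [simulate_expression].
#' @param background_p ER edge probability; default `2.7 / (n_nodes - 1)`.
#' @return list with `edges` (data.frame `node_a`, `node_b`) and `truth`
#'   updated with `module_members`.
#' @export
simulate_interactions <- function(config, truth, background_p = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "planted_truth"))
  if (config$module_size < 3)
    stop("configuration error: module_size must be >= 3")
  set.seed(.sub_seed(config, "interactions"), kind = "Mersenne-Twister")
  de <- truth$de_status
  nodes <- de$feature[de$rna_class == "mrna"]
  n <- length(nodes)
  if (is.null(background_p)) background_p <- 2.7 / (n - 1)
  rev_mrna <- de$feature[de$rna_class == "mrna" & !is.na(de$pattern)]
  if (config$module_size > length(rev_mrna))
    stop("configuration error: module_size exceeds planted reversal mRNAs")
  members <- sort(sample(rev_mrna, config$module_size))

  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < background_p
  edges <- data.frame(node_a = nodes[pairs[1, keep]],
                      node_b = nodes[pairs[2, keep]],
                      stringsAsFactors = FALSE)
  clique <- utils::combn(members, 2)
  edges <- rbind(edges, data.frame(node_a = clique[1, ],
                                   node_b = clique[2, ],
                                   stringsAsFactors = FALSE))
  # canonical order + dedupe
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  edges <- unique(data.frame(node_a = a, node_b = b,
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$node_a, edges$node_b), ]
  rownames(edges) <- NULL
  truth$module_members <- members
  list(edges = edges, truth = truth)
}

#' Write the planted truth to JSON
#' @param truth a `planted_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(truth)
}
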