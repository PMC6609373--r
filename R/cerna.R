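## ceRNA network assembly: a sponge (lncRNA or circRNA) and an mRNA form a
## triple with a miRNA when (1) both carry at least one canonical site for
## that miRNA (shared MRE) and (2) their expression moves in the same
## direction in both contrasts. miRNAs themselves need not be differentially
## expressed (the arrays profile mRNA/lncRNA/circRNA only).

.sign_lookup <- function(r) {
  v <- sign(r$log2fc)
  names(v) <- r$feature
  v
}

#' Build a sponge-miRNA-mRNA ceRNA network
#'
#' @param sponges character vector of sponge (lncRNA/circRNA) feature ids,
#'   each differentially expressed in both contrasts.
#' @param mrnas character vector of mRNA feature ids, each DE in both
#'   contrasts.
#' @param target_map a `target_map` covering the sponges and mRNAs.
#' @param contrast1,contrast2 `contrast_result` objects (disease vs control,
#'   treatment vs disease).
#' @param require_reversal if `TRUE`, additionally require every sponge and
#'   mRNA to have opposite fold-change signs in the two contrasts (the
#'   reversal pattern); default `FALSE` keeps the direction-concordance rule
#'   only.
#' @return An object of class `cerna_network`: list with `triples`
#'   (data.frame `sponge`, `mirna`, `mrna`, `sponge_sites`, `mrna_sites`),
#'   `nodes` (data.frame `id`, `type`, `overlap`), `edges` (data.frame
#'   `from`, `to`, `edge_type`, `n_sites`) and `sponge_summary`.
#' @export
build_cerna_network <- function(sponges, mrnas, target_map,
                                contrast1, contrast2,
                                require_reversal = FALSE) {
  for (f in c(sponges, mrnas)) {
    if (!f %in% contrast1$feature || !f %in% contrast2$feature)
      stop("feature '", f, "' absent from a contrast")
  }
  s1 <- .sign_lookup(contrast1)
  s2 <- .sign_lookup(contrast2)
  sites <- as.data.frame(target_map)
  sites <- sites[sites$transcript %in% c(sponges, mrnas), , drop = FALSE]
  counts <- if (nrow(sites)) {
    cnt <- stats::aggregate(start ~ mirna + transcript, data = sites,
                            FUN = length)
    names(cnt)[3] <- "n_sites"
    cnt
  } else {
    data.frame(mirna = character(), transcript = character(),
               n_sites = integer(), stringsAsFactors = FALSE)
  }

  rows <- list()
  for (mir in unique(counts$mirna)) {
    hit <- counts[counts$mirna == mir, ]
    sp <- hit$transcript[hit$transcript %in% sponges]
    mr <- hit$transcript[hit$transcript %in% mrnas]
    if (!length(sp) || !length(mr)) next
    ns <- stats::setNames(hit$n_sites, hit$transcript)
    for (s in sp) for (m in mr) {
      if (s1[s] != s1[m] || s2[s] != s2[m]) next       # concordance, both contrasts
      if (require_reversal && (s1[s] == s2[s] || s1[m] == s2[m])) next
      rows[[length(rows) + 1L]] <- data.frame(
        sponge = s, mirna = mir, mrna = m,
        sponge_sites = ns[[s]], mrna_sites = ns[[m]],
        stringsAsFactors = FALSE)
    }
  }
  triples <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sponge = character(), mirna = character(),
               mrna = character(), sponge_sites = integer(),
               mrna_sites = integer(), stringsAsFactors = FALSE)
  triples <- triples[order(triples$sponge, triples$mirna, triples$mrna), ,
                     drop = FALSE]
  rownames(triples) <- NULL
  .cerna_from_triples(triples)
}

.cerna_from_triples <- function(triples, overlap = character()) {
  node_block <- function(ids, type)
    data.frame(id = ids, type = rep(type, length(ids)),
               stringsAsFactors = FALSE)
  nodes <- rbind(node_block(unique(triples$sponge), "sponge"),
                 node_block(unique(triples$mirna), "mirna"),
                 node_block(unique(triples$mrna), "mrna"))
  nodes$overlap <- nodes$id %in% overlap
  e1 <- unique(data.frame(from = triples$sponge, to = triples$mirna,
                          edge_type = rep("sponge-mirna", nrow(triples)),
                          n_sites = triples$sponge_sites,
                          stringsAsFactors = FALSE))
  e2 <- unique(data.frame(from = triples$mirna, to = triples$mrna,
                          edge_type = rep("mirna-mrna", nrow(triples)),
                          n_sites = triples$mrna_sites,
                          stringsAsFactors = FALSE))
  edges <- rbind(e1, e2)
  rownames(edges) <- rownames(nodes) <- NULL
  summ <- if (nrow(triples)) {
    do.call(rbind, lapply(split(triples, triples$sponge), function(d)
      data.frame(sponge = d$sponge[1],
                 n_mirnas = length(unique(d$mirna)),
                 n_mrnas = length(unique(d$mrna)),
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(sponge = character(), n_mirnas = integer(),
               n_mrnas = integer(), stringsAsFactors = FALSE)
  }
  rownames(summ) <- NULL
  structure(list(triples = triples, nodes = nodes, edges = edges,
                 sponge_summary = summ), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tab <- table(factor(x$nodes$type, levels = c("sponge", "mirna", "mrna")))
  cat("cerna_network: ", nrow(x$triples), " triples; ",
      tab["sponge"], " sponges, ", tab["mirna"], " miRNAs, ",
      tab["mrna"], " mRNAs; ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @export
#' @method summary cerna_network
summary.cerna_network <- function(object, ...) object$sponge_summary

#' Merge ceRNA networks
#'
#' Node and edge union; nodes present in two or more input networks are
#' flagged `overlap = TRUE`.
#'
#' @param networks list of `cerna_network` objects (>= 2, or 1 for the
#'   trivial self-merge).
#' @return A merged `cerna_network`.
#' @export
merge_networks <- function(networks) {
  stopifnot(length(networks) >= 1,
            all(vapply(networks, inherits, logical(1), "cerna_network")))
  triples <- unique(do.call(rbind, lapply(networks, `[[`, "triples")))
  triples <- triples[order(triples$sponge, triples$mirna, triples$mrna), ,
                     drop = FALSE]
  rownames(triples) <- NULL
  ids <- lapply(networks, function(n) unique(n$nodes$id))
  counts <- table(unlist(ids))
  overlap <- names(counts)[counts >= 2]
  if (length(networks) == 1) overlap <- ids[[1]]   # self-merge flags all
  .cerna_from_triples(triples, overlap = overlap)
}

#' Per-subset shared-target counts (Venn cells) across networks
#'
#' @param networks named list of `cerna_network` objects (>= 2). Unnamed
#'   lists are named `net1`, `net2`, ...
#' @return data.frame with columns `subset` (ampersand-joined network names)
#'   and `count`: the number of mRNAs targeted in exactly that subset of
#'   networks. Counts sum to the size of the mRNA union.
#' @export
shared_targets <- function(networks) {
  stopifnot(length(networks) >= 2)
  if (is.null(names(networks)))
    names(networks) <- paste0("net", seq_along(networks))
  sets <- lapply(networks, function(n)
    unique(n$nodes$id[n$nodes$type == "mrna"]))
  univ <- unique(unlist(sets))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1) member <- matrix(member, nrow = 1,
                                          dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(r)
    paste(names(networks)[r], collapse = "&"))
  nets <- names(networks)
  subsets <- unlist(lapply(seq_along(nets), function(k)
    utils::combn(nets, k, paste, collapse = "&")))
  counts <- vapply(subsets, function(s) sum(key == s), integer(1))
  data.frame(subset = subsets, count = unname(counts),
             stringsAsFactors = FALSE)
}

#' Validate a ceRNA network against the construction rules
#'
#' Re-checks every triple (and every edge) for the shared-MRE and
#' direction-concordance rules; networks produced by [build_cerna_network]
#' yield an empty report.
#'
#' @param net a `cerna_network` (built or loaded).
#' @param contrast1,contrast2 `contrast_result` objects.
#' @param target_map a `target_map`.
#' @return data.frame of violations (`sponge`, `mirna`, `mrna`, `rule`);
#'   zero rows when valid.
#' @export
validate_network <- function(net, contrast1, contrast2, target_map) {
  sites <- as.data.frame(target_map)
  s1 <- .sign_lookup(contrast1)
  s2 <- .sign_lookup(contrast2)
  bad <- list()
  tri <- net$triples
  for (i in seq_len(nrow(tri))) {
    s <- tri$sponge[i]; mir <- tri$mirna[i]; m <- tri$mrna[i]
    n_s <- sum(sites$mirna == mir & sites$transcript == s)
    n_m <- sum(sites$mirna == mir & sites$transcript == m)
    rule <- character()
    if (n_s < 1 || n_m < 1) rule <- c(rule, "shared-MRE")
    conc <- !is.na(s1[s]) && !is.na(s1[m]) && !is.na(s2[s]) && !is.na(s2[m]) &&
      s1[s] == s1[m] && s2[s] == s2[m]
    if (!conc) rule <- c(rule, "concordance")
    if (length(rule))
      bad[[length(bad) + 1L]] <- data.frame(
        sponge = s, mirna = mir, mrna = m,
        rule = paste(rule, collapse = "+"), stringsAsFactors = FALSE)
  }
  # edges not supported by any triple (possible in hand-edited networks)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    supported <- if (e$edge_type == "sponge-mirna")
      any(tri$sponge == e$from & tri$mirna == e$to)
    else any(tri$mirna == e$from & tri$mrna == e$to)
    has_site <- if (e$edge_type == "sponge-mirna")
      any(sites$mirna == e$to & sites$transcript == e$from)
    else any(sites$mirna == e$from & sites$transcript == e$to)
    if (!supported || !has_site)
      bad[[length(bad) + 1L]] <- data.frame(
        sponge = if (e$edge_type == "sponge-mirna") e$from else NA_character_,
        mirna = if (e$edge_type == "sponge-mirna") e$to else e$from,
        mrna = if (e$edge_type == "mirna-mrna") e$to else NA_character_,
        rule = if (!has_site) "shared-MRE" else "unsupported-edge",
        stringsAsFactors = FALSE)
  }
  out <- if (length(bad)) unique(do.call(rbind, bad)) else
    data.frame(sponge = character(), mirna = character(),
               mrna = character(), rule = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Convert a ceRNA network to an igraph object
#' @param net a `cerna_network`.
#' @return An igraph graph with node attributes `type` and `overlap`.
#' @export
cerna_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a ceRNA network as SIF and GraphML
#' @param net a `cerna_network`.
#' @param sif_path,graphml_path output paths (either may be `NULL`).
#' @export
write_cerna_network <- function(net, sif_path = NULL, graphml_path = NULL) {
  if (!is.null(sif_path)) {
    lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$edge_type,
                     net$edges$to)
    writeLines(lines, sif_path)
  }
  if (!is.null(graphml_path))
    igraph::write_graph(cerna_igraph(net), graphml_path, format = "graphml")
  invisible(net)
}
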