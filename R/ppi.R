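#' Read a two-column interaction edge table
#'
#' @param path TSV with columns `node_a`, `node_b` and optional `confidence`
#'   (headerless files are read positionally).
#' @param min_confidence optional confidence filter (no default cutoff).
#' @return data.frame with columns `node_a`, `node_b` (and `confidence` if
#'   present).
#' @export
read_edge_table <- function(path, min_confidence = NULL) {
  first <- readLines(path, n = 1)
  header <- grepl("node_a", first, fixed = TRUE)
  edges <- utils::read.delim(path, header = header,
                             stringsAsFactors = FALSE)
  if (!header) names(edges)[1:2] <- c("node_a", "node_b")
  if (ncol(edges) >= 3 && !header) names(edges)[3] <- "confidence"
  if (!is.null(min_confidence)) {
    if (!"confidence" %in% names(edges))
      stop("edge table has no confidence column")
    edges <- edges[edges$confidence >= min_confidence, , drop = FALSE]
  }
  edges
}

#' Induce the interaction subnetwork on a gene set
#'
#' Builds a simple undirected graph from the edge table (self-loops and
#' duplicate edges removed), restricted to `gene_set`. Members of the gene
#' set that end up isolated are excluded, so the node count can be smaller
#' than the gene set.
#'
#' @param edges data.frame with columns `node_a`, `node_b`.
#' @param gene_set character vector of gene ids.
#' @return An igraph graph.
#' @export
induce_subnetwork <- function(edges, gene_set) {
  if (!all(c("node_a", "node_b") %in% names(edges)))
    stop("edge table needs columns 'node_a' and 'node_b'")
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  g <- igraph::simplify(g)
  keep <- intersect(igraph::V(g)$name, gene_set)
  g <- igraph::induced_subgraph(g, keep)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  attr(g, "n_self_loops_removed") <- n_loops
  g
}

#' Node, edge and mean-neighbor summary of a network
#'
#' @param net an igraph graph.
#' @return list with `n_nodes`, `n_edges`, `avg_neighbors` (2E/n, rounded to
#'   2 decimals; 0 for an empty network).
#' @export
network_summary <- function(net) {
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  list(n_nodes = n, n_edges = e,
       avg_neighbors = if (n == 0) 0 else round(2 * e / n, 2))
}

#' Degree hubs of a network
#'
#' @param net an igraph graph.
#' @param min_degree hub cutoff (default 5 neighbors).
#' @return data.frame with columns `gene`, `degree`, sorted by degree
#'   descending then id.
#' @export
find_hubs <- function(net, min_degree = 5) {
  if (min_degree < 1) stop("'min_degree' must be >= 1")
  deg <- igraph::degree(net)
  deg <- deg[deg >= min_degree]
  o <- order(-deg, names(deg))
  data.frame(gene = names(deg)[o], degree = unname(deg[o]),
             stringsAsFactors = FALSE)
}

#' MCODE parameters
#'
#' @param degree_cutoff nodes below this degree are never seeds (default 2).
#' @param vertex_weight_percentage expansion admits neighbors with weight at
#'   least `(1 - vwp) * seed weight` (default 0.2).
#' @param haircut iteratively remove singly-connected nodes from each module
#'   (default TRUE).
#' @param fluff not implemented; must stay FALSE.
#' @param score_min report modules with score strictly above this (default 4).
#' @return list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2, vertex_weight_percentage = 0.2,
                         haircut = TRUE, fluff = FALSE, score_min = 4) {
  if (vertex_weight_percentage <= 0 || vertex_weight_percentage >= 1)
    stop("'vertex_weight_percentage' must be in (0, 1)")
  if (score_min <= 0) stop("'score_min' must be > 0")
  if (isTRUE(fluff)) stop("fluff post-processing is not implemented")
  structure(list(degree_cutoff = degree_cutoff,
                 vertex_weight_percentage = vertex_weight_percentage,
                 haircut = haircut, fluff = FALSE, score_min = score_min),
            class = "mcode_params")
}

.graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

## MCODE vertex weight: take the closed neighborhood of v, find its highest
## k-core; weight = k * density of that k-core.
.mcode_weights <- function(g, degree_cutoff) {
  ids <- igraph::V(g)$name
  deg <- igraph::degree(g)
  w <- stats::setNames(numeric(length(ids)), ids)
  for (v in ids) {
    if (deg[[v]] < degree_cutoff) next
    nb <- c(v, igraph::neighbors(g, v)$name)
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) next
    kcore <- igraph::induced_subgraph(sub, names(core)[core >= kmax])
    w[[v]] <- kmax * .graph_density(kcore)
  }
  w
}

#' MCODE dense-module detection
#'
#' From-scratch implementation of the molecular complex detection algorithm:
#' vertices are weighted by the density-scaled highest k-core of their closed
#' neighborhood; complexes are grown greedily from the highest-weight unused
#' seed, admitting neighbors whose weight is within
#' `vertex_weight_percentage` of the seed weight; haircut trims
#' singly-connected members. A module's score is its density times its size;
#' modules scoring above `score_min` are returned, each node in at most one
#' module.
#'
#' @param net an igraph graph (undirected, simple).
#' @param params an [mcode_params] object.
#' @return list of modules sorted by score descending (ties by smallest node
#'   id), each a list with `nodes` (sorted ids), `density`, `score`, `seed`.
#' @export
mcode <- function(net, params = mcode_params()) {
  if (igraph::vcount(net) == 0) return(list())
  w <- .mcode_weights(net, params$degree_cutoff)
  ids <- names(w)
  assigned <- stats::setNames(rep(FALSE, length(ids)), ids)
  # deterministic seed order: weight descending, then id
  seed_order <- ids[order(-w, ids)]
  modules <- list()
  for (seed in seed_order) {
    if (assigned[[seed]] || w[[seed]] <= 0) next
    if (igraph::degree(net, seed) < params$degree_cutoff) next
    threshold <- w[[seed]] * (1 - params$vertex_weight_percentage)
    members <- seed
    frontier <- seed
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, function(v)
        igraph::neighbors(net, v)$name)))
      nb <- setdiff(nb, members)
      nb <- nb[!assigned[nb] & w[nb] >= threshold]
      members <- c(members, nb)
      frontier <- nb
    }
    sub <- igraph::induced_subgraph(net, members)
    if (params$haircut) {
      repeat {
        low <- igraph::V(sub)$name[igraph::degree(sub) < 2]
        if (!length(low) || igraph::vcount(sub) <= length(low)) {
          if (length(low)) sub <- igraph::induced_subgraph(sub, character(0))
          break
        }
        sub <- igraph::induced_subgraph(
          sub, setdiff(igraph::V(sub)$name, low))
      }
    }
    final <- igraph::V(sub)$name
    assigned[members] <- TRUE          # consumed even if haircut shrank it
    if (length(final) < 2) next
    dens <- .graph_density(sub)
    score <- dens * length(final)
    if (score > params$score_min)
      modules[[length(modules) + 1L]] <- list(
        nodes = sort(final), density = dens, score = score, seed = seed)
  }
  o <- order(-vapply(modules, `[[`, numeric(1), "score"),
             vapply(modules, function(m) m$nodes[1], character(1)))
  modules[o]
}

#' Write MCODE modules to TSV
#' @param modules output of [mcode].
#' @param path output TSV path (columns `module`, `score`, `density`, `n`,
#'   `nodes`).
#' @export
write_modules <- function(modules, path) {
  tab <- data.frame(
    module = seq_along(modules),
    score = vapply(modules, `[[`, numeric(1), "score"),
    density = vapply(modules, `[[`, numeric(1), "density"),
    n = vapply(modules, function(m) length(m$nodes), integer(1)),
    nodes = vapply(modules, function(m) paste(m$nodes, collapse = ","),
                   character(1)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(modules)
}
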