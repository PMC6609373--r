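#' Upper-tail hypergeometric probability
#'
#' P(X >= k) when drawing `n` elements without replacement from a background
#' of `N` containing `K` marked elements. Evaluated through the distribution
#' function's log-space-stable upper tail.
#'
#' @param k observed overlap (query and set).
#' @param K set size.
#' @param n query size.
#' @param N background size.
#' @return Probability in (0, 1].
#' @examples
#' hypergeom_tail(5, 5, 5, 20)   # 1 / choose(20, 5)
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(k > pmin(K, n)) ||
      any(K > N) || any(n > N))
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues vector of p-values in (0, 1].
#' @return q-values, monotone nondecreasing in p-rank, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric gene-set enrichment with enrichment-factor ranking
#'
#' One result per gene set overlapping the query (k >= 1), ranked by p-value
#' (ascending), ties broken by enrichment factor (descending) then term id.
#' The enrichment factor is `(k/n) / (K/N)`: the query's overlap rate with
#' the set relative to the background rate. Sets are intersected with the
#' background before testing; BH q-values are annotation only.
#'
#' @param query_genes character vector (subset of `background`).
#' @param collection named list of gene sets (e.g. from [read_gmt]).
#' @param background character vector: the measured universe.
#' @param top_n optionally keep only the first `top_n` ranked terms
#'   (default `Inf`; the reporting convention is 30).
#' @return data.frame of class `enrichment_result` with columns `term_id`,
#'   `k`, `K`, `n`, `N`, `p_hyper`, `enrichment_factor`, `q_bh`.
#' @export
enrich <- function(query_genes, collection, background, top_n = Inf) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  query_genes <- unique(query_genes)
  if (length(setdiff(query_genes, background)))
    stop("query gene(s) outside the background: ",
         paste(utils::head(setdiff(query_genes, background), 3),
               collapse = ", "))
  N <- length(background)
  n <- length(query_genes)
  rows <- lapply(names(collection), function(term) {
    set <- intersect(collection[[term]], background)
    K <- length(set)
    k <- length(intersect(set, query_genes))
    if (k < 1) return(NULL)
    data.frame(term_id = term, k = k, K = K, n = n, N = N,
               p_hyper = hypergeom_tail(k, K, n, N),
               enrichment_factor = (k / n) / (K / N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(), k = integer(), K = integer(),
               n = integer(), N = integer(), p_hyper = numeric(),
               enrichment_factor = numeric(), stringsAsFactors = FALSE)
  if (nrow(res)) {
    res$q_bh <- bh_adjust(res$p_hyper)
    res <- res[order(res$p_hyper, -res$enrichment_factor, res$term_id), ]
    rownames(res) <- NULL
    if (is.finite(top_n)) res <- utils::head(res, top_n)
  } else res$q_bh <- numeric()
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Cohen's kappa between two gene sets over a background
#'
#' Agreement of the two binary membership vectors beyond chance. Degenerate
#' cases with a constant marginal (a set that is empty or covers the whole
#' background) return 0 with a warning.
#'
#' @param set_a,set_b character vectors (subsets of `background`).
#' @param background character vector.
#' @return kappa in [-1, 1].
#' @export
kappa_score <- function(set_a, set_b, background) {
  background <- unique(background)
  a <- background %in% set_a
  b <- background %in% set_b
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    warning("degenerate membership marginal; kappa defined as 0")
    return(0)
  }
  po <- mean(a == b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  (po - pe) / (1 - pe)
}

#' Kappa-linked term-interaction network
#'
#' Links enriched terms whose gene sets agree with kappa at or above
#' `kappa_min` (the ClueGO-style convention); functional groups are the
#' connected components, numbered deterministically by smallest term id.
#'
#' @param results an `enrichment_result` (nonempty).
#' @param collection the gene-set collection the results came from.
#' @param background the background universe used for enrichment.
#' @param kappa_min edge threshold; default 0.4.
#' @return An object of class `term_network`: list with `nodes` (data.frame
#'   `term_id`, `k`, `p_hyper`, `group`) and `edges` (data.frame `term_a`,
#'   `term_b`, `kappa`).
#' @export
term_network <- function(results, collection, background, kappa_min = 0.4) {
  if (!nrow(results)) stop("empty enrichment results")
  terms <- results$term_id
  sets <- lapply(collection[terms], intersect, unique(background))
  edges <- list()
  if (length(terms) > 1) {
    for (i in seq_len(length(terms) - 1)) for (j in (i + 1):length(terms)) {
      kp <- suppressWarnings(kappa_score(sets[[i]], sets[[j]], background))
      if (kp >= kappa_min)
        edges[[length(edges) + 1L]] <- data.frame(
          term_a = terms[i], term_b = terms[j], kappa = kp,
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(term_a = character(), term_b = character(),
               kappa = numeric(), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = terms))
  comp <- igraph::components(g)$membership
  # renumber groups by the smallest term id they contain
  smallest <- vapply(split(names(comp), comp), min, character(1))
  renum <- stats::setNames(rank(smallest, ties.method = "first"),
                           names(smallest))
  group <- unname(renum[as.character(comp[terms])])
  nodes <- data.frame(term_id = terms, k = results$k,
                      p_hyper = results$p_hyper, group = group,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "term_network")
}

#' @export
print.term_network <- function(x, ...) {
  cat("term_network: ", nrow(x$nodes), " terms, ", nrow(x$edges),
      " kappa edges, ", length(unique(x$nodes$group)), " groups\n", sep = "")
  invisible(x)
}
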