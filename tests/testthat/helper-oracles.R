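## Independent brute-force oracles, written directly from the definitions the
## implementation is supposed to satisfy. Kept deliberately naive.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGUT", "TGCAA", toupper(s)), "")[[1]]),
        collapse = "")
}

## direct window comparison at every position; `at(p)` reads the base at
## 0-based position p, wrapping for circular transcripts
oracle_seed_sites <- function(seq, mir_seq, circular = FALSE) {
  seq <- chartr("U", "T", toupper(seq))
  mir <- chartr("U", "T", toupper(mir_seq))
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  at <- function(p) {
    if (circular) chars[(p %% L) + 1]
    else if (p >= 0 && p < L) chars[p + 1] else ""
  }
  core <- strsplit(oracle_revcomp(substr(mir, 2, 7)), "")[[1]]
  m8 <- oracle_revcomp(substr(mir, 8, 8))
  out <- list()
  for (p in 0:(L - 1)) {
    if (!all(vapply(0:5, function(k) at(p + k), "") == core)) next
    has_m8 <- at(p - 1) == m8
    has_a1 <- at(p + 6) == "A"
    if (!has_m8 && !has_a1) next
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else "7mer-A1"
    start <- if (has_m8) (p - 1) %% L else p
    if (!circular && has_m8) start <- p - 1
    out[[length(out) + 1]] <- data.frame(start = as.integer(start),
                                         site_type = type,
                                         stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(), site_type = character(),
                      stringsAsFactors = FALSE))
  d <- do.call(rbind, out)
  d <- d[order(d$start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

## exact combinatorial sum for the upper hypergeometric tail
oracle_hyper_tail <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## full enumeration over all draws (tiny N only)
oracle_hyper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}

## hand-applied BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

## Cohen's kappa from the 2x2 membership table
oracle_kappa <- function(a, b, bg) {
  n11 <- length(intersect(a, b))
  n10 <- length(setdiff(a, b))
  n01 <- length(setdiff(b, a))
  n00 <- length(bg) - n11 - n10 - n01
  N <- length(bg)
  po <- (n11 + n00) / N
  pe <- ((n11 + n10) / N) * ((n11 + n01) / N) +
    ((n01 + n00) / N) * ((n10 + n00) / N)
  (po - pe) / (1 - pe)
}

## highest density*n over all node subsets of size >= 2 (graphs <= ~12 nodes)
oracle_best_module <- function(g) {
  ids <- igraph::V(g)$name
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  best <- list(score = -Inf, nodes = character())
  for (mask in 1:(2^length(ids) - 1)) {
    sel <- bitwAnd(mask, 2^(seq_along(ids) - 1)) > 0
    n <- sum(sel)
    if (n < 2) next
    e <- sum(A[sel, sel]) / 2
    score <- 2 * e / (n * (n - 1)) * n
    if (score > best$score) best <- list(score = score, nodes = sort(ids[sel]))
  }
  best
}

## fabricate a contrast_result-shaped table for rule-level tests
make_contrast <- function(features, status,
                          log2fc = ifelse(status == "up", 1,
                                   ifelse(status == "down", -1, 0.1))) {
  d <- data.frame(feature = features, log2fc = log2fc, status = status,
                  stringsAsFactors = FALSE)
  class(d) <- c("contrast_result", "data.frame")
  d
}
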