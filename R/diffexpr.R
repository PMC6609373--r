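#' Differential-expression thresholds
#'
#' The gate used throughout: a feature is called differentially expressed when
#' its linear fold change is at least `fold_change_min` (or at most its
#' reciprocal) and its p-value is strictly below `p_max`. The fold-change
#' boundary is inclusive, the p boundary exclusive.
#'
#' @param fold_change_min minimum linear fold change (> 1); default 1.5.
#' @param p_max p-value cutoff (strict); default 0.05.
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(fold_change_min = 1.5, p_max = 0.05) {
  if (!is.numeric(fold_change_min) || fold_change_min <= 1)
    stop("'fold_change_min' must be > 1")
  if (!is.numeric(p_max) || p_max <= 0 || p_max >= 1)
    stop("'p_max' must be in (0, 1)")
  structure(list(fold_change_min = fold_change_min, p_max = p_max),
            class = "de_thresholds")
}

#' Classify differential-expression status from fold change and p-value
#'
#' @param fold_change positive linear fold change(s), group A over group B.
#' @param p_value two-sided p-value(s).
#' @param thresholds a [de_thresholds] object.
#' @return Character vector in `{"up", "down", "not_de"}`. `up` requires
#'   `fold_change >= fold_change_min` and `p < p_max`; `down` requires
#'   `fold_change <= 1/fold_change_min` and `p < p_max`.
#' @examples
#' classify_de(c(2.44, 0.09, 1.0), c(0.03, 0.00, 0.001))
#' @export
classify_de <- function(fold_change, p_value, thresholds = de_thresholds()) {
  if (any(!is.finite(fold_change) | fold_change <= 0))
    stop("fold changes must be positive and finite")
  sig <- p_value < thresholds$p_max
  status <- rep("not_de", length(fold_change))
  status[sig & fold_change >= thresholds$fold_change_min] <- "up"
  status[sig & fold_change <= 1 / thresholds$fold_change_min] <- "down"
  status
}

#' Two-group contrast: fold change, Welch t-test, DE status
#'
#' Fold changes are ratios of linear-scale group means (computed on the
#' normalized matrix); p-values come from a two-sided Welch t-test on the
#' log2-transformed values. When both groups have zero variance and equal
#' means the p-value is 1 by convention. BH-adjusted q-values are reported as
#' an annotation column only; the DE gate uses the raw p.
#'
#' @param m an [expr_matrix] (normalized linear intensities).
#' @param group_a,group_b group labels; fold change is mean(A)/mean(B).
#' @param thresholds a [de_thresholds] object.
#' @return A data.frame of class `contrast_result` with columns `feature`,
#'   `mean_a`, `mean_b`, `fold_change`, `log2fc`, `p_value`, `q_bh`, `status`,
#'   and attributes `groups` and `thresholds`.
#' @export
compute_contrast <- function(m, group_a, group_b,
                             thresholds = de_thresholds()) {
  stopifnot(inherits(m, "expr_matrix"))
  for (g in c(group_a, group_b))
    if (!g %in% levels(m$groups)) stop("unknown group: ", g)
  ia <- which(m$groups == group_a)
  ib <- which(m$groups == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs >= 2 samples (", group_a, ": ", length(ia),
         ", ", group_b, ": ", length(ib), ")")
  xa <- m$values[, ia, drop = FALSE]
  xb <- m$values[, ib, drop = FALSE]
  mean_a <- rowMeans(xa)
  mean_b <- rowMeans(xb)
  fc <- mean_a / mean_b

  la <- log2(xa); lb <- log2(xb)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate rows: no variance anywhere
  degen <- se2 == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)

  res <- data.frame(feature = rownames(m$values),
                    mean_a = mean_a, mean_b = mean_b,
                    fold_change = fc, log2fc = log2(fc),
                    p_value = p,
                    q_bh = stats::p.adjust(p, method = "BH"),
                    status = classify_de(fc, p, thresholds),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "groups") <- c(a = group_a, b = group_b)
  attr(res, "thresholds") <- thresholds
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' @export
print.contrast_result <- function(x, ...) {
  g <- attr(x, "groups")
  cat("contrast_result: ", g["a"], " vs ", g["b"], " (", nrow(x),
      " features; up ", sum(x$status == "up"), ", down ",
      sum(x$status == "down"), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

.contrast_lookup <- function(r, what) {
  v <- r[[what]]
  names(v) <- r$feature
  v
}

#' Features differentially expressed in both contrasts
#'
#' The Venn intersection of the two contrasts' DE calls (status `up` or
#' `down` in both), over the shared feature universe.
#'
#' @param r1,r2 `contrast_result` objects over a shared feature universe.
#' @return Character vector of feature ids, in `r1` order.
#' @export
intersect_contrasts <- function(r1, r2) {
  shared <- intersect(r1$feature, r2$feature)
  if (!length(shared))
    stop("contrasts have disjoint feature universes")
  s1 <- .contrast_lookup(r1, "status")[shared]
  s2 <- .contrast_lookup(r2, "status")[shared]
  shared[s1 != "not_de" & s2 != "not_de"]
}

#' Classify the dual-contrast pattern of features DE in both contrasts
#'
#' A feature up in the disease contrast and down in the treatment contrast is
#' `reversed-up` (the treatment undoes a disease-induced increase);
#' down-then-up is `reversed-down`; same direction in both contrasts is
#' `concordant-up` / `concordant-down`.
#'
#' @param r1,r2 `contrast_result` objects (contrast 1 = disease vs control,
#'   contrast 2 = treatment vs disease).
#' @param features feature ids, each DE (not `not_de`) in both contrasts;
#'   defaults to [intersect_contrasts] of the two.
#' @return data.frame with columns `feature`, `pattern`.
#' @examples
#' \dontrun{
#' classify_reversal(r1, r2, intersect_contrasts(r1, r2))
#' }
#' @export
classify_reversal <- function(r1, r2, features = intersect_contrasts(r1, r2)) {
  s1 <- .contrast_lookup(r1, "status")[features]
  s2 <- .contrast_lookup(r2, "status")[features]
  if (any(is.na(s1) | is.na(s2)))
    stop("feature(s) absent from a contrast: ",
         paste(features[is.na(s1) | is.na(s2)], collapse = ", "))
  if (any(s1 == "not_de" | s2 == "not_de"))
    stop("pattern is defined only for features DE in both contrasts: ",
         paste(features[s1 == "not_de" | s2 == "not_de"], collapse = ", "))
  pattern <- ifelse(s1 == "up" & s2 == "down", "reversed-up",
             ifelse(s1 == "down" & s2 == "up", "reversed-down",
             ifelse(s1 == "up", "concordant-up", "concordant-down")))
  data.frame(feature = features, pattern = pattern,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Heatmap leaf order from average-linkage correlation clustering
#'
#' Orders features by the leaf order of average-linkage hierarchical
#' clustering with distance 1 - Pearson correlation of the log2 rows.
#' Features are canonicalized by id before clustering, so the result does not
#' depend on input order. Constant (zero-variance) rows are assigned the
#' maximal distance (2) to all others, with a warning.
#'
#' @param m an [expr_matrix].
#' @param features feature ids to order (>= 2).
#' @return Character vector: the features in leaf order.
#' @export
cluster_order <- function(m, features) {
  stopifnot(inherits(m, "expr_matrix"))
  if (length(features) < 2) stop("need >= 2 features to cluster")
  features <- sort(unique(features))
  miss <- setdiff(features, rownames(m$values))
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  x <- log2(m$values[features, , drop = FALSE])
  sds <- apply(x, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(x)))
  if (any(sds == 0)) {
    warning("constant row(s) assigned maximal distance: ",
            paste(features[sds == 0], collapse = ", "))
    cc[sds == 0, ] <- -1
    cc[, sds == 0] <- -1
  }
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  features[hc$order]
}
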