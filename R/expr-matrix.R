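#' Expression matrix with sample group labels
#'
#' Container for a linear-scale intensity matrix (features x samples) together
#' with a group label per sample. All values must be strictly positive and
#' feature/sample identifiers unique; these invariants are checked at
#' construction so downstream stages can rely on them.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids); strictly positive,
#'   linear-scale intensities.
#' @param groups factor or character vector of group labels, one per sample,
#'   named by sample id (or in column order if unnamed).
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `groups` (a named factor).
#' @examples
#' m <- expr_matrix(matrix(2^rnorm(12, 8), 3, 4,
#'                         dimnames = list(paste0("f", 1:3), paste0("s", 1:4))),
#'                  rep(c("normal", "MCD"), each = 2))
#' m
#' @export
expr_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    stop("duplicate feature id(s): ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("nonpositive or non-finite value at feature '",
         rownames(values)[bad[1, 1]], "', sample '",
         colnames(values)[bad[1, 2]], "'")
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values))
      stop("'groups' must have one label per sample")
    names(groups) <- colnames(values)
  }
  missing_s <- setdiff(colnames(values), names(groups))
  if (length(missing_s))
    stop("sample(s) missing a group label: ", paste(missing_s, collapse = ", "))
  groups <- factor(as.character(groups[colnames(values)]))
  names(groups) <- colnames(values)
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x$values), " features x ", ncol(x$values),
      " samples\n", sep = "")
  cat("groups:", paste(sprintf("%s (n=%d)", levels(x$groups),
                               table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample design
#'
#' The matrix file is a TSV with feature ids in the first column and one
#' column per sample; the design file is a two-column TSV (`sample`, `group`).
#'
#' @param path path to the expression TSV.
#' @param design_path path to the sample->group design TSV.
#' @return An [expr_matrix] object.
#' @export
read_expression <- function(path, design_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature id(s) in '", path, "': ",
         paste(dup, collapse = ", "))
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- ids
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(design)))
    stop("design file must have columns 'sample' and 'group'")
  groups <- design$group
  names(groups) <- design$sample
  missing_s <- setdiff(colnames(values), design$sample)
  if (length(missing_s))
    stop("sample(s) missing from design: ", paste(missing_s, collapse = ", "))
  expr_matrix(values, groups[colnames(values)])
}

#' Write an expression matrix and its design to TSV
#'
#' @param m an [expr_matrix].
#' @param path output path for the matrix TSV (first column `feature`).
#' @param design_path output path for the two-column design TSV.
#' @return Invisibly, `m`.
#' @export
write_expression <- function(m, path, design_path) {
  tab <- data.frame(feature = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  design <- data.frame(sample = names(m$groups),
                       group = as.character(m$groups))
  utils::write.table(design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample's intensity distribution onto the common reference
#' distribution (the row-wise mean of the sorted columns). Ties within a
#' column receive the mean of the reference values at their tied ranks.
#' Idempotent, and preserves each column's rank order.
#'
#' @param m an [expr_matrix], or a bare numeric matrix.
#' @return Same type as the input, with normalized values.
#' @export
quantile_normalize <- function(m) {
  is_em <- inherits(m, "expr_matrix")
  x <- if (is_em) m$values else m
  if (ncol(x) < 2) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(m)
  }
  norm <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(norm) <- dimnames(x)
  if (is_em) expr_matrix(norm, m$groups) else norm
}

#' Log2-transform an expression matrix
#'
#' @param m an [expr_matrix] or positive numeric matrix.
#' @return A plain numeric matrix of log2 values (log2 intensities are the
#'   scale on which group comparisons are tested).
#' @export
log2_transform <- function(m) {
  x <- if (inherits(m, "expr_matrix")) m$values else m
  bad <- which(!is.finite(x) | x <= 0, arr.ind = TRUE)
  if (length(bad) && nrow(bad)) {
    fid <- if (is.null(rownames(x))) bad[1, 1] else rownames(x)[bad[1, 1]]
    sid <- if (is.null(colnames(x))) bad[1, 2] else colnames(x)[bad[1, 2]]
    stop("nonpositive value at feature '", fid, "', sample '", sid, "'")
  }
  log2(x)
}
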