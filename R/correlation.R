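#' Drop genes with too many zero values
#'
#' Excludes every feature whose fraction of exactly-zero values is
#' strictly greater than `max_zero_fraction` (default: more than 5% of
#' the samples). The zero test is exact equality to 0 -- normalized
#' level-3 values are non-negative reals, so no epsilon is used. The
#' sample set is unchanged and the operation is idempotent.
#'
#' @param m Expression matrix.
#' @param max_zero_fraction Largest tolerated zero fraction (default 0.05).
#' @return The filtered expression matrix.
#' @export
filter_low_expression <- function(m, max_zero_fraction = 0.05) {
  validate_expression_matrix(m)
  zf <- rowMeans(m == 0)
  keep <- zf <= max_zero_fraction
  message(sprintf("filter_low_expression: removed %d of %d features (> %.0f%% zeros), retained %d",
                  sum(!keep), nrow(m), 100 * max_zero_fraction, sum(keep)))
  m[keep, , drop = FALSE]
}

#' Pearson correlation with two-sided t test
#'
#' Product-moment correlation of two equal-length vectors with the
#' two-sided p-value from the t distribution on n - 2 degrees of
#' freedom, exactly `cor.test(x, y, method = "pearson",
#' alternative = "two.sided")`. p-values are never reported as exactly
#' zero: they are floored at the smallest positive double.
#'
#' @param x,y Numeric vectors of equal length n >= 3, neither constant.
#' @return List with `r`, `p` and `n`.
#' @export
correlation_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate input: constant vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = max(ct$p.value, .p_floor), n = n)
}

#' Correlation table of one target gene against all others
#'
#' Computes Pearson r (and its two-sided t p-value) between the target
#' feature's expression vector and every other feature, then applies
#' the requested ordering. The target itself is excluded from the rows.
#' Ties in r are broken by lexicographic feature id so ranks are
#' reproducible.
#'
#' @param m Expression matrix, already low-expression filtered.
#' @param target_id Target feature; must be a row of `m`.
#' @param sort One of `"by_r_desc"`, `"by_abs_r_desc"`, `"unsorted"`.
#' @return A `correlation_table`: data.frame (`feature_id`, `r`, `p`,
#'   `n`) with attributes `target_id` and `order`.
#' @export
build_correlation_table <- function(m, target_id,
                                    sort = c("by_r_desc", "by_abs_r_desc", "unsorted")) {
  sort <- match.arg(sort)
  validate_expression_matrix(m)
  if (!target_id %in% rownames(m)) stop("target feature not found: ", target_id)
  x <- m[target_id, ]
  if (stats::sd(x) == 0) stop("degenerate input: target expression is constant")
  others <- rownames(m)[rownames(m) != target_id]
  r <- suppressWarnings(as.vector(stats::cor(x, t(m[others, , drop = FALSE]))))
  if (anyNA(r)) {
    stop("constant expression vector(s): ",
         paste(utils::head(others[is.na(r)], 5), collapse = ", "))
  }
  n <- ncol(m)
  tab <- data.frame(feature_id = others, r = r, p = .pearson_p(r, n), n = n,
                    stringsAsFactors = FALSE)
  ord <- switch(sort,
                by_r_desc = order(-tab$r, tab$feature_id),
                by_abs_r_desc = order(-abs(tab$r), tab$feature_id),
                unsorted = seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "target_id") <- target_id
  attr(tab, "order") <- sort
  class(tab) <- c("correlation_table", "data.frame")
  tab
}

#' Pairwise correlation matrix for a gene list
#'
#' Symmetric Pearson r matrix with matching two-sided t p-values (the
#' diagonal p is NA: a gene against itself is not a test).
#'
#' @param m Expression matrix.
#' @param gene_list Character vector of features present in `m`.
#' @return List with matrices `r` and `p`, and the sample count `n`.
#' @export
correlation_matrix <- function(m, gene_list) {
  validate_expression_matrix(m)
  missing <- setdiff(gene_list, rownames(m))
  if (length(missing)) stop("gene(s) not found: ", paste(missing, collapse = ", "))
  sub <- m[gene_list, , drop = FALSE]
  if (any(apply(sub, 1L, stats::sd) == 0)) stop("degenerate input: constant vector")
  r <- stats::cor(t(sub))
  n <- ncol(m)
  p <- matrix(.pearson_p(r, n), nrow(r), ncol(r), dimnames = dimnames(r))
  diag(r) <- 1
  diag(p) <- NA_real_
  list(r = r, p = p, n = n)
}

#' Per-gene summary statistics
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and
#' coefficient of variation (sd/mean) for one or more features. The cv
#' is undefined (NA) when the mean is zero.
#'
#' @param m Expression matrix.
#' @param feature_ids Features to summarise.
#' @return data.frame (`feature_id`, `mean`, `sd`, `cv`).
#' @export
gene_summary <- function(m, feature_ids) {
  validate_expression_matrix(m)
  missing <- setdiff(feature_ids, rownames(m))
  if (length(missing)) stop("feature(s) not found: ", paste(missing, collapse = ", "))
  mu <- rowMeans(m[feature_ids, , drop = FALSE])
  sd <- apply(m[feature_ids, , drop = FALSE], 1L, stats::sd)
  cv <- ifelse(mu > 0, sd / mu, NA_real_)
  data.frame(feature_id = feature_ids, mean = unname(mu), sd = unname(sd),
             cv = unname(cv), stringsAsFactors = FALSE)
}

#' Correlation between features of two expression matrices
#'
#' Correlates selected features of matrix A against selected features of
#' matrix B (e.g. miRNA against mRNA) over their shared samples,
#' order-aligned by sample id.
#'
#' @param matrix_a,matrix_b Expression matrices sharing >= 3 sample ids.
#' @param features_a,features_b Features of each matrix to correlate
#'   (defaults: all).
#' @return data.frame (`a`, `b`, `r`, `p`, `n`) with
#'   |features_a| x |features_b| rows.
#' @export
cross_feature_correlation <- function(matrix_a, matrix_b,
                                      features_a = rownames(matrix_a),
                                      features_b = rownames(matrix_b)) {
  validate_expression_matrix(matrix_a)
  validate_expression_matrix(matrix_b)
  shared <- intersect(colnames(matrix_a), colnames(matrix_b))
  if (length(shared) < 3L) stop("need at least 3 shared samples; found ", length(shared))
  missing <- setdiff(features_a, rownames(matrix_a))
  if (length(missing)) stop("feature(s) not in matrix A: ", paste(missing, collapse = ", "))
  missing <- setdiff(features_b, rownames(matrix_b))
  if (length(missing)) stop("feature(s) not in matrix B: ", paste(missing, collapse = ", "))
  a <- matrix_a[features_a, shared, drop = FALSE]
  b <- matrix_b[features_b, shared, drop = FALSE]
  if (any(apply(a, 1L, stats::sd) == 0) || any(apply(b, 1L, stats::sd) == 0)) {
    stop("degenerate input: constant vector")
  }
  r <- stats::cor(t(a), t(b))
  n <- length(shared)
  data.frame(a = rep(features_a, times = length(features_b)),
             b = rep(features_b, each = length(features_a)),
             r = as.vector(r), p = .pearson_p(as.vector(r), n), n = n,
             stringsAsFactors = FALSE)
}
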