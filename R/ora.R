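#' Pool of top-k genes by absolute correlation
#'
#' The k genes with the highest |r| values in a correlation table
#' (lexicographic tie-break), returned as a set for over-representation
#' analysis. Shares its definition with [top_k_by_abs_r()].
#'
#' @param table A `correlation_table`.
#' @param k Pool size (default 1000).
#' @return Character vector of k gene ids.
#' @export
top_pool <- function(table, k = 1000L) {
  top_k_by_abs_r(table, k)
}

#' Background annotation rate of each gene set
#'
#' The per-gene probability mu of carrying a given annotation,
#' estimated over the analyzable universe:
#' `mu(set) = |members in universe| / |universe|`. A set disjoint from
#' the universe gets mu = 0 (flagged with a message).
#'
#' @param collection A `gene_set_collection`.
#' @param universe Character vector: the analyzable gene universe.
#' @return Named numeric vector of mu values, one per set.
#' @export
set_frequency_mu <- function(collection, universe) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(universe)) stop("universe must be non-empty")
  mu <- vapply(collection$sets,
               function(members) length(intersect(members, universe)) / length(universe),
               numeric(1))
  zero <- names(mu)[mu == 0]
  if (length(zero)) {
    message("set_frequency_mu: set(s) disjoint from the universe: ",
            paste(zero, collapse = ", "))
  }
  mu
}

#' Binomial upper-tail over-representation p-value
#'
#' `P(X > found)` for `X ~ Binomial(pool_size, mu)` -- one minus the
#' CDF at `found` (note the strict inequality: this is the convention
#' of `1 - pbinom(n, size, mu)`, off by one versus `P(X >= found)`).
#' Computed directly as an upper tail, so values far below 1e-16 keep
#' full precision.
#'
#' @param found Observed count(s) in the pool.
#' @param pool_size Pool size (default 1000).
#' @param mu Background rate in [0, 1].
#' @return Upper-tail probability, vectorised over `found`.
#' @export
binomial_tail_p <- function(found, pool_size = 1000L, mu) {
  if (any(found < 0) || any(found > pool_size)) stop("found must lie in [0, pool_size]")
  if (any(mu < 0) || any(mu > 1)) stop("mu must lie in [0, 1]")
  stats::pbinom(found, size = pool_size, prob = mu, lower.tail = FALSE)
}

#' Smallest count reaching over-representation significance
#'
#' The minimum integer n such that `binomial_tail_p(n, pool_size, mu)`
#' falls below `alpha` -- the "expected" column: how many genes of a
#' pathway must appear among the top pool before the binomial test
#' calls it over-represented.
#'
#' @param mu Background rate in (0, 1).
#' @param pool_size Pool size (default 1000).
#' @param alpha Significance level (default 0.05).
#' @return Integer count.
#' @export
expected_min_count <- function(mu, pool_size = 1000L, alpha = 0.05) {
  if (length(mu) != 1L || is.na(mu) || mu <= 0 || mu >= 1) stop("mu must lie strictly in (0, 1)")
  n <- 0:pool_size
  tail <- stats::pbinom(n, pool_size, mu, lower.tail = FALSE)
  n[which(tail < alpha)[1L]]
}

#' Binomial over-representation table for the top correlated genes
#'
#' Pools the top-k genes by |r|, counts each set's members in the pool,
#' and tests the count against the set's background rate mu (estimated
#' on the table's full gene universe) with the binomial upper tail.
#' Rows are sorted by (p, set_id); no multiple-testing correction is
#' applied by default (set `add_q = TRUE` for a Benjamini-Hochberg
#' column).
#'
#' @param table A `correlation_table`.
#' @param collection A `gene_set_collection`.
#' @param k Pool size (default 1000).
#' @param add_q Add a BH-adjusted `q` column (default FALSE).
#' @return data.frame (`set_id`, `name`, `found`, `expected`, `p`,
#'   `mu`), one row per set with a non-zero mu; zero-mu sets are
#'   reported in attribute `"skipped"`.
#' @export
ora_table <- function(table, collection, k = 1000L, add_q = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- table$feature_id
  pool <- top_pool(table, k)
  mu <- set_frequency_mu(collection, universe)
  keep <- names(mu)[mu > 0]
  rows <- lapply(keep, function(id) {
    found <- length(intersect(collection$sets[[id]], pool))
    data.frame(set_id = id, name = unname(collection$desc[id]), found = found,
               expected = expected_min_count(mu[[id]], k),
               p = binomial_tail_p(found, k, mu[[id]]), mu = mu[[id]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no set overlaps the universe")
  if (add_q) out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- setdiff(names(mu), keep)
  out
}
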