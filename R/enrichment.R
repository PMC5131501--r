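#' Rank genes by their correlation to the target
#'
#' Turns a correlation table into a ranked list for running-sum
#' enrichment: either by signed r descending (default; the alignment a
#' set is "scanned through") or by |r| descending. Ties are broken
#' lexicographically by feature id.
#'
#' @param table A `correlation_table`.
#' @param direction `"r_desc"` or `"abs_r_desc"`.
#' @return A `ranked_list`: list with `feature_id`, `score` (the r
#'   values, aligned) and `direction`.
#' @export
rank_by_correlation <- function(table, direction = c("r_desc", "abs_r_desc")) {
  direction <- match.arg(direction)
  stopifnot(inherits(table, "correlation_table"))
  ord <- switch(direction,
                r_desc = order(-table$r, table$feature_id),
                abs_r_desc = order(-abs(table$r), table$feature_id))
  structure(list(feature_id = table$feature_id[ord], score = table$r[ord],
                 direction = direction),
            class = "ranked_list")
}

# Weights along the ranked list: |score|^exponent. exponent = 0 gives
# equal weights (0^0 == 1 in R, so zero scores are safe).
.rank_weights <- function(score, weight_exponent) abs(score)^weight_exponent

# Enrichment score from sorted hit positions, without materialising the
# full running sum: between hits the running difference only decreases,
# so its maximum is attained at a hit position (or is the final value,
# exactly 0). Used for permutation draws.
.es_from_positions <- function(pos, w, N) {
  pos <- sort.int(pos)
  nh <- length(pos)
  cw <- cumsum(w[pos])
  W <- cw[nh]
  if (W == 0) stop("zero total hit weight")
  max(0, max(cw / W - (pos - seq_len(nh)) / (N - nh)))
}

# Batched permutation ES: n_perm draws of nh positions without
# replacement from pool_pos, scored against weights w over N ranks.
# One radix sort covers every draw (column-major keys), and the running
# maxima are accumulated row-wise, so the cost per draw is O(nh) with
# vectorised constants. Value-identical to .es_from_positions on each
# draw, and consumes the RNG exactly like a sample.int() loop.
.null_es_batch <- function(pool_pos, nh, w, N, n_perm) {
  n_pool <- length(pool_pos)
  idx <- vapply(seq_len(n_perm),
                function(i) sample.int(n_pool, nh), integer(nh))
  pos <- matrix(pool_pos[idx], nrow = nh)
  # sort each column with one radix pass: column index dominates the key
  o <- order(rep(seq_len(n_perm), each = nh) * (N + 1) + as.vector(pos))
  pos <- matrix(as.vector(pos)[o], nrow = nh)
  cwv <- cumsum(w[as.vector(pos)])
  ends <- seq.int(nh, nh * n_perm, by = nh)
  off <- c(0, cwv[ends[-n_perm]])
  cw <- cwv - rep(off, each = nh)
  W <- cwv[ends] - off
  if (any(W == 0)) stop("zero total hit weight")
  ph <- cw / rep(W, each = nh)
  pm <- (as.vector(pos) - rep(seq_len(nh), n_perm)) / (N - nh)
  d <- matrix(ph - pm, nrow = nh)
  es <- rep(0, n_perm)
  for (k in seq_len(nh)) es <- pmax(es, d[k, ])
  es
}

# As above but also the minimum of the running difference, which is
# attained just before a hit (where the preceding miss stretch bottoms
# out) or at the final rank (exactly 0).
.es_min_from_positions <- function(pos, w, N) {
  pos <- sort.int(pos)
  nh <- length(pos)
  cw <- cumsum(w[pos])
  W <- cw[nh]
  if (W == 0) stop("zero total hit weight")
  k <- seq_len(nh)
  ph_at <- cw / W
  pm_at <- (pos - k) / (N - nh)
  es <- max(0, max(ph_at - pm_at))
  ph_before <- c(0, ph_at[-nh])
  valid <- pos > 1L # a hit at rank 1 has no 'before' point
  min_d <- min(0, (ph_before - pm_at)[valid])
  c(es, min_d)
}

#' Running-sum enrichment score of a gene set
#'
#' Walks the ranked list tallying set members (hits) against non-members
#' (misses): at rank i, `P_hit(i)` is the normalized cumulative hit
#' weight (weight = |score|^`weight_exponent`; exponent 0 gives equal
#' weights 1/Nh) and `P_miss(i)` the cumulative miss count over
#' `N - Nh`. The enrichment score is the maximum of `P_hit - P_miss`
#' and `min_deficit` its minimum; the running sum always ends at
#' exactly 0.
#'
#' @param ranked A `ranked_list`.
#' @param members Character vector of set members (intersected with the
#'   ranked universe; the intersection must be non-empty and proper).
#' @param weight_exponent Exponent on |score| for hit weights
#'   (default 1; 0 for the unweighted statistic).
#' @return List with `running` (length-N numeric), `es`, `min_deficit`
#'   and `nh`.
#' @export
running_score <- function(ranked, members, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  N <- length(ranked$feature_id)
  hit <- ranked$feature_id %in% members
  nh <- sum(hit)
  if (nh == 0L) stop("empty set: no members in the ranked universe")
  if (nh == N) stop("degenerate set: every ranked gene is a member")
  w <- .rank_weights(ranked$score, weight_exponent)
  hw <- ifelse(hit, w, 0)
  W <- sum(hw)
  if (W == 0) stop("zero total hit weight")
  running <- cumsum(hw) / W - cumsum(!hit) / (N - nh)
  list(running = running, es = max(running), min_deficit = min(running), nh = nh)
}

#' Permutation null for the enrichment score
#'
#' Draws `n_perm` random gene sets of size `nh` uniformly without
#' replacement from the ranked universe, computes the enrichment score
#' of each with the same weighting, and returns the null mean, standard
#' deviation (n - 1) and the samples themselves (e.g. for a null
#' histogram).
#'
#' @param ranked A `ranked_list`.
#' @param nh Set size to draw (1 <= nh < N).
#' @param n_perm Number of draws (default 1000).
#' @param seed Optional seed; identical seeds give identical nulls.
#' @param weight_exponent Exponent on |score| (default 1).
#' @return List with `null_mean`, `null_sd`, `null_samples`.
#' @export
permutation_null <- function(ranked, nh, n_perm = 1000L, seed = NULL,
                             weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  N <- length(ranked$feature_id)
  if (nh < 1L || nh >= N) stop("need 1 <= nh < N")
  w <- .rank_weights(ranked$score, weight_exponent)
  samples <- with_seed(seed, .null_es_batch(seq_len(N), nh, w, N, n_perm))
  list(null_mean = mean(samples), null_sd = stats::sd(samples),
       null_samples = samples)
}

#' p-value of an enrichment score against its permutation null
#'
#' `normal_approx` (the default) is the upper-tail probability of a
#' normal distribution with the null mean and sd at the observed score;
#' `empirical` is the add-one permutation p: one plus the number of
#' null draws at or above `es`, divided by `n_perm + 1`.
#'
#' @param es Observed enrichment score.
#' @param null_mean,null_sd Null moments (from [permutation_null()]).
#' @param mode `"normal_approx"` or `"empirical"`.
#' @param null_samples Null draws; required for `"empirical"`.
#' @return p-value in (0, 1].
#' @export
set_p_value <- function(es, null_mean, null_sd,
                        mode = c("normal_approx", "empirical"),
                        null_samples = NULL) {
  mode <- match.arg(mode)
  if (mode == "normal_approx") {
    if (is.na(null_sd) || null_sd <= 0) stop("degenerate null: sd is zero")
    p <- stats::pnorm(es, mean = null_mean, sd = null_sd, lower.tail = FALSE)
    max(min(p, 1), .p_floor)
  } else {
    if (is.null(null_samples)) stop("empirical mode needs null_samples")
    (1 + sum(null_samples >= es)) / (length(null_samples) + 1)
  }
}

#' Scan a gene-set collection against one correlation ranking
#'
#' Computes the running-sum enrichment score of every set (intersected
#' with the ranked universe; empty or saturating intersections are
#' skipped with a message), a gene-set permutation null per set, a
#' p-value, and Benjamini-Hochberg q over the scan.
#'
#' @param table A `correlation_table`.
#' @param collection A `gene_set_collection`.
#' @param n_perm Permutations per set (default 1000).
#' @param seed Optional seed for the permutation stream.
#' @param weight_exponent Exponent on |score| (default 1).
#' @param direction Ranking direction (default `"r_desc"`).
#' @param p_mode p-value mode (see [set_p_value()]).
#' @return data.frame (`set_id`, `name`, `nh`, `es`, `min_deficit`,
#'   `null_mean`, `null_sd`, `p`, `q`) sorted by es descending; skipped
#'   set ids in attribute `"skipped"`.
#' @export
pathway_scan <- function(table, collection, n_perm = 1000L, seed = NULL,
                         weight_exponent = 1, direction = "r_desc",
                         p_mode = "normal_approx") {
  stopifnot(inherits(collection, "gene_set_collection"))
  ranked <- rank_by_correlation(table, direction)
  N <- length(ranked$feature_id)
  w <- .rank_weights(ranked$score, weight_exponent)
  with_seed(seed, {
    rows <- list()
    skipped <- character()
    for (id in names(collection$sets)) {
      members <- intersect(collection$sets[[id]], ranked$feature_id)
      if (length(members) == 0L || length(members) == N) {
        message("pathway_scan: skipping set '", id, "' (empty or saturating intersection)")
        skipped <- c(skipped, id)
        next
      }
      rs <- running_score(ranked, members, weight_exponent)
      null <- .null_es_batch(seq_len(N), rs$nh, w, N, n_perm)
      nm <- mean(null); ns <- stats::sd(null)
      p <- set_p_value(rs$es, nm, ns, mode = p_mode, null_samples = null)
      rows[[id]] <- data.frame(set_id = id, name = unname(collection$desc[id]),
                               nh = rs$nh, es = rs$es, min_deficit = rs$min_deficit,
                               null_mean = nm, null_sd = ns, p = p,
                               stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no set overlaps the ranked universe")
    out$q <- bh_adjust(out$p)
    out <- out[order(-out$es, out$set_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
  })
}

#' Enrichment of one gene set across many probe genes
#'
#' For each probe gene, builds that probe's correlation ranking (the
#' probe itself, r = 1, removed), scores the given set against it, and
#' derives a permutation p; q is Benjamini-Hochberg across probes. This
#' asks which genes' co-expression neighbourhoods are enriched for the
#' set.
#'
#' @param m Expression matrix (filtered).
#' @param members Character vector: the gene set.
#' @param probe_genes Probe genes, each present in `m`.
#' @param n_perm Permutations per probe (default 1000).
#' @param seed Optional seed.
#' @param weight_exponent Exponent on |score| (default 1).
#' @param direction Ranking direction (default `"r_desc"`).
#' @param p_mode p-value mode (see [set_p_value()]).
#' @return data.frame (`probe`, `nh`, `es`, `null_mean`, `null_sd`,
#'   `p`, `q`), one row per probe, in probe order.
#' @export
gene_scan_for_set <- function(m, members, probe_genes, n_perm = 1000L,
                              seed = NULL, weight_exponent = 1,
                              direction = "r_desc", p_mode = "normal_approx") {
  validate_expression_matrix(m)
  missing <- setdiff(probe_genes, rownames(m))
  if (length(missing)) stop("probe(s) not found: ", paste(missing, collapse = ", "))
  with_seed(seed, {
    rows <- lapply(probe_genes, function(probe) {
      tab <- build_correlation_table(m, probe, sort = "unsorted")
      ranked <- rank_by_correlation(tab, direction)
      set_here <- intersect(members, ranked$feature_id)
      if (!length(set_here)) stop("set has no members in the ranked universe of probe ", probe)
      rs <- running_score(ranked, set_here, weight_exponent)
      w <- .rank_weights(ranked$score, weight_exponent)
      N <- length(ranked$feature_id)
      null <- .null_es_batch(seq_len(N), rs$nh, w, N, n_perm)
      nm <- mean(null); ns <- stats::sd(null)
      data.frame(probe = probe, nh = rs$nh, es = rs$es, null_mean = nm,
                 null_sd = ns,
                 p = set_p_value(rs$es, nm, ns, mode = p_mode, null_samples = null),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- bh_adjust(out$p)
    rownames(out) <- NULL
    out
  })
}
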