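# Build a ranked_list directly from ids and scores (already ordered).
mk_ranked <- function(ids, scores) {
  tab <- data.frame(feature_id = ids, r = scores, p = 0.5, n = 10,
                    stringsAsFactors = FALSE)
  class(tab) <- c("correlation_table", "data.frame")
  attr(tab, "target_id") <- "t"
  rank_by_correlation(tab, "r_desc")
}

test_that("ranking is stable, direction-aware and lexicographically tie-broken", {
  tab <- data.frame(feature_id = c("b", "a", "c", "d"),
                    r = c(0.5, 0.5, -0.9, 0.1), p = 0.5, n = 10,
                    stringsAsFactors = FALSE)
  class(tab) <- c("correlation_table", "data.frame")
  rd <- rank_by_correlation(tab, "r_desc")
  expect_identical(rd$feature_id, c("a", "b", "d", "c"))
  expect_true(all(diff(rd$score) <= 0))
  ra <- rank_by_correlation(tab, "abs_r_desc")
  expect_identical(ra$feature_id[1], "c")
  expect_true(all(diff(abs(ra$score)) <= 0))
  # determinism
  expect_identical(rank_by_correlation(tab, "r_desc"), rd)
})

test_that("running score hits its boundary values and always ends at zero", {
  ids <- sprintf("g%02d", 1:20)
  scores <- seq(1, -1, length.out = 20)
  ranked <- mk_ranked(ids, scores)
  # all members on top: es = 1 for any weighting
  for (wexp in c(0, 1, 2)) {
    rs <- running_score(ranked, ids[1:5], weight_exponent = wexp)
    expect_equal(rs$es, 1)
    expect_equal(rs$running[length(ids)], 0)
  }
  # all members at the bottom: es = 0, attained at the final rank
  rs_bot <- running_score(ranked, ids[16:20], weight_exponent = 0)
  expect_equal(rs_bot$es, 0)
  expect_equal(rs_bot$min_deficit, -1)
  # errors: empty and saturating sets
  expect_error(running_score(ranked, c("nope")), "empty set")
  expect_error(running_score(ranked, ids), "degenerate set")
})

test_that("running score equals the brute-force prefix oracle on random instances", {
  set.seed(202)
  for (i in 1:300) {
    N <- sample(5:50, 1)
    ids <- sprintf("g%03d", 1:N)
    scores <- sort(rnorm(N), decreasing = TRUE)
    nh <- sample(seq_len(N - 1), 1)
    members <- sample(ids, nh)
    wexp <- sample(c(0, 1, 2), 1)
    ranked <- mk_ranked(ids, scores)
    got <- running_score(ranked, members, weight_exponent = wexp)
    want <- oracle_running(ids, scores, members, wexp)
    expect_equal(got$running, want$running, tolerance = 1e-12)
    expect_equal(got$es, want$es, tolerance = 1e-12)
    expect_equal(got$min_deficit, want$min_deficit, tolerance = 1e-12)
    # the position-only fast path agrees with the full running sum
    pos <- which(ids %in% members)
    w <- abs(scores)^wexp
    expect_equal(coexcis:::.es_from_positions(pos, w, N), max(0, want$es),
                 tolerance = 1e-12)
    em <- coexcis:::.es_min_from_positions(pos, w, N)
    expect_equal(em[1], max(0, want$es), tolerance = 1e-12)
    expect_equal(em[2], min(0, want$min_deficit), tolerance = 1e-12)
  }
})

test_that("the permutation null is reproducible, positive-mean and boundary-safe", {
  ids <- sprintf("g%03d", 1:100)
  ranked <- mk_ranked(ids, sort(rnorm(100), decreasing = TRUE))
  a <- permutation_null(ranked, nh = 10, n_perm = 200, seed = 9)
  b <- permutation_null(ranked, nh = 10, n_perm = 200, seed = 9)
  expect_identical(a, b)
  # null mean strictly positive across random configurations (the max of
  # a walk that ends at zero)
  set.seed(31)
  for (i in 1:100) {
    N <- sample(10:80, 1)
    rk <- mk_ranked(sprintf("h%03d", 1:N), sort(rnorm(N), decreasing = TRUE))
    nh <- sample(seq_len(N - 1), 1)
    nul <- permutation_null(rk, nh, n_perm = 30)
    expect_gt(nul$null_mean, 0)
  }
  # nh = N - 1 nearly saturates the universe yet stays well defined
  sat <- permutation_null(ranked, nh = 99, n_perm = 50, seed = 1)
  expect_true(all(sat$null_samples >= 0 & sat$null_samples <= 1))
  expect_error(permutation_null(ranked, nh = 100), "nh < N")
})

test_that("p-values respond correctly in both modes", {
  expect_equal(set_p_value(0.4, 0.4, 0.1), 0.5)
  expect_lt(set_p_value(0.9, 0.4, 0.1), 1e-6)
  nulls <- seq(0.1, 0.5, length.out = 99)
  expect_equal(set_p_value(0.99, mean(nulls), sd(nulls), mode = "empirical",
                           null_samples = nulls), 1 / 100)
  expect_error(set_p_value(0.5, 0.4, 0), "degenerate null")
  # the two modes agree for moderate z on a simulated null
  set.seed(77)
  ranked <- mk_ranked(sprintf("g%03d", 1:150), sort(rnorm(150), decreasing = TRUE))
  nul <- permutation_null(ranked, nh = 12, n_perm = 2000, seed = 4)
  es <- quantile(nul$null_samples, 0.8)
  p_n <- set_p_value(es, nul$null_mean, nul$null_sd)
  p_e <- set_p_value(es, nul$null_mean, nul$null_sd, mode = "empirical",
                     null_samples = nul$null_samples)
  expect_lt(abs(p_n - p_e), 0.02)
})

test_that("empirical set p-values are uniform under a random-member null", {
  set.seed(55)
  N <- 200
  reps <- 200
  pvals <- numeric(reps)
  for (i in seq_len(reps)) {
    ranked <- mk_ranked(sprintf("g%03d", 1:N), sort(rnorm(N), decreasing = TRUE))
    members <- sample(ranked$feature_id, 10)
    rs <- running_score(ranked, members)
    nul <- permutation_null(ranked, 10, n_perm = 200)
    pvals[i] <- set_p_value(rs$es, nul$null_mean, nul$null_sd,
                            mode = "empirical", null_samples = nul$null_samples)
  }
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("pathway scans recover the planted set and satisfy BH properties", {
  spec <- small_spec(n_samples_per_condition = 200L)
  normal <- generate_expression_condition(spec, "normal")
  tab <- suppressMessages(build_correlation_table(filter_low_expression(normal),
                                                  spec$target_gene))
  sets <- generate_gene_sets(spec)
  scan <- suppressMessages(pathway_scan(tab, sets, n_perm = 200, seed = 12))
  expect_identical(scan$set_id[1], spec$planted_set_id)
  expect_lte(nrow(scan), length(sets$sets))
  expect_true(all(scan$q >= scan$p))
  expect_equal(scan$q, oracle_bh(scan$p), tolerance = 1e-12)
  # determinism under fixed seed
  scan2 <- suppressMessages(pathway_scan(tab, sets, n_perm = 200, seed = 12))
  expect_equal(scan, scan2, ignore_attr = TRUE)
})

test_that("gene scans rank member probes above random probes for the planted set", {
  spec <- small_spec(n_samples_per_condition = 100L)
  normal <- generate_expression_condition(spec, "normal")
  nf <- suppressMessages(filter_low_expression(normal))
  members <- c(spec$target_gene, sprintf("MOD%02d", seq_len(spec$module_size - 1)))
  members <- intersect(members, rownames(nf))
  set.seed(8)
  random_probes <- sample(setdiff(rownames(nf), members), 8)
  res <- gene_scan_for_set(nf, members, c(members, random_probes),
                           n_perm = 100, seed = 21)
  es_members <- res$es[res$probe %in% members]
  es_random <- res$es[res$probe %in% random_probes]
  expect_gt(median(es_members), median(es_random))
  # single probe: q equals p
  one <- gene_scan_for_set(nf, members, members[1], n_perm = 100, seed = 3)
  expect_equal(one$q, one$p)
  # deterministic under fixed seed
  one2 <- gene_scan_for_set(nf, members, members[1], n_perm = 100, seed = 3)
  expect_equal(one, one2)
  expect_error(gene_scan_for_set(nf, members, "NOPE"), "not found")
})
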