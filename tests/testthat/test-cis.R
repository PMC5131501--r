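test_that("cis pools split a chromosome at the window boundary", {
  ann <- data.frame(
    gene = c("TGT", "NEAR", "FAR", "ELSEWHERE", "EDGE", "N2", "N3", "N4", "N5"),
    chromosome = c("8", "8", "8", "2", "8", "8", "8", "8", "8"),
    cytoband = "8q11.1",
    tss_bp = c(5000000L, 5900000L, 6100000L, 5500000L, 6000000L,
               4500000L, 9000000L, 10000000L, 11000000L),
    stringsAsFactors = FALSE)
  universe <- setdiff(ann$gene, "TGT")
  pools <- build_cis_pools(ann, "TGT", universe = universe)
  expect_setequal(pools$gi, c("NEAR", "EDGE", "N2"))       # |d| <= 1 Mbp, closed
  expect_setequal(pools$go, c("FAR", "N3", "N4", "N5"))    # same chromosome, outside
  expect_false("ELSEWHERE" %in% c(pools$gi, pools$go))
  expect_false("TGT" %in% c(pools$gi, pools$go))
  expect_equal(pools$nh, 3)
  expect_length(intersect(pools$gi, pools$go), 0)
  # degenerate cases are named errors
  expect_error(build_cis_pools(ann, "TGT", window_bp = 1000L, universe = universe),
               "degenerate window")
  expect_error(build_cis_pools(ann, "NOPE", universe = universe), "not annotated")
  expect_error(build_cis_pools(ann, "TGT", window_bp = 3000000L, universe = universe),
               "insufficient null pool")
})

test_that("cis pools partition every synthetic chromosome correctly", {
  spec <- small_spec(n_genes = 400L)
  ann <- generate_annotations(spec)
  universe <- ann$gene
  for (probe in c(spec$target_gene, "CIS01", "G0018")) {
    pools <- build_cis_pools(ann, probe, universe = universe)
    chrom_p <- ann$chromosome[ann$gene == probe]
    same <- setdiff(ann$gene[ann$chromosome == chrom_p], probe)
    expect_setequal(c(pools$gi, pools$go), same)
    expect_length(intersect(pools$gi, pools$go), 0)
  }
})

test_that("a manually enriched neighbourhood yields es = 1 and a tiny p", {
  # gi genes occupy the top nh ranks by construction
  ids <- sprintf("g%03d", 1:120)
  r <- seq(0.95, -0.95, length.out = 120)
  tab <- data.frame(feature_id = ids, r = r, p = 0.5, n = 42,
                    stringsAsFactors = FALSE)
  class(tab) <- c("correlation_table", "data.frame")
  attr(tab, "target_id") <- "TGT"
  pools <- structure(list(target = "TGT", gi = ids[1:8], go = ids[9:108], nh = 8L),
                     class = "cis_pools")
  res <- cis_es_test(tab, pools, n_perm = 300, seed = 5)
  expect_equal(res$es, 1)
  expect_lt(res$p, 1e-6)
  # determinism and target mismatch guard
  res2 <- cis_es_test(tab, pools, n_perm = 300, seed = 5)
  expect_equal(res, res2)
  pools$target <- "OTHER"
  expect_error(cis_es_test(tab, pools, n_perm = 10), "does not match")
})

test_that("the tumor condition shows a stronger cis effect than normal", {
  # the artifact-scale restatement of the published normal/tumor ES contrast
  es_n <- es_t <- p_t <- numeric(5)
  for (i in 1:5) {
    spec <- small_spec(seed = 100L + i, n_genes = 400L,
                       n_samples_per_condition = 42L)
    ann <- generate_annotations(spec)
    st <- generate_paired_study(spec)
    suppressMessages({
      nf <- filter_low_expression(st$normal)
      tf <- filter_low_expression(st$tumor)
    })
    tabn <- build_correlation_table(nf, spec$target_gene)
    tabt <- build_correlation_table(tf, spec$target_gene)
    pn <- build_cis_pools(ann, spec$target_gene, universe = tabn$feature_id)
    pt <- build_cis_pools(ann, spec$target_gene, universe = tabt$feature_id)
    es_n[i] <- cis_es_test(tabn, pn, n_perm = 200, seed = 1)$es
    rest <- cis_es_test(tabt, pt, n_perm = 200, seed = 1)
    es_t[i] <- rest$es
    p_t[i] <- rest$p
  }
  expect_gt(mean(es_t), mean(es_n))
  # the planted cis block is detected in most tumor replicates
  expect_gte(mean(p_t < 0.05), 0.8)
})

test_that("genome-wide scans adjust with BH and report skipped probes", {
  spec <- small_spec(n_genes = 400L, n_samples_per_condition = 42L)
  ann <- generate_annotations(spec)
  tumor <- generate_expression_condition(spec, "tumor")
  tf <- suppressMessages(filter_low_expression(tumor))
  probes <- intersect(ann$gene[ann$chromosome == "1"], rownames(tf))[1:25]
  scan <- genomewide_cis_scan(tf, ann, n_perm = 100, seed = 2, probe_genes = probes)
  expect_equal(nrow(scan) + length(attr(scan, "skipped")), length(probes))
  expect_equal(scan$q, oracle_bh(scan$p), tolerance = 1e-12)
  expect_true(all(scan$q >= scan$p))
  expect_true(all(scan$p > 0 & scan$p < 1))
  # single-probe scan: q = p, and the scan's fast path reproduces
  # cis_es_test exactly (same null draws under the same seed)
  one <- genomewide_cis_scan(tf, ann, n_perm = 100, seed = 2,
                             probe_genes = spec$target_gene)
  expect_equal(one$q, one$p)
  tab <- build_correlation_table(tf, spec$target_gene)
  pools <- build_cis_pools(ann, spec$target_gene, universe = tab$feature_id)
  direct <- cis_es_test(tab, pools, n_perm = 100, seed = 2)
  expect_equal(one[, colnames(direct)], direct, ignore_attr = TRUE)
  # determinism
  one2 <- genomewide_cis_scan(tf, ann, n_perm = 100, seed = 2,
                              probe_genes = spec$target_gene)
  expect_equal(one, one2, ignore_attr = TRUE)
})

test_that("the planted cis block gives the target high power at n = 42", {
  # seeded replicates of the tumor condition; the test should reject at
  # alpha = 0.05 in at least 90% of them
  hits <- logical(60)
  for (i in seq_along(hits)) {
    spec <- small_spec(seed = 500L + i, n_genes = 400L,
                       n_samples_per_condition = 42L)
    ann <- generate_annotations(spec)
    tumor <- generate_expression_condition(spec, "tumor")
    tf <- suppressMessages(filter_low_expression(tumor))
    if (!spec$target_gene %in% rownames(tf)) next
    tab <- build_correlation_table(tf, spec$target_gene)
    pools <- build_cis_pools(ann, spec$target_gene, universe = tab$feature_id)
    hits[i] <- cis_es_test(tab, pools, n_perm = 200, seed = 1)$p < 0.05
  }
  expect_gte(mean(hits), 0.9)
})
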