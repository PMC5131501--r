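# Shared fixture builders. Everything is generated in code; no data files.

# Tiny hand-written expression matrix.
toy_matrix <- function() {
  m <- matrix(c(10, 20, 30,
                20, 40, 60,
                5, 1, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("GENEA", "GENEB", "GENEC"),
                              c("S1", "S2", "S3")))
  m
}

# Write an expression TSV from a matrix of strings/numbers (allows
# malformed fixtures).
write_raw_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Small synthetic spec used across tests; 200 genes on 5 chromosomes at
# the default human-like density.
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(seed = 11L, n_genes = 200L, n_samples_per_condition = 30L)
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}

# Independent brute-force running-sum oracle: builds the full P_hit and
# P_miss vectors rank by rank, no shortcuts shared with the package.
oracle_running <- function(ids, scores, members, wexp = 1) {
  hit <- ids %in% members
  w <- abs(scores)^wexp
  ph <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
  pm <- cumsum(ifelse(hit, 0, 1)) / sum(!hit)
  list(running = ph - pm, es = max(ph - pm), min_deficit = min(ph - pm))
}

# Independent BH step-up oracle (textbook construction).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[o[i]] <- min(q[o[i]], q[o[i + 1]])
  pmin(q, 1)
}

# Metadata table with n_normal normals and tumors for the first
# n_matched participant tags (plus optional extra tumors).
paired_metadata <- function(n_normal, n_matched, extra_tumors = 0) {
  tags <- sprintf("TCGA-XX-%04d", seq_len(n_normal))
  md <- data.frame(
    sample_id = c(paste0(tags, "-11"), paste0(tags[seq_len(n_matched)], "-01")),
    participant_tag = c(tags, tags[seq_len(n_matched)]),
    condition = c(rep("normal", n_normal), rep("tumor", n_matched)),
    stringsAsFactors = FALSE)
  if (extra_tumors > 0) {
    md <- rbind(md, data.frame(
      sample_id = paste0(tags[seq_len(extra_tumors)], "-01B"),
      participant_tag = tags[seq_len(extra_tumors)],
      condition = "tumor", stringsAsFactors = FALSE))
  }
  md
}
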