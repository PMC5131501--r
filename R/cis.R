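#' Build the cis (Gi) and control (Go) gene pools of a target
#'
#' Gi is the set of genes other than the target that lie on the
#' target's chromosome within `window_bp` of its TSS (closed interval
#' on |TSS difference|); Go is the same-chromosome remainder. Both are
#' intersected with the correlation universe (the features actually
#' ranked), and Nh = |Gi|. Strand is ignored for distances.
#'
#' @param annotations Annotation data.frame (`gene`, `chromosome`,
#'   `cytoband`, `tss_bp`).
#' @param target Target gene symbol; must be annotated.
#' @param window_bp Window half-width in bp (default 1,000,000).
#' @param universe Features present in the correlation table (the
#'   target itself need not be included).
#' @return A `cis_pools` list: `target`, `gi`, `go`, `nh`.
#' @export
build_cis_pools <- function(annotations, target, window_bp = 1000000L, universe) {
  ti <- match(target, annotations$gene)
  if (is.na(ti)) stop("target not annotated: ", target)
  chrom_t <- annotations$chromosome[ti]
  tss_t <- annotations$tss_bp[ti]
  same <- annotations[annotations$chromosome == chrom_t &
                        annotations$gene != target &
                        annotations$gene %in% universe, , drop = FALSE]
  in_window <- abs(same$tss_bp - tss_t) <= window_bp
  gi <- same$gene[in_window]
  go <- same$gene[!in_window]
  if (length(gi) == 0L) stop("degenerate window: no genes within ", window_bp, " bp of ", target)
  if (length(go) < length(gi)) {
    stop(sprintf("insufficient null pool: |Go| = %d < Nh = %d", length(go), length(gi)))
  }
  structure(list(target = target, gi = gi, go = go, nh = length(gi)),
            class = "cis_pools")
}

# Shared core, position-based: ES and min deficit of the gi positions in
# a ranked list of N weights, plus a null of n_perm ES values of nh
# positions drawn without replacement from the go positions, and the
# resulting p. Identical in value to running_score() on the same input
# (tested), but O(nh log nh) per evaluation instead of O(N).
.cis_es_core_pos <- function(gi_pos, go_pos, w, N, n_perm, p_mode) {
  nh <- length(gi_pos)
  obs <- .es_min_from_positions(gi_pos, w, N)
  null <- .null_es_batch(go_pos, nh, w, N, n_perm)
  nm <- mean(null)
  ns <- stats::sd(null)
  list(es = obs[[1L]], min_deficit = obs[[2L]], nh = nh,
       null_mean = nm, null_sd = ns,
       p = set_p_value(obs[[1L]], nm, ns, mode = p_mode, null_samples = null))
}

#' Chromosomal cis-effect enrichment test for one target
#'
#' Scores the target's 1-Mbp TSS neighbourhood (Gi) against the
#' target's own correlation ranking (target removed), builds a null
#' from `n_perm` draws of Nh genes taken without replacement from the
#' same-chromosome control pool (Go), and reports the one-sided
#' upper-tail normal-approximation p (the enrichment direction).
#'
#' @param table A `correlation_table` whose target equals
#'   `pools$target` (the target row is already absent).
#' @param pools A `cis_pools` from [build_cis_pools()].
#' @param n_perm Number of null draws (default 1000).
#' @param seed Optional seed.
#' @param weight_exponent Exponent on |score| (default 1).
#' @param direction Ranking direction (default `"r_desc"`).
#' @param p_mode p-value mode (see [set_p_value()]).
#' @return One-row data.frame (`target`, `nh`, `es`, `min_deficit`,
#'   `null_mean`, `null_sd`, `p`).
#' @export
cis_es_test <- function(table, pools, n_perm = 1000L, seed = NULL,
                        weight_exponent = 1, direction = "r_desc",
                        p_mode = "normal_approx") {
  stopifnot(inherits(pools, "cis_pools"))
  if (!identical(attr(table, "target_id"), pools$target)) {
    stop("correlation table target (", attr(table, "target_id"),
         ") does not match pools target (", pools$target, ")")
  }
  ranked <- rank_by_correlation(table, direction)
  w <- .rank_weights(ranked$score, weight_exponent)
  gi_pos <- match(pools$gi, ranked$feature_id)
  go_pos <- match(pools$go, ranked$feature_id)
  if (anyNA(gi_pos) || anyNA(go_pos)) {
    stop("pool gene(s) missing from the correlation table universe")
  }
  res <- with_seed(seed, .cis_es_core_pos(gi_pos, go_pos, w,
                                          length(ranked$feature_id), n_perm, p_mode))
  data.frame(target = pools$target, nh = res$nh, es = res$es,
             min_deficit = res$min_deficit, null_mean = res$null_mean,
             null_sd = res$null_sd, p = res$p, stringsAsFactors = FALSE)
}

#' Genome-wide chromosomal cis-effect scan
#'
#' Runs the cis enrichment test with every probe gene as the target (a
#' fresh correlation ranking per probe, the probe removed from its own
#' list) and adjusts the p-values across the scan by
#' Benjamini-Hochberg. Probes whose pools fail a precondition (no
#' neighbour in the window, or a control pool smaller than Nh) are
#' reported in the `"skipped"` attribute, never silently dropped.
#'
#' @param m Expression matrix (filtered).
#' @param annotations Annotation data.frame.
#' @param window_bp Window half-width in bp (default 1,000,000).
#' @param n_perm Null draws per probe (default 1000).
#' @param seed Optional seed.
#' @param probe_genes Probes to scan (default: every annotated gene
#'   present in `m`).
#' @param weight_exponent Exponent on |score| (default 1).
#' @param p_mode p-value mode (see [set_p_value()]).
#' @return data.frame (`target`, `nh`, `es`, `min_deficit`,
#'   `null_mean`, `null_sd`, `p`, `q`), one row per scanned probe,
#'   sorted by p ascending; skipped probes (with reasons) in attribute
#'   `"skipped"`.
#' @export
genomewide_cis_scan <- function(m, annotations, window_bp = 1000000L,
                                n_perm = 1000L, seed = NULL,
                                probe_genes = NULL, weight_exponent = 1,
                                p_mode = "normal_approx") {
  validate_expression_matrix(m)
  universe <- intersect(rownames(m), annotations$gene)
  if (is.null(probe_genes)) probe_genes <- universe
  missing <- setdiff(probe_genes, universe)
  if (length(missing)) {
    stop("probe(s) not annotated or absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  sub <- m[universe, , drop = FALSE]
  if (any(apply(sub, 1L, stats::sd) == 0)) stop("degenerate input: constant vector")
  big_r <- stats::cor(t(sub)) # all pairwise correlations, one pass
  ann <- annotations[match(universe, annotations$gene), , drop = FALSE]
  G <- length(universe)
  lex <- rank(universe, ties.method = "first") # numeric lexicographic tie-break key
  # pools as integer indices into `universe`, computed once per probe
  chrom_of <- ann$chromosome
  tss_of <- ann$tss_bp
  pool_idx <- function(pi) {
    same <- which(chrom_of == chrom_of[pi])
    same <- same[same != pi]
    inw <- abs(tss_of[same] - tss_of[pi]) <= window_bp
    list(gi = same[inw], go = same[!inw])
  }
  with_seed(seed, {
    rows <- vector("list", length(probe_genes))
    names(rows) <- probe_genes
    skipped <- character()
    posof <- integer(G) # scratch: rank position of each universe index
    for (probe in probe_genes) {
      pi <- match(probe, universe)
      pools <- pool_idx(pi)
      if (length(pools$gi) == 0L) {
        skipped[probe] <- sprintf("degenerate window: no genes within %d bp", window_bp)
        next
      }
      if (length(pools$go) < length(pools$gi)) {
        skipped[probe] <- sprintf("insufficient null pool: |Go| = %d < Nh = %d",
                                  length(pools$go), length(pools$gi))
        next
      }
      r <- big_r[, pi][-pi]
      ord <- order(-r, lex[-pi])
      w <- abs(r[ord])^weight_exponent
      # positions in the probe-removed ranking, by original index
      shift <- c(seq_len(pi - 1L), if (pi < G) seq.int(pi + 1L, G))
      posof[shift[ord]] <- seq_len(G - 1L)
      res <- .cis_es_core_pos(posof[pools$gi], posof[pools$go], w, G - 1L,
                              n_perm, p_mode)
      rows[[probe]] <- data.frame(target = probe, nh = res$nh, es = res$es,
                                  min_deficit = res$min_deficit,
                                  null_mean = res$null_mean, null_sd = res$null_sd,
                                  p = res$p, stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) stop("every probe was skipped")
    out <- do.call(rbind, rows)
    out$q <- bh_adjust(out$p)
    out <- out[order(out$p, out$target), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
  })
}
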