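#' Convert cytoband strings to scalar plot coordinates
#'
#' A band `ApB.N` (p arm) maps to `A - B.N/100` and `AqB.N` (q arm) to
#' `A + B.N/100`; for example `8p11.2` gives 7.888 and `8q11.2` gives
#' 8.112. X and Y map to chromosome number 23 (one combined column).
#' Bands without a sub-band decimal (`8q13`) read `B.N = 13`, giving
#' 8.13. Multi-digit sub-bands (`12p13.31`) use the full decimal,
#' 12 - 13.31/100 = 11.8669 -- consistent with the formula as written,
#' even though it makes 13.31 sort past 13.9 within an arm.
#'
#' @param band Character vector of cytoband strings
#'   (`<chrom><p|q><band>[.<sub-band>]`).
#' @return Numeric vector of float coordinates. Within one arm the
#'   coordinate is strictly monotone in the band number (decreasing
#'   along p, increasing along q).
#' @export
cytoband_to_float <- function(band) {
  m <- regmatches(band, regexec("^([0-9]{1,2}|XY|X|Y)([pq])([0-9]+(?:\\.[0-9]+)?)$", band))
  vapply(seq_along(band), function(i) {
    f <- m[[i]]
    if (length(f) != 4L) stop("unparseable cytoband string: '", band[i], "'")
    a <- if (f[2L] %in% c("X", "Y", "XY")) 23 else as.numeric(f[2L])
    bn <- as.numeric(f[4L])
    if (f[3L] == "p") a - bn / 100 else a + bn / 100
  }, numeric(1))
}

#' Top k features by absolute correlation
#'
#' The k features with the largest |r| in a correlation table; ties at
#' the boundary are broken lexicographically by feature id, so the
#' output has size exactly k and is reproducible.
#'
#' @param table A `correlation_table`.
#' @param k Number of features to keep (default 500).
#' @return Character vector of k feature ids, in decreasing |r| order.
#' @export
top_k_by_abs_r <- function(table, k = 500L) {
  stopifnot(inherits(table, "correlation_table"))
  if (k > nrow(table)) stop(sprintf("k = %d exceeds table size %d", k, nrow(table)))
  if (k < 1L) stop("k must be >= 1")
  ord <- order(-abs(table$r), table$feature_id)
  table$feature_id[ord[seq_len(k)]]
}

#' Chromosome-coordinate points for the top correlated genes
#'
#' Pools the k genes with the highest |r| and maps each onto its
#' cytoband float coordinate, producing the plot-ready (cytoband, r)
#' point set used to visualise chromosomal concentration of
#' co-expression.
#'
#' @param table A `correlation_table`.
#' @param annotations Annotation data.frame covering every top-k gene.
#' @param k Number of top-|r| genes to map (default 500).
#' @param y `"r"` (signed, default) or `"abs_r"` for the y value.
#' @return data.frame (`feature_id`, `cytoband`, `chrom_float`, `r`),
#'   one row per top-k gene. p-arm points satisfy `chrom_float < A` and
#'   q-arm points `chrom_float > A` for chromosome number A.
#' @export
build_cytoband_points <- function(table, annotations, k = 500L, y = c("r", "abs_r")) {
  y <- match.arg(y)
  top <- top_k_by_abs_r(table, k)
  idx <- match(top, annotations$gene)
  if (anyNA(idx)) {
    stop("missing annotation for gene(s): ",
         paste(utils::head(top[is.na(idx)], 5), collapse = ", "))
  }
  r <- table$r[match(top, table$feature_id)]
  data.frame(feature_id = top,
             cytoband = annotations$cytoband[idx],
             chrom_float = cytoband_to_float(annotations$cytoband[idx]),
             r = if (y == "r") r else abs(r),
             stringsAsFactors = FALSE)
}
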