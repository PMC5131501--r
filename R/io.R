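#' Read a gene-by-sample expression table
#'
#' Reads a tab-separated expression table whose first column (named
#' `gene`) holds feature identifiers and whose remaining columns are
#' samples, and returns a validated numeric matrix (features in rows).
#' Values are normalized expression levels (RSEM-like, dimensionless)
#' and must be finite and non-negative; missing cells are not permitted
#' in this dialect (absence must be encoded as 0 upstream).
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with feature rownames and sample colnames, in
#'   file order.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a 'gene' column plus at least one sample column")
  ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate feature identifier(s): ", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample identifier(s): ", paste(unique(dup), collapse = ", "))
  m <- matrix(NA_real_, nrow(df), length(sample_ids), dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing value at row '%s', column '%s'",
                   ids[bad[1L]], sample_ids[j]))
    }
    m[, j] <- num
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative value at row '%s', column '%s'",
                 ids[neg[1L, 1L]], sample_ids[neg[1L, 2L]]))
  }
  validate_expression_matrix(m)
  m
}

#' Validate an expression matrix
#'
#' Checks the invariants every downstream statistic relies on: unique
#' feature and sample identifiers, and finite non-negative values.
#'
#' @param m Numeric matrix, features in rows, samples in columns.
#' @return `m`, invisibly; stops with an informative error otherwise.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) stop("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate feature identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
  if (any(!is.finite(m))) stop("expression values must be finite")
  if (any(m < 0)) stop("expression values must be non-negative")
  invisible(m)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]; numbers are written with 15
#' significant digits so a write/read round trip reproduces values to
#' within printed precision, and output is byte-identical across runs.
#'
#' @param m Expression matrix.
#' @param path Output path.
#' @export
write_expression_table <- function(m, path) {
  validate_expression_matrix(m)
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.15g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read a gene annotation table
#'
#' Expects tab-separated columns `gene`, `chromosome`, `cytoband`,
#' `tss_bp` (1-based transcription start position in base pairs).
#'
#' @param path Path to a TSV file.
#' @return data.frame with one row per gene.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", "chromosome", "cytoband", "tss_bp")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene)) stop("duplicate gene in annotation table")
  df$chromosome <- as.character(df$chromosome)
  df$tss_bp <- as.integer(df$tss_bp)
  if (any(is.na(df$tss_bp)) || any(df$tss_bp < 1L)) stop("tss_bp must be a positive integer")
  df[need]
}

#' Write a gene annotation table
#' @param ann Annotation data.frame (`gene`, `chromosome`, `cytoband`, `tss_bp`).
#' @param path Output path.
#' @export
write_annotation_table <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `participant_tag`, `condition`
#' (`normal` or `tumor`), followed by free attribute columns such as
#' anatomical site or smoking history.
#'
#' @param path Path to a TSV file.
#' @return data.frame with one row per sample.
#' @export
read_metadata_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "participant_tag", "condition")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(df$condition), c("normal", "tumor"))
  if (length(bad)) stop("condition must be 'normal' or 'tumor'; found: ", paste(bad, collapse = ", "))
  df
}

#' Write sample metadata
#' @param md Metadata data.frame.
#' @param path Output path.
#' @export
write_metadata_table <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated as
#' `set_id<TAB>description<TAB>member1<TAB>member2...`. Duplicate
#' members within a line are collapsed (set semantics).
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   character vectors) and `desc` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop(sprintf("GMT line %d has fewer than 3 fields", i))
    id <- f[1L]
    if (id %in% names(sets)) stop("duplicate set id: ", id)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("GMT line %d defines an empty set", i))
    sets[[id]] <- members
    desc[id] <- f[2L]
  }
  structure(list(sets = sets, desc = desc), class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#' @param collection A `gene_set_collection` (see [read_gmt()]).
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$desc[[id]], collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection with %d sets (sizes %d-%d)\n",
              length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Subset an expression matrix by sample attributes
#'
#' Restricts the matrix to the samples whose metadata attributes all
#' equal the given values (e.g. `site = "oral cavity"`). The feature
#' list and retained values are untouched.
#'
#' @param m Expression matrix.
#' @param metadata Metadata data.frame (see [read_metadata_table()]);
#'   must cover every sample in `m`.
#' @param ... Named attribute constraints, each `column = value`.
#' @return Expression matrix restricted to the matching samples, column
#'   order preserved.
#' @export
subset_samples <- function(m, metadata, ...) {
  validate_expression_matrix(m)
  missing_md <- setdiff(colnames(m), metadata$sample_id)
  if (length(missing_md)) {
    stop("sample(s) absent from metadata: ", paste(utils::head(missing_md, 5), collapse = ", "))
  }
  constraints <- list(...)
  if (length(constraints) && is.null(names(constraints))) stop("constraints must be named")
  keep <- metadata$sample_id
  for (col in names(constraints)) {
    if (!col %in% colnames(metadata)) stop("unknown metadata column: ", col)
    keep <- intersect(keep, metadata$sample_id[metadata[[col]] %in% constraints[[col]]])
  }
  cols <- colnames(m)[colnames(m) %in% keep]
  if (!length(cols)) stop("zero samples matched the constraints")
  m[, cols, drop = FALSE]
}

#' Extract participant tags from sample identifiers
#'
#' Default rule: the prefix of the sample id up to the Nth delimiter
#' (TCGA-barcode-like; `TCGA-XX-XXXX-01` with `n_fields = 3` gives
#' `TCGA-XX-XXXX`).
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param delim Field delimiter (default `"-"`).
#' @param n_fields Number of leading fields that form the tag (default 3).
#' @return Character vector of participant tags.
#' @export
participant_tag_from_id <- function(sample_ids, delim = "-", n_fields = 3L) {
  vapply(strsplit(sample_ids, delim, fixed = TRUE), function(f) {
    paste(f[seq_len(min(n_fields, length(f)))], collapse = delim)
  }, character(1))
}

#' Match normal and tumor samples by participant tag
#'
#' One pair is formed for every participant tag that has exactly one
#' normal sample and at least one tumor sample; when several tumor
#' aliquots exist the first one in file order is chosen. Normals (and
#' tumors) that cannot be paired are reported, never silently dropped.
#'
#' @param metadata Metadata data.frame with `sample_id`,
#'   `participant_tag` and `condition` columns.
#' @return List with `pairs` (data.frame `participant_tag`, `normal`,
#'   `tumor`), `unmatched_normal` and `unmatched_tumor` (character
#'   vectors of sample ids).
#' @export
match_normal_tumor_pairs <- function(metadata) {
  stopifnot(all(c("sample_id", "participant_tag", "condition") %in% colnames(metadata)))
  normals <- metadata[metadata$condition == "normal", , drop = FALSE]
  tumors <- metadata[metadata$condition == "tumor", , drop = FALSE]
  tags <- unique(normals$participant_tag)
  rows <- lapply(tags, function(tag) {
    n_ids <- normals$sample_id[normals$participant_tag == tag]
    t_ids <- tumors$sample_id[tumors$participant_tag == tag]
    if (length(n_ids) == 1L && length(t_ids) >= 1L) {
      data.frame(participant_tag = tag, normal = n_ids, tumor = t_ids[1L],
                 stringsAsFactors = FALSE)
    }
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) {
    pairs <- data.frame(participant_tag = character(), normal = character(),
                        tumor = character(), stringsAsFactors = FALSE)
  }
  list(pairs = pairs,
       unmatched_normal = setdiff(normals$sample_id, pairs$normal),
       unmatched_tumor = setdiff(tumors$sample_id, pairs$tumor))
}

# Presentation formatting for one numeric result column: correlations and
# scores keep >= 3 decimals, probabilities switch to scientific notation
# below 1e-3, integers stay integers.
.format_result_col <- function(x) {
  if (!is.numeric(x)) return(as.character(x))
  if (all(x == round(x), na.rm = TRUE) && all(abs(x) < .Machine$integer.max, na.rm = TRUE)) {
    return(format(as.integer(round(x)), trim = TRUE, scientific = FALSE))
  }
  out <- ifelse(!is.na(x) & abs(x) < 1e-3 & x != 0,
                sprintf("%.4e", x), sprintf("%.4f", x))
  out[is.na(x)] <- "NA"
  out
}

#' Write a result table as TSV
#'
#' Generic writer for the package's result data.frames (correlation
#' tables, enrichment scans, over-representation tables, cytoband
#' points). Correlations are printed with 4 decimals and p/q values in
#' scientific notation when below 1e-3; a read-back therefore matches to
#' printed precision.
#'
#' @param rows A data.frame of results (rows sharing a schema).
#' @param path Output path.
#' @export
write_result_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- as.data.frame(lapply(rows, .format_result_col),
                       stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out) <- colnames(rows)
  if (nrow(rows) == 0L) {
    writeLines(paste(colnames(rows), collapse = "\t"), path)
  } else {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
}

#' Read back a result table written by [write_result_table()]
#' @param path Path to a TSV file.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
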