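#' Specification of a synthetic paired expression study
#'
#' Bundles every knob of the synthetic generator. The generator plants
#' two kinds of structure around one target gene: a trans-acting
#' co-expression module active in the `normal` condition (a
#' COP9-signalosome-like subunit family, scattered across chromosomes)
#' and a cis-correlated block of chromosomal neighbours active in the
#' `tumor` condition (genes within the 1-Mbp TSS window of the target,
#' emulating co-amplification). Defaults describe a desk-scale bulk
#' RNA-seq study: 42 participant-matched sample pairs, 2,000 genes at a
#' human-like gene density of one gene per 150 kbp, log-normal
#' expression with grand mean `exp(base_log_mean)` ~ 1,100 and
#' coefficient of variation ~0.53, and a 1% dropout-zero rate.
#'
#' The planted groups use a single latent factor anchored on the
#' target: the factor is the target's own standardized log-expression,
#' and every other group member loads `sqrt(rho)` on it. Member-member
#' log-scale correlation is therefore exactly `rho`, while
#' target-member correlation is `sqrt(rho)`: the target is the hub of
#' its planted group, which is what makes target-centred recovery
#' (correlation ranking, cis-scan minima) well defined.
#'
#' @param seed Integer seed; every generator operation derives its RNG
#'   stream from `seed` plus a fixed per-operation offset.
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of chromosomes; genes are assigned
#'   round-robin, so each chromosome carries `n_genes / n_chromosomes`
#'   genes.
#' @param tss_spacing_bp Distance in bp between consecutive TSS on a
#'   chromosome.
#' @param n_samples_per_condition Samples per condition (participant
#'   pairs).
#' @param target_gene Symbol given to the planted target.
#' @param module_size Size of the trans module, target included.
#' @param rho_module Log-scale correlation among non-target module
#'   members in the normal condition, in [0, 1).
#' @param cis_window_bp Cis window half-width in bp (default 1,000,000).
#' @param cis_block_size Number of cis-block genes (target excluded),
#'   spread across the target's cis window on both sides.
#' @param rho_cis Log-scale correlation among cis-block members in the
#'   tumor condition, in [0, 1).
#' @param log_sigma Log-scale noise standard deviation.
#' @param base_log_mean Log of the grand-mean expression level.
#' @param dropout_rate Probability that any value is independently
#'   zeroed after exponentiation, in [0, 1).
#' @param planted_set_id Set id given to the planted module in the
#'   generated gene-set collection.
#' @param n_decoy_sets Number of random decoy gene sets.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genes = 2000L,
                           n_chromosomes = 5L,
                           tss_spacing_bp = 150000L,
                           n_samples_per_condition = 42L,
                           target_gene = "COPS5",
                           module_size = 9L,
                           rho_module = 0.8,
                           cis_window_bp = 1000000L,
                           cis_block_size = 8L,
                           rho_cis = 0.7,
                           log_sigma = 0.5,
                           base_log_mean = 7,
                           dropout_rate = 0.01,
                           planted_set_id = "planted_module",
                           n_decoy_sets = 50L) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_chromosomes = as.integer(n_chromosomes),
               tss_spacing_bp = as.integer(tss_spacing_bp),
               n_samples_per_condition = as.integer(n_samples_per_condition),
               target_gene = target_gene, module_size = as.integer(module_size),
               rho_module = rho_module, cis_window_bp = as.integer(cis_window_bp),
               cis_block_size = as.integer(cis_block_size), rho_cis = rho_cis,
               log_sigma = log_sigma, base_log_mean = base_log_mean,
               dropout_rate = dropout_rate, planted_set_id = planted_set_id,
               n_decoy_sets = as.integer(n_decoy_sets))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

#' Validate a synthetic study specification
#' @param spec A `synthetic_spec`.
#' @return `spec`, invisibly; stops on an invariant violation.
#' @export
validate_synthetic_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with(spec, {
    if (n_genes < 2L || n_chromosomes < 1L) stop("need n_genes >= 2 and n_chromosomes >= 1")
    if (module_size + cis_block_size > n_genes) stop("module_size + cis_block_size must not exceed n_genes")
    if (module_size < 1L) stop("module_size must be >= 1")
    if (rho_module < 0 || rho_module >= 1 || rho_cis < 0 || rho_cis >= 1) {
      stop("rho values must lie in [0, 1)")
    }
    if (tss_spacing_bp < 1L || cis_window_bp < 1L) stop("bp spacings must be positive")
    if (log_sigma <= 0) stop("log_sigma must be positive")
    if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must lie in [0, 1)")
    if (n_samples_per_condition < 3L) stop("need at least 3 samples per condition")
    if (module_size > 1L && n_chromosomes < 2L) {
      stop("trans module needs at least 2 chromosomes")
    }
  })
  offs <- .cis_offsets(spec)
  gpc1 <- length(seq.int(1L, spec$n_genes, by = spec$n_chromosomes))
  k_t <- ceiling(gpc1 / 2)
  ko <- k_t + offs %/% spec$tss_spacing_bp
  if (any(ko < 1L) || any(ko > gpc1)) stop("target chromosome too short for the cis block")
  invisible(spec)
}

# TSS offsets (in bp, relative to the target) of the planted cis-block
# genes: spread evenly over 90% of the cis window on both sides and
# snapped to the TSS grid. Spreading the block across the window (rather
# than packing it tightly around the target) mirrors a regional
# co-amplification: the target's window captures every block gene, while
# block members far from the centre do not see each other.
.cis_offsets <- function(spec) {
  b <- spec$cis_block_size
  if (b == 0L) return(numeric(0))
  hi <- ceiling(b / 2)
  lo <- b - hi
  snap <- function(j, n_side) {
    round(0.9 * spec$cis_window_bp * j / n_side / spec$tss_spacing_bp) *
      spec$tss_spacing_bp
  }
  off_hi <- snap(seq_len(hi), hi)
  off_lo <- if (lo > 0L) snap(seq_len(lo), lo) else numeric(0)
  offs <- c(-rev(off_lo), off_hi)
  if (any(offs == 0) || anyDuplicated(c(-off_lo, off_hi)) ||
      any(abs(offs) > spec$cis_window_bp)) {
    stop("cis block does not fit inside cis_window_bp at this tss_spacing_bp")
  }
  offs
}

# Deterministic gene layout shared by all generator operations.
# Gene i sits on chromosome ((i-1) mod C) + 1 at TSS ordinal
# ((i-1) div C) + 1; the target is the middle gene of chromosome 1; the
# cis block sits at the .cis_offsets() TSS positions around the target;
# the trans module takes the first gene of chromosomes 2, 3, ...
# (wrapping to the next TSS ordinal if needed), so module members never
# share the target's chromosome.
.gene_layout <- function(spec) {
  G <- spec$n_genes; C <- spec$n_chromosomes
  idx <- seq_len(G)
  chrom <- ((idx - 1L) %% C) + 1L
  ordinal <- ((idx - 1L) %/% C) + 1L
  tss <- ordinal * spec$tss_spacing_bp
  chr1 <- which(chrom == 1L)
  k_t <- ceiling(length(chr1) / 2)
  target_idx <- chr1[k_t]
  b <- spec$cis_block_size
  offs <- .cis_offsets(spec)
  ko <- k_t + offs %/% spec$tss_spacing_bp
  if (any(ko < 1L) || any(ko > length(chr1))) stop("cis block falls off the target chromosome")
  cis_idx <- chr1[ko]
  n_mod <- spec$module_size - 1L
  mod_idx <- integer(0)
  if (n_mod > 0L) {
    pool <- which(chrom != 1L) # ordered by index: chrom 2..C ordinal 1, then ordinal 2, ...
    mod_idx <- pool[seq_len(n_mod)]
  }
  symbols <- sprintf("G%04d", idx)
  symbols[target_idx] <- spec$target_gene
  if (n_mod > 0L) symbols[mod_idx] <- sprintf("MOD%02d", seq_len(n_mod))
  symbols[cis_idx] <- sprintf("CIS%02d", seq_len(b))
  list(symbols = symbols, chrom = chrom, ordinal = ordinal, tss = tss,
       target_idx = target_idx, cis_idx = cis_idx, mod_idx = mod_idx)
}

#' Generate gene annotations for a synthetic study
#'
#' Genes are assigned round-robin to chromosomes with TSS positions at
#' multiples of `tss_spacing_bp`. Cytoband strings are synthesized
#' consistently with position: the first half of each chromosome is the
#' p arm, the second the q arm, and band numbers increase away from the
#' centromere, so the cytoband-to-float conversion is monotone in TSS
#' within each arm. The planted cis-block genes sit on the target's
#' chromosome, spread across both sides of the target's `cis_window_bp`
#' neighbourhood: every block gene lies within the window of the
#' target, but distant block genes do not lie within each other's
#' windows -- the signature of a regional cis effect centred on the
#' target.
#'
#' @param spec A `synthetic_spec`.
#' @return Annotation data.frame (`gene`, `chromosome`, `cytoband`,
#'   `tss_bp`), one row per gene in layout order.
#' @export
generate_annotations <- function(spec) {
  validate_synthetic_spec(spec)
  lay <- .gene_layout(spec)
  ann <- data.frame(gene = lay$symbols, chromosome = as.character(lay$chrom),
                    tss_bp = as.integer(lay$tss), stringsAsFactors = FALSE)
  cyto <- character(spec$n_genes)
  for (c in unique(lay$chrom)) {
    on_c <- which(lay$chrom == c)
    len <- max(lay$tss[on_c])
    rel <- lay$tss[on_c] / len
    arm <- ifelse(rel <= 0.5, "p", "q")
    d <- ifelse(rel <= 0.5, 0.5 - rel, rel - 0.5)
    band <- sprintf("%.2f", 10 + 40 * d)
    cyto[on_c] <- paste0(c, arm, band)
  }
  ann$cytoband <- cyto
  ann[, c("gene", "chromosome", "cytoband", "tss_bp")]
}

#' Generate one condition of a synthetic expression study
#'
#' Log-scale model: `z_gs` is standard normal noise; in the `normal`
#' condition each non-target module member is replaced by
#' `sqrt(rho_module) * z_target + sqrt(1 - rho_module) * z_g`, and in
#' the `tumor` condition each cis-block member by the analogous
#' combination with `rho_cis` (the module coupling is removed).
#' Expression is `exp(base_log_mean + log_sigma * z - log_sigma^2 / 2)`,
#' so the grand mean is approximately `exp(base_log_mean)`; finally each
#' value is independently zeroed with probability `dropout_rate`.
#' Identical `spec` + `condition` always yields an identical matrix.
#'
#' @param spec A `synthetic_spec`.
#' @param condition `"normal"` or `"tumor"`.
#' @return Expression matrix (genes x samples); sample ids are
#'   TCGA-barcode-like, sharing participant tags across conditions.
#' @export
generate_expression_condition <- function(spec, condition = c("normal", "tumor")) {
  condition <- match.arg(condition)
  validate_synthetic_spec(spec)
  lay <- .gene_layout(spec)
  G <- spec$n_genes; S <- spec$n_samples_per_condition
  offset <- if (condition == "normal") 1L else 2L
  with_seed(spec$seed * 10L + offset, {
    z <- matrix(stats::rnorm(G * S), G, S)
    zt <- z[lay$target_idx, ]
    if (condition == "normal") {
      rho <- spec$rho_module
      for (i in lay$mod_idx) z[i, ] <- sqrt(rho) * zt + sqrt(1 - rho) * z[i, ]
    } else {
      rho <- spec$rho_cis
      for (i in lay$cis_idx) z[i, ] <- sqrt(rho) * zt + sqrt(1 - rho) * z[i, ]
    }
    vals <- exp(spec$base_log_mean + spec$log_sigma * z - spec$log_sigma^2 / 2)
    if (spec$dropout_rate > 0) {
      drop <- matrix(stats::runif(G * S) < spec$dropout_rate, G, S)
      vals[drop] <- 0
    }
    suffix <- if (condition == "normal") "11" else "01"
    dimnames(vals) <- list(lay$symbols,
                           sprintf("TCGA-HN-%04d-%s", seq_len(S), suffix))
    vals
  })
}

#' Generate a gene-set collection with one planted set
#'
#' The planted set contains exactly the module genes (target included)
#' under `planted_set_id`; decoy sets draw members uniformly from the
#' whole gene universe with sizes spanning 10-200.
#'
#' @param spec A `synthetic_spec`.
#' @return A `gene_set_collection`.
#' @export
generate_gene_sets <- function(spec) {
  validate_synthetic_spec(spec)
  lay <- .gene_layout(spec)
  module <- lay$symbols[c(lay$target_idx, lay$mod_idx)]
  with_seed(spec$seed * 10L + 3L, {
    sets <- list()
    desc <- character()
    sets[[spec$planted_set_id]] <- module
    desc[spec$planted_set_id] <- "planted co-expressed module"
    if (spec$n_decoy_sets > 0L) {
      sizes <- sample(10:200, spec$n_decoy_sets, replace = TRUE)
      sizes <- pmin(sizes, spec$n_genes)
      for (j in seq_len(spec$n_decoy_sets)) {
        id <- sprintf("DECOY%02d", j)
        sets[[id]] <- sample(lay$symbols, sizes[j])
        desc[id] <- "random decoy set"
      }
    }
    structure(list(sets = sets, desc = desc), class = "gene_set_collection")
  })
}

#' Generate a paired normal/tumor synthetic study
#'
#' Produces both condition matrices plus a sample metadata table whose
#' participant tags pair each normal with its tumor, so that
#' [match_normal_tumor_pairs()] recovers exactly
#' `n_samples_per_condition` pairs. Anatomical site, smoking history and
#' age group are drawn per participant (shared by both samples of a
#' pair).
#'
#' @param spec A `synthetic_spec`.
#' @return List with `normal`, `tumor` (expression matrices) and
#'   `metadata` (data.frame).
#' @export
generate_paired_study <- function(spec) {
  validate_synthetic_spec(spec)
  normal <- generate_expression_condition(spec, "normal")
  tumor <- generate_expression_condition(spec, "tumor")
  S <- spec$n_samples_per_condition
  tags <- participant_tag_from_id(colnames(normal))
  md <- with_seed(spec$seed * 10L + 4L, {
    site <- sample(c("oral cavity", "tongue", "larynx", "oropharynx"), S,
                   replace = TRUE, prob = c(0.35, 0.30, 0.25, 0.10))
    smoking <- sample(c("current", "former", "never"), S,
                      replace = TRUE, prob = c(0.45, 0.35, 0.20))
    age_group <- sample(c("<50", "50-65", ">65"), S,
                        replace = TRUE, prob = c(0.2, 0.45, 0.35))
    data.frame(
      sample_id = c(colnames(normal), colnames(tumor)),
      participant_tag = c(tags, tags),
      condition = rep(c("normal", "tumor"), each = S),
      site = c(site, site), smoking = c(smoking, smoking),
      age_group = c(age_group, age_group), stringsAsFactors = FALSE)
  })
  list(normal = normal, tumor = tumor, metadata = md)
}
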