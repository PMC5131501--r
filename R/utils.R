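#' @keywords internal
"_PACKAGE"

# Smallest p-value the package ever reports. Upper-tail probabilities are
# computed directly (never as 1 - CDF), so this floor only guards the
# exactly-degenerate cases (e.g. r = 1 gives t = Inf).
.p_floor <- .Machine$double.xmin

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All seeded operations in the package go
# through this so that a call is reproducible without clobbering the
# session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Benjamini-Hochberg step-up adjustment; q_(i) = min_{j >= i} p_(j) * m / j.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Two-sided p-value of a Pearson correlation under the t_{n-2} reference
# distribution; vectorised, floored away from exact zero.
.pearson_p <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
  pmax(pmin(p, 1), .p_floor)
}
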