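---
title: "Target-gene co-expression, chromosomal cis-effects and set enrichment"
author: "coexcis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-gene co-expression, chromosomal cis-effects and set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexcis)
```

## The question the package answers

Groups of genes whose products must act together — the subunits of an
obligate protein complex are the canonical example — tend to be
co-expressed in healthy tissue: each subunit's mRNA tracks the others
across individuals. `coexcis` quantifies that coordination around a
chosen *target gene* in a normalized gene-by-sample expression matrix,
and asks two follow-up questions:

1. **What co-varies with the target, and why?** A correlation table
   ranks every other gene by Pearson r against the target; gene-set
   enrichment (a running-sum score over the ranking) and binomial
   over-representation (of the top-|r| pool) attach functional meaning
   to the top of that ranking.
2. **Is the co-variation functional or positional?** In tumors,
   regional genomic events (e.g. co-amplification) can make a gene's
   chromosomal *neighbours* co-vary with it regardless of function. The
   cis-effect test scores the genes within 1 Mbp of the target's TSS
   against the target's ranking, with a null built from same-chromosome
   genes outside the window, so a positive result is positional
   enrichment over and above the chromosome's baseline.

A paired normal/tumor design sharpens the contrast: coordination of a
functional module in normal tissue, its loss in tumor tissue, and the
emergence of the cis signature there.

## Statistics

### Correlation tables

For a target t and every other gene g, the package computes the Pearson
product-moment correlation r over samples and the two-sided p-value
from t = r sqrt((n-2)/(1-r^2)) against the t distribution on n-2
degrees of freedom (identical to `cor.test(..., method = "pearson")`).
Before any correlation, genes with zero values in more than 5% of
samples are removed (`filter_low_expression`; the boundary is strict,
5% exactly is kept, and the zero test is exact equality — normalized
values carry no epsilon). Ties in r are broken lexicographically by
gene id everywhere, so ranks are reproducible. p-values are floored at
the smallest positive double, never printed as 0.

### Cytoband coordinates

A band string `ApB.N` maps to the float A − B.N/100 and `AqB.N` to
A + B.N/100 (`8p11.2` → 7.888, `8q11.2` → 8.112); X and Y share the
numeric column 23. The conversion is strictly monotone in band number
within one arm, which is all the scatter of (cytoband, r) points needs.
Two conventions are worth flagging: a band without sub-band decimal
(`8q13`) reads B.N = 13 (→ 8.13), and a multi-digit sub-band
(`12p13.31`) uses the full decimal (→ 11.8669), which makes 13.31 sort
past 13.9 within an arm — an accepted artefact of the formula as
defined.

### Running-sum enrichment score

Given a ranking of N genes and a set with Nh members in it, walk the
ranking and accumulate P_hit (the normalized cumulative weight of
members, weight = |r|^w) against P_miss (the cumulative count of
non-members over N − Nh). The enrichment score ES is the maximum of
P_hit − P_miss, the *min deficit* its minimum; the running sum ends at
exactly 0. ES = 1 iff all members precede all non-members. The weight
exponent defaults to w = 1 (the classic weighted statistic); w = 0
gives the unweighted version. The null is *gene-set permutation*:
ES values of random Nh-gene draws (without replacement) from the
ranking, summarised by their mean and SD; the default p-value is the
upper tail of a normal at those moments, with an add-one empirical
mode (`p_mode = "empirical"`) as an alternative. There is no NES,
phenotype permutation or leading-edge extraction here — deliberately.

### Cis-effect test

For target t with annotated TSS, Gi = same-chromosome genes with
|TSS − TSS_t| ≤ 1 Mbp (a closed interval; the boundary convention is
ours, strand is ignored) and Go = the same-chromosome remainder, both
intersected with the correlation universe; t itself (r = 1) is removed
from its own ranking before scoring. ES(Gi) is compared against
permutation draws of Nh genes *from Go only*, which controls for the
chromosome's own co-expression baseline. The p-value is one-sided
upper-tail (enrichment, not depletion). A genome-wide scan repeats this
with every gene as target and adjusts by Benjamini–Hochberg
(step-up, q(i) = min over j ≥ i of p(j)·m/j); probes whose window is
empty or whose Go pool is smaller than Nh are reported as skipped, not
dropped.

### Binomial over-representation

The top k genes by |r| form the pool (default k = 1000, the published
convention for a ~20,000-gene universe; the analysis scripts use
k = 100 on the 2,000-gene synthetic universe to keep the same 5%
fraction). For each set, mu = |members ∩ universe| / |universe| is the
per-gene background rate, and the p-value is P(X > found) for
X ~ Binomial(k, mu) — note the strict inequality, the convention of
`1 - pbinom(n, k, mu)`. The upper tail is computed directly
(`lower.tail = FALSE`), so heavily enriched sets keep full precision
instead of collapsing to a 1.1e-16 floor. The "expected" column is the
smallest count whose tail probability drops below 0.05: the bar a
pathway must clear. Published tables of this statistic sometimes show
mu values slightly larger than member-count/universe (annotation
multi-counting upstream of the test); this package uses the
transparent set-semantics definition only. No multiple-testing
correction is applied by default (rows are sorted by raw p);
`add_q = TRUE` adds a BH column.

## The synthetic study generator

Because the real cohorts behind these methods are controlled-access,
the package ships a generator whose planted structure gives every
statistic a ground truth.

**Layout.** Genes are placed round-robin on `n_chromosomes`
chromosomes with TSS every `tss_spacing_bp`. Defaults: 2,000 genes on
5 chromosomes at 150 kbp spacing — one gene per 150 kbp is the human
genome's average density, so a ±1 Mbp window holds ~12 neighbours and
each chromosome ~400 genes, keeping Nh ≪ |Go| (a null pool much larger
than the draw size matters: drawing Nh from a small disjoint pool is
negatively dependent on the tested set and anticonservative).
Cytobands are synthesized consistently with position (p arm in the
first chromosome half, q arm in the second, band numbers increasing
away from the centromere), so coordinate monotonicity is testable.

**Planted correlation.** All structure lives on the log scale:
z-scores with a single latent factor per planted group, exponentiated
as `exp(base_log_mean + log_sigma·z − log_sigma²/2)` so the grand mean
is ~e^7 ≈ 1,100 (an RSEM-normalized scale) with log-sd 0.5 (cv ≈ 0.53,
typical of bulk data). The factor is *anchored on the target*: the
target's own standardized log-expression is the shared signal and every
other group member loads √rho on it. Member–member correlation is
therefore exactly rho, while target–member correlation is √rho — the
target is the hub of its group. The anchored design is deliberate: with
a fully exchangeable equicorrelated group, no member is distinguishable
from the target, and target-centred recovery (the target's q being the
scan minimum) would be a coin flip among members rather than a
property of the plant. Scientifically it reads as neighbours tracking
the target's locus activity.

In the normal condition the trans module (target + 8 genes named
`MOD01..MOD08`, never on the target's chromosome) is coupled at
rho_module = 0.8; in the tumor condition that coupling is removed and
the cis block (`CIS01..CIS08`) couples at rho_cis = 0.7 — the paired
sample sizes (42) and rho values are the study conditions the
acceptance checks run at. rho_cis has no published value; 0.7 is a
calibration choice for a strong regional event.

**Cis-block placement.** The block genes are spread across 90% of the
±1 Mbp window on both sides of the target rather than packed tightly
around it. Packed neighbours are mutually within each other's windows,
which makes every block member's cis test statistically equivalent to
the target's; spreading reproduces what a regional co-amplification
centred on the target looks like: the target's window captures the
whole block, while distal block members miss each other and even
contaminate each other's Go pools.

**Dropout.** After exponentiation each value is independently zeroed
with probability `dropout_rate` (default 0.01 — bulk level-3 data has
rare zeros). This gives the >5% filter true positives and negatives by
construction; it also means a planted gene is occasionally filtered
out, which downstream code must tolerate (and the tests do).

**Reproducibility.** Every generator operation seeds its own RNG
stream from `spec$seed` plus a fixed per-operation offset and restores
the caller's RNG state, so individual operations are independently
reproducible and identical spec + seed gives byte-identical TSV output.

**What the generator does not emulate:** library-size or GC artefacts,
batch effects, count-level (negative binomial) noise, expression-level
dependent dropout, realistic gene-density variation, or LD-like
correlation decay with distance. Passing tests on this generator show
the statistics recover the planted structure under log-normal noise;
they do not certify behaviour under real-data artefacts.

## Numerical and design choices

- Sample SD uses the n−1 denominator throughout (the `cor.test`/`sd`
  convention).
- The permutation ES for null draws is computed from hit positions
  only (the running maximum is attained at a hit, the minimum just
  before one); this is algebraically identical to the full running sum
  and tested against it to 1e−12, and all draws of a scan are scored
  in one batched radix pass for speed.
- `set_p_value`'s normal approximation is convenient and matches the
  published procedure, but the ES null is the maximum of a random walk
  and right-skewed, so the normal upper tail is mildly anticonservative:
  in a 3,000-replicate null study at the default design point its true
  type-I level at nominal 0.05 is ≈ 0.075, versus ≈ 0.057 for the
  empirical mode. Users who need exact size should use
  `p_mode = "empirical"` with enough permutations.
- Tumor aliquot choice in pairing is first-in-file-order — a documented
  convention, not data-driven.
- Problem sizes used by the test-suite recovery and calibration checks:
  2,000 genes × 42 samples, 200 permutation draws, 500 null replicates
  and 20 recovery seeds — chosen as the smallest sizes at which the
  planted effects and the size of the test are cleanly measurable.

## Known limitations

- The cis test measures positional enrichment only; it cannot say
  *why* neighbours co-vary (copy number, chromatin domain, shared
  enhancer).
- The normal-approximation p inherits the skew bias above; genome-wide
  q values based on it are correspondingly slightly liberal.
- mu in the ORA counts each gene once per set; annotation sources that
  multi-count appearances will give larger mu (and more conservative
  expected counts) than this definition.
- The generator's single-factor plant cannot represent overlapping
  modules or graded membership.
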