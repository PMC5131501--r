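# coexcis

Target-gene co-expression analysis for bulk expression studies:
correlation tables around a chosen target gene, chromosomal
(cytoband/TSS) mapping of the top-correlated genes, a cis-effect
enrichment test with a same-chromosome permutation null, running-sum
gene-set enrichment, and binomial over-representation — plus a
synthetic paired normal/tumor study generator with planted ground
truth.

## Who this is for

Genes that work together — subunits of an obligate complex, members of
one pathway — are co-expressed across individuals in normal tissue.
`coexcis` is for asking, from a normalized gene-by-sample matrix
(RSEM-like "level 3" values), three questions about one target gene:

1. which genes co-vary with it (Pearson correlation table, two-sided
   t-test p-values);
2. what those co-varying genes do (running-sum enrichment of
   annotation sets against the r-ranking; binomial over-representation
   of the top-|r| pool);
3. whether the co-variation is *functional* or merely *positional* —
   driven by chromosomal proximity, e.g. co-amplification in tumors
   (the cis-effect test).

## The core statistics

**Correlation table.** For target t and each gene g, Pearson r over n
samples with p from t = r·√((n−2)/(1−r²)) on n−2 df. Genes with zeros
in more than 5% of samples are excluded first.

**Cytoband coordinate.** Band `ApB.N` → A − B.N/100, `AqB.N` →
A + B.N/100 (so `8p11.2` → 7.888, `8q11.2` → 8.112); X/Y combine into
column 23. The top-k |r| genes plotted at (cytoband, r) reveal
chromosomal concentration.

**Enrichment score.** Walking the ranked list, ES = max(P_hit − P_miss)
where P_hit accumulates member weights (|r|^w, default w = 1) and
P_miss counts non-members over N − Nh. Null: ES of random Nh-gene
draws; p from the normal upper tail at the null mean/sd (empirical
mode available).

**Cis-effect test.** Gi = genes within 1 Mbp of the target's TSS on
its chromosome; Go = the same-chromosome remainder. ES(Gi) against the
target's own ranking (target removed), null draws from Go only,
one-sided upper-tail p; genome-wide scans get Benjamini–Hochberg q.

**Over-representation.** Among the top k genes by |r|, a set with
background rate mu = |members ∩ universe|/|universe| and count *found*
gets p = P(X > found), X ~ Binomial(k, mu), plus the smallest count
that would reach p < 0.05 ("expected").

## Worked example

The numbered scripts under `analysis/` run the full workflow on the
synthetic paired study (2,000 genes, 42 normal/tumor pairs, a planted
9-gene trans module active in normal tissue and a planted 8-gene cis
block active in tumor tissue):

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_coexpression_tables.R
Rscript analysis/03_cytoband_map.R
Rscript analysis/04_set_enrichment_ora.R
Rscript analysis/05_cis_enrichment.R
```

Output from a run (tables land under `results/`):

```
simulated 2000 genes x 42+42 samples; 42 recoverable pairs, 0 unmatched normals
COPS5 (normal): mean 1136.1, sd 441.87, cv 0.39; transcriptome mean cv 0.533 (+/- 0.084)
module mean pairwise r (normal): 0.720
module mean pairwise r (tumor): 0.004
top of the normal table: MOD03, MOD05, MOD08, MOD04, MOD06
top of the tumor table: CIS07, CIS06, CIS02, CIS08, CIS03
normal: 19% of the top 100 |r| genes lie on chromosome 1
tumor: 28% of the top 100 |r| genes lie on chromosome 1
top set by ES: planted_module (ES = 1.000, Nh = 7, p = 1.79e-04, q = 9.15e-03)
top set by binomial ORA: planted_module (found 7, expected >= 1 for p < 0.05, mu = 0.0036, p = 3.54e-09)
normal: ES = 0.18, Nh = 12, p = 0.69
tumor: ES = 0.94, Nh = 12, p = 3.57e-06
tumor chromosome scan: 398 probes, target q = 0.000338 (scan minimum: TRUE)
```

Reading it: in the normal condition the planted module is tightly
coordinated (mean pairwise r 0.72) and dominates both enrichment
rankings; in the matched tumor condition that coordination collapses
(r ≈ 0) and the target's correlation ranking is instead headed by its
chromosomal neighbours — the cis-effect test jumps from ES 0.18
(p 0.69) to ES 0.94 (p 3.6e-06), and the target has the smallest q in
a scan of its whole chromosome.

A minimal interactive session:

```r
library(coexcis)
spec <- synthetic_spec(seed = 1)
study <- generate_paired_study(spec)
m <- filter_low_expression(study$normal)
tab <- build_correlation_table(m, "COPS5")
head(tab)                         # genes ranked by r against COPS5
cytoband_to_float("8q13.2")       # 8.132
```

## Layout

- `R/` — the package: IO (`read_expression_table`, `read_gmt`, ...),
  generator (`synthetic_spec`, `generate_paired_study`, ...),
  correlation (`build_correlation_table`, `correlation_matrix`, ...),
  cytoband mapping, set enrichment (`pathway_scan`,
  `gene_scan_for_set`), cis test (`build_cis_pools`, `cis_es_test`,
  `genomewide_cis_scan`), ORA (`ora_table`).
- `analysis/` — the numbered workflow above.
- `vignettes/coexpression-cis-enrichment.Rmd` — models, parameters,
  design choices and limitations.
- `tests/testthat/` — unit, property and acceptance tests.
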