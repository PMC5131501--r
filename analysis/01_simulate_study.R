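#!/usr/bin/env Rscript
# Step 1 -- simulate the paired normal/tumor expression study.
#
# Generates the synthetic study that stands in for a paired bulk RNA-seq
# cohort: 42 participant-matched normal/tumor pairs over 2,000 genes on
# 5 chromosomes. A 9-gene trans-acting module (the target plus MOD01-08,
# scattered across chromosomes) is co-expressed in the normal condition;
# in the tumor condition that coupling is lost and an 8-gene cis block
# (CIS01-08, spread across the target's 1-Mbp TSS window) becomes
# correlated with the target instead. Writes all study inputs as TSV/GMT
# under results/data/.

suppressPackageStartupMessages(library(coexcis))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
spec <- synthetic_spec(seed = 20260924L)

ann <- generate_annotations(spec)
st <- generate_paired_study(spec)
sets <- generate_gene_sets(spec)

write_expression_table(st$normal, "results/data/expression_normal.tsv")
write_expression_table(st$tumor, "results/data/expression_tumor.tsv")
write_annotation_table(ann, "results/data/annotations.tsv")
write_metadata_table(st$metadata, "results/data/metadata.tsv")
write_gmt(sets, "results/data/gene_sets.gmt")

pairs <- match_normal_tumor_pairs(st$metadata)
message(sprintf("simulated %d genes x %d+%d samples; %d recoverable pairs, %d unmatched normals",
                nrow(st$normal), ncol(st$normal), ncol(st$tumor),
                nrow(pairs$pairs), length(pairs$unmatched_normal)))
message(sprintf("planted: module of %d genes (rho = %.2f, normal), cis block of %d genes (rho = %.2f, tumor)",
                spec$module_size, spec$rho_module, spec$cis_block_size, spec$rho_cis))
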