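#!/usr/bin/env Rscript
# Step 2 -- target-gene co-expression in normal versus tumor tissue.
#
# Filters out genes with zeros in more than 5% of samples, summarises
# the target's expression stability (mean, sd, cv) against the whole
# transcriptome, builds the 9x9 module correlation matrices for both
# conditions (the loss-of-coordination contrast), and writes the full
# target correlation table for each condition.

suppressPackageStartupMessages(library(coexcis))

spec <- synthetic_spec(seed = 20260924L)
target <- spec$target_gene
normal <- read_expression_table("results/data/expression_normal.tsv")
tumor <- read_expression_table("results/data/expression_tumor.tsv")

nf <- filter_low_expression(normal)
tf <- filter_low_expression(tumor)

# target stability relative to the transcriptome
gs <- gene_summary(nf, target)
all_cv <- gene_summary(nf, rownames(nf))$cv
message(sprintf("%s (normal): mean %.1f, sd %.2f, cv %.2f; transcriptome mean cv %.3f (+/- %.3f)",
                target, gs$mean, gs$sd, gs$cv,
                mean(all_cv, na.rm = TRUE), sd(all_cv, na.rm = TRUE)))
write_result_table(gs, "results/target_summary.tsv")

# module correlation matrices, normal vs tumor
module <- c(target, sprintf("MOD%02d", seq_len(spec$module_size - 1)))
for (cond in c("normal", "tumor")) {
  m <- if (cond == "normal") nf else tf
  cm <- correlation_matrix(m, intersect(module, rownames(m)))
  off <- cm$r[upper.tri(cm$r)]
  message(sprintf("module mean pairwise r (%s): %.3f", cond, mean(off)))
  tab <- data.frame(gene = rownames(cm$r), round(cm$r, 3), check.names = FALSE)
  write_result_table(tab, sprintf("results/module_correlation_%s.tsv", cond))
}

# full target correlation tables
for (cond in c("normal", "tumor")) {
  m <- if (cond == "normal") nf else tf
  tab <- build_correlation_table(m, target, sort = "by_r_desc")
  write_result_table(tab, sprintf("results/correlation_table_%s.tsv", cond))
  message(sprintf("top of the %s table: %s", cond,
                  paste(utils::head(tab$feature_id, 5), collapse = ", ")))
}
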