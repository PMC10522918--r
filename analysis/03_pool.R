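#!/usr/bin/env Rscript
# Step 3: meta-analytic pooling of the per-cohort coefficients.
#
# For each gene surviving the screen, pools the five univariate
# dichotomized-group log-hazard coefficients: fixed effects when Cochran's
# Q is non-significant and I-squared <= 50%, DerSimonian-Laird random
# effects otherwise. The pooled betas become the score weights.

suppressPackageStartupMessages(library(prognoscore))

evidence <- read_table("results/gene_screen.tsv")
final_genes <- readLines("results/prognostic_genes.txt")
scr <- structure(list(evidence = evidence,
                      summary = data.frame(gene = final_genes),
                      final_genes = final_genes),
                 class = "gene_screen")

pooled <- pool_screen(scr, genes = final_genes, rule = heterogeneity_rule())
write_table(pooled, "results/pooled_betas.tsv")

cat(nrow(pooled), "genes pooled:\n")
print(pooled[, c("gene", "model", "q_p", "i2", "beta_pooled", "se_pooled")],
      row.names = FALSE, digits = 3)
cat(sum(pooled$model == "random"), "gene(s) pooled under random effects\n")
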