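#!/usr/bin/env Rscript
# Stage 2: normalization chain. Median-of-ratios size factors + log2
# transform of the counts, regression of expression and ln(IC50) on tissue
# and histology covariates, Z-scaling of the drug sensitivities.

suppressMessages(library(ribopanel))
out <- "results"

expr <- read_expression(file.path(out, "expr_counts.tsv"),
                        file.path(out, "annotations.tsv"))
drugs <- read_drug_table(file.path(out, "drugs_lnic50.tsv"))
pre <- preprocess_pipeline(expr, drugs)

write_expression(pre$expr, file.path(out, "expr_residual.tsv"))
write_drug_table(pre$drugs, file.path(out, "drugs_zscaled.tsv"))
message(sprintf("residual expression: %d genes x %d samples; drugs Z-scaled",
                length(pre$expr$gene_ids), length(pre$expr$sample_ids)))
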