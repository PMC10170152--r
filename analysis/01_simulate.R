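#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study. A 2000-gene x 120-cell-line count
# matrix with four planted co-expression modules (factor loading 0.7, so
# within-module correlation ~0.49), three tissues with additive offsets,
# four DNA-damaging drugs whose ln(IC50) is coupled to module 1 (slope -1.5,
# noise sd 0.5), and an 8-gene "ribosome biogenesis" panel inside module 1
# carrying extra drug-coupled signal. Ground truth goes to results/truth/.

suppressMessages(library(ribopanel))
seed <- 17
out <- "results"
dir.create(file.path(out, "truth"), recursive = TRUE, showWarnings = FALSE)

design <- simulation_design(n_genes = 2000, seed = seed)
sim <- simulate_expression(design, seed = seed)
dr <- simulate_drug_response(design, sim$truth$factors, seed = seed + 1)

write_expression(sim$expr, file.path(out, "expr_counts.tsv"))
utils::write.table(sim$expr$annotations, file.path(out, "annotations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_drug_table(dr$drugs, file.path(out, "drugs_lnic50.tsv"))

truth_labels <- data.frame(gene = names(sim$truth$labels),
                           module = unname(sim$truth$labels))
utils::write.table(truth_labels, file.path(out, "truth/modules.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sim$truth$panel_genes, file.path(out, "truth/panel_genes.txt"))

# annotation gene set (GMT): the planted panel plus 20 background genes
bg <- truth_labels$gene[truth_labels$module == "background"]
writeLines(paste(c("RIBOSOME_BIOGENESIS", "synthetic annotation set",
                   sim$truth$panel_genes, head(bg, 20)), collapse = "\t"),
           file.path(out, "annotation_sets.gmt"))

message(sprintf("simulated %d genes x %d samples, %d drugs; panel: %s",
                design$n_genes, design$n_samples, length(design$drugs),
                paste(sim$truth$panel_genes, collapse = " ")))
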