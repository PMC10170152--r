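#!/usr/bin/env Rscript
# Stage 4: panel discovery. Per-gene Pearson correlation screen against each
# drug's Z-scaled ln(IC50) with BH FDR, pre-ranked GSEA of the annotation
# set on the correlation ranking, hypergeometric enrichment, and the
# intersection workflow: signature-module genes that are significantly
# negatively correlated (FDR < 0.05) intersected with the annotation set.

suppressMessages(library(ribopanel))
out <- "results"

tab <- utils::read.delim(file.path(out, "expr_residual.tsv"),
                         check.names = FALSE)
vals <- as.matrix(tab[, -1]); rownames(vals) <- tab$gene_id
dtab <- utils::read.delim(file.path(out, "drugs_zscaled.tsv"),
                          check.names = FALSE)
dvals <- as.matrix(dtab[, -1]); rownames(dvals) <- dtab$sample_id
drugs <- drug_response_table(dvals, scale = "zscaled")
net <- build_network(vals, drugs, network_params(cut_height = 0.97),
                     beta = 6)

corr <- gene_drug_correlations(vals, drugs)
sets <- read_gmt(file.path(out, "annotation_sets.gmt"))
annot <- sets$RIBOSOME_BIOGENESIS$members

panel <- derive_candidate_panel(net$signatures, corr, annot,
                                fdr_threshold = 0.05)

# enrichment of the annotation set in the olaparib correlation ranking
ranking <- with(corr[corr$drug == corr$drug[1], ],
                stats::setNames(-r_z, gene))  # most negative r ranked first
gsea <- preranked_gsea(ranking, annot, n_perm = 1000, seed = 17)
hyp <- hypergeometric_enrichment(panel$panel, annot, rownames(vals))

write_report(list(
  correlations = as.data.frame(corr),
  candidates = data.frame(gene = panel$candidates),
  panel = data.frame(gene = panel$panel)),
  file.path(out, "panel"),
  config = list(fdr = 0.05, mode = panel$mode), seed = 17L)

truth_panel <- readLines(file.path(out, "truth/panel_genes.txt"))
message(sprintf(
  "candidates: %d genes; panel: %d genes (planted panel recovered: %s)",
  length(panel$candidates), length(panel$panel),
  setequal(panel$panel, truth_panel)))
message(sprintf(
  "annotation-set GSEA: ES = %.3f, NES = %.2f, P = %.4g; hypergeometric overlap %d, P = %.3g",
  gsea$es, gsea$nes, gsea$p, hyp$overlap, hyp$p))
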