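#!/usr/bin/env Rscript
# Stage 5: the validation cohort. Simulates 60 patients' tumor expression
# from the same design, scores them with the discovered panel (first-PC
# projection, median dichotomization), and calls HR status two ways:
# signature-3 exposure refit by NNLS from simulated 96-context catalogs
# (cohort quartile rule), and shallowHRD-style LGA classes from planted
# copy-number segment profiles (the labels used downstream).

suppressMessages(library(ribopanel))
out <- "results"
seed <- 17

design <- simulation_design(n_genes = 2000, seed = seed)
design$n_samples <- design$cohort$n_patients
pat <- simulate_expression(design, seed = seed + 11)
vst <- vst_like_transform(pat$expr)

panel <- utils::read.delim(file.path(out, "panel/panel.tsv"))$gene
scores <- dichotomize_by_median(pca_panel_score(vst, panel))

# HR status from mutational catalogs (quartile rule on signature-3 exposure)
S <- synthetic_signature_matrix(4, seed = seed + 12)
set.seed(seed + 12)
expos <- t(vapply(seq_len(nrow(scores)), function(i) {
  e <- c(0.4, 0.1, stats::runif(1, 0, 0.5), 0.1)
  e / sum(e)
}, numeric(4)))
rownames(expos) <- scores$sample_id
catal <- simulate_mutation_catalog(design, S, exposures = expos,
                                   seed = seed + 13)
fit <- fit_signature_exposures(catal$catalog, S)
sig3_calls <- classify_hr_by_signature3(fit, rule = "quartile")

# HR status from segment profiles (shallowHRD-style LGA classes)
hr_truth <- rep(c("deficient", "proficient", "borderline"),
                length.out = nrow(scores))
lga_plant <- ifelse(hr_truth == "deficient", 22,
                    ifelse(hr_truth == "borderline", 16, 4))
segs <- simulate_segments(design, sample_ids = scores$sample_id,
                          lga_counts = lga_plant)
lga_calls <- classify_hr_by_lga(segs$profiles)

write_report(list(
  scores = as.data.frame(scores),
  signature_exposures = as.data.frame(fit),
  hr_signature3 = as.data.frame(sig3_calls),
  hr_lga = as.data.frame(lga_calls)),
  file.path(out, "cohort"), config = list(rule = "quartile"), seed = seed)
write_expression(vst, file.path(out, "cohort/expr_vst.tsv"))

message(sprintf(
  "%d patients scored (%d high); signature-3 cutoff %.2f; LGA classes: %s",
  nrow(scores), sum(scores$label == "high"), attr(sig3_calls, "cutoff"),
  paste(names(table(lga_calls$label)), table(lga_calls$label),
        sep = "=", collapse = ", ")))
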