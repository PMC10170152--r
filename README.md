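# ribopanel

Discovery and clinical validation of a co-expressed gene panel predicting
PARP-inhibitor/cisplatin response, with combined homologous-recombination
(HR) status calling.

## The problem

PARP inhibitors and platinum are most effective in HR-deficient
("BRCAness") tumors, yet many HR-proficient patients respond too, and
mutation-based biomarkers cannot identify them. `ribopanel` implements a
transcriptional biomarker pipeline for exactly that gap:

1. **Normalize** cell-line RNA-seq counts (median-of-ratios size factors,
   log2), regress expression and ln(IC50) drug sensitivities on tissue /
   histology covariates, Z-scale sensitivities.
2. **Network**: signed weighted co-expression network
   `a_ij = ((1+r_ij)/2)^β`, topological-overlap similarity, average-linkage
   module detection, module eigengenes; each drug's *signature module* is
   the module most negatively correlated with its ln(IC50), and drugs are
   grouped by signature-module similarity.
3. **Panel discovery**: per-gene Pearson screen against ln(IC50) with
   Benjamini–Hochberg FDR, pre-ranked GSEA and hypergeometric enrichment;
   the panel = signature-module genes ∩ significantly negatively
   correlated genes (FDR < 0.05) ∩ an annotation set (ribosome-biogenesis
   genes in the motivating biology).
4. **Scoring**: per-sample PCA panel score (first principal component of
   the standardized panel submatrix), dichotomized at the cohort median.
5. **HR status**: 96-context mutational catalogs refit against a
   COSMIC-v2-layout signature matrix by non-negative least squares
   (signature-3 exposure, cohort quartile/tertile cutoff), or
   shallow-WGS-style large-scale genomic alteration (LGA) counts
   (proficient < 15, borderline 15–19, deficient > 19).
6. **Clinical validation**: predicted responder iff panel high OR HR
   deficient; observed resistance = progression/death before 300 days;
   accuracy, Kaplan–Meier, log-rank, Cox proportional hazards, and a
   random-gene-panel permutation null for the panel hazard ratio.

A first-class synthetic-data module (`simulation_design()`,
`simulate_*()`) generates ground-truth-bearing inputs for every stage, so
the whole pipeline is testable without access-restricted data.

## Worked example

The numbered scripts under `analysis/` run the full study on a synthetic
2000-gene × 120-cell-line compendium with four planted modules and four
drugs coupled to module 1, then validate on a simulated 60-patient cohort:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_network.R
Rscript analysis/04_panel.R
Rscript analysis/05_score_hr.R
Rscript analysis/06_clinical.R
```

Output of a complete run (tables land under `results/`):

```
simulated 2000 genes x 120 samples, 4 drugs; panel: G0001 ... G0008
residual expression: 2000 genes x 120 samples; drugs Z-scaled
4 modules detected (ARI vs truth = 0.997); drug groups: cisplatin=1,
  olaparib=1, rucaparib=1, talazoparib=1
candidates: 50 genes; panel: 8 genes (planted panel recovered: TRUE)
annotation-set GSEA: ES = 0.756, NES = 2.20, P = 0.001709;
  hypergeometric overlap 8, P = 4.96e-16
60 patients scored (30 high); signature-3 cutoff 859.36;
  LGA classes: borderline=20, deficient=20, proficient=20
accuracy 60.9% (28/46 evaluable); HR-proficient accuracy 52.9%
log-rank P (panel high vs low) = 0.02173
multivariate Cox: panel_low B = 0.91 (HR 2.47, P 0.0153);
  hr_deficient B = -0.53 (HR 0.59, P 0.149)
permutation test (HR-proficient, B = 1000): observed HR 1.28,
  one-tailed P = 0.3387
```

Reading this: the network stage recovers the four planted modules almost
exactly (adjusted Rand index 0.997) and assigns all four DNA-damaging
drugs the same signature module, so they form one drug group. The
intersection workflow returns exactly the 8 planted annotation-set genes,
and the annotation set is strongly enriched among negative correlations.
On the validation cohort, a low panel score multiplies the hazard by 2.47
(P = 0.015) alongside HR status, and panel-high patients separate from
panel-low on the Kaplan–Meier curves (log-rank P = 0.022). The
combined-rule accuracy (60.9%) and the HR-proficient-stratum permutation
p (n = 20 patients) are honest small-cohort figures under the generator's
event rates — see the methods vignette
(`vignettes/panel-discovery-methods.Rmd`) for why.

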