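# ---------------------------------------------------------------------------
# End-to-end driver: simulate (or accept) inputs, preprocess, build the
# network, derive the panel, score samples, call HR status, predict response
# and run the survival analyses; write deterministic TSV outputs.
# ---------------------------------------------------------------------------

#' Run the whole discovery-and-validation pipeline on a synthetic study
#'
#' Generates a complete synthetic study from a [simulation_design()]
#' (expression with planted modules, drug responses, mutation catalogs,
#' segment profiles, survival cohort), runs every analysis stage, and — when
#' `out_dir` is given — writes deterministic TSVs plus a JSON manifest.
#' Identical design and seed give byte-identical outputs.
#'
#' @param design a [simulation_design()].
#' @param out_dir optional output directory for [write_report()].
#' @param seed integer master seed; stage seeds derive from it.
#' @param params a [network_params()].
#' @param beta soft-threshold power for the network stage. The default 6 is
#'   the package's choice for the synthetic study: a planted factor design
#'   is not scale-free, so data-driven power selection is unreliable there,
#'   while a moderate power maximizes module contrast at the generator's
#'   within-module correlation (see the methods vignette). Pass `NULL` to
#'   select the power by the scale-free criterion.
#' @param annotation_extra number of non-module genes added to the synthetic
#'   annotation set next to the planted panel genes.
#' @param perm_B permutations for the panel hazard-ratio test.
#' @return list with every stage's result: `sim`, `pre`, `net`, `corr`,
#'   `panel`, `scores`, `hr`, `clinical`, `predictions`, `evaluation`,
#'   `cox`, `perm`.
#' @export
run_pipeline <- function(design = simulation_design(), out_dir = NULL,
                         seed = design$seed, params = network_params(),
                         beta = 6L, annotation_extra = 20, perm_B = 200) {
  sim <- simulate_expression(design, seed = seed)
  dr <- simulate_drug_response(design, sim$truth$factors, seed = seed + 1)
  pre <- preprocess_pipeline(sim$expr, dr$drugs)
  net <- build_network(pre$expr, pre$drugs, params, beta = beta)
  corr <- gene_drug_correlations(pre$expr, pre$drugs)
  # synthetic annotation set: planted panel genes + background genes
  bg <- names(sim$truth$labels)[sim$truth$labels == "background"]
  annot_set <- c(sim$truth$panel_genes,
                 utils::head(bg, annotation_extra))
  panel <- derive_candidate_panel(net$signatures, corr, annot_set)
  scores <- pca_panel_score(pre$expr, panel$panel)
  scores <- dichotomize_by_median(scores)

  # clinical stage: a fresh patient cohort scored with the same panel genes
  n_pat <- design$cohort$n_patients
  pat_design <- design
  pat_design$n_samples <- n_pat
  pat_sim <- simulate_expression(pat_design, seed = seed + 11)
  pat_pre <- vst_like_transform(pat_sim$expr)
  pat_scores <- dichotomize_by_median(
    pca_panel_score(pat_pre, panel$panel))
  S <- synthetic_signature_matrix(4, seed = seed + 12)
  hr_truth <- rep(c("deficient", "proficient", "borderline"),
                  length.out = n_pat)
  lga_plant <- ifelse(hr_truth == "deficient", 22,
                      ifelse(hr_truth == "borderline", 16, 4))
  segs <- simulate_segments(pat_design,
                            sample_ids = pat_sim$expr$sample_ids,
                            lga_counts = lga_plant)
  hr <- classify_hr_by_lga(segs$profiles)
  coh <- simulate_cohort(pat_design,
                         panel_scores = zscale(pat_scores$score),
                         hr_labels = hr$label, seed = seed + 13)
  clin <- coh$clinical
  clin$patient_id <- pat_sim$expr$sample_ids
  clin$panel_label <- pat_scores$label
  clin$hr_label <- hr$label
  predicted <- predict_response(clin$panel_label, clin$hr_label)
  observed <- define_observed_resistance(clin)
  evaluation <- evaluate_predictions(predicted, observed, clin$hr_label)
  cox <- cox_fit(cbind(panel_low = as.numeric(clin$panel_label == "low"),
                       hr_deficient = as.numeric(clin$hr_label == "deficient")),
                 clin$time_days, clin$event)
  hp <- clin$hr_label == "proficient"
  perm <- permutation_panel_test(pat_pre$values[, clin$patient_id[hp]],
                                 clin[hp, ], panel$panel,
                                 pool = "all_genes", B = perm_B,
                                 seed = seed + 14)
  res <- list(sim = sim, pre = pre, net = net, corr = corr, panel = panel,
              scores = scores, hr = hr, clinical = clin,
              predictions = data.frame(patient_id = clin$patient_id,
                                       predicted = predicted,
                                       observed = observed,
                                       stringsAsFactors = FALSE),
              evaluation = evaluation, cox = cox, perm = perm)
  if (!is.null(out_dir)) {
    tabs <- list(
      modules = data.frame(gene = names(net$decomposition$labels),
                           module = unname(net$decomposition$labels),
                           stringsAsFactors = FALSE),
      eigengenes = matrix_to_df(net$decomposition$eigengenes, "sample_id"),
      drug_signatures = do.call(rbind, lapply(net$signatures, function(s)
        data.frame(drug = s$drug, module = s$module, r = s$r, p = s$p,
                   weak = s$weak, stringsAsFactors = FALSE))),
      drug_groups = net$groups,
      correlations = as.data.frame(corr),
      panel = data.frame(gene = panel$panel, stringsAsFactors = FALSE),
      candidates = data.frame(gene = panel$candidates,
                              stringsAsFactors = FALSE),
      scores = as.data.frame(scores),
      hr_calls = as.data.frame(hr),
      clinical = as.data.frame(clin),
      predictions = res$predictions,
      survival_fit = data.frame(term = c("panel_low", "hr_deficient"),
                                coef = cox$coef, hr = cox$hr,
                                ci_lower = cox$ci_lower,
                                ci_upper = cox$ci_upper, p = cox$p_wald,
                                stringsAsFactors = FALSE))
    write_report(tabs, out_dir,
                 config = list(n_genes = design$n_genes,
                               n_samples = design$n_samples,
                               beta = net$beta, perm_B = perm_B),
                 seed = seed)
    scal <- list(accuracy = evaluation$accuracy,
                 permutation_p = perm$p,
                 observed_hr = perm$observed_hr)
    jsonlite::write_json(scal, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
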