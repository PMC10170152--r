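# ---------------------------------------------------------------------------
# Clinical validation: the combined panel + HR decision rule, the 300-day
# resistance definition, accuracy evaluation, survival statistics
# (Kaplan-Meier, log-rank, Cox PH), and the random-gene-panel permutation
# null for the panel hazard ratio.
# ---------------------------------------------------------------------------

#' Combined panel + HR status response prediction
#'
#' A patient is predicted a responder iff the panel label is `"high"` OR the
#' HR label is `"deficient"`; borderline HR is treated as not-deficient, so
#' the panel decides. A missing label gives `"indeterminate"`.
#'
#' @param panel_label `"high"` / `"low"` (vectorized).
#' @param hr_label `"deficient"` / `"borderline"` / `"proficient"`.
#' @return `"responder"` / `"resistant"` / `"indeterminate"`.
#' @export
predict_response <- function(panel_label, hr_label) {
  n <- max(length(panel_label), length(hr_label))
  panel_label <- rep(panel_label, length.out = n)
  hr_label <- rep(hr_label, length.out = n)
  ok <- panel_label %in% c("high", "low") &
    hr_label %in% c("deficient", "borderline", "proficient")
  out <- rep("indeterminate", n)
  out[ok] <- ifelse(panel_label[ok] == "high" | hr_label[ok] == "deficient",
                    "responder", "resistant")
  if (any(!ok))
    message(sprintf("predict_response: %d records with missing labels",
                    sum(!ok)))
  out
}

#' Observed resistance from progression-free survival
#'
#' Patients who progressed or died before the threshold are resistant; any
#' patient followed beyond the threshold (event or censored) is sensitive;
#' patients censored before the threshold are indeterminate (their outcome
#' is unobservable).
#'
#' @param clinical a [clinical_table()] with a PFS endpoint.
#' @param threshold_days resistance window (default 300 days = 10 months).
#' @return character vector `"resistant"` / `"sensitive"` /
#'   `"indeterminate"`, one per patient.
#' @export
define_observed_resistance <- function(clinical, threshold_days = 300) {
  if (any(clinical$time_days < 0)) stop("negative follow-up time")
  ifelse(clinical$time_days >= threshold_days, "sensitive",
         ifelse(clinical$event == 1, "resistant", "indeterminate"))
}

#' Evaluate response predictions against observed outcomes
#'
#' Accuracy is correct calls over non-indeterminate observations
#' (`responder` matches `sensitive`, `resistant` matches `resistant`);
#' indeterminate observations are excluded from the denominator. Accuracy is
#' also reported for the HR-proficient stratum when HR labels are supplied.
#'
#' @param predicted `"responder"` / `"resistant"` vector.
#' @param observed `"sensitive"` / `"resistant"` / `"indeterminate"` vector.
#' @param hr_label optional HR labels for the stratified accuracy.
#' @return list with `accuracy`, `n_evaluable`, `n_correct`, `confusion`
#'   (table), and `accuracy_hr_proficient` (NA when not computable).
#' @export
evaluate_predictions <- function(predicted, observed, hr_label = NULL) {
  stopifnot(length(predicted) == length(observed))
  eval_idx <- observed != "indeterminate" & predicted != "indeterminate"
  if (!any(eval_idx)) stop("no evaluable records")
  correct <- (predicted == "responder" & observed == "sensitive") |
    (predicted == "resistant" & observed == "resistant")
  acc <- sum(correct[eval_idx]) / sum(eval_idx)
  conf <- table(predicted = predicted[eval_idx], observed = observed[eval_idx])
  acc_hp <- NA_real_
  if (!is.null(hr_label)) {
    hp <- eval_idx & hr_label == "proficient"
    if (any(hp)) acc_hp <- sum(correct[hp]) / sum(hp)
  }
  list(accuracy = acc, n_evaluable = sum(eval_idx),
       n_correct = sum(correct[eval_idx]), confusion = conf,
       accuracy_hr_proficient = acc_hp)
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times follow-up times.
#' @param events event indicators (1 = observed).
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv` (one row per
#'   unique event time; `S(0) = 1` implicitly).
#' @export
kaplan_meier <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
             n_event = fit$n.event[keep], surv = fit$surv[keep])
}

#' Two-group log-rank test
#'
#' @param groups two-level group labels.
#' @param times follow-up times.
#' @param events event indicators.
#' @return list with `chisq` (1 df) and `p`.
#' @export
logrank_test <- function(groups, times, events) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly 2 groups required")
  if (any(table(g) == 0)) stop("one group is empty")
  if (sum(events) < 1) stop("at least one event required")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chisq = sd$chisq, p = stats::pchisq(sd$chisq, df = 1,
                                           lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Wraps a partial-likelihood fit (Efron tie handling by default) and
#' returns coefficients, hazard ratios with Wald 95% confidence intervals,
#' Wald and score (log-rank) p-values, and a convergence flag; monotone
#' likelihood (separation) is detected via an infinite-coefficient warning
#' or a runaway estimate and flagged as non-converged.
#'
#' @param covariates numeric vector, matrix or data.frame of covariates.
#' @param times follow-up times.
#' @param events event indicators (at least one event required).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list of class `survival_fit`: `coef`, `hr`, `ci_lower`,
#'   `ci_upper`, `se`, `p_wald`, `p_score`, `n`, `events`, `converged`,
#'   `ties`.
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(events) < 1) stop("at least one event required")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const)) stop("constant covariate: ",
                       paste(colnames(X)[const], collapse = ", "))
  storage.mode(X) <- "double"
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 50)
  fit <- suppressWarnings(survival::coxph.fit(
    X, survival::Surv(as.numeric(times), as.numeric(events)),
    strata = NULL, offset = NULL, init = rep(0, ncol(X)), control = ctrl,
    weights = NULL, method = ties, rownames = NULL))
  b <- unname(fit$coefficients)
  se <- sqrt(diag(as.matrix(fit$var)))
  # monotone partial likelihood (separation) shows up as a runaway estimate
  # or a fit that exhausts its iterations
  sep_flag <- any(!is.finite(b)) || any(abs(b) > 15) ||
    any(!is.finite(se)) || fit$iter >= ctrl$iter.max
  p_score <- stats::pchisq(fit$score, df = ncol(X), lower.tail = FALSE)
  structure(list(coef = b, hr = exp(b),
                 ci_lower = exp(b - 1.96 * se), ci_upper = exp(b + 1.96 * se),
                 se = se,
                 p_wald = 2 * stats::pnorm(-abs(b / se)),
                 p_score = p_score,
                 n = length(times), events = sum(events),
                 converged = !sep_flag, ties = ties),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("cox fit (%s ties): n = %d, events = %d%s\n", x$ties, x$n,
              x$events, if (!x$converged) " [NOT CONVERGED]" else ""))
  for (i in seq_along(x$coef))
    cat(sprintf("  B = %.4f  HR = %.4g (95%% CI %.4g-%.4g)  P = %.4g\n",
                x$coef[i], x$hr[i], x$ci_lower[i], x$ci_upper[i], x$p_wald[i]))
  invisible(x)
}

#' Random-gene-panel permutation test of the panel hazard ratio
#'
#' The observed statistic is the hazard ratio of the low-versus-high
#' dichotomized PCA panel score on the supplied cohort (covariate = 1 for
#' "low", so a protective high-expression panel yields HR > 1). Each of the
#' B permutations draws a random same-size gene list from the pool,
#' recomputes score, median label and hazard ratio the same way, and the
#' one-tailed empirical p is `(1 + #\{null HR >= observed\}) / (B' + 1)` over
#' the B' converged null fits (non-convergent fits are dropped and
#' counted).
#'
#' @param expr [expression_matrix()] or genes x samples matrix covering the
#'   cohort samples (columns matched to `clinical$patient_id`).
#' @param clinical a [clinical_table()] already restricted to the cohort of
#'   interest (e.g. HR-proficient patients).
#' @param panel_genes the gene panel (k genes).
#' @param pool `"all_genes"` (every expressed gene) or a character vector of
#'   candidate genes (e.g. top negatively correlated genes).
#' @param B number of permutations (default 1000).
#' @param seed integer seed.
#' @return list of class `permutation_result`: `observed_hr`, `null_hr`,
#'   `p`, `B`, `B_used`, `n_nonconverged`, `pool_size`, `seed`.
#' @export
permutation_panel_test <- function(expr, clinical, panel_genes,
                                   pool = "all_genes", B = 1000, seed = 17) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else expr
  idx <- match(clinical$patient_id, colnames(vals))
  if (anyNA(idx)) stop("patients missing from expression: ",
                       paste(clinical$patient_id[is.na(idx)], collapse = ", "))
  vals <- vals[, idx, drop = FALSE]
  pool_genes <- if (identical(pool, "all_genes")) rownames(vals)
  else intersect(pool, rownames(vals))
  k <- length(panel_genes)
  if (length(pool_genes) < k) stop("pool smaller than the panel size")
  hr_for <- function(genes) {
    sc <- pca_panel_score(vals, genes)
    lab <- dichotomize_by_median(sc$score)
    fit <- cox_fit(as.numeric(lab == "low"), clinical$time_days,
                   clinical$event)
    c(hr = fit$hr, ok = fit$converged)
  }
  obs <- hr_for(panel_genes)
  set.seed(seed)
  null <- t(vapply(seq_len(B), function(i) {
    hr_for(sample(pool_genes, k))
  }, numeric(2)))
  ok <- null[, 2] == 1
  null_hr <- null[ok, 1]
  p <- (1 + sum(null_hr >= obs["hr"])) / (length(null_hr) + 1)
  structure(list(observed_hr = unname(obs["hr"]), null_hr = unname(null_hr),
                 p = p, B = B, B_used = length(null_hr),
                 n_nonconverged = sum(!ok), pool_size = length(pool_genes),
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation test: observed HR = %.3f, one-tailed P = %.4g (B' = %d of %d, pool = %d genes)\n",
    x$observed_hr, x$p, x$B_used, x$B, x$pool_size))
  invisible(x)
}
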