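# ---------------------------------------------------------------------------
# Panel discovery: per-gene drug-sensitivity correlation screen with FDR,
# pre-ranked gene-set enrichment, hypergeometric annotation enrichment, and
# the intersection workflow producing the candidate panel.
# ---------------------------------------------------------------------------

#' Gene-by-drug Pearson correlation screen
#'
#' For every gene x drug pair with at least `min_n` pairwise-complete
#' observations: Pearson r, r Z-scaled across genes within drug, two-sided p
#' from `t = r * sqrt((n - 2) / (1 - r^2))`, and Benjamini-Hochberg q within
#' drug. Genes with zero variance are skipped with a warning.
#'
#' @param expr_residual [expression_matrix()] (residual scale) or matrix.
#' @param drugs [drug_response_table()] (Z-scaled) or samples x drugs matrix.
#' @param min_n minimum pairwise-complete sample count (default 10).
#' @return data.frame of class `correlation_table` with columns `gene`,
#'   `drug`, `r`, `r_z`, `p`, `q`, `n`.
#' @export
gene_drug_correlations <- function(expr_residual, drugs, min_n = 10) {
  ev <- if (inherits(expr_residual, "expression_matrix"))
    expr_residual$values else expr_residual
  dv <- if (inherits(drugs, "drug_response_table")) drugs$values else drugs
  common <- intersect(colnames(ev), rownames(dv))
  if (length(common) < min_n) stop("fewer than min_n shared samples")
  ev <- ev[, common, drop = FALSE]
  dv <- dv[common, , drop = FALSE]
  sds <- apply(ev, 1, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    warning(sprintf("%d constant genes skipped", sum(sds == 0, na.rm = TRUE)))
    ev <- ev[!is.na(sds) & sds > 0, , drop = FALSE]
  }
  out <- list()
  for (d in colnames(dv)) {
    y <- dv[, d]
    obs <- !is.na(y)
    if (!any(obs)) stop("drug entirely missing: ", d)
    r <- suppressWarnings(
      as.vector(stats::cor(t(ev), y, use = "pairwise.complete.obs")))
    n <- rowSums(!is.na(ev) & matrix(obs, nrow(ev), length(y), byrow = TRUE))
    keep <- !is.na(r) & n >= min_n
    r <- r[keep]; n <- n[keep]
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    out[[d]] <- data.frame(gene = rownames(ev)[keep], drug = d, r = r,
                           r_z = zscale(r), p = p, q = adjust_fdr(p), n = n,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("correlation_table", "data.frame")
  res
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return q-values (monotone, capped at 1), same order as input.
#' @export
adjust_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pre-ranked gene-set enrichment
#'
#' Classic weighted running-sum statistic on a ranked gene list: hits are
#' incremented by `|score|^weight` normalized over the set, misses
#' decremented by `1 / (N - |S|)`; the enrichment score (ES) is the maximum
#' deviation from zero. The null is formed by permuting gene labels; NES is
#' ES divided by the mean |null ES| of matching sign, and the empirical p is
#' plus-one smoothed over the same-signed null.
#'
#' @param scores named numeric vector of per-gene ranking scores (e.g.
#'   gene-drug correlations); ranked internally in decreasing order, ties
#'   broken by gene name for determinism.
#' @param gene_set character vector of member gene ids.
#' @param weight exponent on |score| for hit increments (default 1).
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list of class `gsea_result`: `es`, `nes`, `p`, `n_hits`,
#'   `leading_edge`.
#' @export
preranked_gsea <- function(scores, gene_set, weight = 1, n_perm = 1000,
                           seed = 17) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  hits <- names(scores) %in% gene_set
  nh <- sum(hits)
  if (nh < 2) stop("fewer than 2 set genes among the ranked scores")
  if (nh == length(scores)) stop("gene set spans the whole ranking")
  es_stat <- function(hits, s) {
    w <- abs(s)^weight
    inc <- numeric(length(s))
    tot <- sum(w[hits])
    if (tot == 0) { inc[hits] <- 1 / sum(hits) } else
      inc[hits] <- w[hits] / tot
    inc[!hits] <- -1 / (length(s) - sum(hits))
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }
  es <- es_stat(hits, scores)
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    es_stat(sample(hits), scores)
  }, numeric(1))
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
  run_idx <- which.max(abs(cumsum({
    w <- abs(scores)^weight
    inc <- numeric(length(scores))
    inc[hits] <- if (sum(w[hits]) == 0) 1 / nh else w[hits] / sum(w[hits])
    inc[!hits] <- -1 / (length(scores) - nh)
    inc
  })))
  le <- if (es >= 0) names(scores)[seq_len(run_idx)][hits[seq_len(run_idx)]]
  else names(scores)[run_idx:length(scores)][hits[run_idx:length(scores)]]
  structure(list(es = es, nes = nes, p = p, n_hits = nh, leading_edge = le),
            class = "gsea_result")
}

#' Hypergeometric annotation enrichment
#'
#' Upper-tail hypergeometric p-value for observing at least the given overlap
#' between a gene panel and an annotation set drawn from a finite universe.
#'
#' @param panel character vector (must lie inside `universe`).
#' @param annotation_set character vector (intersected with `universe`).
#' @param universe character vector of all testable genes.
#' @return list with `overlap`, `fold` (observed / expected), `p`.
#' @export
hypergeometric_enrichment <- function(panel, annotation_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(panel, universe)))
    stop("panel genes outside the universe")
  set <- intersect(unique(annotation_set), universe)
  ov <- length(intersect(panel, set))
  m <- length(set); n <- length(universe) - m; k <- length(panel)
  p <- stats::phyper(ov - 1, m, n, k, lower.tail = FALSE)
  expected <- k * m / length(universe)
  list(overlap = ov, fold = if (expected > 0) ov / expected else NA_real_,
       p = p)
}

#' Derive the candidate gene panel (intersection workflow)
#'
#' Candidates are the signature-module genes that are significantly
#' negatively correlated with drug sensitivity (r < 0 and q below the FDR
#' threshold); the panel is the candidates intersected with the annotation
#' set, ordered by ascending correlation (most negative first). With several
#' drugs (a drug group), a gene qualifies when it is significant for at
#' least half of the drugs (`mode = "half"`) or for all of them
#' (`mode = "all"`).
#'
#' @param signatures a single `drug_signature` or list of them (a drug
#'   group); their signature-module gene sets are unioned.
#' @param corr a `correlation_table` from [gene_drug_correlations()].
#' @param annotation_set character vector of annotated genes (e.g. the
#'   ribosome-biogenesis set).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param mode `"half"` (default) or `"all"`: fraction of group drugs for
#'   which a gene must be significant.
#' @return list of class `panel_definition`: `panel` (ordered), `candidates`,
#'   `module` label(s), `fdr_threshold`, `mode`.
#' @export
derive_candidate_panel <- function(signatures, corr, annotation_set,
                                   fdr_threshold = 0.05,
                                   mode = c("half", "all")) {
  mode <- match.arg(mode)
  if (inherits(signatures, "drug_signature")) signatures <- list(signatures)
  module_genes <- unique(unlist(lapply(signatures, `[[`, "members")))
  if (!length(module_genes)) stop("signature module is empty")
  drugs <- vapply(signatures, `[[`, character(1), "drug")
  sub <- corr[corr$drug %in% drugs, , drop = FALSE]
  sig <- sub$r < 0 & sub$q < fdr_threshold
  n_sig <- tapply(sig, sub$gene, sum)
  need <- if (mode == "all") length(drugs) else ceiling(length(drugs) / 2)
  sig_genes <- names(n_sig)[n_sig >= need]
  candidates <- intersect(module_genes, sig_genes)
  panel <- intersect(candidates, annotation_set)
  if (length(panel)) {
    mean_r <- tapply(sub$r[sub$gene %in% panel],
                     sub$gene[sub$gene %in% panel], mean)
    panel <- names(sort(mean_r))
  } else {
    warning("empty panel")
    panel <- character(0)
  }
  structure(list(panel = panel, candidates = sort(candidates),
                 module = unique(vapply(signatures, `[[`, character(1),
                                        "module")),
                 fdr_threshold = fdr_threshold, mode = mode),
            class = "panel_definition")
}
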