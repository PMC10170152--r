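# ---------------------------------------------------------------------------
# Signed weighted co-expression network: soft-threshold selection, signed
# adjacency, topological overlap, average-linkage module detection, module
# eigengenes, per-drug signature modules and drug grouping.
# ---------------------------------------------------------------------------

#' Network construction parameters
#'
#' @param powers candidate soft-threshold powers (positive integers).
#' @param rsq_target scale-free model fit target R-squared in (0,1].
#' @param cut_height dendrogram cut height on topological-overlap
#'   dissimilarity (1 - TOM) in (0,1].
#' @param min_module_size smallest cluster kept as a module.
#' @param merge_cor eigengene correlation above which modules are merged;
#'   `NULL` disables merging.
#' @return list of class `network_params`.
#' @export
network_params <- function(powers = 1:20, rsq_target = 0.80,
                           cut_height = 0.95, min_module_size = 20,
                           merge_cor = 0.75) {
  if (any(powers < 1) || any(powers != round(powers)))
    stop("powers must be positive integers")
  stopifnot(rsq_target > 0, rsq_target <= 1,
            cut_height > 0, cut_height <= 1)
  structure(list(powers = as.integer(powers), rsq_target = rsq_target,
                 cut_height = cut_height,
                 min_module_size = as.integer(min_module_size),
                 merge_cor = merge_cor),
            class = "network_params")
}

expr_cor <- function(expr_values) {
  if (any(apply(expr_values, 1, stats::sd) == 0))
    stop("constant genes present; filter before network construction")
  r <- stats::cor(t(expr_values), use = "pairwise.complete.obs")
  if (anyNA(r)) stop("pairwise-complete n < 3 for some gene pair")
  r
}

#' Scale-free fit index for one soft power
#'
#' Bins connectivity into `n_bins` equal-width bins and regresses log10 of
#' the empirical frequency p(k) on log10 of the mean connectivity per bin;
#' the index is `-sign(slope) * R^2`, so a scale-free (decreasing) degree
#' distribution yields a positive index. At least 8 occupied bins are
#' required, otherwise `NA`.
#' @keywords internal
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  cut_k <- cut(k, breaks = n_bins, include.lowest = TRUE)
  pk <- tabulate(cut_k, nbins = nlevels(cut_k)) / length(k)
  mk <- tapply(k, cut_k, mean)
  ok <- pk > 0 & !is.na(mk) & mk > 0
  if (sum(ok) < 8) return(NA_real_)
  fit <- stats::lm(log10(pk[ok]) ~ log10(mk[ok]))
  r2 <- summary(fit)$r.squared
  unname(-sign(stats::coef(fit)[2]) * r2)
}

#' Select the soft-threshold power for a signed network
#'
#' Returns the smallest candidate power whose scale-free fit index reaches
#' the target; when none qualifies, falls back to 12 with a warning.
#'
#' @param expr_residual an [expression_matrix()] (scale `"residual"`) or a
#'   genes x samples matrix.
#' @param params a [network_params()].
#' @return Integer power, with the per-power fit table in attribute `fits`.
#' @export
select_soft_threshold <- function(expr_residual, params = network_params()) {
  vals <- if (inherits(expr_residual, "expression_matrix"))
    expr_residual$values else expr_residual
  if (ncol(vals) < 20)
    warning("fewer than 20 samples; soft-threshold selection is unstable")
  s <- (1 + expr_cor(vals)) / 2
  diag(s) <- 0
  fits <- vapply(params$powers, function(b) {
    scale_free_fit(rowSums(s^b))
  }, numeric(1))
  tab <- data.frame(power = params$powers, fit = fits)
  qual <- which(!is.na(fits) & fits >= params$rsq_target)
  if (length(qual)) {
    beta <- params$powers[qual[1]]
  } else {
    warning("no candidate power reaches the scale-free target; using 12")
    beta <- 12L
  }
  attr(beta, "fits") <- tab
  beta
}

#' Signed adjacency matrix
#'
#' `a_ij = ((1 + cor(g_i, g_j)) / 2)^beta` with unit diagonal; under the
#' signed convention anti-correlated genes get adjacency near 0.
#'
#' @param expr_residual [expression_matrix()] or genes x samples matrix.
#' @param beta soft-threshold power (>= 1).
#' @return genes x genes adjacency matrix.
#' @export
signed_adjacency <- function(expr_residual, beta) {
  if (beta < 1) stop("beta must be >= 1")
  vals <- if (inherits(expr_residual, "expression_matrix"))
    expr_residual$values else expr_residual
  a <- ((1 + expr_cor(vals)) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' shared-neighbor sum over `u != i, j` and connectivity `k_i = sum_{u != i}
#' a_iu`; diagonal 1.
#'
#' @param a symmetric adjacency with entries in \[0,1\] and unit diagonal.
#' @return genes x genes TOM similarity.
#' @export
tom_similarity <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-12)) stop("adjacency must be symmetric")
  if (any(a < -1e-12) || any(a > 1 + 1e-12)) stop("adjacency entries must lie in [0,1]")
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  num <- a0 %*% a0 + a0
  den <- outer(k, k, pmin) + 1 - a0
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on dissimilarity `1 - TOM`, flat
#' clusters by cutting at the configured height; clusters below the minimum
#' module size are relabelled `"unassigned"`. When `merge_cor` is set and
#' expression is supplied, modules whose eigengenes correlate above the
#' threshold are merged iteratively. Surviving modules are renamed `M1, M2,
#' ...` in decreasing size order (ties by first gene id).
#'
#' @param tom TOM similarity matrix with gene dimnames.
#' @param params a [network_params()].
#' @param expr_residual optional expression (needed for the eigengene merge
#'   step and for the returned eigengenes).
#' @return list of class `module_decomposition`: `labels` (named gene ->
#'   module map), `members` (list per module), `eigengenes` (samples x
#'   modules, when expression given), `beta` (`NA` here; filled by
#'   [build_network()]), `connectivity` (named vector, when `a` supplied via
#'   attribute).
#' @export
detect_modules <- function(tom, params = network_params(),
                           expr_residual = NULL) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = params$cut_height)
  genes <- rownames(tom)
  labels <- stats::setNames(rep("unassigned", length(genes)), genes)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= params$min_module_size]
  for (g in keep) labels[cl == as.integer(g)] <- paste0("C", g)
  vals <- if (inherits(expr_residual, "expression_matrix"))
    expr_residual$values else expr_residual
  if (!is.null(vals) && !is.null(params$merge_cor)) {
    repeat {
      mods <- setdiff(unique(labels), "unassigned")
      if (length(mods) < 2) break
      eg <- sapply(mods, function(m)
        module_eigengene(vals, names(labels)[labels == m]))
      cc <- stats::cor(eg)
      diag(cc) <- -Inf
      mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (cc[mx[1], mx[2]] <= params$merge_cor) break
      labels[labels == mods[mx[2]]] <- mods[mx[1]]
    }
  }
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) {
    warning("all genes unassigned")
    return(structure(list(labels = labels, members = list(),
                          eigengenes = NULL, beta = NA_integer_,
                          connectivity = NULL),
                     class = "module_decomposition"))
  }
  sz <- vapply(mods, function(m) sum(labels == m), integer(1))
  first_gene <- vapply(mods, function(m) min(names(labels)[labels == m]),
                       character(1))
  ord <- order(-sz, first_gene)
  newname <- stats::setNames(paste0("M", seq_along(mods)), mods[ord])
  labels[labels != "unassigned"] <- newname[labels[labels != "unassigned"]]
  members <- lapply(stats::setNames(nm = sort(unname(newname))), function(m)
    names(labels)[labels == m])
  # order members list M1, M2, ... numerically
  members <- members[order(as.integer(sub("^M", "", names(members))))]
  eigengenes <- NULL
  if (!is.null(vals))
    eigengenes <- sapply(members, function(g) module_eigengene(vals, g))
  structure(list(labels = labels, members = members, eigengenes = eigengenes,
                 beta = NA_integer_, connectivity = NULL),
            class = "module_decomposition")
}

#' @export
print.module_decomposition <- function(x, ...) {
  cat(sprintf("module_decomposition: %d modules, %d genes (%d unassigned)\n",
              length(x$members), length(x$labels),
              sum(x$labels == "unassigned")))
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the gene-standardized member submatrix,
#' scaled to unit (sample) variance, sign-oriented so its correlation with
#' the mean standardized member profile is positive.
#'
#' @param expr_residual [expression_matrix()] or genes x samples matrix.
#' @param members character vector of >= 2 member gene ids.
#' @return Named sample-score vector with attribute `var_explained`.
#' @export
module_eigengene <- function(expr_residual, members) {
  vals <- if (inherits(expr_residual, "expression_matrix"))
    expr_residual$values else expr_residual
  if (length(members) < 2) stop("eigengene needs >= 2 member genes")
  miss <- setdiff(members, rownames(vals))
  if (length(miss)) stop("members absent from expression: ",
                         paste(miss, collapse = ", "))
  X <- vals[members, , drop = FALSE]
  X <- (X - rowMeans(X)) / apply(X, 1, stats::sd)
  sv <- svd(X, nu = 0, nv = 1)
  e <- sv$v[, 1]
  e <- e / stats::sd(e)
  if (stats::cor(e, colMeans(X)) < 0) e <- -e
  names(e) <- colnames(vals)
  attr(e, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  e
}

#' Signature module for one drug
#'
#' Pearson correlation of each module eigengene with the drug's (Z-scaled)
#' ln(IC50); the signature module is the most negatively correlated one, with
#' ties broken by larger module then label order. A `weak` flag is raised
#' when even the minimum correlation exceeds -0.3.
#'
#' @param decomposition a `module_decomposition` with eigengenes.
#' @param drug_sens named numeric vector of sensitivities (names = samples).
#' @param drug_id label recorded in the result.
#' @return list of class `drug_signature`: `drug`, `module`, `r`, `p`,
#'   `members`, `weak`, and the full per-module table `all_modules`.
#' @export
signature_module_for_drug <- function(decomposition, drug_sens,
                                      drug_id = "drug") {
  if (!length(decomposition$members)) stop("no modules in decomposition")
  eg <- decomposition$eigengenes
  common <- intersect(rownames(eg), names(drug_sens)[!is.na(drug_sens)])
  if (length(common) < 3) stop("fewer than 3 samples with both eigengene and sensitivity")
  tab <- do.call(rbind, lapply(colnames(eg), function(m) {
    ct <- stats::cor.test(eg[common, m], drug_sens[common])
    data.frame(module = m, r = unname(ct$estimate), p = ct$p.value,
               size = length(decomposition$members[[m]]),
               stringsAsFactors = FALSE)
  }))
  ord <- order(tab$r, -tab$size, tab$module)
  best <- tab[ord[1], ]
  structure(list(drug = drug_id, module = best$module, r = best$r, p = best$p,
                 members = decomposition$members[[best$module]],
                 weak = best$r > -0.3, all_modules = tab),
            class = "drug_signature")
}

#' Group drugs by signature-module similarity
#'
#' Builds a graph over drugs with an edge when the Jaccard similarity of
#' their signature-module gene sets is at least 0.5 (identical module labels
#' are trivially similarity 1); groups are the connected components. Drugs
#' whose largest between-group Jaccard falls in \[0.3, 0.5) are flagged
#' transitional.
#'
#' @param signatures list of `drug_signature` objects.
#' @return data.frame with `drug`, `module`, `group`, `transitional`.
#' @export
group_drugs_by_signature <- function(signatures) {
  if (!length(signatures)) stop("at least one drug required")
  n <- length(signatures)
  sets <- lapply(signatures, `[[`, "members")
  jac <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    u <- length(union(sets[[i]], sets[[j]]))
    jac[i, j] <- jac[j, i] <- if (u == 0) 0 else
      length(intersect(sets[[i]], sets[[j]])) / u
  }
  adj <- jac >= 0.5
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  transitional <- vapply(seq_len(n), function(i) {
    other <- comp != comp[i]
    any(other) && max(jac[i, other]) >= 0.3 && max(jac[i, other]) < 0.5
  }, logical(1))
  data.frame(drug = vapply(signatures, `[[`, character(1), "drug"),
             module = vapply(signatures, `[[`, character(1), "module"),
             group = comp, transitional = transitional,
             stringsAsFactors = FALSE)
}

#' Build the full network and signature-module analysis
#'
#' Convenience wrapper: selects the soft power, forms the signed adjacency
#' and TOM, detects modules, and assigns each drug its signature module.
#'
#' @param expr_residual [expression_matrix()] on the residual scale.
#' @param drugs [drug_response_table()] (Z-scaled).
#' @param params a [network_params()].
#' @param beta optional fixed soft power (skips selection).
#' @return list with `decomposition`, `beta`, `signatures`, `groups`.
#' @export
build_network <- function(expr_residual, drugs, params = network_params(),
                          beta = NULL) {
  if (is.null(beta)) beta <- select_soft_threshold(expr_residual, params)
  a <- signed_adjacency(expr_residual, beta)
  tom <- tom_similarity(a)
  dec <- detect_modules(tom, params, expr_residual)
  dec$beta <- as.integer(beta)
  a0 <- a; diag(a0) <- 0
  dec$connectivity <- rowSums(a0)
  sigs <- NULL; groups <- NULL
  if (!is.null(drugs) && length(dec$members)) {
    sigs <- lapply(drugs$drug_ids, function(d)
      signature_module_for_drug(dec, drugs$values[, d], drug_id = d))
    names(sigs) <- drugs$drug_ids
    groups <- group_drugs_by_signature(sigs)
  }
  list(decomposition = dec, beta = as.integer(beta), signatures = sigs,
       groups = groups)
}
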