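# ---------------------------------------------------------------------------
# Panel scoring: first-principal-component summary of panel expression per
# sample, dichotomized at the cohort median.
# ---------------------------------------------------------------------------

#' PCA panel score per sample
#'
#' The panel submatrix is gene-standardized across the cohort (mean 0, sd 1
#' per gene); the score is each sample's projection on the first principal
#' component (unit-norm loadings), sign-oriented so that its correlation
#' with the mean standardized panel expression is positive — a high score
#' means high panel expression. Panel genes missing from the expression
#' matrix or constant across the cohort are dropped with a warning; at least
#' two usable genes and at least half of the panel must remain.
#'
#' @param expr [expression_matrix()] (any scale) or genes x samples matrix.
#' @param panel_genes character vector of panel gene ids.
#' @return data.frame of class `panel_score` with columns `sample_id`,
#'   `score`; attributes `loadings` (named unit-norm weights) and
#'   `genes_used`.
#' @export
pca_panel_score <- function(expr, panel_genes) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else expr
  if (ncol(vals) < 3) stop("at least 3 samples required")
  present <- intersect(panel_genes, rownames(vals))
  if (length(present) < length(panel_genes))
    message(sprintf("pca_panel_score: %d panel genes absent from expression",
                    length(panel_genes) - length(present)))
  if (length(present) < length(panel_genes) / 2)
    stop("fewer than half of the panel genes present")
  X <- vals[present, , drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant panel genes dropped: ",
            paste(present[sds == 0], collapse = ", "))
    X <- X[sds > 0, , drop = FALSE]
  }
  if (nrow(X) < 2) stop("fewer than 2 usable panel genes")
  Xs <- (X - rowMeans(X)) / apply(X, 1, stats::sd)
  sv <- svd(Xs, nu = 1, nv = 0)
  w <- sv$u[, 1]                       # unit-norm gene loadings
  score <- as.vector(t(Xs) %*% w)
  if (stats::cor(score, colMeans(Xs)) < 0) { score <- -score; w <- -w }
  names(w) <- rownames(Xs)
  out <- data.frame(sample_id = colnames(vals), score = score,
                    stringsAsFactors = FALSE)
  attr(out, "loadings") <- w
  attr(out, "genes_used") <- rownames(Xs)
  class(out) <- c("panel_score", "data.frame")
  out
}

#' Dichotomize scores at the cohort median
#'
#' Label `"high"` iff score > median; scores equal to the median are labelled
#' `"low"` (ties go to low — conservative for responder calls). The median is
#' stored for reuse on held-out samples.
#'
#' @param scores numeric vector or a `panel_score` data.frame.
#' @param cutoff optional externally stored median; default computes the
#'   median of `scores`.
#' @return If given a vector, a character vector of labels with attribute
#'   `cutoff`; if given a `panel_score`, the same data.frame with a `label`
#'   column added.
#' @export
dichotomize_by_median <- function(scores, cutoff = NULL) {
  df <- NULL
  if (is.data.frame(scores)) { df <- scores; scores <- scores$score }
  if (length(scores) < 2) stop("at least 2 samples required")
  if (length(unique(scores)) == 1) stop("all scores identical; degenerate cohort")
  if (is.null(cutoff)) cutoff <- stats::median(scores)
  labels <- ifelse(scores > cutoff, "high", "low")
  if (!is.null(df)) {
    df$label <- labels
    attr(df, "cutoff") <- cutoff
    return(df)
  }
  attr(labels, "cutoff") <- cutoff
  labels
}
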