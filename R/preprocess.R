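# ---------------------------------------------------------------------------
# Normalization chain: variance-stabilizing-style transform of counts,
# covariate regression of expression and drug sensitivity, Z-scaling of
# sensitivities.
# ---------------------------------------------------------------------------

#' Variance-stabilizing-style transform of a count matrix
#'
#' Median-of-ratios size factors followed by `log2(count / size_factor + 1)`.
#' The per-sample size factor is the median over all-positive genes of the
#' ratio of the sample's count to the gene's geometric mean across samples.
#' When no gene is positive in every sample, size factors fall back to
#' library size divided by the mean library size (with a warning).
#'
#' @param expr an [expression_matrix()] with `scale = "counts"`.
#' @return An [expression_matrix()] with `scale = "transformed"`; the size
#'   factors used are kept in attribute `size_factors`.
#' @export
vst_like_transform <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$scale != "counts") stop("input must be on the counts scale")
  counts <- expr$values
  if (any(counts < 0)) stop("counts must be non-negative")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (any(allpos)) {
    loggeo <- rowMeans(log(counts[allpos, , drop = FALSE]))
    sf <- apply(exp(log(counts[allpos, , drop = FALSE]) - loggeo), 2,
                stats::median)
  } else {
    warning("no gene with all-positive counts; falling back to library-size factors")
    ls <- colSums(counts)
    sf <- ls / mean(ls)
  }
  out <- log2(sweep(counts, 2, sf, "/") + 1)
  res <- expression_matrix(out, expr$annotations, scale = "transformed")
  attr(res, "size_factors") <- sf[match(res$sample_ids, names(sf))]
  res
}

#' Build a covariate design matrix from sample annotations
#'
#' Categorical covariates are treatment-coded against the lexicographically
#' first level, with an intercept. Empty levels are dropped; a rank-deficient
#' design is an error naming the collinear columns.
#'
#' @param annotations data.frame with `sample_id` plus categorical columns.
#' @param covariates character vector of annotation columns to use; defaults
#'   to all non-id columns.
#' @return A list of class `covariate_design` with `matrix` (samples x
#'   columns), `covariates`, `sample_ids`.
#' @export
covariate_design <- function(annotations,
                             covariates = setdiff(names(annotations), "sample_id")) {
  miss <- setdiff(covariates, names(annotations))
  if (length(miss)) stop("unknown covariates: ", paste(miss, collapse = ", "))
  df <- annotations[, covariates, drop = FALSE]
  for (j in seq_along(df)) {
    if (anyNA(df[[j]]))
      stop("missing annotation values in `", covariates[j],
           "` must be encoded explicitly (e.g. \"unknown\")")
    df[[j]] <- factor(df[[j]], levels = sort(unique(as.character(df[[j]]))))
  }
  # single-level covariates carry no information beyond the intercept
  df <- df[, vapply(df, nlevels, integer(1)) > 1, drop = FALSE]
  X <- if (ncol(df)) stats::model.matrix(~ ., data = df) else
    matrix(1, nrow(annotations), 1, dimnames = list(NULL, "(Intercept)"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(list(matrix = X, covariates = covariates,
                 sample_ids = annotations$sample_id),
            class = "covariate_design")
}

#' Regress covariates out of a rows x samples value matrix
#'
#' Per row, ordinary-least-squares residuals against the indicator design
#' (intercept included). Missing entries are excluded from the fit and stay
#' missing in the output.
#'
#' @param values numeric matrix, rows are genes or drugs, columns are the
#'   samples of `design` (in the same order).
#' @param design a [covariate_design()].
#' @return Residual matrix of the same shape, dimnames preserved.
#' @export
regress_out_covariates <- function(values, design) {
  stopifnot(inherits(design, "covariate_design"))
  X <- design$matrix
  if (ncol(values) != nrow(X))
    stop("columns of `values` must match the design's samples")
  ok_rows <- rowSums(!is.na(values)) >= 2
  if (any(!ok_rows))
    stop("rows with fewer than 2 non-missing values: ",
         paste(utils::head(rownames(values)[!ok_rows], 5), collapse = ", "))
  res <- values
  complete <- !anyNA(values)
  if (complete) {
    qrX <- qr(X)
    res[] <- t(qr.resid(qrX, t(values)))
  } else {
    qrX <- qr(X)
    for (i in seq_len(nrow(values))) {
      y <- values[i, ]
      obs <- !is.na(y)
      if (all(obs)) {
        res[i, ] <- qr.resid(qrX, y)
      } else {
        Xi <- X[obs, , drop = FALSE]
        keep <- qr(Xi)$rank == ncol(Xi)
        if (!keep) {
          # drop empty levels for this row's observed samples
          Xi <- Xi[, qr(Xi)$pivot[seq_len(qr(Xi)$rank)], drop = FALSE]
        }
        res[i, obs] <- qr.resid(qr(Xi), y[obs])
        res[i, !obs] <- NA
      }
    }
  }
  res
}

#' Z-scale rows of a matrix (or a vector)
#'
#' `(x - mean) / sd` per row with the sample standard deviation (n - 1
#' denominator); missing values are ignored in the statistics and preserved
#' in the output.
#'
#' @param x numeric vector or matrix (rows scaled independently).
#' @return Same shape as `x`.
#' @export
zscale <- function(x) {
  scale_one <- function(v, label) {
    obs <- !is.na(v)
    if (sum(obs) < 2) stop("fewer than 2 non-missing values in ", label)
    s <- stats::sd(v[obs])
    if (s == 0) stop("zero standard deviation in ", label)
    (v - mean(v[obs])) / s
  }
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x)))
      out[i, ] <- scale_one(x[i, ], rownames(x)[i] %||% paste("row", i))
    out
  } else scale_one(x, "input vector")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full normalization chain on expression and drug data
#'
#' Transforms counts, regresses both expression and ln(IC50) on the
#' annotation covariates, then Z-scales the drug sensitivities (regression
#' first, scaling second).
#'
#' @param expr an [expression_matrix()] with counts.
#' @param drugs a [drug_response_table()] with raw ln(IC50).
#' @param covariates annotation columns to regress on; default all.
#' @param zscale_drugs logical; set `FALSE` to skip the final Z-scaling.
#' @return list with `expr` (scale `"residual"`), `drugs` (scale `"zscaled"`
#'   or `"residual"`), and the `design` used.
#' @export
preprocess_pipeline <- function(expr, drugs,
                                covariates = setdiff(names(expr$annotations),
                                                     "sample_id"),
                                zscale_drugs = TRUE) {
  vst <- vst_like_transform(expr)
  des <- covariate_design(vst$annotations, covariates)
  # drop genes constant after transform (cannot be correlated downstream)
  keep <- apply(vst$values, 1, function(v) stats::sd(v) > 0)
  if (any(!keep))
    message(sprintf("preprocess: dropping %d constant genes", sum(!keep)))
  expr_res <- regress_out_covariates(vst$values[keep, , drop = FALSE], des)
  eout <- expression_matrix(expr_res, vst$annotations, scale = "residual")
  common <- intersect(drugs$sample_ids, vst$sample_ids)
  if (length(common) < length(drugs$sample_ids))
    message(sprintf("preprocess: %d drug samples lack expression; dropped",
                    length(drugs$sample_ids) - length(common)))
  dv <- t(drugs$values[common, , drop = FALSE])       # drugs x samples
  idx <- match(common, des$sample_ids)
  des_d <- structure(list(matrix = des$matrix[idx, , drop = FALSE],
                          covariates = des$covariates, sample_ids = common),
                     class = "covariate_design")
  dres <- regress_out_covariates(dv, des_d)
  if (zscale_drugs) {
    dres <- zscale(dres)
    dscale <- "zscaled"
  } else dscale <- "residual"
  dout <- drug_response_table(t(dres), scale = dscale)
  list(expr = eout, drugs = dout, design = des)
}
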