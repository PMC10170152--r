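# ---------------------------------------------------------------------------
# HR-deficiency calling two ways: COSMIC-style signature-3 exposure from
# 96-context catalogs (cohort quartile/tertile rules), and shallowHRD-style
# LGA-count classes from copy-number segment profiles.
# ---------------------------------------------------------------------------

#' The 96 substitution classes in COSMIC-v2 order
#'
#' Order: substitutions C>A, C>G, C>T, T>A, T>C, T>G; within each, 5' flank
#' then 3' flank cycling over A, C, G, T — i.e. A\[C>A\]A ... T\[T>G\]T.
#'
#' @return character vector of length 96.
#' @export
cosmic_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(f, t)
      paste0(f, "[", s, "]", t))))))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(b) paste(rev(b), collapse = ""),
                character(1)))
}

#' Tally mutation records into a 96-context catalog
#'
#' Single-nucleotide substitutions only; records with a purine reference are
#' reverse-complemented into the pyrimidine (C/T reference) convention.
#' Records with non-ACGT letters, multi-nucleotide alleles, or a context
#' whose middle base differs from the reference are rejected and counted.
#'
#' @param records a [mutation_record_table()].
#' @return samples x 96 integer matrix (class columns in COSMIC-v2 order),
#'   with attribute `n_rejected`.
#' @export
build_mutation_catalog <- function(records) {
  stopifnot(inherits(records, "mutation_record_table"))
  ref <- toupper(records$ref); alt <- toupper(records$alt)
  ctx <- toupper(records$context)
  ok <- nchar(ref) == 1 & nchar(alt) == 1 & nchar(ctx) == 3 &
    grepl("^[ACGT]$", ref) & grepl("^[ACGT]$", alt) &
    grepl("^[ACGT]{3}$", ctx) & ref != alt &
    substr(ctx, 2, 2) == ref
  n_rej <- sum(!ok)
  if (n_rej) message(sprintf("build_mutation_catalog: %d records rejected",
                             n_rej))
  ref <- ref[ok]; alt <- alt[ok]; ctx <- ctx[ok]
  sample_id <- records$sample_id[ok]
  pur <- ref %in% c("A", "G")
  ref[pur] <- chartr("ACGT", "TGCA", ref[pur])
  alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
  ctx[pur] <- revcomp(ctx[pur])
  cls <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3),
                recycle0 = TRUE)
  classes <- cosmic_contexts()
  samples <- sort(unique(records$sample_id))
  cat_mat <- matrix(0L, length(samples), 96,
                    dimnames = list(samples, classes))
  tab <- table(factor(sample_id, levels = samples),
               factor(cls, levels = classes))
  cat_mat[] <- as.integer(tab)
  attr(cat_mat, "n_rejected") <- n_rej
  cat_mat
}

#' Refit signature exposures by non-negative least squares
#'
#' Per sample, solves `min ||catalog - S e||_2` subject to `e >= 0`;
#' exposures are in mutation-count units. The signature-3 level is the
#' exposure of the matrix's third column (or the column named
#' `Signature.3`).
#'
#' @param catalog samples x 96 count matrix.
#' @param signature_matrix 96 x K probability matrix (columns sum to 1).
#' @return data.frame of class `signature_exposure`: `sample_id`, one column
#'   per signature, `residual` (Euclidean norm of the reconstruction error),
#'   `sig3` (signature-3 exposure), `all_zero` flag.
#' @export
fit_signature_exposures <- function(catalog, signature_matrix) {
  if (ncol(catalog) != 96) stop("catalog must have 96 context columns")
  cs <- colSums(signature_matrix)
  if (any(abs(cs - 1) > 1e-6)) stop("signature columns must sum to 1")
  K <- ncol(signature_matrix)
  sig3_col <- if ("Signature.3" %in% colnames(signature_matrix))
    "Signature.3" else colnames(signature_matrix)[min(3, K)]
  res <- lapply(seq_len(nrow(catalog)), function(i) {
    y <- as.numeric(catalog[i, ])
    if (all(y == 0))
      return(c(rep(0, K), 0, TRUE))
    fit <- pracma::lsqnonneg(signature_matrix, y)
    c(fit$x, sqrt(sum((y - signature_matrix %*% fit$x)^2)), FALSE)
  })
  m <- do.call(rbind, res)
  out <- data.frame(sample_id = rownames(catalog),
                    m[, seq_len(K), drop = FALSE],
                    residual = m[, K + 1], all_zero = as.logical(m[, K + 2]),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[1 + seq_len(K)] <- colnames(signature_matrix)
  out$sig3 <- out[[sig3_col]]
  class(out) <- c("signature_exposure", "data.frame")
  out
}

#' Classify HR status from cohort signature-3 levels
#'
#' The cohort cutoff is the first quartile (`rule = "quartile"`) or lower
#' tertile (`rule = "tertile"`) of the signature-3 levels (linear
#' interpolation quantiles). Samples below the cutoff are `"proficient"`
#' (normal HR function) and samples at or above it `"deficient"`. The cutoff
#' is stored with every call so classifications are auditable.
#'
#' @param sig3_levels named numeric vector (or `signature_exposure`
#'   data.frame) of signature-3 exposures across the cohort.
#' @param rule `"quartile"` (default; at least 4 samples) or `"tertile"` (at
#'   least 3 samples).
#' @return data.frame of class `hr_call` with `sample_id`, `method`,
#'   `basis` (the level), `label`; attribute `cutoff`.
#' @export
classify_hr_by_signature3 <- function(sig3_levels, rule = c("quartile", "tertile")) {
  rule <- match.arg(rule)
  if (is.data.frame(sig3_levels))
    sig3_levels <- stats::setNames(sig3_levels$sig3, sig3_levels$sample_id)
  n_min <- if (rule == "quartile") 4 else 3
  if (length(sig3_levels) < n_min)
    stop("need at least ", n_min, " samples for the ", rule, " rule")
  q <- if (rule == "quartile") 0.25 else 1 / 3
  cutoff <- unname(stats::quantile(sig3_levels, q, type = 7))
  out <- data.frame(sample_id = names(sig3_levels) %||%
                      paste0("S", seq_along(sig3_levels)),
                    method = "signature3", basis = unname(sig3_levels),
                    label = ifelse(sig3_levels < cutoff, "proficient",
                                   "deficient"),
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  attr(out, "rule") <- rule
  class(out) <- c("hr_call", "data.frame")
  out
}

#' Count large-scale genomic alterations in a segment profile
#'
#' An LGA is a breakpoint between two adjacent segments on the same
#' chromosome where both segments reach the size threshold and the copy
#' numbers differ by at least the jump threshold; each qualifying breakpoint
#' counts once.
#'
#' @param profile one `segment_profile` (sorted, non-overlapping).
#' @param min_size_mb minimum segment length in Mb (default 10).
#' @param min_cn_jump minimum absolute copy-number difference (default 0.3).
#' @return Integer count.
#' @export
count_lga <- function(profile, min_size_mb = 10, min_cn_jump = 0.3) {
  stopifnot(inherits(profile, "data.frame"))
  total <- 0L
  for (chr in unique(profile$chrom)) {
    seg <- profile[profile$chrom == chr, , drop = FALSE]
    if (is.unsorted(seg$start)) stop("unsorted segments on ", chr)
    if (nrow(seg) < 2) next
    len_mb <- (seg$end - seg$start + 1) / 1e6
    big <- len_mb >= min_size_mb
    jump <- abs(diff(seg$cn)) >= min_cn_jump
    total <- total + sum(big[-nrow(seg)] & big[-1] & jump)
  }
  as.integer(total)
}

#' Classify HR status from an LGA count (shallowHRD-style classes)
#'
#' `"proficient"` for LGA < 15 (non-HR deficiency), `"borderline"` for
#' 15 <= LGA <= 19, `"deficient"` for LGA > 19.
#'
#' @param lga non-negative integer LGA count (vectorized).
#' @return character label(s).
#' @export
classify_shallow_hrd <- function(lga) {
  if (any(lga < 0)) stop("LGA count must be non-negative")
  ifelse(lga < 15, "proficient", ifelse(lga <= 19, "borderline", "deficient"))
}

#' HR calls for a set of segment profiles
#'
#' @param profiles named list of segment profiles.
#' @param min_size_mb,min_cn_jump thresholds passed to [count_lga()].
#' @return data.frame of class `hr_call` with `sample_id`, `method`
#'   (`"shallowHRD"`), `basis` (LGA count), `label`.
#' @export
classify_hr_by_lga <- function(profiles, min_size_mb = 10, min_cn_jump = 0.3) {
  lga <- vapply(profiles, count_lga, integer(1),
                min_size_mb = min_size_mb, min_cn_jump = min_cn_jump)
  out <- data.frame(sample_id = names(profiles), method = "shallowHRD",
                    basis = as.numeric(lga), label = classify_shallow_hrd(lga),
                    stringsAsFactors = FALSE)
  class(out) <- c("hr_call", "data.frame")
  out
}
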