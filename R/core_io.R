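#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Domain types (S3). All constructors validate their invariants and sort
# genes/samples lexicographically so downstream results are independent of
# input file row order.
# ---------------------------------------------------------------------------

#' Construct an expression matrix object
#'
#' Container for a gene x sample expression matrix plus per-sample categorical
#' annotations. Genes and samples are stored in lexicographic order; the
#' `scale` tag tracks what the values are (`"counts"`, `"transformed"` after
#' the variance-stabilizing-style transform, or `"residual"` after covariate
#' regression).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames.
#' @param annotations data.frame keyed by `sample_id`, one row per sample;
#'   remaining columns are categorical covariates (e.g. `tissue_of_origin`,
#'   `histology`).
#' @param scale one of `"counts"`, `"transformed"`, `"residual"`.
#' @return An object of class `expression_matrix` with fields `gene_ids`,
#'   `sample_ids`, `values`, `annotations`, `scale`.
#' @export
expression_matrix <- function(values, annotations, scale = "counts") {
  scale <- match.arg(scale, c("counts", "transformed", "residual"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(annotations))
    stop("annotations must have a `sample_id` column")
  missing <- setdiff(colnames(values), annotations$sample_id)
  if (length(missing))
    stop("samples missing from annotations: ", paste(missing, collapse = ", "))
  values <- values[order(rownames(values)), order(colnames(values)),
                   drop = FALSE]
  annotations <- annotations[match(colnames(values), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(gene_ids = rownames(values), sample_ids = colnames(values),
                 values = values, annotations = annotations, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (scale = %s)\n",
              length(x$gene_ids), length(x$sample_ids), x$scale))
  invisible(x)
}

#' Construct a drug response table
#'
#' Sample x drug matrix of ln(IC50) values (natural-log micromolar). Missing
#' values are allowed and encoded as `NA`.
#'
#' @param values numeric matrix, samples in rows, drugs in columns, dimnames
#'   required.
#' @param scale one of `"raw"`, `"residual"`, `"zscaled"`.
#' @return An object of class `drug_response_table`.
#' @export
drug_response_table <- function(values, scale = "raw") {
  scale <- match.arg(scale, c("raw", "residual", "zscaled"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample rownames and drug colnames")
  values <- values[order(rownames(values)), order(colnames(values)),
                   drop = FALSE]
  structure(list(sample_ids = rownames(values), drug_ids = colnames(values),
                 values = values, scale = scale),
            class = "drug_response_table")
}

#' @export
print.drug_response_table <- function(x, ...) {
  cat(sprintf("drug_response_table: %d samples x %d drugs (scale = %s)\n",
              length(x$sample_ids), length(x$drug_ids), x$scale))
  invisible(x)
}

#' Construct a clinical time-to-event table
#'
#' @param df data.frame with columns `patient_id`, `time_days` (non-negative),
#'   `event` (0/1), `endpoint` (`"OS"`, `"PFI"`, `"DFI"` or `"PFS"`),
#'   `treatment`; extra covariate columns (panel score/label, HR label) pass
#'   through.
#' @return data.frame of class `clinical_table`.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_days", "event", "endpoint", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(df$time_days)) || any(df$time_days < 0))
    stop("time_days must be finite and >= 0; first offending patient: ",
         df$patient_id[which(!is.finite(df$time_days) | df$time_days < 0)[1]])
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 or 1; first offending patient: ",
         df$patient_id[which(!df$event %in% c(0, 1))[1]])
  bad <- !df$endpoint %in% c("OS", "PFI", "DFI", "PFS")
  if (any(bad)) stop("unknown endpoint tag: ", df$endpoint[which(bad)[1]])
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Construct segment profiles from a segment data.frame
#'
#' @param df data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `cn` (absolute copy number); coordinates 1-based inclusive.
#' @return A named list of `segment_profile` objects (one per sample), each a
#'   data.frame sorted by chromosome and start with non-overlapping segments.
#' @export
segment_profiles <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "cn")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("segment table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$end < df$start))
    stop("segment with end < start: sample ", df$sample_id[df$end < df$start][1])
  out <- lapply(split(df, df$sample_id), function(s) {
    s <- s[order(s$chrom, s$start), , drop = FALSE]
    for (chr in unique(s$chrom)) {
      seg <- s[s$chrom == chr, , drop = FALSE]
      if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)]))
        stop("overlapping segments on ", chr, " for sample ", s$sample_id[1])
    }
    rownames(s) <- NULL
    class(s) <- c("segment_profile", "data.frame")
    s
  })
  out[order(names(out))]
}

#' Validate a table of somatic single-nucleotide mutation records
#'
#' Context is the 3-letter upstream-site-downstream sequence on the reported
#' strand; the reference allele must equal the middle base.
#'
#' @param df data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `context`.
#' @return The validated data.frame with class `mutation_record_table`.
#' @export
mutation_record_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "context")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mutation table missing columns: ",
                         paste(miss, collapse = ", "))
  class(df) <- c("mutation_record_table", "data.frame")
  df
}

# ---------------------------------------------------------------------------
# Readers
# ---------------------------------------------------------------------------

read_tsv_strict <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = "")
}

#' Read an expression matrix with sample annotations
#'
#' Ingestion applies the preprocessing rules used throughout: rows sharing a
#' gene id are summed into one record, genes whose expression is zero in every
#' sample are dropped, and (optionally) genes absent from a coding-gene
#' whitelist are dropped. Counts removed by each rule are reported via
#' `message()`.
#'
#' @param path expression TSV: first column `gene_id`, one column per sample.
#' @param annotation_path annotation TSV keyed by `sample_id` with categorical
#'   covariate columns (`tissue_of_origin`, `histology`, ...).
#' @param coding_genes optional character vector (or path to a one-column
#'   file) of gene ids to keep; `NULL` keeps all.
#' @return An [expression_matrix()] with `scale = "counts"`.
#' @export
read_expression <- function(path, annotation_path, coding_genes = NULL) {
  raw <- read_tsv_strict(path)
  if (names(raw)[1] != "gene_id")
    stop("expression TSV must start with a `gene_id` column")
  gene <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(raw[[bad + 1]]))))[1]
    stop(sprintf("non-numeric expression value at gene `%s`, sample `%s`",
                 gene[badrow], names(raw)[bad + 1]))
  }
  n0 <- length(gene)
  if (anyDuplicated(gene)) {
    mat <- rowsum(mat, group = gene, reorder = TRUE)
  } else {
    rownames(mat) <- gene
  }
  n_dup <- n0 - nrow(mat)
  allzero <- rowSums(mat != 0, na.rm = TRUE) == 0
  mat <- mat[!allzero, , drop = FALSE]
  n_wl <- 0L
  if (!is.null(coding_genes)) {
    if (length(coding_genes) == 1 && file.exists(coding_genes))
      coding_genes <- readLines(coding_genes)
    keep <- rownames(mat) %in% coding_genes
    n_wl <- sum(!keep)
    mat <- mat[keep, , drop = FALSE]
  }
  message(sprintf(
    "read_expression: %d input rows; %d collapsed as duplicates, %d all-zero genes dropped, %d outside whitelist; %d genes retained",
    n0, n_dup, sum(allzero), n_wl, nrow(mat)))
  ann <- read_tsv_strict(annotation_path)
  expression_matrix(mat, ann, scale = "counts")
}

#' Read a sample x drug ln(IC50) table
#'
#' @param path TSV with a `sample_id` column then one column per drug; blank
#'   cells are missing.
#' @param min_n minimum non-missing values required per drug before any
#'   correlation involving it may be computed (recorded, enforced
#'   downstream).
#' @return A [drug_response_table()] with `scale = "raw"` and attribute
#'   `min_n`.
#' @export
read_drug_table <- function(path, min_n = 10) {
  raw <- read_tsv_strict(path)
  if (names(raw)[1] != "sample_id")
    stop("drug TSV must start with a `sample_id` column")
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- as.character(raw$sample_id)
  storage.mode(mat) <- "double"
  out <- drug_response_table(mat, scale = "raw")
  attr(out, "min_n") <- min_n
  message(sprintf("read_drug_table: %d samples x %d drugs",
                  nrow(mat), ncol(mat)))
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Member lists are deduplicated; empty sets are rejected.
#'
#' @param path GMT file path.
#' @return Named list of class `gene_set_collection`; each element has
#'   `description` and `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with no members: ", f[1])
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set: ", f[1])
    list(description = f[2], members = members)
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  class(sets) <- "gene_set_collection"
  sets
}

#' Read copy-number segments (SEG)
#'
#' @param path TSV with columns `sample_id`, `chrom`, `start`, `end`, `cn`
#'   (absolute copy number, 1-based inclusive coordinates).
#' @return Named list of segment profiles; see [segment_profiles()].
#' @export
read_seg <- function(path) {
  segment_profiles(read_tsv_strict(path))
}

#' Read somatic mutation records (MAF-lite)
#'
#' @param path TSV with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `context`.
#' @return A [mutation_record_table()].
#' @export
read_maf <- function(path) {
  mutation_record_table(read_tsv_strict(path))
}

#' Read a clinical time-to-event table
#'
#' @param path TSV with columns `patient_id`, `time_days`, `event`,
#'   `endpoint`, `treatment` (extra columns pass through).
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  clinical_table(read_tsv_strict(path))
}

#' Read a 96-context mutational signature matrix
#'
#' Expects 96 rows in the canonical COSMIC-v2 substitution-class order
#' (A\[C>A\]A ... T\[T>G\]T) in a `context` column, one column per signature;
#' each signature column must sum to 1 (within 1e-6).
#'
#' @param path signature TSV.
#' @return Numeric 96 x K matrix with context rownames.
#' @export
read_signature_matrix <- function(path) {
  raw <- read_tsv_strict(path)
  if (names(raw)[1] != "context")
    stop("signature TSV must start with a `context` column")
  S <- as.matrix(raw[, -1, drop = FALSE])
  rownames(S) <- raw$context
  if (!identical(rownames(S), cosmic_contexts()))
    stop("signature matrix rows must be the 96 COSMIC-v2 classes in order")
  cs <- colSums(S)
  if (any(abs(cs - 1) > 1e-6))
    stop("signature columns must sum to 1; offending: ",
         paste(colnames(S)[abs(cs - 1) > 1e-6], collapse = ", "))
  S
}

# ---------------------------------------------------------------------------
# Writers. All numeric output is formatted with a fixed 15-significant-digit
# rule so reruns with identical inputs are byte-identical.
# ---------------------------------------------------------------------------

fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.15g", x))
}

write_tsv_det <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

matrix_to_df <- function(mat, id_col) {
  df <- data.frame(rownames(mat), as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  df
}

#' Write an expression matrix to TSV
#' @param x [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  write_tsv_det(matrix_to_df(x$values, "gene_id"), path)
}

#' Write a drug response table to TSV
#' @param x [drug_response_table()].
#' @param path output path.
#' @export
write_drug_table <- function(x, path) {
  write_tsv_det(matrix_to_df(x$values, "sample_id"), path)
}

#' Write pipeline results and a run manifest
#'
#' Emits deterministic TSV files (one per result element that is a data frame
#' or matrix) plus `manifest.json` recording the configuration, seed and
#' package version.
#'
#' @param results named list; data.frame/matrix elements become
#'   `<name>.tsv`, scalar elements are recorded in the manifest.
#' @param out_dir output directory (created if needed).
#' @param config named list recorded verbatim in the manifest.
#' @param seed integer seed used for the run.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, out_dir, config = list(), seed = NA_integer_) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  scalars <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.matrix(x)) x <- matrix_to_df(x, "id")
    if (is.data.frame(x)) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      write_tsv_det(x, p)
      paths <- c(paths, p)
    } else scalars[[nm]] <- x
  }
  manifest <- list(package = "ribopanel",
                   version = as.character(utils::packageVersion("ribopanel")),
                   seed = seed, config = config, scalars = scalars,
                   files = basename(paths))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}
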