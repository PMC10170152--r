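# ---------------------------------------------------------------------------
# Synthetic-data generators. Every generator returns its ground truth
# alongside the simulated object so downstream stages can be tested against
# known structure. All randomness flows through an explicit seed.
# ---------------------------------------------------------------------------

#' Define a simulation design
#'
#' One object holds every parameter of the synthetic study: a factor model
#' for co-expressed gene modules, linear module-to-drug coupling, mutational
#' catalogs as Poisson mixtures of signature profiles, copy-number segment
#' profiles with a planted count of large-scale genomic alterations (LGA),
#' and a proportional-hazards survival cohort driven by panel score and HR
#' status.
#'
#' Defaults define the study conditions used throughout the package's own
#' validation: 4 planted modules of 50 genes (factor loading 0.7) plus 300
#' background genes over 120 samples and 3 tissues; 4 drugs coupled to module
#' 1 with slope -1.5 and noise sd 0.5; an 8-gene panel inside module 1 that
#' carries additional drug-coupled signal; a 60-patient cohort with panel
#' log-hazard coefficient -1, HR-deficiency coefficient -0.5, baseline hazard
#' 1/400 per day and censoring rate 1/800 per day.
#'
#' @param n_genes total number of genes.
#' @param n_samples number of cell-line samples.
#' @param modules list of `list(size=, lambda=)`; `lambda` in (0,1] is the
#'   latent-factor loading, so within-module latent correlation is lambda^2.
#' @param noise_sd standard deviation of gene-level latent noise.
#' @param tissues named numeric vector of per-tissue additive offsets on the
#'   latent scale; samples are assigned tissues round-robin.
#' @param lib_size target library size (expected total counts per sample).
#' @param drugs list of `list(name=, module=, b=, sd=)`; ln(IC50) = b *
#'   f_module + extra panel coupling + N(0, sd). Negative `b` encodes "high
#'   module expression => sensitive".
#' @param panel list(module=, size=, lambda=, b=): the planted panel genes
#'   are the first `size` genes of module `module`; they load with `lambda`
#'   on an extra latent factor that also enters every drug with slope `b`.
#' @param cohort list(n_patients=, beta_panel=, beta_hrd=, baseline_hazard=,
#'   censor_rate=): proportional-hazards survival generator parameters (rates
#'   per day).
#' @param catalog list(total=, exposures=): mean mutation count per sample
#'   and a default exposure fraction vector over signatures.
#' @param segments list(lga=): planted LGA count per simulated profile.
#' @param seed integer seed recorded with the design.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 500, n_samples = 120,
                              modules = rep(list(list(size = 50, lambda = 0.7)), 4),
                              noise_sd = 1,
                              tissues = c(breast = 0, ovary = 0.6, lung = -0.6),
                              lib_size = 2e5,
                              drugs = list(
                                list(name = "olaparib",    module = 1, b = -1.5, sd = 0.5),
                                list(name = "rucaparib",   module = 1, b = -1.5, sd = 0.5),
                                list(name = "talazoparib", module = 1, b = -1.5, sd = 0.5),
                                list(name = "cisplatin",   module = 1, b = -1.5, sd = 0.5)),
                              panel = list(module = 1, size = 8, lambda = 0.45,
                                           b = -0.6),
                              cohort = list(n_patients = 60, beta_panel = -1,
                                            beta_hrd = -0.5,
                                            baseline_hazard = 1 / 400,
                                            censor_rate = 1 / 800),
                              catalog = list(total = 5000,
                                             exposures = c(0.5, 0.2, 0.2, 0.1)),
                              segments = list(lga = 12),
                              seed = 17) {
  sizes <- vapply(modules, `[[`, numeric(1), "size")
  lambdas <- vapply(modules, `[[`, numeric(1), "lambda")
  if (length(modules) && any(sizes <= 0)) stop("module sizes must be positive")
  if (length(modules) && any(lambdas <= 0 | lambdas > 1))
    stop("module loadings must lie in (0, 1]")
  if (sum(sizes) > n_genes)
    stop("module sizes exceed n_genes")
  if (n_genes <= 0 || n_samples <= 0) stop("sizes must be positive")
  for (d in drugs)
    if (length(modules) && (d$module < 1 || d$module > length(modules)))
      stop("drug target module index out of range: ", d$name)
  if (!is.null(cohort) &&
      (cohort$baseline_hazard <= 0 || cohort$censor_rate <= 0))
    stop("hazard and censoring rates must be positive")
  structure(list(n_genes = n_genes, n_samples = n_samples, modules = modules,
                 noise_sd = noise_sd, tissues = tissues, lib_size = lib_size,
                 drugs = drugs, panel = panel, cohort = cohort,
                 catalog = catalog, segments = segments, seed = seed),
            class = "simulation_design")
}

gene_names <- function(n) sprintf("G%04d", seq_len(n))
sample_names <- function(n) sprintf("S%03d", seq_len(n))

#' Simulate a count expression matrix with planted co-expressed modules
#'
#' Each module m has a latent sample factor f_m ~ N(0,1); a member gene g has
#' latent value lambda * f_m + sqrt(1 - lambda^2) * noise, so the expected
#' within-module latent correlation is lambda^2. Background genes are pure
#' noise. Genes of the planted panel additionally load on a panel factor that
#' the drug generator shares. Per-tissue offsets are added to every gene's
#' latent value, latents are mapped to Poisson counts via exp() scaled to the
#' target library size.
#'
#' @param design a [simulation_design()].
#' @param seed integer; defaults to the design seed.
#' @return list with `expr` (an [expression_matrix()], scale `"counts"`) and
#'   `truth`: `labels` (gene -> module, `"background"` for noise genes,
#'   modules named `"M1"`...), `factors` (samples x modules+panel matrix of
#'   latent factors), `panel_genes`, `latent` (genes x samples latent values).
#' @export
simulate_expression <- function(design, seed = design$seed) {
  set.seed(seed)
  p <- design$n_genes; n <- design$n_samples
  genes <- gene_names(p); samples <- sample_names(n)
  k <- length(design$modules)
  labels <- rep("background", p)
  latent <- matrix(stats::rnorm(p * n, sd = design$noise_sd), p, n,
                   dimnames = list(genes, samples))
  factors <- matrix(0, n, k + 1,
                    dimnames = list(samples,
                                    c(if (k) paste0("M", seq_len(k)), "panel")))
  idx <- 0
  for (m in seq_len(k)) {
    sz <- design$modules[[m]]$size
    lam <- design$modules[[m]]$lambda
    f <- stats::rnorm(n)
    factors[, m] <- f
    rows <- idx + seq_len(sz)
    latent[rows, ] <- lam * matrix(f, sz, n, byrow = TRUE) +
      sqrt(1 - lam^2) * matrix(stats::rnorm(sz * n), sz, n)
    labels[rows] <- paste0("M", m)
    idx <- idx + sz
  }
  panel_genes <- character(0)
  if (!is.null(design$panel) && k) {
    pm <- design$panel$module
    start <- if (pm > 1) sum(vapply(design$modules[seq_len(pm - 1)], `[[`,
                                    numeric(1), "size")) else 0
    rows <- start + seq_len(design$panel$size)
    panel_genes <- genes[rows]
    fp <- stats::rnorm(n)
    factors[, "panel"] <- fp
    lp <- design$panel$lambda
    # panel genes: renormalized blend of module, panel and noise components
    lam <- design$modules[[pm]]$lambda
    resid_sd <- sqrt(max(0, 1 - lam^2 - lp^2))
    latent[rows, ] <- lam * matrix(factors[, pm], length(rows), n, byrow = TRUE) +
      lp * matrix(fp, length(rows), n, byrow = TRUE) +
      resid_sd * matrix(stats::rnorm(length(rows) * n), length(rows), n)
  }
  tissue <- rep(names(design$tissues), length.out = n)
  latent_off <- latent +
    matrix(design$tissues[tissue], p, n, byrow = TRUE)
  mu <- exp(latent_off)
  mu <- sweep(mu, 2, colSums(mu), "/") * design$lib_size
  counts <- matrix(stats::rpois(p * n, mu), p, n,
                   dimnames = list(genes, samples))
  ann <- data.frame(sample_id = samples, tissue_of_origin = tissue,
                    histology = rep(c("carcinoma", "adenocarcinoma"),
                                    length.out = n),
                    stringsAsFactors = FALSE)
  names(labels) <- genes
  list(expr = expression_matrix(counts, ann, scale = "counts"),
       truth = list(labels = labels, factors = factors,
                    panel_genes = panel_genes, latent = latent))
}

#' Simulate ln(IC50) drug responses coupled to module factors
#'
#' ln(IC50) for a drug targeting module m is `b * f_m + b_panel * f_panel +
#' N(0, sd)`; negative slopes encode sensitivity at high module expression.
#' The panel term is only added when the design defines a planted panel.
#'
#' @param design a [simulation_design()].
#' @param factors samples x factors matrix from [simulate_expression()].
#' @param seed integer seed.
#' @return list with `drugs` (a [drug_response_table()], scale `"raw"`) and
#'   `truth` (per-drug target module, slope, noise sd).
#' @export
simulate_drug_response <- function(design, factors, seed = design$seed + 1) {
  set.seed(seed)
  n <- nrow(factors)
  vals <- sapply(design$drugs, function(d) {
    if (d$module > ncol(factors) - 1 || d$module < 1)
      stop("target module index out of range: ", d$module)
    y <- d$b * factors[, d$module] + stats::rnorm(n, sd = d$sd)
    if (!is.null(design$panel) && "panel" %in% colnames(factors))
      y <- y + design$panel$b * factors[, "panel"]
    y
  })
  colnames(vals) <- vapply(design$drugs, `[[`, character(1), "name")
  rownames(vals) <- rownames(factors)
  truth <- data.frame(drug = colnames(vals),
                      module = vapply(design$drugs, `[[`, numeric(1), "module"),
                      b = vapply(design$drugs, `[[`, numeric(1), "b"),
                      sd = vapply(design$drugs, `[[`, numeric(1), "sd"),
                      stringsAsFactors = FALSE)
  list(drugs = drug_response_table(vals, scale = "raw"), truth = truth)
}

#' Generate a synthetic 96-context signature matrix
#'
#' Builds K probability profiles over the 96 substitution classes in
#' COSMIC-v2 layout. Each signature concentrates its mass on a distinct
#' random subset of contexts so the columns are far from collinear and NNLS
#' refitting is well conditioned. This is a synthetic stand-in with the same
#' format as a COSMIC-v2 signature file, not the COSMIC signatures
#' themselves.
#'
#' @param n_signatures number of signatures K.
#' @param seed integer seed.
#' @return 96 x K matrix, columns summing to 1, named `Signature.1` ...
#' @export
synthetic_signature_matrix <- function(n_signatures = 4, seed = 1) {
  set.seed(seed)
  ctx <- cosmic_contexts()
  S <- sapply(seq_len(n_signatures), function(k) {
    w <- stats::rgamma(96, shape = 0.3)
    peaks <- sample.int(96, 8)
    w[peaks] <- w[peaks] + stats::rgamma(8, shape = 8)
    w / sum(w)
  })
  dimnames(S) <- list(ctx, paste0("Signature.", seq_len(n_signatures)))
  S
}

#' Simulate per-sample 96-context mutation catalogs
#'
#' Counts are Poisson with mean `total * S %*% e` where `e` is the sample's
#' exposure fraction vector (summing to 1) over the signature columns of `S`.
#'
#' @param design a [simulation_design()]; `design$catalog$total` is the mean
#'   total mutation count and `design$catalog$exposures` the default
#'   exposure fractions.
#' @param signature_matrix 96 x K probability matrix.
#' @param exposures optional samples x K matrix of exposure fractions (rows
#'   sum to 1); defaults to the design vector replicated.
#' @param n_samples number of catalogs when `exposures` is not given.
#' @param seed integer seed.
#' @return list with `catalog` (samples x 96 count matrix) and `truth`
#'   (exposure fractions and totals used).
#' @export
simulate_mutation_catalog <- function(design, signature_matrix,
                                      exposures = NULL, n_samples = 10,
                                      seed = design$seed + 2) {
  set.seed(seed)
  K <- ncol(signature_matrix)
  if (is.null(exposures)) {
    e <- design$catalog$exposures
    if (length(e) != K) stop("exposure vector length must match signatures")
    exposures <- matrix(e, n_samples, K, byrow = TRUE)
    rownames(exposures) <- sprintf("C%03d", seq_len(n_samples))
  }
  if (any(exposures < 0)) stop("exposures must be non-negative")
  rs <- rowSums(exposures)
  if (any(abs(rs - 1) > 1e-8)) {
    warning("exposure rows do not sum to 1; normalizing")
    exposures <- exposures / rs
  }
  colnames(exposures) <- colnames(signature_matrix)
  mu <- design$catalog$total * exposures %*% t(signature_matrix)
  counts <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu),
                   dimnames = dimnames(mu))
  list(catalog = counts, truth = list(exposures = exposures,
                                      total = design$catalog$total))
}

#' Simulate copy-number segment profiles with a planted LGA count
#'
#' Uses a toy genome of 22 chromosomes of 100 Mb. The planted large-scale
#' genomic alterations (LGA) are breakpoints between adjacent segments that
#' both reach the size threshold and differ in copy number by at least the
#' jump threshold; they are laid down as alternating-copy-number runs of
#' 12 Mb segments. Distractor chromosomes carry breakpoints violating
#' exactly one criterion each (a 5 Mb segment with a large jump; two large
#' segments with a 0.1 jump).
#'
#' @param design a [simulation_design()]; `design$segments$lga` is the
#'   planted count.
#' @param sample_ids character vector of profile names.
#' @param lga_counts optional integer vector (recycled) of per-sample planted
#'   counts; defaults to the design value.
#' @param min_size_mb,min_cn_jump thresholds the planted breakpoints satisfy
#'   (and distractors violate); keep in sync with [count_lga()].
#' @return list with `profiles` (named list of segment profiles) and `truth`
#'   (planted counts).
#' @export
simulate_segments <- function(design, sample_ids = "P001",
                              lga_counts = design$segments$lga,
                              min_size_mb = 10, min_cn_jump = 0.3) {
  lga_counts <- rep(as.integer(lga_counts), length.out = length(sample_ids))
  if (any(lga_counts < 0)) stop("planted LGA count must be >= 0")
  mb <- 1e6
  seg_len <- 12 * mb
  per_chr <- floor(100 * mb / seg_len) - 1   # breakpoints per planted chrom
  n_distractor <- 2
  max_lga <- (22 - n_distractor) * per_chr
  rows <- list()
  for (i in seq_along(sample_ids)) {
    L <- lga_counts[i]
    if (L > max_lga)
      stop("planted count ", L, " exceeds genome capacity ", max_lga)
    chr_i <- 1
    remaining <- L
    while (remaining > 0) {
      k <- min(remaining, per_chr)            # k breakpoints = k+1 segments
      cn <- rep(c(2, 3), length.out = k + 1)
      start <- seq(0, k) * seg_len + 1
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sample_ids[i], chrom = sprintf("chr%d", chr_i),
        start = start, end = start + seg_len - 1, cn = cn,
        stringsAsFactors = FALSE)
      remaining <- remaining - k
      chr_i <- chr_i + 1
    }
    # distractor 1: big jump but one segment below the size threshold
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sample_ids[i], chrom = "chr21",
      start = c(1, 20 * mb + 1, 25 * mb + 1),
      end = c(20 * mb, 25 * mb, 45 * mb),
      cn = c(2, 3.5, 2), stringsAsFactors = FALSE)
    # distractor 2: both segments large but jump below the threshold
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sample_ids[i], chrom = "chr22",
      start = c(1, 40 * mb + 1),
      end = c(40 * mb, 80 * mb),
      cn = c(2, 2 + min_cn_jump / 3), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  list(profiles = segment_profiles(df),
       truth = data.frame(sample_id = sample_ids, lga = lga_counts,
                          stringsAsFactors = FALSE))
}

#' Simulate a survival cohort under a proportional-hazards model
#'
#' Event times are exponential with hazard `baseline_hazard * exp(beta_panel
#' * score + beta_hrd * 1[HR-deficient])`; censoring times are independent
#' exponential with the censoring rate; observed time is the minimum and the
#' event flag marks which came first.
#'
#' @param design a [simulation_design()] (its `cohort` element supplies the
#'   coefficients and rates).
#' @param panel_scores numeric vector, one per patient.
#' @param hr_labels character vector (`"deficient"`, `"borderline"`,
#'   `"proficient"`), one per patient; only `"deficient"` enters the hazard.
#' @param endpoint endpoint tag for the resulting table.
#' @param seed integer seed.
#' @return list with `clinical` (a [clinical_table()] carrying `panel_score`
#'   and `hr_label` columns) and `truth` (the generating coefficients).
#' @export
simulate_cohort <- function(design, panel_scores, hr_labels,
                            endpoint = "PFS", seed = design$seed + 3) {
  if (length(panel_scores) != length(hr_labels))
    stop("one score and one HR label per patient required")
  ch <- design$cohort
  if (ch$baseline_hazard <= 0 || ch$censor_rate <= 0)
    stop("rates must be positive")
  set.seed(seed)
  n <- length(panel_scores)
  lin <- ch$beta_panel * panel_scores + ch$beta_hrd * (hr_labels == "deficient")
  t_event <- stats::rexp(n, rate = ch$baseline_hazard * exp(lin))
  t_cens <- stats::rexp(n, rate = ch$censor_rate)
  df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                   time_days = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens),
                   endpoint = endpoint, treatment = "PARPi",
                   panel_score = panel_scores, hr_label = hr_labels,
                   stringsAsFactors = FALSE)
  list(clinical = clinical_table(df),
       truth = list(beta_panel = ch$beta_panel, beta_hrd = ch$beta_hrd,
                    baseline_hazard = ch$baseline_hazard,
                    censor_rate = ch$censor_rate))
}
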