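test_that("gene-drug correlations match the hand t-test example and the naive oracle", {
  # hand example: r = 0.6, t = 1.0607, p ~ 0.40
  ev <- rbind(g1 = c(1, 2, 3, 4))
  colnames(ev) <- sprintf("s%d", 1:4)
  dv <- cbind(d1 = c(2, 1, 4, 3))
  rownames(dv) <- colnames(ev)
  ct <- suppressWarnings(gene_drug_correlations(rbind(ev, g2 = c(4, 1, 3, 2)),
                                                dv, min_n = 4))
  row <- ct[ct$gene == "g1", ]
  expect_equal(row$r, 0.6, tolerance = 1e-12)
  expect_equal(row$r * sqrt((row$n - 2) / (1 - row$r^2)), 1.0607,
               tolerance = 1e-4)
  expect_equal(row$p, 2 * pt(-1.06066, df = 2), tolerance = 1e-4)

  # random matrices vs naive two-pass Pearson
  set.seed(7)
  ev2 <- matrix(rnorm(20 * 15), 20, 15,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:15)))
  dv2 <- matrix(rnorm(15 * 3), 15, 3,
                dimnames = list(colnames(ev2), c("d1", "d2", "d3")))
  ct2 <- gene_drug_correlations(ev2, dv2, min_n = 10)
  for (i in sample(nrow(ct2), 20)) {
    expect_equal(ct2$r[i],
                 naive_pearson(ev2[ct2$gene[i], ], dv2[, ct2$drug[i]]),
                 tolerance = 1e-12)
  }
})

test_that("perfectly coupled and constant genes are handled as specified", {
  y <- c(1.5, -0.5, 2, 0.25, 1)
  ev <- rbind(same = y, flat = rep(2, 5), other = c(5, 1, 2, 0, 4))
  colnames(ev) <- sprintf("s%d", 1:5)
  dv <- cbind(d = y); rownames(dv) <- colnames(ev)
  expect_warning(ct <- gene_drug_correlations(ev, dv, min_n = 5), "constant")
  expect_equal(ct$r[ct$gene == "same"], 1, tolerance = 1e-12)
  expect_false("flat" %in% ct$gene)
  dv[] <- NA
  expect_error(suppressWarnings(gene_drug_correlations(ev, dv, min_n = 2)),
               "missing")
})

test_that("BH adjustment matches the hand step-up and its invariants", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_error(adjust_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))       # monotone in sorted p
  perm <- sample(50)
  expect_equal(adjust_fdr(p[perm]), q[perm])           # order invariant
  expect_true(all(q >= p - 1e-15) && all(q <= 1))
})

test_that("GSEA ES equals the brute-force running sum on small rankings", {
  set.seed(9)
  for (i in 1:10) {
    scores <- setNames(rnorm(6), paste0("g", 1:6))
    gene_set <- sample(names(scores), 2)
    res <- preranked_gsea(scores, gene_set, n_perm = 50, seed = i)
    expect_equal(res$es, gsea_es_oracle(scores, gene_set), tolerance = 1e-12)
  }
  scores <- setNames(c(3, 2, 1, -1, -2, -3), paste0("g", 1:6))
  expect_error(preranked_gsea(scores, names(scores)), "whole ranking")
  expect_error(preranked_gsea(scores, "g1"), "fewer than 2")
  # bottom-tied non-set genes shift ES only through the miss decrement
  sc2 <- c(scores, g7 = -3, g8 = -3)
  res2 <- preranked_gsea(sc2, c("g1", "g2"), n_perm = 10, seed = 1)
  expect_equal(res2$es, gsea_es_oracle(sc2, c("g1", "g2")), tolerance = 1e-12)
})

test_that("GSEA finds planted enrichment and its permutation p behaves", {
  set.seed(10)
  scores <- setNames(c(sort(rnorm(40, 2), decreasing = TRUE),
                       rnorm(160)), sprintf("g%03d", 1:200))
  res <- preranked_gsea(scores, sprintf("g%03d", 1:20), n_perm = 200, seed = 3)
  expect_gt(res$es, 0.5)
  expect_lte(res$p, 0.01)
  expect_gte(res$p, 1 / 201)
  # deterministic under a fixed seed
  res2 <- preranked_gsea(scores, sprintf("g%03d", 1:20), n_perm = 200, seed = 3)
  expect_identical(res, res2)
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  universe <- sprintf("u%02d", 1:20)
  annot <- universe[1:5]
  panel <- universe[1:3]
  res <- hypergeometric_enrichment(panel, annot, universe)
  expect_equal(res$overlap, 3)
  expect_equal(res$p, choose(5, 3) / choose(20, 3), tolerance = 1e-12)
  # disjoint: p = 1
  expect_equal(hypergeometric_enrichment(universe[6:8], annot, universe)$p, 1)
  # universe = set: overlap = |panel|, p = 1
  expect_equal(hypergeometric_enrichment(panel, universe, universe)$p, 1)
  expect_error(hypergeometric_enrichment(c("zzz"), annot, universe), "outside")
})

test_that("candidate panel derivation is the stated set algebra", {
  sig <- structure(list(drug = "d1", module = "M1",
                        members = c("A", "B", "C", "D")),
                   class = "drug_signature")
  corr <- data.frame(gene = c("A", "B", "C", "D", "E", "F"),
                     drug = "d1",
                     r = c(0.5, -0.4, -0.6, -0.1, -0.5, 0.2),
                     p = 1, q = c(0.5, 0.01, 0.001, 0.5, 0.01, 0.9),
                     stringsAsFactors = FALSE)
  pd <- derive_candidate_panel(sig, corr, annotation_set = c("C", "F"))
  expect_equal(pd$candidates, c("B", "C"))
  expect_equal(pd$panel, "C")
  # annotation set = universe: panel = candidates (ordered by ascending r)
  pd2 <- derive_candidate_panel(sig, corr, annotation_set = corr$gene)
  expect_setequal(pd2$panel, pd2$candidates)
  expect_equal(pd2$panel, c("C", "B"))   # most negative first
  expect_warning(derive_candidate_panel(sig, corr, annotation_set = "ZZ"),
                 "empty")
})

test_that("group-mode panel derivation requires significance in half or all drugs", {
  sig <- lapply(c("d1", "d2"), function(d)
    structure(list(drug = d, module = "M1", members = c("A", "B")),
              class = "drug_signature"))
  corr <- data.frame(gene = rep(c("A", "B"), each = 2),
                     drug = rep(c("d1", "d2"), 2),
                     r = c(-0.5, -0.5, -0.5, -0.5),
                     p = 1, q = c(0.01, 0.01, 0.01, 0.5),
                     stringsAsFactors = FALSE)
  half <- derive_candidate_panel(sig, corr, annotation_set = c("A", "B"),
                                 mode = "half")
  expect_setequal(half$panel, c("A", "B"))    # B significant for 1 of 2 drugs
  all_ <- derive_candidate_panel(sig, corr, annotation_set = c("A", "B"),
                                 mode = "all")
  expect_equal(all_$panel, "A")
})

test_that("the FDR screen is calibrated under a global null", {
  # no expression-IC50 coupling: fraction of q < 0.05 calls stays near 0
  calls <- vapply(1:50, function(s) {
    set.seed(s)
    ev <- matrix(rnorm(50 * 30), 50, 30,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:30)))
    dv <- cbind(d = rnorm(30)); rownames(dv) <- colnames(ev)
    ct <- gene_drug_correlations(ev, dv, min_n = 20)
    mean(ct$q < 0.05)
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / (50 * 50))
  expect_lte(mean(calls), 0.05 + 2 * se)
})
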