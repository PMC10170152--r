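test_that("signed adjacency maps correlation extremes as expected", {
  s <- seq(0, 1, length.out = 10)
  x <- rbind(g1 = s, g2 = s, g3 = rev(s))
  colnames(x) <- sprintf("s%02d", 1:10)
  a <- signed_adjacency(x, beta = 6)
  expect_equal(a["g1", "g2"], 1)           # r = 1
  expect_equal(a["g1", "g3"], 0)           # r = -1
  set.seed(1)
  y <- matrix(rnorm(40), 2, 20, dimnames = list(c("a", "b"), NULL))
  r <- cor(y[1, ], y[2, ])
  expect_equal(signed_adjacency(y, 6)["a", "b"], ((1 + r) / 2)^6)
  # r = 0 exactly gives (1/2)^6
  z <- rbind(u = c(1, -1, 1, -1), v = c(1, 1, -1, -1))
  colnames(z) <- letters[1:4]
  expect_equal(signed_adjacency(z, 6)["u", "v"], 0.015625)
  expect_error(signed_adjacency(rbind(c = rep(1, 4), d = 1:4), 6), "constant")
})

test_that("TOM matches hand values and the triple-loop oracle", {
  # 2-gene network: TOM equals adjacency
  a2 <- matrix(c(1, .37, .37, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(tom_similarity(a2)["a", "b"], 0.37, tolerance = 1e-12)
  # complete graph: TOM identically 1
  a1 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(abs(tom_similarity(a1) - 1) < 1e-12))
  # 3-gene chain hand value
  a3 <- diag(3)
  a3[1, 2] <- a3[2, 1] <- 0.8
  a3[2, 3] <- a3[3, 2] <- 0.5
  dimnames(a3) <- list(letters[1:3], letters[1:3])
  expect_equal(tom_similarity(a3)[1, 3], 0.4 / 1.5, tolerance = 1e-12)
  # random 10-gene networks vs oracle
  for (s in 1:5) {
    set.seed(s)
    r <- matrix(runif(100), 10)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    dimnames(a) <- list(sprintf("g%02d", 1:10), sprintf("g%02d", 1:10))
    expect_lt(max(abs(tom_similarity(a) - tom_oracle(a))), 1e-10)
  }
  expect_error(tom_similarity(matrix(c(1, .2, .6, 1), 2, 2)), "symmetric")
})

test_that("TOM and adjacency are symmetric in [0,1] with unit diagonal", {
  fx <- default_fixture(seed = 21,
                        simulation_design(n_genes = 60, n_samples = 50,
                                          modules = list(list(size = 20, lambda = 0.7)),
                                          panel = NULL, seed = 21))
  a <- signed_adjacency(fx$pre$expr, 6)
  tom <- tom_similarity(a)
  for (m in list(a, tom)) {
    expect_true(isSymmetric(unname(m)))
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
  }
})

test_that("module detection separates perfect blocks and names by size", {
  n1 <- 6; n2 <- 4
  tom <- diag(n1 + n2)
  tom[1:n1, 1:n1] <- 1
  tom[n1 + 1:n2, n1 + 1:n2] <- 1
  g <- sprintf("g%02d", 1:(n1 + n2))
  dimnames(tom) <- list(g, g)
  dec <- detect_modules(tom, network_params(min_module_size = 3,
                                            merge_cor = NULL))
  expect_equal(unname(dec$labels[1:n1]), rep("M1", n1))
  expect_equal(unname(dec$labels[n1 + 1:n2]), rep("M2", n2))
})

test_that("pure-noise expression leaves at least 90% of genes unassigned", {
  frac <- vapply(1:10, function(s) {
    d <- simulation_design(n_genes = 100, n_samples = 60, modules = list(),
                           panel = NULL, drugs = list(), seed = s)
    sim <- simulate_expression(d, seed = s)
    pre <- suppressMessages(preprocess_pipeline(
      sim$expr, drug_response_table(matrix(rnorm(60), 60, 1,
        dimnames = list(sim$expr$sample_ids, "d")))))
    a <- signed_adjacency(pre$expr, 6)
    dec <- suppressWarnings(detect_modules(tom_similarity(a), network_params()))
    mean(dec$labels == "unassigned")
  }, numeric(1))
  expect_true(all(frac >= 0.9))
})

test_that("eigengene has unit variance, positive orientation, and matches eigen oracle", {
  set.seed(31)
  x <- matrix(rnorm(18), 3, 6,
              dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:6)))
  e <- module_eigengene(x, c("g1", "g2", "g3"))
  expect_equal(sd(e), 1, tolerance = 1e-10)
  xs <- t(scale(t(x)))
  expect_gt(cor(e, colMeans(xs)), 0)
  # brute-force eigendecomposition of the sample covariance of standardized genes
  ev <- eigen(crossprod(xs))$vectors[, 1]
  ev <- ev / sd(ev)
  if (cor(ev, colMeans(xs)) < 0) ev <- -ev
  expect_equal(unname(e), unname(ev), tolerance = 1e-10, ignore_attr = TRUE)

  # two identical genes: eigengene is their standardized profile
  y <- rbind(a = 1:6, b = 1:6)
  colnames(y) <- sprintf("s%d", 1:6)
  e2 <- module_eigengene(y, c("a", "b"))
  expect_equal(unname(e2), unname(scale(1:6)[, 1]), tolerance = 1e-10,
               ignore_attr = TRUE)

  # noiseless factor model: eigengene recovers the latent factor
  f <- rnorm(20)
  z <- outer(c(0.5, 1, 2, 3), f)
  dimnames(z) <- list(letters[1:4], sprintf("s%02d", 1:20))
  e3 <- module_eigengene(z, letters[1:4])
  expect_equal(abs(cor(e3, f)), 1, tolerance = 1e-10)

  expect_error(module_eigengene(y, "a"), ">= 2")
})

test_that("eigengene is invariant to member order and sample relabeling", {
  set.seed(32)
  x <- matrix(rnorm(50), 5, 10,
              dimnames = list(letters[1:5], sprintf("s%02d", 1:10)))
  e1 <- module_eigengene(x, c("a", "b", "c", "d", "e"))
  e2 <- module_eigengene(x, c("e", "c", "a", "d", "b"))
  expect_equal(e1, e2, tolerance = 1e-12)
  x2 <- x
  colnames(x2) <- sprintf("t%02d", 1:10)
  e3 <- module_eigengene(x2, letters[1:5])
  expect_equal(unname(e3), unname(e1), tolerance = 1e-12)
})

test_that("signature module is the most negative correlation with stated ties and flags", {
  set.seed(41)
  n <- 30
  eg <- cbind(M1 = rnorm(n), M2 = rnorm(n))
  rownames(eg) <- sprintf("s%02d", 1:n)
  dec <- structure(list(labels = NULL,
                        members = list(M1 = letters[1:5], M2 = letters[6:9]),
                        eigengenes = eg),
                   class = "module_decomposition")
  y <- -0.9 * eg[, "M1"] + 0.1 * rnorm(n)
  names(y) <- rownames(eg)
  sig <- signature_module_for_drug(dec, y, "drugA")
  expect_equal(sig$module, "M1")
  expect_false(sig$weak)
  # weak flag when nothing is strongly negative
  y2 <- rnorm(n) * 0.01 + 100
  names(y2) <- rownames(eg)
  y2 <- y2 - mean(y2)
  sig2 <- signature_module_for_drug(dec, y2, "drugB")
  expect_true(sig2$weak)
})

test_that("planted drug-coupled module is recovered by the signature rule", {
  hits <- vapply(1:20, function(s) {
    fx <- default_fixture(seed = s,
      simulation_design(n_genes = 160, n_samples = 120,
                        modules = rep(list(list(size = 40, lambda = 0.7)), 2),
                        panel = NULL,
                        drugs = list(list(name = "d", module = 1,
                                          b = -1.5, sd = 0.5)),
                        seed = s))
    net <- build_network(fx$pre$expr, fx$pre$drugs,
                         network_params(min_module_size = 10), beta = 6)
    truth_m1 <- names(fx$sim$truth$labels)[fx$sim$truth$labels == "M1"]
    sel <- net$signatures[["d"]]$members
    length(intersect(sel, truth_m1)) / length(union(sel, truth_m1)) > 0.8
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("drug grouping follows Jaccard components with transitional flags", {
  mk <- function(drug, members, module = "M1")
    structure(list(drug = drug, module = module, members = members),
              class = "drug_signature")
  # same module gene set: one group
  g <- group_drugs_by_signature(list(mk("a", letters[1:4]),
                                     mk("b", letters[1:4])))
  expect_equal(g$group, c(1, 1))
  # disjoint: two groups
  g2 <- group_drugs_by_signature(list(mk("a", letters[1:4]),
                                      mk("b", letters[5:8], "M2")))
  expect_equal(length(unique(g2$group)), 2)
  # hub transitivity: pairwise Jaccard (a,b)=0.6, (b,c)=0.6, (a,c) small
  sa <- sprintf("g%02d", 1:10)
  sb <- c(sprintf("g%02d", 3:10), "h1", "h2")          # |ab|=8/12 = 0.67
  sc <- c("h1", "h2", sprintf("g%02d", 5:10), "k1", "k2")
  g3 <- group_drugs_by_signature(list(mk("a", sa), mk("b", sb), mk("c", sc)))
  expect_equal(length(unique(g3$group)), 1)
})

test_that("soft threshold selection applies the smallest-qualifying rule and fallback", {
  fx <- default_fixture(seed = 51,
    simulation_design(n_genes = 80, n_samples = 60,
                      modules = list(list(size = 30, lambda = 0.8)),
                      panel = NULL, seed = 51))
  b <- suppressWarnings(select_soft_threshold(fx$pre$expr))
  fits <- attr(b, "fits")
  qual <- fits$power[!is.na(fits$fit) & fits$fit >= 0.80]
  if (length(qual)) expect_equal(as.integer(b), as.integer(qual[1]))
  else expect_equal(as.integer(b), 12L)
  # unreachable target forces the fallback with a warning
  expect_warning(
    b2 <- select_soft_threshold(fx$pre$expr,
                                network_params(rsq_target = 0.999999)),
    "12")
  expect_equal(as.integer(b2), 12L)
})

test_that("module partitions are robust across moderate powers", {
  fx <- default_fixture(seed = 61)
  part <- lapply(c(6, 8), function(b) {
    a <- signed_adjacency(fx$pre$expr, b)
    detect_modules(tom_similarity(a), network_params(), fx$pre$expr)$labels
  })
  common <- intersect(names(part[[1]]), names(part[[2]]))
  expect_gte(ari(part[[1]][common], part[[2]][common]), 0.8)
})
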