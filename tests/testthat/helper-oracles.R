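# Independent oracles and small fixture builders shared across tests.

# Naive two-pass Pearson correlation
naive_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Triple-loop topological overlap oracle
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- sapply(seq_len(n), function(i) sum(a[i, -i]))
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Brute-force GSEA running-sum enumeration (weighted hits, uniform misses)
gsea_es_oracle <- function(scores, gene_set, weight = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  hits <- names(s) %in% gene_set
  run <- 0; best <- 0
  tot <- sum(abs(s[hits])^weight)
  for (i in seq_along(s)) {
    run <- run + if (hits[i]) abs(s[i])^weight / tot else
      -1 / (length(s) - sum(hits))
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Hand-coded Cox partial log-likelihood (no ties, Breslow = Efron)
cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

cox_grid_oracle <- function(x, times, events, grid = seq(-5, 5, by = 1e-3)) {
  ll <- vapply(grid, cox_loglik, numeric(1), x = x, times = times,
               events = events)
  grid[which.max(ll)]
}

# Adjusted Rand index between two label vectors
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small expression fixture with annotations
toy_expression <- function(values, tissues = NULL) {
  if (is.null(tissues)) tissues <- rep("t1", ncol(values))
  ann <- data.frame(sample_id = colnames(values), tissue_of_origin = tissues,
                    stringsAsFactors = FALSE)
  expression_matrix(values, ann, scale = "counts")
}

default_fixture <- function(seed = 1, design = simulation_design(seed = seed)) {
  sim <- simulate_expression(design, seed = seed)
  dr <- simulate_drug_response(design, sim$truth$factors, seed = seed + 1)
  pre <- suppressMessages(preprocess_pipeline(sim$expr, dr$drugs))
  list(design = design, sim = sim, dr = dr, pre = pre)
}
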