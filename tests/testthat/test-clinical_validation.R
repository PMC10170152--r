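test_that("combined decision rule reproduces the full truth table", {
  grid <- expand.grid(panel = c("high", "low"),
                      hr = c("deficient", "borderline", "proficient"),
                      stringsAsFactors = FALSE)
  pred <- predict_response(grid$panel, grid$hr)
  expected <- c("responder",  # high, deficient
                "responder",  # low,  deficient
                "responder",  # high, borderline (panel decides)
                "resistant",  # low,  borderline
                "responder",  # high, proficient
                "resistant")  # low,  proficient
  expect_equal(pred, expected)
  expect_equal(suppressMessages(predict_response(NA, "proficient")),
               "indeterminate")
})

test_that("observed resistance uses the 300-day boundary with indeterminate censoring", {
  clin <- clinical_table(data.frame(
    patient_id = paste0("P", 1:5),
    time_days = c(250, 400, 200, 300, 299),
    event = c(1, 0, 0, 1, 1),
    endpoint = "PFS", treatment = "PARPi", stringsAsFactors = FALSE))
  obs <- define_observed_resistance(clin)
  expect_equal(obs, c("resistant", "sensitive", "indeterminate",
                      "sensitive", "resistant"))
})

test_that("accuracy excludes indeterminate records from the denominator", {
  pred <- c(rep("responder", 10), rep("resistant", 6))
  obs <- c(rep("sensitive", 9), "resistant", rep("resistant", 6))
  ev <- evaluate_predictions(pred, obs)
  expect_equal(ev$accuracy, 15 / 16)
  expect_equal(round(100 * ev$accuracy, 1), 93.8)
  ev2 <- evaluate_predictions(c("responder", "responder", "resistant",
                                "resistant", "responder"),
                              c("sensitive", "resistant", "sensitive",
                                "resistant", "indeterminate"))
  expect_equal(ev2$accuracy, 0.5)
  expect_equal(ev2$n_evaluable, 4)
  expect_equal(evaluate_predictions(pred, obs)$n_correct, 15)
  expect_error(evaluate_predictions("responder", "indeterminate"), "evaluable")
  # perfect agreement
  expect_equal(evaluate_predictions(c("responder", "resistant"),
                                    c("sensitive", "resistant"))$accuracy, 1)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km0 <- kaplan_meier(c(3, 8, 12), c(0, 0, 0))
  expect_equal(nrow(km0), 0)               # no events: S stays 1
  km1 <- kaplan_meier(c(10, 20, 30, 40), c(1, 0, 0, 0))
  expect_equal(km1$surv[km1$time == 10], 0.75)
  km <- kaplan_meier(c(5, 10, 10, 15), c(1, 1, 0, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0))
  expect_equal(km$time, c(5, 10, 15))
})

test_that("log-rank test matches a hand O-E computation and is symmetric", {
  # identical groups: statistic 0, p = 1
  t0 <- c(5, 8, 12, 5, 8, 12)
  e0 <- c(1, 1, 0, 1, 1, 0)
  g0 <- rep(c("a", "b"), each = 3)
  lr0 <- logrank_test(g0, t0, e0)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # 6-patient toy vs hand O-E
  times <- c(2, 4, 6, 8, 10, 12)
  events <- c(1, 1, 1, 1, 0, 1)
  groups <- c("a", "b", "a", "b", "a", "b")
  hand <- local({
    O <- 0; E <- 0; V <- 0
    for (t in sort(unique(times[events == 1]))) {
      at_risk <- times >= t
      d <- sum(times == t & events == 1)
      d_a <- sum(times == t & events == 1 & groups == "a")
      n <- sum(at_risk); n_a <- sum(at_risk & groups == "a")
      O <- O + d_a
      E <- E + d * n_a / n
      if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
  })
  lr <- logrank_test(groups, times, events)
  expect_equal(lr$chisq, hand, tolerance = 1e-10)
  lr_sw <- logrank_test(ifelse(groups == "a", "b", "a"), times, events)
  expect_equal(lr_sw$chisq, lr$chisq, tolerance = 1e-12)
  expect_error(logrank_test(rep("a", 6), times, events), "2 groups")
})

test_that("Cox fit matches the partial-likelihood grid oracle and flags separation", {
  # two identical groups: B = 0, HR = 1
  tt <- c(3, 5, 7, 9, 3, 5, 7, 9)
  ee <- c(1, 1, 0, 1, 1, 1, 0, 1)
  xx <- rep(c(0, 1), each = 4)
  fit0 <- cox_fit(xx, tt, ee)
  expect_equal(fit0$coef, 0, tolerance = 1e-8)
  expect_equal(fit0$hr, 1, tolerance = 1e-8)
  expect_true(fit0$ci_lower <= fit0$hr && fit0$hr <= fit0$ci_upper)

  # 8-patient toy without ties vs grid search
  set.seed(20)
  times <- c(1.5, 2.3, 3.1, 4.8, 5.2, 6.7, 7.4, 9.9)
  events <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 0, 1, 0, 1, 1, 0, 0)
  fit <- cox_fit(x, times, events)
  expect_lt(abs(fit$coef - cox_grid_oracle(x, times, events)), 2e-3)
  expect_true(fit$converged)

  # complete separation: all events early in one group
  ts <- c(1, 2, 3, 4, 50, 60, 70, 80)
  es <- c(1, 1, 1, 1, 0, 0, 0, 0)
  xs <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fit_sep <- cox_fit(xs, ts, es)
  expect_false(fit_sep$converged)

  expect_error(cox_fit(rep(1, 8), times, events), "constant")
  expect_error(cox_fit(x, times, rep(0, 8)), "at least one event")
})

test_that("log-rank and univariate Wald rejection decisions usually agree", {
  agree <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 200
    x <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, rate = 0.01 * exp(0.7 * x))
    t_c <- rexp(n, rate = 0.004)
    tt <- pmin(t_ev, t_c); ee <- as.integer(t_ev <= t_c)
    f <- cox_fit(x, tt, ee)
    lr <- logrank_test(x, tt, ee)
    (f$p_wald < 0.05) == (lr$p < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})

test_that("permutation test honors its bounds, determinism, and degenerate pool", {
  set.seed(22)
  d <- simulation_design(seed = 22)
  sim <- simulate_expression(d, seed = 22)
  vst <- vst_like_transform(sim$expr)
  sc <- dichotomize_by_median(pca_panel_score(vst, sim$truth$panel_genes))
  coh <- simulate_cohort(d, zscale(sc$score),
                         rep("proficient", length(sc$score)), seed = 23)
  clin <- coh$clinical
  clin$patient_id <- sim$expr$sample_ids
  # pool = exactly the panel genes: every draw reproduces the observed HR
  res <- permutation_panel_test(vst, clin, sim$truth$panel_genes,
                                pool = sim$truth$panel_genes, B = 20, seed = 1)
  expect_equal(res$p, 1)
  expect_true(all(abs(res$null_hr - res$observed_hr) < 1e-12))
  # p floor: plus-one smoothing
  res2 <- permutation_panel_test(vst, clin, sim$truth$panel_genes,
                                 pool = "all_genes", B = 50, seed = 2)
  expect_gte(res2$p, 1 / (res2$B_used + 1))
  expect_lte(res2$p, 1)
  res3 <- permutation_panel_test(vst, clin, sim$truth$panel_genes,
                                 pool = "all_genes", B = 50, seed = 2)
  expect_identical(res2[c("observed_hr", "null_hr", "p")],
                   res3[c("observed_hr", "null_hr", "p")])
  expect_error(permutation_panel_test(vst, clin, sim$truth$panel_genes,
                                      pool = sim$truth$panel_genes[1:4]),
               "pool smaller")
})
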