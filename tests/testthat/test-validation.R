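test_that("AUC equals pair enumeration, with the documented edge cases", {
  # spec-style worked example: cases {3,1}, controls {2,0} -> 3/4 pairs
  expect_equal(auc(c(3, 1, 2, 0), c("case", "case", "control", "control")),
               0.75)
  # perfect separation and all-tied scores
  expect_equal(auc(c(5, 6, 1, 2), c("case", "case", "control", "control")), 1)
  expect_equal(auc(rep(2, 6), rep(c("case", "control"), 3)), 0.5)
  expect_error(auc(1:4, rep("case", 4)), "both classes")

  # random small inputs against the enumeration oracle
  set.seed(41)
  for (i in 1:100) {
    n1 <- sample(2:8, 1); n0 <- sample(2:8, 1)
    scores <- sample(0:5, n1 + n0, replace = TRUE)  # ties likely
    labels <- rep(c("case", "control"), c(n1, n0))
    expect_equal(auc(scores, labels), auc_enumerate(scores, labels),
                 tolerance = 1e-12)
  }

  # invariance under strictly monotone transforms
  set.seed(42)
  sc <- rnorm(30); lb <- rep(c("case", "control"), 15)
  expect_equal(auc(exp(sc), lb), auc(sc, lb))
  expect_equal(auc(rank(sc), lb), auc(sc, lb))
})

test_that("diagnostic screening orientation-maximizes and flags by threshold", {
  sim <- generate_expression(200, 100, 30, deg_fraction = 0.1,
                             effect_log2fc = 2, noise_sd = 1, seed = 51)
  ds <- sim$dataset
  out <- screen_diagnostic(ds, ds$gene_ids, threshold = 0.70)
  planted <- out[out$gene %in% sim$deg_genes, ]
  nulls <- out[!out$gene %in% sim$deg_genes, ]
  expect_gte(mean(planted$auc), 0.9)
  expect_true(all(planted$diagnostic_flag))
  # down-shifted planted genes are reported with "down" orientation
  down <- names(sim$deg_sign)[sim$deg_sign < 0]
  expect_true(all(planted$orientation[planted$gene %in% down] == "down"))
  expect_true(all(out$auc >= 0.5, na.rm = TRUE))
  expect_lt(mean(nulls$diagnostic_flag), 0.05)

  # unattainable threshold flags nothing; unmeasured candidates yield NA rows
  none <- screen_diagnostic(ds, ds$gene_ids, threshold = 1.01)
  expect_false(any(none$diagnostic_flag))
  mixed <- screen_diagnostic(ds, c(ds$gene_ids[1], "MISSING"))
  expect_true(is.na(mixed$auc[mixed$gene == "MISSING"]))
  expect_error(screen_diagnostic(ds, "MISSING"), "no candidate")
})

test_that("Cox fit maximizes the partial likelihood and flips sign with x", {
  ds <- generate_expression(10, 60, 40, 0, 1, 0.5, seed = 61)$dataset
  g <- ds$gene_ids[1]
  surv <- generate_survival(ds, setNames(1.0, g), baseline_hazard = 1 / 500,
                            censor_time_max = 4000, seed = 62)
  x <- as.vector(scale(ds$matrix[g, ]))
  beta <- fit_univariate_cox(x, surv)
  # independent oracle: dense grid search on the Breslow partial likelihood
  beta_grid <- cox_grid_mle(x, surv$time_days, surv$event)
  expect_equal(beta, beta_grid, tolerance = 1e-3)
  # covariate negation symmetry
  expect_equal(fit_univariate_cox(-x, surv), -beta, tolerance = 1e-8)

  expect_error(fit_univariate_cox(rep(1, nrow(surv)), surv), "constant")
  surv0 <- surv; surv0$event <- 0
  expect_error(fit_univariate_cox(x, surv0), "no events")
})

test_that("Cox estimates recover the planted log-hazard coefficient", {
  hits <- 0
  for (s in 1:50) {
    ds <- generate_expression(5, 150, 150, 0, 1, 0.5,
                              seed = 700 + s)$dataset
    g <- ds$gene_ids[1]
    surv <- generate_survival(ds, setNames(1.0, g), baseline_hazard = 1 / 800,
                              censor_time_max = 6000, seed = 900 + s)
    x <- as.vector(scale(ds$matrix[g, ]))
    beta <- tryCatch(fit_univariate_cox(x, surv), error = function(e) NA)
    if (!is.na(beta) && beta >= 0.8 && beta <= 1.2) hits <- hits + 1
  }
  expect_gte(hits, 45)   # >= 90% of 50 replicates
})

test_that("null Cox estimates center at zero", {
  betas <- vapply(1:50, function(s) {
    ds <- generate_expression(2, 50, 50, 0, 1, 0.5, seed = 1000 + s)$dataset
    surv <- generate_survival(ds, setNames(numeric(0), character(0)),
                              baseline_hazard = 1 / 800,
                              censor_time_max = 6000, seed = 1100 + s)
    x <- as.vector(scale(ds$matrix[1, ]))
    tryCatch(fit_univariate_cox(x, surv), error = function(e) NA)
  }, 0.0)
  betas <- betas[!is.na(betas)]
  expect_lt(abs(mean(betas)), 0.1)
  expect_gt(mean(betas > 0), 0.3)
  expect_lt(mean(betas > 0), 0.7)
})

test_that("risk-group split is a deterministic median rule", {
  g <- split_risk_groups(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  # ties at the median go low; all-equal collapses to one group
  expect_equal(as.character(split_risk_groups(c(1, 1, 1, 5))),
               c("low", "low", "low", "high"))
  expect_true(all(split_risk_groups(rep(2, 4)) == "low"))
  # odd n: group sizes differ by exactly 1
  go <- split_risk_groups(c(10, 20, 30, 40, 50))
  expect_equal(abs(sum(go == "high") - sum(go == "low")), 1)
  expect_error(split_risk_groups(3), "at least 2")
})

test_that("Kaplan-Meier matches the hand product-limit estimator", {
  # all events, no censoring: empirical survival 2/3, 1/3, 0
  km <- kaplan_meier(data.frame(time_days = c(1, 2, 3), event = c(1, 1, 1)))
  expect_equal(km$surv, c(2, 1, 0) / 3)
  # censored-only data: S identically 1
  km0 <- kaplan_meier(data.frame(time_days = c(5, 8), event = c(0, 0)))
  expect_equal(km0$fn(c(0, 10)), c(1, 1))
  # mixed censoring against the direct product oracle
  set.seed(71)
  time <- round(rexp(10, 1 / 10), 1)
  event <- rbinom(10, 1, 0.7)
  km2 <- kaplan_meier(data.frame(time_days = time, event = event))
  oracle <- km_hand(time, event)
  expect_equal(km2$time, oracle$time)
  expect_equal(km2$surv, oracle$surv, tolerance = 1e-12)
  expect_equal(km2$fn(oracle$time), oracle$surv)   # right-continuity
  expect_error(kaplan_meier(data.frame(time_days = numeric(0),
                                       event = integer(0))), "empty")
})

test_that("log-rank O/E accumulation reproduces the worked example", {
  surv <- data.frame(time_days = c(1, 2, 3, 4), event = c(1, 1, 1, 0))
  grp <- factor(c("g1", "g1", "g2", "g2"), levels = c("g1", "g2"))
  lr <- logrank(surv, grp)
  expect_equal(lr$O1, 2)
  expect_equal(lr$E1, 5 / 6, tolerance = 1e-10)
  expect_equal(lr$O2, 1)
  expect_equal(lr$E2, 13 / 6, tolerance = 1e-10)
  expect_equal(lr$hr, 5.2, tolerance = 1e-10)
  # conservation: O1+O2 = E1+E2 = total events
  expect_equal(lr$O1 + lr$O2, 3)
  expect_equal(lr$E1 + lr$E2, 3, tolerance = 1e-10)

  # exchangeability: relabeling swaps (O1,E1) with (O2,E2), inverts HR
  lr_sw <- logrank(surv, factor(as.character(grp), levels = c("g2", "g1")))
  expect_equal(lr_sw$O1, lr$O2)
  expect_equal(lr_sw$E1, lr$E2, tolerance = 1e-10)
  expect_equal(lr_sw$hr, 1 / lr$hr, tolerance = 1e-10)

  # identical survival copies in both groups: no signal
  dup <- data.frame(time_days = rep(c(2, 5, 9), 2), event = rep(c(1, 1, 0), 2))
  lr_dup <- logrank(dup, rep(c("a", "b"), each = 3))
  expect_equal(lr_dup$chi2, 0, tolerance = 1e-10)
  expect_equal(lr_dup$p, 1, tolerance = 1e-10)
  expect_equal(lr_dup$hr, 1, tolerance = 1e-10)

  expect_error(logrank(surv, rep("g1", 4)), "2 non-empty groups")
})

test_that("prognostic screening flags planted genes and stays calibrated", {
  flagged <- 0
  for (s in 1:10) {
    ds <- generate_expression(30, 150, 150, 0, 1, 0.5, seed = 1200 + s)$dataset
    g <- ds$gene_ids[1]
    surv <- generate_survival(ds, setNames(1.0, g), baseline_hazard = 1 / 800,
                              censor_time_max = 6000, seed = 1300 + s)
    out <- screen_prognostic(ds, surv, c(g, "ABSENT"))
    row <- out[out$gene == g, ]
    if (isTRUE(row$prognostic_flag) && row$hr > 1) flagged <- flagged + 1
    # O/E conservation holds on every run
    expect_equal(row$O1 + row$O2, sum(surv$event))
    expect_equal(row$E1 + row$E2, sum(surv$event), tolerance = 1e-8)
    # absent candidate reported as NA row, run continues
    expect_true(is.na(out$beta[out$gene == "ABSENT"]))
  }
  expect_gte(flagged, 9)
})

test_that("O/E hazard ratio tracks exp(beta) under proportional hazards", {
  ds <- generate_expression(5, 300, 300, 0, 1, 0.5, seed = 81)$dataset
  g <- ds$gene_ids[1]
  surv <- generate_survival(ds, setNames(0.8, g), baseline_hazard = 1 / 500,
                            censor_time_max = 8000, seed = 82)
  expect_gt(sum(surv$event), 100)
  x <- as.vector(scale(ds$matrix[g, ]))
  grp <- split_risk_groups(fit_univariate_cox(x, surv) * x)
  lr <- logrank(surv, grp)
  # two-group Cox on the same split
  b2 <- fit_univariate_cox(as.numeric(grp == "high"), surv)
  expect_equal(lr$hr, exp(b2), tolerance = 0.15)
})
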