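test_that("generate_expression plants the requested signal and validates input", {
  sim <- generate_expression(100, 10, 10, deg_fraction = 0.2,
                             effect_log2fc = 1, noise_sd = 0.5, seed = 7)
  expect_length(sim$deg_genes, 20)
  expect_setequal(names(sim$deg_sign), sim$deg_genes)
  expect_true(all(sim$deg_sign %in% c(-1, 1)))
  expect_s3_class(sim$dataset, "ExpressionDataset")
  expect_equal(dim(sim$dataset$matrix), c(100, 20))

  null_sim <- generate_expression(100, 5, 5, deg_fraction = 0,
                                  effect_log2fc = 2, noise_sd = 0.5, seed = 1)
  expect_length(null_sim$deg_genes, 0)

  expect_error(generate_expression(100, 2, 5, seed = 1), "3 samples")
  expect_error(generate_expression(0, 5, 5, seed = 1), "n_genes")
  expect_error(generate_expression(10, 5, 5, deg_fraction = 1.5, seed = 1),
               "deg_fraction")
})

test_that("generators are pure functions of their seed", {
  a <- generate_expression(50, 5, 5, 0.2, 1, 0.5, seed = 7)
  b <- generate_expression(50, 5, 5, 0.2, 1, 0.5, seed = 7)
  expect_identical(a, b)
  c <- generate_expression(50, 5, 5, 0.2, 1, 0.5, seed = 8)
  expect_false(identical(a$dataset$matrix, c$dataset$matrix))

  expect_identical(generate_ppi(100, 2, seed = 3), generate_ppi(100, 2, seed = 3))
  g <- sprintf("G%03d", 1:200)
  expect_identical(
    generate_bipartite(20, g, n_active = 3, deg_genes = g[1:40], seed = 2),
    generate_bipartite(20, g, n_active = 3, deg_genes = g[1:40], seed = 2))

  ds <- generate_expression(20, 10, 10, 0, 1, 0.5, seed = 1)$dataset
  co <- c(G0001 = 1)
  names(co) <- rownames(ds$matrix)[1]
  expect_identical(generate_survival(ds, co, seed = 5),
                   generate_survival(ds, co, seed = 5))

  expect_identical(generate_bundle(n_genes = 100, seed = 11),
                   generate_bundle(n_genes = 100, seed = 11))
})

test_that("planted case/control shift appears with the planted sign", {
  sim <- generate_expression(200, 20, 20, deg_fraction = 0.1,
                             effect_log2fc = 2, noise_sd = 0.5, seed = 3)
  ds <- sim$dataset
  is_case <- ds$sample_labels == "case"
  lfc <- rowMeans(ds$matrix[, is_case]) - rowMeans(ds$matrix[, !is_case])
  # planted genes show the shift in the planted direction
  expect_true(all(sign(lfc[sim$deg_genes]) == sim$deg_sign[sim$deg_genes]))
  expect_true(all(abs(lfc[sim$deg_genes]) > 1))
  nulls <- setdiff(rownames(ds$matrix), sim$deg_genes)
  expect_true(mean(abs(lfc[nulls])) < 0.5)
})

test_that("preferential-attachment PPI is simple, connected, heavy-tailed", {
  el <- generate_ppi(5, 1, seed = 1)
  expect_equal(nrow(el), 4)   # m = 1 grows a tree: n - 1 edges
  g <- as_network(el)
  expect_true(igraph::is_connected(g))

  el2 <- generate_ppi(200, 2, seed = 3)
  g2 <- as_network(el2)
  expect_true(igraph::is_connected(g2))
  expect_false(igraph::any_multiple(g2))
  expect_equal(sum(igraph::which_loop(g2)), 0L)
  deg <- igraph::degree(g2)
  expect_gte(max(deg), 5 * median(deg))   # hub presence

  expect_error(generate_ppi(4, 4, seed = 1), "attach_m")
})

test_that("bipartite generator enriches active neighborhoods for DEGs", {
  genes <- sprintf("G%04d", 1:500)
  degs <- genes[1:100]
  net <- generate_bipartite(50, genes, targets_per_feature = c(5, 20),
                            n_active = 5, deg_genes = degs,
                            enrichment = 0.9, seed = 2)
  expect_length(net$active, 5)
  frac <- vapply(split(net$edges$gene, net$edges$feature),
                 function(t) mean(t %in% degs), 0.0)
  expect_true(all(frac[net$active] >= 0.5))
  inactive <- setdiff(names(frac), net$active)
  expect_lt(mean(frac[inactive]), 0.4)

  # enrichment = 0 gives no separation between active and inactive features
  null_net <- generate_bipartite(50, genes, n_active = 25, deg_genes = degs,
                                 enrichment = 0, seed = 9)
  frac0 <- vapply(split(null_net$edges$gene, null_net$edges$feature),
                  function(t) mean(t %in% degs), 0.0)
  tt <- t.test(frac0[null_net$active],
               frac0[setdiff(names(frac0), null_net$active)])
  expect_gt(tt$p.value, 0.01)

  expect_error(generate_bipartite(10, character(0), seed = 1), "empty")
  expect_error(generate_bipartite(10, genes, n_active = 11, seed = 1),
               "n_active")
})

test_that("survival generator respects the hazard model and censoring limits", {
  ds <- generate_expression(50, 100, 50, 0, 1, 0.5, seed = 4)$dataset
  g1 <- rownames(ds$matrix)[1]
  surv <- generate_survival(ds, setNames(1.0, g1), baseline_hazard = 1 / 500,
                            censor_time_max = 5000, seed = 6)
  expect_equal(nrow(surv), 150)
  expect_true(all(surv$time_days >= 0))
  expect_true(all(surv$event %in% 0:1))
  # high expression of the planted gene means shorter event times
  x <- ds$matrix[g1, surv$sample]
  ev <- surv$event == 1
  expect_lt(cor(x[ev], surv$time_days[ev]), 0)

  # censor_time_max -> 0 censors everything at time 0
  s0 <- generate_survival(ds, setNames(1.0, g1), censor_time_max = 0, seed = 1)
  expect_true(all(s0$event == 0))
  expect_true(all(s0$time_days == 0))

  expect_error(generate_survival(ds, setNames(1, "NOPE"), seed = 1), "absent")
  expect_error(generate_survival(ds, setNames(1, g1), baseline_hazard = 0,
                                 seed = 1), "baseline_hazard")
})

test_that("bundle round-trips through the on-disk dialect", {
  b <- generate_bundle(n_genes = 120, n_tf = 10, n_receptor = 10,
                       n_active_tf = 2, n_active_receptor = 2,
                       val_n_case = 20, val_n_control = 10, seed = 5)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "expression_1.tsv", "labels_1.tsv", "ppi.tsv", "tf_targets.tsv",
    "receptor_net.tsv", "validation_expression.tsv", "validation_labels.tsv",
    "survival.tsv", "truth.json")))))

  ds <- read_expression(file.path(dir, "expression_2.tsv"),
                        file.path(dir, "labels_2.tsv"))
  expect_equal(ds$matrix, b$datasets[[2]]$matrix, tolerance = 1e-12)
  expect_equal(unname(ds$sample_labels),
               unname(b$datasets[[2]]$sample_labels))

  surv <- read_survival(file.path(dir, "survival.tsv"))
  expect_equal(surv$event, b$validation$survival$event)

  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$deg_genes, b$truth$deg_genes)
  expect_setequal(truth$active_tfs, b$truth$active_tfs)
})
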