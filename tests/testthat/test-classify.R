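# Class balancing, stratified CV, the RBF-SVM grid experiment and its
# reporting.

test_that("balancing undersamples the majority class deterministically", {
  feat <- mock_feature_table(n_bl = 29, n_nbl = 65)
  bal <- balance_dataset(feat, seed = 3)
  expect_identical(nrow(bal), 58L)
  expect_identical(unname(table(bal$label)["BL"]), 29L)
  expect_identical(unname(table(bal$label)["NBL"]), 29L)
  expect_identical(balance_dataset(feat, seed = 3), bal)
  expect_false(identical(balance_dataset(feat, seed = 4), bal))
  # already balanced input: same multiset of rows
  even <- mock_feature_table(n_bl = 10, n_nbl = 10)
  bal2 <- balance_dataset(even, seed = 1)
  expect_identical(sort(bal2$record_id), sort(even$record_id))
  # a missing class is an error
  expect_error(balance_dataset(feat[feat$label == "BL", ], 1), "both classes")
})

test_that("confusion metrics follow their definitions", {
  m <- confusion_metrics(tp = 31, fn = 4, tn = 30, fp = 5)
  expect_equal(unname(m["sensitivity"]), 100 * 31 / 35, tolerance = 1e-12)
  expect_equal(unname(m["specificity"]), 100 * 30 / 35, tolerance = 1e-12)
  expect_equal(unname(m["oa"]), 100 * 61 / 70, tolerance = 1e-12)
})

test_that("stratified CV tests each record exactly once and separates separable data", {
  feat <- mock_feature_table(n_bl = 20, n_nbl = 20)
  cv <- run_cv(feat, gamma = 0.001, C = 2, seed = 1)
  expect_equal(unname(sum(cv$counts)), 40)              # every record tested once
  expect_equal(unname(cv$counts["tp"] + cv$counts["fn"]), 20)
  expect_gte(cv$metrics[["oa"]], 95)
})

test_that("label-shuffled data classifies at chance", {
  feat <- mock_feature_table(n_bl = 20, n_nbl = 20)
  oas <- sapply(1:20, function(s) {
    shuffled <- feat
    shuffled$label <- ppgtrend:::with_seed(500 + s, sample(feat$label))
    run_cv(shuffled, gamma = 0.01, C = 2, seed = s)$metrics[["oa"]]
  })
  expect_gt(mean(oas), 35)
  expect_lt(mean(oas), 65)
})

test_that("the experiment averages over the protocol's runs and is reproducible", {
  feat <- mock_feature_table(n_bl = 8, n_nbl = 12)
  grid <- build_param_grid()
  grid$gamma <- 0.001
  grid$C <- 2
  cfg <- experiment_config(n_resamples = 2, n_permutations = 3, seed = 11)
  res <- run_experiment(feat, cfg, grid)
  expect_identical(res$n_runs, 6L)
  expect_identical(dim(res$counts), c(1L, 1L, 6L, 4L))
  # single-cell consistency: the experiment equals direct run_cv averaging
  oas <- sapply(seq_len(cfg$n_resamples), function(r) {
    bal <- balance_dataset(feat, seed = cfg$seed + 1000L * r)
    sapply(seq_len(cfg$n_permutations), function(p)
      run_cv(bal, gamma = 0.001, C = 2, seed = cfg$seed + 1000L * r + p)$metrics[["oa"]])
  })
  expect_equal(unname(res$mean_oa[1, 1]), mean(oas), tolerance = 1e-12)
  # pure function of the seed
  res2 <- run_experiment(feat, cfg, grid)
  expect_identical(res$mean_oa, res2$mean_oa)
  expect_identical(res$counts, res2$counts)
})

test_that("balanced classes make overall accuracy the mean of sensitivity and specificity", {
  feat <- mock_feature_table(n_bl = 10, n_nbl = 14, gap = FALSE)
  grid <- reduced_param_grid()
  grid$gamma <- c(0.001, 0.1)
  grid$C <- c(1, 100)
  res <- run_experiment(feat, experiment_config(n_resamples = 2,
                                                n_permutations = 2, seed = 2),
                        grid)
  expect_equal(res$mean_oa, (res$mean_sensitivity + res$mean_specificity) / 2,
               tolerance = 1e-9)
})

test_that("reports round-trip and the confusion table is column-normalized", {
  feat <- mock_feature_table(n_bl = 8, n_nbl = 12)
  grid <- reduced_param_grid()
  grid$gamma <- c(0.001, 0.1)
  grid$C <- c(1, 100)
  res <- run_experiment(feat, experiment_config(n_resamples = 2,
                                                n_permutations = 2, seed = 3),
                        grid)
  ct <- confusion_table(res)
  expect_equal(unname(colSums(ct)), c(100, 100), tolerance = 1e-9)
  path <- file.path(withr::local_tempdir(), "res.json")
  report_experiment(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$optimal$oa, res$optimal$oa, tolerance = 1e-12)
  expect_equal(back$mean_oa, unname(res$mean_oa), tolerance = 1e-12)
  # the echoed optimal cell is the argmax of the OA grid
  expect_equal(res$optimal$oa, max(res$mean_oa), tolerance = 1e-12)
})
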