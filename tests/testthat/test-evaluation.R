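test_that("Set A / Set B partition the held-out compounds", {
  membership <- data.frame(
    compound_id = c("c1", "c1", "c2", "c3", "c3"),
    assay_id = c("a1", "a2", "a2", "a2", "a3"), stringsAsFactors = FALSE)
  sets <- split_sets(c("c1", "c2", "c3"), "a2", membership)
  expect_identical(sets$set_a, c("c1", "c3"))
  expect_identical(sets$set_b, "c2")
  expect_length(intersect(sets$set_a, sets$set_b), 0)
  expect_setequal(c(sets$set_a, sets$set_b), c("c1", "c2", "c3"))
})

test_that("the CIAT-count filter is strict at its threshold", {
  expect_false(ciat_count_filter(rep("CIAT", 5)))
  expect_true(ciat_count_filter(rep("CIAT", 6)))
  expect_false(ciat_count_filter(rep("NCIAT", 10)))
})

test_that("LOAO reports are complete, consistent and restricted to a common subset", {
  cmp <- get_small_campaign()
  fp <- get_small_fingerprints()
  rep <- loao_run(cmp, "AlphaScreen", fingerprints = fp, seed = 1,
                  hyperparameters = list(num_trees = 100L, max_depth = 0L,
                                         min_node_size = 1L, mtry = "sqrt"))
  passing <- unique(rep$holdout_assay[is.na(rep$excluded_reason)])
  scored <- rep[is.na(rep$excluded_reason), ]
  expect_equal(nrow(scored), length(passing) * 3 * 3)  # methods x subsets
  # the common-predictable rule: identical n for all methods per subset
  for (a in passing) for (s in c("all", "set_a", "set_b")) {
    ns <- scored$n[scored$holdout_assay == a & scored$subset == s]
    expect_equal(length(unique(ns)), 1)
  }
  # set_a + set_b = all within each method
  for (a in passing) {
    n_all <- scored$n[scored$holdout_assay == a & scored$subset == "all" &
                        scored$method == "rfc"]
    n_ab <- sum(scored$n[scored$holdout_assay == a & scored$subset != "all" &
                           scored$method == "rfc"])
    expect_lte(n_ab, n_all)  # common subset can shrink sets differently
  }
  expect_true(all(scored$mcc >= -1 & scored$mcc <= 1, na.rm = TRUE))
})

test_that("stratified cross-validation keeps folds disjoint and errors on tiny classes", {
  ds <- get_small_dataset("AlphaScreen")
  cv <- crossval_10fold(ds, seed = 2, folds = 5,
                        hyperparameters = list(num_trees = 100L, max_depth = 0L,
                                               min_node_size = 1L,
                                               mtry = "sqrt"))
  expect_equal(nrow(cv$folds), 5)
  expect_true(cv$mean_auc > 0.5)
  tiny <- ds
  keep <- c(which(tiny$table$label == "CIAT")[1:3],
            which(tiny$table$label == "NCIAT"))
  tiny$table <- tiny$table[keep, ]
  tiny$fingerprints <- tiny$fingerprints[keep, ]
  expect_error(crossval_10fold(tiny, folds = 10), "fewer members")
})

test_that("nearest-neighbor analysis reports per-class similarities", {
  ds <- get_small_dataset("AlphaScreen")
  train_fp <- ds$fingerprints
  labels <- ds$table$label
  # evaluate three training CIATs against the training set itself:
  # their CIAT-NN average must include a self-similarity of 1
  idx <- which(labels == "CIAT")[1:3]
  nn <- nn_analysis(train_fp[idx, , drop = FALSE],
                    predicted = c(TRUE, TRUE, FALSE),
                    train_fp = train_fp, train_labels = labels, k = 5)
  expect_identical(nn$group, c("TP", "TP", "FN"))
  expect_true(all(nn$mean_tc_ciat > 0))
  # k = 1 reduces to the single maximum similarity (self -> 1)
  nn1 <- nn_analysis(train_fp[idx, , drop = FALSE],
                     predicted = rep(TRUE, 3),
                     train_fp = train_fp, train_labels = labels, k = 1)
  expect_equal(nn1$mean_tc_ciat, rep(1, 3))
  expect_warning(expect_warning(
    nn_analysis(train_fp[idx, , drop = FALSE], rep(TRUE, 3),
                train_fp[1:8, , drop = FALSE], labels[1:8], k = 50),
    "smaller than k"), "smaller than k")
})

test_that("true positives sit closer to training CIATs than false negatives", {
  cmp <- get_small_campaign()
  fp <- get_small_fingerprints()
  ds <- get_small_dataset("AlphaScreen")
  # train on half the compounds, evaluate CIATs of the other half
  set.seed(8)
  half <- sample(nrow(ds$table)) <= nrow(ds$table) / 2
  train <- ds; train$table <- ds$table[half, ]
  train$fingerprints <- ds$fingerprints[half, , drop = FALSE]
  test_tab <- ds$table[!half & ds$table$label == "CIAT", ]
  model <- train_rfc(train, seed = 1)
  p <- predict(model, fp[test_tab$compound_id, , drop = FALSE])
  nn <- nn_analysis(fp[test_tab$compound_id, , drop = FALSE],
                    predicted = p >= 0.5,
                    train_fp = train$fingerprints,
                    train_labels = train$table$label, k = 5)
  expect_gte(mean(nn$mean_tc_ciat[nn$group == "TP"]),
             mean(nn$mean_tc_ciat[nn$group == "FN"]))
})

test_that("the scaling experiment at fraction 1 reproduces plain LOAO scoring", {
  cmp <- get_small_campaign()
  fp <- get_small_fingerprints()
  rfc_rep <- loao_run(cmp, "FRET", methods = "rfc", fingerprints = fp,
                      seed = 1,
                      hyperparameters = list(num_trees = 100L, max_depth = 0L,
                                             min_node_size = 1L,
                                             mtry = "sqrt"))
  sc <- bsf_scaling_experiment(cmp, "FRET", fractions = c(0.4, 1.0),
                               seeds = 1:2, rfc_report = rfc_rep)
  expect_setequal(unique(sc$curve$fraction), c(0.4, 1.0))
  # fraction 1.0 uses the full panel: identical metrics across seeds
  f1 <- sc$curve[sc$curve$fraction == 1, ]
  expect_equal(f1$auc[1], f1$auc[2])
  expect_true(is.numeric(sc$rfc_auc))
  expect_true(identical(sc$crossover, "none") ||
                (is.numeric(sc$crossover) && sc$crossover <= 1))
  expect_true(all(sc$curve$mean_tests > 0))
})

test_that("consolidated reports summarize by unweighted per-assay means", {
  cmp <- get_small_campaign()
  fp <- get_small_fingerprints()
  rep <- loao_run(cmp, "TR-FRET", methods = c("bsf", "pains"),
                  fingerprints = fp, seed = 1)
  out <- compare_report(rep)
  expect_true(all(c("report", "summary") %in% names(out)))
  scored <- rep[is.na(rep$excluded_reason) & rep$method == "bsf" &
                  rep$subset == "all", ]
  srow <- out$summary[out$summary$method == "bsf" &
                        out$summary$subset == "all", ]
  expect_equal(srow$auc, mean(scored$auc, na.rm = TRUE))
  expect_equal(srow$n_assays, nrow(scored))
  p <- plot_method_comparison(rep)
  expect_s3_class(p, "ggplot")
})
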