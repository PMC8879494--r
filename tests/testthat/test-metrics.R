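test_that("confusion counts respect the inclusive threshold", {
  cc <- confusion_counts(c(1, 0), c(0.9, 0.1))
  expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
               list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  cc0 <- confusion_counts(c(1, 0, 0), c(0.2, 0.9, 0.0), threshold = 0)
  expect_equal(cc0$TP + cc0$FP, 3L)
  cceq <- confusion_counts(c(1, 0), c(0.5, 0.5), threshold = 0.5)
  expect_equal(cceq$TP, 1L)      # score == threshold is a positive call
  expect_equal(cceq$FP, 1L)
  withr::with_seed(3, {
    for (i in 1:10) {
      n <- sample(5:50, 1)
      y <- rbinom(n, 1, 0.4); s <- runif(n)
      cc <- confusion_counts(y, s, runif(1))
      expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, n)
    }
  })
})

test_that("SN, SP, ACC and MCC follow the printed formulas", {
  c1 <- structure(list(TP = 3, FP = 0, TN = 0, FN = 1),
                  class = "confusion_counts")
  expect_equal(sn(c1), 0.75)
  c2 <- structure(list(TP = 2, TN = 3, FP = 1, FN = 1),
                  class = "confusion_counts")
  expect_equal(mcc(c2), 5 / 12)
  expect_equal(acc(c2), 5 / 7)
  expect_equal(sp(c2), 0.75)
  perfect <- structure(list(TP = 4, TN = 6, FP = 0, FN = 0),
                       class = "confusion_counts")
  m <- classification_metrics(perfect)
  expect_equal(unlist(m), c(SN = 1, SP = 1, ACC = 1, MCC = 1))
  none <- structure(list(TP = 0, TN = 5, FP = 0, FN = 0),
                    class = "confusion_counts")
  expect_warning(v <- sn(none), "undefined")
  expect_true(is.nan(v))
  expect_warning(expect_true(is.nan(mcc(none))), "undefined")
})

test_that("ACC decomposes as SN * pi + SP * (1 - pi)", {
  withr::with_seed(17, {
    for (i in 1:10) {
      n <- 60
      y <- rbinom(n, 1, 0.3); s <- runif(n)
      if (sum(y) == 0 || sum(y) == n) next
      cc <- confusion_counts(y, s)
      pi <- mean(y)
      expect_equal(acc(cc), sn(cc) * pi + sp(cc) * (1 - pi), tolerance = 1e-12)
    }
  })
})

test_that("ROC handles the canonical cases", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(auroc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  r <- roc_curve(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_error(roc_curve(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("AUROC equals the tied-pair rank statistic and survives monotone maps", {
  withr::with_seed(29, {
    for (i in 1:15) {
      n <- sample(10:60, 1)
      y <- rbinom(n, 1, 0.4)
      if (sum(y) == 0 || sum(y) == n) next
      s <- round(runif(n), 1)            # coarse grid forces ties
      expect_equal(auroc(y, s), auc_rank_oracle(y, s), tolerance = 1e-12)
      expect_equal(auroc(y, plogis(3 * s + 1)), auroc(y, s), tolerance = 1e-12)
    }
  })
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(41, {
    y <- rbinom(80, 1, 0.5); s <- runif(80)
    expect_equal(auroc(y, s),
                 as.numeric(pROC::auc(pROC::roc(
                   y, s, quiet = TRUE, direction = "<", levels = c(0, 1)))),
                 tolerance = 1e-12)
  })
})

test_that("cross-validation partitions samples into stratified folds", {
  withr::with_seed(61, {
    X <- matrix(rnorm(100 * 4), 100, 4)
    y <- rep(c(0, 1), each = 50)
    ds <- prip:::new_dataset(X, y, paste0("f", 1:4), "test")
    folds <- prip:::stratified_folds(y, 5, seed = 2)
    expect_equal(as.integer(table(folds)), rep(20L, 5))
    expect_equal(sort(unique(folds)), 1:5)
    # stratification: each fold has 10 of each class
    for (f in 1:5) expect_equal(sum(y[folds == f]), 10)
    cv1 <- kfold_cv(ds, k = 5, seed = 3,
                    params = gbt_params(nrounds = 5, max_depth = 2))
    cv2 <- kfold_cv(ds, k = 5, seed = 3,
                    params = gbt_params(nrounds = 5, max_depth = 2))
    expect_identical(cv1$folds, cv2$folds)
    expect_equal(nrow(cv1$folds), 5)
    expect_true(all(c("SN", "SP", "ACC", "MCC", "AUROC") %in%
                      names(cv1$folds)))
  })
})

test_that("chain-grouped folds keep all windows of a chain together", {
  withr::with_seed(71, {
    n <- 120
    chain_ids <- rep(sprintf("c%02d", 1:12), each = 10)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- rbinom(n, 1, 0.3)
    ds <- prip:::new_dataset(X, y, paste0("f", 1:3), "test")
    cv <- kfold_cv(ds, k = 3, seed = 5, chain_ids = chain_ids,
                   params = gbt_params(nrounds = 3, max_depth = 2))
    expect_equal(nrow(cv$folds), 3)
  })
})

test_that("cross-validation recovers a planted compositional signal", {
  ch <- simulate_chains(sim_config(n_chains = 60, length_range = c(60, 80),
                                   seed = 5))
  dict <- train_embedding(ch, fast_embed(seed = 5, epochs = 20))
  ds <- embed_segments(segment_chains(ch, 5), dict)
  cv <- kfold_cv(ds, k = 3, seed = 5,
                 params = gbt_params(nrounds = 30, max_depth = 3))
  expect_gt(cv$means$AUROC, 0.75)
  expect_gt(cv$means$SN, 0.5)   # imbalance weighting yields the high-SN regime
})

test_that("window scan evaluates each requested length once", {
  ch <- simulate_chains(sim_config(n_chains = 12, length_range = c(50, 60),
                                   seed = 9))
  sc <- window_scan(ch, lengths = c(5, 9),
                    embed_params = fast_embed(dim = 4, epochs = 8),
                    params = gbt_params(nrounds = 8, max_depth = 2),
                    k = 2, seed = 4)
  expect_equal(sc$length, c(5, 9))
  expect_true(all(sc$auroc > 0 & sc$auroc < 1))
  sc1 <- window_scan(ch, lengths = 7,
                     embed_params = fast_embed(dim = 4, epochs = 8),
                     params = gbt_params(nrounds = 8, max_depth = 2),
                     k = 2, seed = 4)
  expect_equal(nrow(sc1), 1L)
  expect_error(window_scan(ch, lengths = c(4, 8)), "odd")
})
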