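test_that("logistic derivatives match their closed form and finite differences", {
  gh <- logistic_grad_hess(1, 0)
  expect_equal(gh$g, -0.5)
  expect_equal(gh$h, 0.25)
  gh0 <- logistic_grad_hess(0, 0)
  expect_equal(gh0$g, 0.5)
  expect_equal(gh0$h, 0.25)

  wloss <- function(y, m, w) {
    p <- plogis(m)
    -(if (y == 1) w else 1) * (y * log(p) + (1 - y) * log(1 - p))
  }
  eps <- 1e-5
  for (y in c(0, 1)) for (w in c(1, 3.7)) {
    m <- 0.3
    gh <- logistic_grad_hess(y, m, w)
    gnum <- (wloss(y, m + eps, w) - wloss(y, m - eps, w)) / (2 * eps)
    hnum <- (wloss(y, m + eps, w) - 2 * wloss(y, m, w) +
               wloss(y, m - eps, w)) / eps^2
    expect_equal(gh$g, gnum, tolerance = 1e-6)
    expect_equal(gh$h, hnum, tolerance = 1e-4)
  }
})

test_that("leaf weight minimizes the per-leaf quadratic objective", {
  expect_equal(leaf_weight(0, 5, 1), 0)
  expect_equal(leaf_weight(2, 3, 1), -0.5)
  withr::with_seed(4, {
    for (i in 1:20) {
      G <- rnorm(1, sd = 3); H <- rexp(1); lam <- rexp(1)
      w_star <- leaf_weight(G, H, lam)
      obj <- function(w) G * w + 0.5 * (H + lam) * w^2
      probes <- rnorm(1000, sd = 5)
      expect_true(all(obj(w_star) <= obj(probes) + 1e-12))
    }
  })
})

test_that("structure objective equals the substituted leaf optimum", {
  expect_equal(leaf_objective(2, 3, 1, 1), 0.5)
  expect_equal(leaf_objective(c(0, 0), c(1, 2), 1, 0), 0)
  withr::with_seed(8, {
    for (i in 1:20) {
      T <- sample(1:6, 1)
      G <- rnorm(T, sd = 2); H <- rexp(T); lam <- rexp(1); gam <- rexp(1)
      w <- leaf_weight(G, H, lam)
      expect_equal(leaf_objective(G, H, lam, gam),
                   sum(G * w + 0.5 * (H + lam) * w^2) + gam * T,
                   tolerance = 1e-12)
    }
  })
})

test_that("split gain follows its closed form and is linear in gamma", {
  expect_equal(split_gain(1, 1, 1, 1, 0, 0), 0)
  expect_equal(split_gain(-2, 2, 2, 2, 0, 0), 2)
  withr::with_seed(12, {
    for (i in 1:10) {
      GL <- rnorm(1); HL <- rexp(1); GR <- rnorm(1); HR <- rexp(1)
      gam <- rexp(1)
      expect_equal(split_gain(GL, HL, GR, HR, 0.5, gam),
                   split_gain(GL, HL, GR, HR, 0.5, 0) - gam)
    }
  })
})

test_that("a depth-1 tree finds the hand-computed split and leaf weights", {
  X <- matrix(c(0, 1, 2, 3), ncol = 1)
  tr <- grow_tree(X, g = c(-1, -1, 1, 1), h = rep(1, 4),
                  gbt_params(max_depth = 1, reg_lambda = 0, reg_gamma = 0,
                             min_child_hessian = 0))
  expect_equal(tr$feature[1], 1L)
  expect_equal(tr$threshold[1], 1.5)
  leaves <- tr[tr$is_leaf, ]
  expect_equal(sort(leaves$weight), c(-1, 1))

  # no positive gain: homogeneous derivatives on a constant feature
  tr2 <- grow_tree(matrix(1, 4, 1), g = rep(2, 4), h = rep(1, 4),
                   gbt_params(max_depth = 3, reg_lambda = 1))
  expect_equal(nrow(tr2), 1L)
  expect_true(tr2$is_leaf[1])
  expect_equal(tr2$weight[1], -8 / 5)
})

test_that("root split equals the exhaustive-enumeration oracle on random data", {
  withr::with_seed(99, {
    for (i in 1:50) {
      X <- matrix(sample(0:5, 24, replace = TRUE) + rnorm(24, sd = 0.01), 8, 3)
      g <- rnorm(8); h <- rexp(8)
      lam <- sample(c(0, 1), 1); gam <- sample(c(0, 0.1), 1)
      tr <- grow_tree(X, g, h, gbt_params(max_depth = 1, reg_lambda = lam,
                                          reg_gamma = gam,
                                          min_child_hessian = 0))
      ob <- oracle_best_split(X, g, h, lam, gam)
      if (is.na(ob$feature)) {
        expect_true(tr$is_leaf[1])
      } else {
        expect_equal(tr$feature[1], ob$feature)
        expect_equal(tr$threshold[1], ob$threshold, tolerance = 1e-12)
        gl <- sum(g[X[, ob$feature] < ob$threshold])
        hl <- sum(h[X[, ob$feature] < ob$threshold])
        expect_equal(split_gain(gl, hl, sum(g) - gl, sum(h) - hl, lam, gam),
                     ob$gain, tolerance = 1e-12)
      }
    }
  })
})

test_that("boosting separates a separable toy problem and respects K = 0", {
  X <- matrix(rep(c(0, 1), each = 10), ncol = 1)
  y <- rep(c(0, 1), each = 10)
  p <- gbt_params(nrounds = 20, max_depth = 1, min_child_hessian = 0)
  fit <- gbt_fit(X, y, p)
  pr <- predict(fit, X)
  expect_equal(as.integer(pr >= 0.5), y)
  expect_true(all(pr > 0 & pr < 1))

  fit0 <- gbt_fit(X, y, gbt_params(nrounds = 0, base_score = 0.37))
  expect_equal(predict(fit0, X), rep(0.37, 20))
})

test_that("the regularized training objective is non-increasing over rounds", {
  train_objective <- function(fit, X, y, upto) {
    sub <- fit
    sub$trees <- fit$trees[seq_len(upto)]
    m <- if (upto == 0) rep(fit$base_margin, nrow(X))
         else predict(sub, X, type = "margin")
    p <- plogis(m)
    w <- ifelse(y == 1, fit$scale_pos_weight, 1)
    loss <- -sum(w * (y * log(p) + (1 - y) * log(1 - p)))
    om <- 0
    lam <- fit$params$reg_lambda
    for (tr in fit$trees[seq_len(upto)]) {
      wts <- tr$weight[tr$is_leaf]
      om <- om + 0.5 * lam * sum(wts^2)
    }
    loss + om
  }
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- 30
      X <- matrix(rnorm(n * 2), n, 2)
      y <- as.integer(X[, 1] + 0.5 * rnorm(n) > 0)
      if (length(unique(y)) < 2) next
      p <- gbt_params(nrounds = 8, max_depth = 2, learning_rate = 0.3,
                      reg_lambda = 1, reg_gamma = 0, scale_pos_weight = 1)
      fit <- gbt_fit(X, y, p)
      objs <- vapply(0:8, function(t) train_objective(fit, X, y, t), numeric(1))
      expect_true(all(diff(objs) <= 1e-8))
    }
  })
})

test_that("fitting is invariant to sample order and duplicated features", {
  withr::with_seed(33, {
    n <- 40
    X <- matrix(rnorm(n * 3), n, 3)
    y <- as.integer(X[, 2] > 0.2)
    p <- gbt_params(nrounds = 5, max_depth = 3)
    Xtest <- matrix(rnorm(10 * 3), 10, 3)
    base <- predict(gbt_fit(X, y, p), Xtest)

    perm <- sample(n)
    expect_equal(predict(gbt_fit(X[perm, ], y[perm], p), Xtest), base)

    Xdup <- cbind(X, X[, 1])
    pd <- gbt_params(nrounds = 5, max_depth = 3)
    expect_equal(predict(gbt_fit(Xdup, y, pd), cbind(Xtest, Xtest[, 1])), base)
  })
})

test_that("probabilities agree with an independent boosting implementation", {
  skip_if_not_installed("xgboost")
  withr::with_seed(55, {
    n <- 200
    X <- matrix(rnorm(n * 4), n, 4)
    y <- as.integer(X[, 1] - X[, 3] + rnorm(n, sd = 0.5) > 0)
    p <- gbt_params(nrounds = 10, max_depth = 2, learning_rate = 0.3,
                    reg_lambda = 1, reg_gamma = 0, min_child_hessian = 1,
                    scale_pos_weight = 1)
    ours <- predict(gbt_fit(X, y, p), X)
    ref <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 2, eta = 0.3,
                    lambda = 1, gamma = 0, min_child_weight = 1,
                    base_score = 0.5, tree_method = "exact", nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1), nrounds = 10)
    theirs <- predict(ref, xgboost::xgb.DMatrix(X))
    expect_lt(mean(abs(ours - theirs)), 0.05)
  })
})

test_that("tidy and glance expose the ensemble structure", {
  X <- matrix(rnorm(60), 30, 2)
  y <- as.integer(X[, 1] > 0)
  fit <- gbt_fit(X, y, gbt_params(nrounds = 3, max_depth = 2))
  td <- tidy(fit)
  expect_setequal(unique(td$tree), 1:3)
  expect_true(all(!is.na(td$weight[td$is_leaf])))
  g <- glance(fit)
  expect_equal(g$n_trees, 3L)
  expect_equal(g$n_pos + g$n_neg, 30)
})
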