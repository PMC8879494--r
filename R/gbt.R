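#' Boosted-tree hyperparameters
#'
#' Parameters of the regularized second-order boosting classifier. The split
#' gain and leaf weights carry an L2 penalty `reg_lambda` on leaf weights and
#' a per-leaf complexity charge `reg_gamma`; a split is made only when the
#' best gain is positive and both children reach `min_child_hessian`.
#' `scale_pos_weight = NULL` resolves at fit time to N_neg / N_pos, which
#' shifts the operating point toward sensitivity on heavily imbalanced
#' interface data.
#'
#' @param nrounds number of boosting rounds K.
#' @param max_depth maximum tree depth.
#' @param learning_rate shrinkage eta in (0, 1], applied to every leaf weight.
#' @param reg_lambda L2 penalty on leaf weights (>= 0).
#' @param reg_gamma per-leaf complexity penalty (>= 0).
#' @param min_child_hessian minimum child hessian sum to allow a split.
#' @param scale_pos_weight weight multiplier on positive-class derivatives,
#'   or `NULL` for N_neg / N_pos.
#' @param base_score prior probability; boosting starts from its logit.
#' @param seed integer seed (recorded; training itself is deterministic).
#' @param loss `"logistic"` (binary classification, default) or `"squared"`.
#' @return an object of class `gbt_params`.
#' @export
gbt_params <- function(nrounds = 100, max_depth = 6, learning_rate = 0.3,
                       reg_lambda = 1, reg_gamma = 0, min_child_hessian = 1,
                       scale_pos_weight = NULL, base_score = 0.5, seed = 1,
                       loss = c("logistic", "squared")) {
  loss <- match.arg(loss)
  assert_that(nrounds >= 0, "nrounds must be >= 0")
  assert_that(max_depth >= 1, "max_depth must be >= 1")
  assert_that(learning_rate > 0 && learning_rate <= 1,
              "learning_rate must lie in (0, 1]")
  assert_that(reg_lambda >= 0 && reg_gamma >= 0,
              "reg_lambda and reg_gamma must be >= 0")
  assert_that(min_child_hessian >= 0, "min_child_hessian must be >= 0")
  assert_that(base_score > 0 && base_score < 1, "base_score must be in (0, 1)")
  assert_that(is.null(scale_pos_weight) || scale_pos_weight > 0,
              "scale_pos_weight must be positive")
  structure(list(nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, reg_lambda = reg_lambda,
                 reg_gamma = reg_gamma, min_child_hessian = min_child_hessian,
                 scale_pos_weight = scale_pos_weight, base_score = base_score,
                 seed = as.integer(seed), loss = loss),
            class = "gbt_params")
}

#' First and second derivatives of the weighted logistic loss
#'
#' With `p = 1 / (1 + exp(-margin))` and per-sample weight `w`
#' (`scale_pos_weight` for positives, 1 otherwise): `g = w (p - y)`,
#' `h = w p (1 - p)`.
#'
#' @param y 0/1 labels.
#' @param margin current additive-model margins.
#' @param scale_pos_weight positive-class weight (default 1).
#' @return list with numeric vectors `g` and `h`.
#' @export
logistic_grad_hess <- function(y, margin, scale_pos_weight = 1) {
  assert_that(all(y %in% c(0, 1)), "y must be 0/1")
  assert_that(all(is.finite(margin)), "margins must be finite")
  p <- plogis(margin)
  w <- ifelse(y == 1, scale_pos_weight, 1)
  list(g = w * (p - y), h = w * p * (1 - p))
}

#' Optimal leaf weight
#'
#' The weight minimizing the per-leaf quadratic objective
#' `G w + (H + lambda) w^2 / 2`, namely `-G / (H + lambda)`.
#'
#' @param G,H sums of first/second derivatives over the leaf's samples.
#' @param lambda L2 penalty.
#' @return numeric (vectorized over leaves).
#' @export
leaf_weight <- function(G, H, lambda) {
  assert_that(all(H + lambda > 0), "H + lambda must be positive")
  -G / (H + lambda)
}

#' Minimized structure objective of a fixed tree
#'
#' `-1/2 sum_j G_j^2 / (H_j + lambda) + gamma T` over the `T` leaves.
#'
#' @param G,H per-leaf derivative sums (equal-length vectors).
#' @param lambda,gamma regularization parameters.
#' @return the scalar objective.
#' @export
leaf_objective <- function(G, H, lambda, gamma) {
  assert_that(length(G) == length(H), "G and H must have equal length")
  assert_that(all(H + lambda > 0), "H + lambda must be positive")
  -0.5 * sum(G^2 / (H + lambda)) + gamma * length(G)
}

#' Gain of a candidate split
#'
#' `1/2 [GL^2/(HL+lambda) + GR^2/(HR+lambda) - (GL+GR)^2/(HL+HR+lambda)] - gamma`.
#'
#' @param GL,HL,GR,HR derivative sums in the left/right children.
#' @param lambda,gamma regularization parameters.
#' @return the scalar gain.
#' @export
split_gain <- function(GL, HL, GR, HR, lambda, gamma) {
  assert_that(all(HL + lambda > 0) && all(HR + lambda > 0),
              "child hessian + lambda must be positive")
  0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
           (GL + GR)^2 / (HL + HR + lambda)) - gamma
}

#' Grow a single regression tree on given derivatives
#'
#' Greedy exact search: every feature, midpoint thresholds between
#' consecutive distinct sorted values; the split with maximum gain is taken
#' when positive and both children satisfy `min_child_hessian`; ties break
#' toward the lower feature index, then the lower threshold. Leaf weights are
#' the unshrunk optima `-G/(H+lambda)`.
#'
#' @param X numeric feature matrix.
#' @param g,h per-sample first/second derivatives.
#' @param params a [gbt_params()] object.
#' @return a tibble of nodes (`node`, `feature` 1-based, `threshold`, `left`,
#'   `right`, `weight`, `is_leaf`), class `gbt_tree`.
#' @export
grow_tree <- function(X, g, h, params = gbt_params()) {
  X <- as.matrix(X)
  assert_that(all(is.finite(X)), "features must be finite")
  assert_that(all(h >= 0), "hessians must be non-negative")
  tr <- .grow_tree_cpp(X, as.numeric(g), as.numeric(h), params$max_depth,
                       params$reg_lambda, params$reg_gamma,
                       params$min_child_hessian)
  out <- tibble::tibble(node = seq_along(tr$feature),
                        feature = ifelse(tr$is_leaf, NA_integer_,
                                         tr$feature + 1L),
                        threshold = ifelse(tr$is_leaf, NA_real_, tr$threshold),
                        left = ifelse(tr$left < 0, NA_integer_, tr$left + 1L),
                        right = ifelse(tr$right < 0, NA_integer_, tr$right + 1L),
                        weight = ifelse(tr$is_leaf, tr$weight, NA_real_),
                        is_leaf = tr$is_leaf)
  class(out) <- c("gbt_tree", class(out))
  out
}

#' Fit the boosted classifier
#'
#' Starts from `margin = logit(base_score)`; each round computes derivatives
#' of the (optionally class-weighted) loss at the current margins, grows one
#' tree, and adds `learning_rate` times its leaf weights to the margins.
#' Training is deterministic given the data and parameters.
#'
#' @param x a `prip_dataset`, or a numeric feature matrix.
#' @param y 0/1 labels (ignored when `x` is a dataset).
#' @param params a [gbt_params()] object.
#' @return an object of class `prip_gbt`.
#' @export
gbt_fit <- function(x, y = NULL, params = gbt_params()) {
  if (inherits(x, "prip_dataset")) { y <- x$y; x <- x$X }
  X <- as.matrix(x)
  assert_that(all(is.finite(X)), "features must be finite")
  assert_that(length(y) == nrow(X), "y length must equal nrow(x)")
  assert_that(all(y %in% c(0, 1)), "y must be 0/1")
  spw <- params$scale_pos_weight
  if (is.null(spw)) {
    npos <- sum(y == 1)
    spw <- if (npos > 0 && npos < length(y)) (length(y) - npos) / npos else 1
  }
  logistic <- params$loss == "logistic"
  base_margin <- if (logistic) qlogis(params$base_score) else params$base_score
  fit <- .fit_gbt_cpp(X, as.numeric(y), params$nrounds, params$max_depth,
                      params$learning_rate, params$reg_lambda,
                      params$reg_gamma, params$min_child_hessian, spw,
                      base_margin, logistic)
  structure(list(trees = fit$trees, params = params,
                 scale_pos_weight = spw, base_margin = base_margin,
                 feature_dim = ncol(X), feature_names = colnames(X),
                 n_pos = sum(y == 1), n_neg = sum(y == 0)),
            class = "prip_gbt")
}

#' @export
print.prip_gbt <- function(x, ...) {
  cat("<prip_gbt> ", length(x$trees), " trees, depth <= ",
      x$params$max_depth, ", ", x$feature_dim, " features (",
      x$params$loss, " loss, scale_pos_weight = ",
      signif(x$scale_pos_weight, 4), ")\n", sep = "")
  invisible(x)
}

#' Predict from a boosted classifier
#'
#' @param object a `prip_gbt`.
#' @param newdata a `prip_dataset` or numeric matrix with `feature_dim` columns.
#' @param type `"response"` (probability, logistic loss) or `"margin"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.prip_gbt <- function(object, newdata, type = c("response", "margin"),
                             ...) {
  type <- match.arg(type)
  if (inherits(newdata, "prip_dataset")) newdata <- newdata$X
  X <- as.matrix(newdata)
  assert_that(ncol(X) == object$feature_dim,
              "feature dimension mismatch with fitted model")
  m <- .predict_margin_cpp(object$trees, X, object$base_margin)
  if (type == "margin" || object$params$loss == "squared") as.numeric(m)
  else plogis(as.numeric(m))
}

#' @export
tidy.prip_gbt <- function(x, ...) {
  purrr::imap_dfr(x$trees, function(tr, k) {
    tibble::tibble(tree = k, node = seq_along(tr$feature),
                   feature = ifelse(tr$is_leaf, NA_integer_, tr$feature + 1L),
                   threshold = ifelse(tr$is_leaf, NA_real_, tr$threshold),
                   weight = ifelse(tr$is_leaf, tr$weight, NA_real_),
                   is_leaf = tr$is_leaf)
  })
}

#' @export
glance.prip_gbt <- function(x, ...) {
  n_leaves <- sum(vapply(x$trees, function(tr) sum(tr$is_leaf), numeric(1)))
  tibble::tibble(n_trees = length(x$trees), max_depth = x$params$max_depth,
                 learning_rate = x$params$learning_rate,
                 reg_lambda = x$params$reg_lambda,
                 reg_gamma = x$params$reg_gamma, n_leaves = n_leaves,
                 scale_pos_weight = x$scale_pos_weight,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

# internal: serializable form of a fitted classifier
gbt_to_list <- function(model) {
  list(trees = lapply(model$trees, function(tr)
         lapply(tr, function(v) unname(v))),
       params = unclass(model$params),
       scale_pos_weight = model$scale_pos_weight,
       base_margin = model$base_margin, feature_dim = model$feature_dim,
       n_pos = model$n_pos, n_neg = model$n_neg)
}

gbt_from_list <- function(x) {
  trees <- lapply(x$trees, function(tr) {
    list(feature = as.integer(tr$feature), threshold = as.numeric(tr$threshold),
         left = as.integer(tr$left), right = as.integer(tr$right),
         weight = as.numeric(tr$weight), is_leaf = as.logical(tr$is_leaf))
  })
  p <- x$params
  params <- gbt_params(p$nrounds, p$max_depth, p$learning_rate, p$reg_lambda,
                       p$reg_gamma, p$min_child_hessian, p$scale_pos_weight,
                       p$base_score, p$seed, p$loss)
  structure(list(trees = trees, params = params,
                 scale_pos_weight = x$scale_pos_weight,
                 base_margin = x$base_margin,
                 feature_dim = as.integer(x$feature_dim),
                 feature_names = NULL,
                 n_pos = x$n_pos, n_neg = x$n_neg),
            class = "prip_gbt")
}
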