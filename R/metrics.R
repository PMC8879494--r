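#' Confusion counts at a threshold
#'
#' A score counts as a positive call when `score >= threshold` (boundary
#' inclusive).
#'
#' @param y 0/1 labels.
#' @param scores numeric scores in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return a list of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y, scores, threshold = 0.5) {
  assert_that(length(y) == length(scores), "y and scores must match in length")
  assert_that(all(y %in% c(0, 1)), "y must be 0/1")
  pred <- scores >= threshold
  structure(list(TP = sum(pred & y == 1), FP = sum(pred & y == 0),
                 TN = sum(!pred & y == 0), FN = sum(!pred & y == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("TP =", x$TP, " FP =", x$FP, " TN =", x$TN, " FN =", x$FN, "\n")
  invisible(x)
}

metric_or_nan <- function(num, den, name) {
  if (den == 0) { warning(name, " undefined (zero denominator)"); return(NaN) }
  num / den
}

#' Sensitivity, specificity, accuracy and MCC
#'
#' The four confusion-matrix summaries: `SN = TP/(TP+FN)`, `SP = TN/(TN+FP)`,
#' `ACC = (TP+TN)/N` and the Matthews correlation coefficient. Undefined
#' ratios (zero denominator) return `NaN` with a warning.
#'
#' @param cc a [confusion_counts()] object.
#' @return `classification_metrics`: one-row tibble `SN`, `SP`, `ACC`, `MCC`;
#'   the single-metric helpers return scalars.
#' @export
classification_metrics <- function(cc) {
  tibble::tibble(SN = sn(cc), SP = sp(cc), ACC = acc(cc), MCC = mcc(cc))
}

#' @rdname classification_metrics
#' @export
sn <- function(cc) metric_or_nan(cc$TP, cc$TP + cc$FN, "SN")

#' @rdname classification_metrics
#' @export
sp <- function(cc) metric_or_nan(cc$TN, cc$TN + cc$FP, "SP")

#' @rdname classification_metrics
#' @export
acc <- function(cc) metric_or_nan(cc$TP + cc$TN,
                                  cc$TP + cc$FP + cc$TN + cc$FN, "ACC")

#' @rdname classification_metrics
#' @export
mcc <- function(cc) {
  den2 <- prod(as.numeric(c(cc$TN + cc$FN, cc$TN + cc$FP,
                            cc$TP + cc$FN, cc$TP + cc$FP)))
  if (den2 == 0) { warning("MCC undefined (zero denominator)"); return(NaN) }
  (as.numeric(cc$TP) * cc$TN - as.numeric(cc$FP) * cc$FN) / sqrt(den2)
}

#' ROC curve and AUROC
#'
#' Sweeps thresholds over the distinct scores (equal scores grouped into one
#' step) and integrates by the trapezoidal rule, which equals the probability
#' that a random positive outscores a random negative with ties counted 1/2.
#'
#' @param y 0/1 labels (both classes must be present).
#' @param scores numeric scores.
#' @return an object of class `prip_roc`: tibble `fpr`, `tpr` from (0,0) to
#'   (1,1) with attribute `auroc`.
#' @export
roc_curve <- function(y, scores) {
  assert_that(length(y) == length(scores), "y and scores must match in length")
  assert_that(all(y %in% c(0, 1)), "y must be 0/1")
  P <- sum(y == 1); N <- sum(y == 0)
  assert_that(P > 0 && N > 0, "ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  step_end <- c(ss[-1] != ss[-length(ss)], TRUE)   # last index of each tie group
  tp <- cumsum(ys == 1)[step_end]
  fp <- cumsum(ys == 0)[step_end]
  pts <- tibble::tibble(fpr = c(0, fp / N), tpr = c(0, tp / P))
  auroc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(pts, class = c("prip_roc", class(pts)), auroc = auroc)
}

#' @rdname roc_curve
#' @export
auroc <- function(y, scores) attr(roc_curve(y, scores), "auroc")

#' @export
print.prip_roc <- function(x, ...) {
  cat("<prip_roc> ", nrow(x), " points, AUROC = ",
      sprintf("%.4f", attr(x, "auroc")), "\n", sep = "")
  invisible(x)
}

# stratified fold assignment: within each class, a seeded shuffle then
# round-robin; returns an integer fold id per sample
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' k-fold cross-validation of the classifier
#'
#' Stratified segment-level partition by default; `chain_ids` switches to
#' grouped folds so that all windows of a chain share a fold (overlapping
#' windows otherwise leak across folds).
#'
#' @param dataset a `prip_dataset`.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param params classifier parameters ([gbt_params()]).
#' @param threshold decision threshold for SN/SP/ACC/MCC.
#' @param trainer optional `function(X, y)` returning a scorer
#'   `function(X) -> scores`; defaults to [gbt_fit()] with `params`.
#' @param chain_ids optional per-sample chain ids for chain-level folds.
#' @return an object of class `prip_cv`: list with per-fold tibble `folds`,
#'   one-row tibble `means`, `k`, `seed`.
#' @export
kfold_cv <- function(dataset, k = 5, seed = 1, params = gbt_params(),
                     threshold = 0.5, trainer = NULL, chain_ids = NULL) {
  assert_that(k >= 2, "k must be >= 2")
  y <- dataset$y
  assert_that(sum(y == 1) >= k && sum(y == 0) >= k,
              "each class needs at least k samples")
  if (is.null(trainer))
    trainer <- function(X, ytr) {
      m <- gbt_fit(X, ytr, params)
      function(Xte) predict(m, Xte)
    }
  if (is.null(chain_ids)) {
    folds <- stratified_folds(y, k, seed)
  } else {
    assert_that(length(chain_ids) == length(y),
                "chain_ids must match the dataset rows")
    ids <- unique(chain_ids)
    fold_of <- setNames(integer(length(ids)), ids)
    withr::with_seed(seed, fold_of[sample(ids)] <- rep_len(seq_len(k), length(ids)))
    folds <- unname(fold_of[chain_ids])
  }
  rows <- purrr::map_dfr(seq_len(k), function(f) {
    te <- folds == f
    scorer <- trainer(dataset$X[!te, , drop = FALSE], y[!te])
    s <- scorer(dataset$X[te, , drop = FALSE])
    cm <- classification_metrics(confusion_counts(y[te], s, threshold))
    dplyr::mutate(cm, fold = f, AUROC = auroc(y[te], s), .before = 1)
  })
  rows <- rows[, c("fold", "SN", "SP", "ACC", "MCC", "AUROC")]
  means <- dplyr::summarise(rows, dplyr::across(-"fold", mean))
  structure(list(folds = rows, means = means, k = k, seed = seed),
            class = "prip_cv")
}

#' @export
print.prip_cv <- function(x, ...) {
  cat("<prip_cv> ", x$k, "-fold cross-validation (seed ", x$seed, ")\n",
      sep = "")
  m <- x$means
  cat(sprintf("  mean  SN %.2f  SP %.2f  ACC %.2f  MCC %.2f  AUROC %.2f\n",
              m$SN, m$SP, m$ACC, m$MCC, m$AUROC))
  invisible(x)
}

#' @export
tidy.prip_cv <- function(x, ...) x$folds

#' @export
glance.prip_cv <- function(x, ...)
  dplyr::mutate(x$means, k = x$k, seed = x$seed)

#' Scan window lengths by cross-validated AUROC
#'
#' Runs the full pipeline (shared embedding, segmentation at each length,
#' concatenated-embedding features, cross-validated boosting) for every
#' window length in the grid and reports the mean AUROC per length. The
#' embedding is trained once: the corpus does not depend on the window.
#'
#' @param chains labelled chains tibble.
#' @param lengths odd window lengths (default `seq(21, 39, by = 2)`).
#' @param embed_params embedding parameters.
#' @param params classifier parameters.
#' @param k folds (default 5).
#' @param seed master seed.
#' @return a tibble `length`, `auroc` of class `prip_scan`.
#' @export
window_scan <- function(chains, lengths = seq(21, 39, by = 2),
                        embed_params = embedding_params(),
                        params = gbt_params(), k = 5, seed = 1) {
  assert_that(all(lengths %% 2 == 1) && all(lengths >= 3),
              "window lengths must be odd and >= 3")
  check_chains(chains, labelled = TRUE)
  dict <- train_embedding(chains, embed_params)
  out <- purrr::map_dfr(lengths, function(L) {
    seg <- segment_chains(chains, (L - 1L) / 2L)
    ds <- embed_segments(seg, dict)
    cv <- kfold_cv(ds, k = k, seed = fanout_seed(seed, L), params = params)
    tibble::tibble(length = L, auroc = cv$means$AUROC)
  })
  class(out) <- c("prip_scan", class(out))
  out
}
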