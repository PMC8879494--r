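# End-to-end pipeline: corpus -> dictionary -> segments -> features ->
# boosted classifier, persisted as one JSON bundle.

#' Train the full predictor
#'
#' Runs the complete pipeline: the corpus (by default the training chains
#' themselves) trains the semantic dictionary; chains are divided into
#' windows of length `2 * window_n + 1`; windows are featurized by
#' concatenated embeddings; a boosted classifier is fitted on the features.
#'
#' @param chains labelled chains tibble (training set).
#' @param window_n half-window (default 19, i.e. the selected length 39).
#' @param embed_params embedding parameters ([embedding_params()]).
#' @param params classifier parameters ([gbt_params()]).
#' @param corpus optional corpus chains for the dictionary; defaults to
#'   `chains`.
#' @param disrupt shuffle the negative windows before encoding (the PRIP*
#'   variant); the shuffle seed is fanned out from `embed_params$seed`.
#' @return an object of class `prip_model`: `dictionary`, `classifier`,
#'   `window_n`, `version`.
#' @export
prip_train <- function(chains, window_n = 19,
                       embed_params = embedding_params(),
                       params = gbt_params(), corpus = NULL,
                       disrupt = FALSE) {
  check_chains(chains, labelled = TRUE)
  dict <- train_embedding(corpus %||% chains, embed_params)
  seg <- segment_chains(chains, window_n)
  if (disrupt) {
    neg <- disrupt_negatives(seg[seg$label == 0L, , drop = FALSE],
                             seed = fanout_seed(embed_params$seed, 7L))
    seg <- dplyr::arrange(dplyr::bind_rows(seg[seg$label == 1L, , drop = FALSE],
                                           neg),
                          .data$chain_id, .data$center_pos)
  }
  ds <- embed_segments(seg, dict)
  clf <- gbt_fit(ds, params = params)
  new_prip_model(dict, clf, window_n)
}

new_prip_model <- function(dict, clf, window_n) {
  expected <- (2L * as.integer(window_n) + 1L) * ncol(dict$vectors)
  assert_that(clf$feature_dim == expected,
              "featurizer dimension does not match the classifier")
  structure(list(dictionary = dict, classifier = clf,
                 window_n = as.integer(window_n), version = "prip/0.1.0"),
            class = "prip_model")
}

#' @export
print.prip_model <- function(x, ...) {
  cat("<prip_model> window ", 2 * x$window_n + 1, ", dictionary ",
      length(x$dictionary$vocab), "x", ncol(x$dictionary$vectors),
      ", ", length(x$classifier$trees), " trees\n", sep = "")
  invisible(x)
}

#' Predict interface probabilities for chains
#'
#' @param model a `prip_model`.
#' @param chains chains tibble (labels not required).
#' @param threshold call threshold (default 0.5).
#' @return a tibble `chain_id`, `position`, `residue`, `probability`, `call`.
#' @export
prip_predict <- function(model, chains, threshold = 0.5) {
  chains <- check_chains(chains)
  seg <- segment_chains(chains, model$window_n)
  ds <- embed_segments(seg, model$dictionary)
  p <- predict(model$classifier, ds)
  tibble::tibble(chain_id = seg$chain_id, position = seg$center_pos,
                 residue = substr(seg$tokens, model$window_n + 1L,
                                  model$window_n + 1L),
                 probability = p, call = as.integer(p >= threshold))
}

#' Evaluate a model on labelled chains
#'
#' @inheritParams prip_predict
#' @return list with `metrics` (one-row tibble SN/SP/ACC/MCC/AUROC),
#'   `confusion`, `roc` and the prediction tibble.
#' @export
prip_evaluate <- function(model, chains, threshold = 0.5) {
  check_chains(chains, labelled = TRUE)
  pred <- prip_predict(model, chains, threshold)
  y <- unlist(chains$labels)
  cc <- confusion_counts(y, pred$probability, threshold)
  roc <- roc_curve(y, pred$probability)
  metrics <- dplyr::mutate(classification_metrics(cc),
                           AUROC = attr(roc, "auroc"))
  list(metrics = metrics, confusion = cc, roc = roc, predictions = pred)
}

# full-precision number -> string helpers so bundles reload bit-exactly
num_out <- function(x) sprintf("%.17g", as.numeric(x))
num_in <- function(x) as.numeric(x)

#' Persist a trained model as one JSON document
#'
#' The bundle stores the embedding table, the tree ensemble and all
#' parameters; doubles are written with 17 significant digits so a reload is
#' bit-exact.
#'
#' @param model a `prip_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  d <- model$dictionary
  clf <- gbt_to_list(model$classifier)
  clf$base_margin <- num_out(clf$base_margin)
  clf$scale_pos_weight <- num_out(clf$scale_pos_weight)
  clf$trees <- lapply(clf$trees, function(tr) {
    tr$threshold <- num_out(tr$threshold)
    tr$weight <- num_out(tr$weight)
    tr
  })
  doc <- list(version = model$version, window_n = model$window_n,
              dictionary = list(vocab = d$vocab,
                                vectors = apply(d$vectors, 1, num_out,
                                                simplify = FALSE),
                                params = unclass(d$params),
                                epoch_loss = num_out(d$epoch_loss)),
              classifier = clf)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = FALSE)
  invisible(path)
}

#' Load a model bundle written by [write_model()]
#'
#' @param path path to the JSON bundle.
#' @return a `prip_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  dp <- doc$dictionary$params
  params <- embedding_params(dp$structure, dp$dim, dp$window, dp$negative,
                             dp$epochs, dp$seed, dp$initial_lr, dp$min_lr,
                             dp$noise_exponent)
  vocab <- doc$dictionary$vocab
  vectors <- do.call(rbind, lapply(doc$dictionary$vectors, num_in))
  rownames(vectors) <- vocab
  dict <- structure(list(vocab = vocab, vectors = vectors, params = params,
                         epoch_loss = num_in(doc$dictionary$epoch_loss)),
                    class = "semantic_dictionary")
  clf <- doc$classifier
  if (length(clf$params$scale_pos_weight) == 0)
    clf$params$scale_pos_weight <- NULL
  clf$base_margin <- num_in(clf$base_margin)
  clf$scale_pos_weight <- num_in(clf$scale_pos_weight)
  clf$trees <- lapply(clf$trees, function(tr) {
    tr$threshold <- num_in(tr$threshold)
    tr$weight <- num_in(tr$weight)
    tr
  })
  model <- gbt_from_list(clf)
  new_prip_model(dict, model, doc$window_n)
}
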