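# Fixtures built in code; no data files.

AA20_FIX <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# a tiny labelled chain set with a fixed composition
toy_chains <- function() {
  tibble::tibble(
    chain_id = c("c1", "c2"),
    sequence = c("TGDFPLM", "ARKGARKG"),
    labels = list(c(0L, 0L, 0L, 1L, 0L, 0L, 0L),
                  c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L)))
}

# random standard-alphabet chains, unlabelled
random_chains <- function(n = 5, len = 40, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    chain_id = sprintf("r%02d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(AA20_FIX, len, replace = TRUE), collapse = ""),
      character(1)),
    labels = vector("list", n)))
}

# hand-built semantic dictionary (no training), for encoder tests
manual_dictionary <- function(vocab, vectors) {
  rownames(vectors) <- vocab
  structure(list(vocab = vocab, vectors = vectors,
                 params = prip::embedding_params(dim = ncol(vectors), epochs = 1),
                 epoch_loss = numeric(0)),
            class = "semantic_dictionary")
}

# small, fast embedding parameter set for tests
fast_embed <- function(seed = 1, dim = 8, epochs = 15, ...)
  prip::embedding_params(dim = dim, epochs = epochs, seed = seed, ...)

# segments tibble from raw token strings
make_segments <- function(tokens, label = 0L, chain_id = "t") {
  tibble::tibble(chain_id = chain_id, center_pos = seq_along(tokens),
                 tokens = tokens,
                 label = rep_len(as.integer(label), length(tokens)))
}

# the synthetic-study pipeline: train/test split by chains, embedding +
# concatenated-embedding features + boosting, held-out AUROC
holdout_auroc <- function(chains, seed, window_n = 9, dim = 12, epochs = 40,
                          nrounds = 70, max_depth = 4, train_frac = 0.8) {
  ntr <- floor(nrow(chains) * train_frac)
  tr <- chains[seq_len(ntr), ]
  te <- chains[-seq_len(ntr), ]
  dict <- prip::train_embedding(tr, prip::embedding_params(
    dim = dim, epochs = epochs, seed = seed))
  dstr <- prip::embed_segments(prip::segment_chains(tr, window_n), dict)
  dste <- prip::embed_segments(prip::segment_chains(te, window_n), dict)
  fit <- prip::gbt_fit(dstr, params = prip::gbt_params(
    nrounds = nrounds, max_depth = max_depth, seed = seed))
  list(auroc = prip::auroc(dste$y, predict(fit, dste)),
       y = dste$y, scores = predict(fit, dste))
}
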