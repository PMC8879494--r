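#' Embedding training parameters
#'
#' Defaults are the published setting for this predictor: CBOW, 25-dimensional
#' vectors, context window 5, 5 negative samples, 200 epochs, one worker
#' (training is strictly sequential, so a fixed seed reproduces the dictionary
#' bit for bit). The noise distribution is the unigram distribution raised to
#' `noise_exponent`; the learning rate decays linearly from `initial_lr` to
#' `min_lr` over all scheduled updates.
#'
#' @param structure `"cbow"` or `"skipgram"`.
#' @param dim embedding dimension (default 25).
#' @param window context half-window in tokens (default 5).
#' @param negative number of negative samples per target (default 5).
#' @param epochs training epochs (default 200).
#' @param seed integer seed.
#' @param initial_lr,min_lr linear learning-rate schedule endpoints.
#' @param noise_exponent exponent on unigram frequencies for noise sampling.
#' @return an object of class `embedding_params`.
#' @export
embedding_params <- function(structure = c("cbow", "skipgram"), dim = 25,
                             window = 5, negative = 5, epochs = 200, seed = 1,
                             initial_lr = 0.025, min_lr = 1e-4,
                             noise_exponent = 0.75) {
  structure <- match.arg(structure)
  assert_that(dim >= 1, "dim must be >= 1")
  assert_that(window >= 1, "window must be >= 1")
  assert_that(negative >= 0, "negative must be >= 0")
  assert_that(epochs >= 1, "epochs must be >= 1")
  out <- list(structure = structure, dim = as.integer(dim),
              window = as.integer(window), negative = as.integer(negative),
              epochs = as.integer(epochs), seed = as.integer(seed),
              initial_lr = initial_lr, min_lr = min_lr,
              noise_exponent = noise_exponent)
  class(out) <- "embedding_params"
  out
}

#' Tokenize chains into residue sentences
#'
#' Each chain becomes one sentence whose words are its residues, in order.
#'
#' @param chains a chains tibble.
#' @return a named list of character vectors.
#' @export
tokenize_corpus <- function(chains) {
  chains <- check_chains(chains)
  setNames(strsplit(chains$sequence, "", fixed = TRUE), chains$chain_id)
}

#' Train the semantic dictionary
#'
#' Trains residue-level word embeddings (CBOW or skip-gram with negative
#' sampling) on the given corpus. The returned dictionary maps every token
#' seen in the corpus to a vector; out-of-vocabulary tokens -- notably the
#' padding letter 'X' when absent from the corpus -- look up as the zero
#' vector, i.e. padding is semantically neutral.
#'
#' @param corpus a chains tibble, or a list of character-vector sentences.
#' @param params an [embedding_params()] object.
#' @return an object of class `semantic_dictionary` with elements `vocab`,
#'   `vectors` (|vocab| x dim, rownames = vocab), `params`, `epoch_loss`.
#' @export
train_embedding <- function(corpus, params = embedding_params()) {
  if (is.data.frame(corpus)) corpus <- tokenize_corpus(corpus)
  assert_that(is.list(corpus) && length(corpus) > 0, "empty corpus")
  vocab <- sort(unique(unlist(corpus)))
  assert_that(length(vocab) >= 2, "vocabulary must contain at least 2 tokens")
  sentences <- lapply(corpus, function(s) match(s, vocab) - 1L)
  fit <- .train_word2vec_cpp(sentences, length(vocab),
                             params$structure == "cbow", params$dim,
                             params$window, params$negative, params$epochs,
                             as.double(params$seed), params$initial_lr,
                             params$min_lr, params$noise_exponent)
  vectors <- fit$vectors
  rownames(vectors) <- vocab
  structure(list(vocab = vocab, vectors = vectors, params = params,
                 epoch_loss = as.numeric(fit$epoch_loss)),
            class = "semantic_dictionary")
}

#' @export
print.semantic_dictionary <- function(x, ...) {
  cat("<semantic_dictionary> ", length(x$vocab), " tokens x ",
      ncol(x$vectors), " dims (", x$params$structure, ", ",
      x$params$epochs, " epochs)\n", sep = "")
  invisible(x)
}

#' Look up token vectors in a dictionary
#'
#' @param dict a `semantic_dictionary`.
#' @param tokens character vector of tokens.
#' @return a `length(tokens)` x dim matrix; out-of-vocabulary rows are zero.
#' @export
lookup_vectors <- function(dict, tokens) {
  V <- rbind(dict$vectors, 0)
  idx <- match(tokens, dict$vocab, nomatch = nrow(V))
  out <- V[idx, , drop = FALSE]
  rownames(out) <- tokens
  out
}

#' Cosine similarity between two vectors
#'
#' @param a,b numeric vectors of equal length; both must be non-zero.
#' @return the cosine, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  assert_that(length(a) == length(b), "vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  assert_that(na > 0 && nb > 0, "cosine undefined for a zero vector")
  min(1, max(-1, sum(a * b) / (na * nb)))
}

#' @export
tidy.semantic_dictionary <- function(x, ...) {
  tibble::tibble(token = rep(x$vocab, each = ncol(x$vectors)),
                 dimension = rep(seq_len(ncol(x$vectors)), length(x$vocab)),
                 value = as.numeric(t(x$vectors)))
}

#' @export
glance.semantic_dictionary <- function(x, ...) {
  tibble::tibble(vocab_size = length(x$vocab), dim = ncol(x$vectors),
                 structure = x$params$structure, epochs = x$params$epochs,
                 final_loss = tail(x$epoch_loss, 1))
}

# ---- negative-sampling objective, stated in closed form --------------------
# The trainer's update rule is stochastic gradient descent on exactly these
# functions; they are exported so the gradients can be checked numerically.

sigmoid_ <- function(x) 1 / (1 + exp(-x))

#' Negative-sampling loss and gradients (CBOW)
#'
#' For a context matrix `C` (one row per context token), hidden state
#' `h = colMeans(C)`, output vectors `O` (first row the true centre token,
#' then the sampled noise tokens) and labels `z` (1 for the true token, 0 for
#' noise), the loss is `-sum(z*log s(O h) + (1-z)*log(1 - s(O h)))`.
#'
#' @param context_vecs c x d matrix of context input vectors.
#' @param out_vecs (1+k) x d matrix of output vectors (target then negatives).
#' @param labels 0/1 vector of length `nrow(out_vecs)`.
#' @return `ns_loss_cbow`: the scalar loss. `ns_grad_cbow`: list with
#'   `d_context` (c x d) and `d_out` ((1+k) x d) analytic gradients.
#' @export
ns_loss_cbow <- function(context_vecs, out_vecs, labels) {
  h <- colMeans(context_vecs)
  f <- sigmoid_(as.numeric(out_vecs %*% h))
  -sum(labels * log(f) + (1 - labels) * log(1 - f))
}

#' @rdname ns_loss_cbow
#' @export
ns_grad_cbow <- function(context_vecs, out_vecs, labels) {
  cc <- nrow(context_vecs)
  h <- colMeans(context_vecs)
  f <- sigmoid_(as.numeric(out_vecs %*% h))
  err <- f - labels                       # dL/d(dot)
  d_out <- err %o% h
  d_h <- as.numeric(t(out_vecs) %*% err)
  d_context <- matrix(rep(d_h / cc, each = cc), nrow = cc)
  list(d_context = d_context, d_out = d_out)
}

#' Negative-sampling loss and gradients (skip-gram)
#'
#' Same objective with the centre token's input vector as the hidden state.
#'
#' @param center_vec length-d input vector of the centre token.
#' @param out_vecs (1+k) x d matrix of output vectors (target then negatives).
#' @param labels 0/1 vector of length `nrow(out_vecs)`.
#' @return `ns_loss_skipgram`: the scalar loss. `ns_grad_skipgram`: list with
#'   `d_center` (length d) and `d_out` ((1+k) x d).
#' @export
ns_loss_skipgram <- function(center_vec, out_vecs, labels) {
  f <- sigmoid_(as.numeric(out_vecs %*% center_vec))
  -sum(labels * log(f) + (1 - labels) * log(1 - f))
}

#' @rdname ns_loss_skipgram
#' @export
ns_grad_skipgram <- function(center_vec, out_vecs, labels) {
  f <- sigmoid_(as.numeric(out_vecs %*% center_vec))
  err <- f - labels
  list(d_center = as.numeric(t(out_vecs) %*% err),
       d_out = err %o% center_vec)
}
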