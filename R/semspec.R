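# Semantic-specificity analysis: are the pairwise cosine relations learned
# from real binding-protein sequences distinguishable from those learned on
# randomly altered sequences?

#' Randomly alter a fraction of residues in each chain
#'
#' Per chain, `round(fraction * L)` positions are chosen uniformly without
#' replacement and each is replaced by a residue drawn uniformly from the 19
#' other standard residues (so at `fraction = 1` every position differs from
#' the original). Labels, lengths and chain count are preserved.
#'
#' @param chains a chains tibble.
#' @param fraction fraction of positions to alter, in `[0, 1]`.
#' @param seed integer seed.
#' @return the altered chains tibble.
#' @export
shuffle_corpus <- function(chains, fraction, seed) {
  chains <- check_chains(chains)
  assert_that(fraction >= 0 && fraction <= 1, "fraction must be in [0, 1]")
  withr::with_seed(seed, {
    chains$sequence <- vapply(chains$sequence, function(s) {
      ch <- seq_chars(s)
      m <- round(fraction * length(ch))
      if (m > 0) {
        at <- sample(length(ch), m)
        ch[at] <- vapply(ch[at], function(orig)
          sample(setdiff(AA20, orig), 1), character(1))
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  chains
}

#' Pairwise cosine relation matrix of the 20 standard residues
#'
#' @param dict a `semantic_dictionary` whose vocabulary contains all 20
#'   standard residues.
#' @param source free-text tag recording where the dictionary came from.
#' @return a 20 x 20 symmetric matrix of cosines (class `relation_matrix`,
#'   attribute `source`), unit diagonal.
#' @export
relation_matrix <- function(dict, source = "corpus") {
  assert_that(all(AA20 %in% dict$vocab),
              "dictionary must contain all 20 standard residues")
  V <- dict$vectors[AA20, , drop = FALSE]
  nrm <- sqrt(rowSums(V^2))
  assert_that(all(nrm > 0), "zero embedding vector; cosine undefined")
  M <- tcrossprod(V / nrm)
  M <- pmin(pmax(M, -1), 1)
  diag(M) <- 1
  M <- (M + t(M)) / 2
  dimnames(M) <- list(AA20, AA20)
  structure(M, class = c("relation_matrix", "matrix"), source = source)
}

#' Relation matrices from one corpus at several epoch settings
#'
#' Retrains the embedding on the same corpus with the same seed for each
#' entry of `epochs_list` and returns the resulting relation matrices -- the
#' "true" ensemble of the specificity test.
#'
#' @param corpus a chains tibble (or token sentences).
#' @param base_params embedding parameters; only `epochs` is varied.
#' @param epochs_list epoch settings (default 100, 200, 300, 400).
#' @return a list of `relation_matrix` objects, one per epoch setting.
#' @export
true_ensemble <- function(corpus, base_params = embedding_params(),
                          epochs_list = c(100, 200, 300, 400)) {
  lapply(epochs_list, function(ep) {
    p <- base_params
    p$epochs <- as.integer(ep)
    relation_matrix(train_embedding(corpus, p),
                    source = paste0("true_epochs", ep))
  })
}

#' Relation matrices from shuffled-corpus nulls
#'
#' For each alteration fraction, the corpus is randomly altered once
#' ([shuffle_corpus()], seeds fanned out from `seed`) and an embedding is
#' trained on it -- the stochastic null ensemble.
#'
#' @param chains a chains tibble.
#' @param fractions alteration fractions (default 0.40, 0.45, 0.50, 0.55).
#' @param params embedding parameters.
#' @param seed master seed for the alterations.
#' @return a list of `relation_matrix` objects, one per fraction.
#' @export
null_ensemble <- function(chains, fractions = c(0.40, 0.45, 0.50, 0.55),
                          params = embedding_params(), seed = 1) {
  purrr::imap(as.list(fractions), function(f, i) {
    sh <- shuffle_corpus(chains, f, fanout_seed(seed, i))
    relation_matrix(train_embedding(sh, params),
                    source = paste0("null_frac", f))
  })
}

# pooled two-sample t-test; documented conventions for degenerate variance
pooled_t_p <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  if (welch) {
    vx <- var(x); vy <- var(y)
    se2 <- vx / nx + vy / ny
    if (se2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
    tt <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    if (sp2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  2 * pt(-abs(tt), df)
}

#' p-value matrix comparing true and null cosine ensembles
#'
#' For every off-diagonal residue pair, the cosines across the true ensemble
#' are compared with those across the null ensemble by a two-sided pooled
#' (equal-variance) two-sample t-test; with two ensembles of four matrices
#' the test has 6 degrees of freedom. Zero pooled variance returns p = 1 on
#' equal means and p = 0 otherwise. No multiple-testing correction is
#' applied by default.
#'
#' @param true_ms,null_ms lists of `relation_matrix` objects (each length >= 2).
#' @param alpha significance level recorded on the result (default 0.05).
#' @param welch use Welch's unequal-variance test instead of the pooled test.
#' @param adjust `"none"` (default) or `"bonferroni"` over the 190 pairs.
#' @return a 20 x 20 symmetric matrix of p-values (class `pvalue_matrix`,
#'   diagonal `NA`, attribute `alpha`).
#' @export
pvalue_matrix <- function(true_ms, null_ms, alpha = 0.05, welch = FALSE,
                          adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  assert_that(length(true_ms) >= 2 && length(null_ms) >= 2,
              "both ensembles need at least 2 matrices")
  P <- matrix(NA_real_, 20, 20, dimnames = list(AA20, AA20))
  for (i in 1:19) for (j in (i + 1):20) {
    x <- vapply(true_ms, function(M) M[i, j], numeric(1))
    y <- vapply(null_ms, function(M) M[i, j], numeric(1))
    p <- pooled_t_p(x, y, welch)
    P[i, j] <- P[j, i] <- p
  }
  if (adjust == "bonferroni")
    P <- pmin(P * 190, 1)
  structure(P, class = c("pvalue_matrix", "matrix"), alpha = alpha)
}

#' Positional residue enrichment between positive and negative segments
#'
#' For every window position (centre = 0) and standard residue, the
#' occurrence fractions in the positive and negative segment sets are
#' compared with a two-proportion z-test; the residue is called `enriched`
#' at a position when its positive fraction is significantly higher
#' (`p < alpha`), `depleted` when significantly lower, `neither` otherwise.
#'
#' @param pos_segments,neg_segments segments tibbles of equal window length.
#' @param alpha significance level (default 0.05).
#' @return a tibble of class `enrichment_table`: `position` (relative to the
#'   centre), `residue`, `pos_fraction`, `neg_fraction`, `difference`,
#'   `p_value`, `call`.
#' @export
positional_enrichment <- function(pos_segments, neg_segments, alpha = 0.05) {
  assert_that(nrow(pos_segments) > 0 && nrow(neg_segments) > 0,
              "both segment sets must be non-empty")
  L <- nchar(pos_segments$tokens[1])
  assert_that(all(nchar(pos_segments$tokens) == L) &&
                all(nchar(neg_segments$tokens) == L),
              "all segments must share one window length")
  n <- (L - 1L) / 2L
  Mp <- do.call(rbind, strsplit(pos_segments$tokens, "", fixed = TRUE))
  Mn <- do.call(rbind, strsplit(neg_segments$tokens, "", fixed = TRUE))
  np <- nrow(Mp); nn <- nrow(Mn)
  rows <- purrr::map_dfr(seq_len(L), function(col) {
    cp <- tabulate(match(Mp[, col], AA20), nbins = 20)
    cn <- tabulate(match(Mn[, col], AA20), nbins = 20)
    purrr::map_dfr(seq_along(AA20), function(a) {
      fp <- cp[a] / np; fn_ <- cn[a] / nn
      p <- if (fp == fn_) 1
           else suppressWarnings(
             prop.test(c(cp[a], cn[a]), c(np, nn), correct = FALSE)$p.value)
      tibble::tibble(position = col - n - 1L, residue = AA20[a],
                     pos_fraction = fp, neg_fraction = fn_,
                     difference = fp - fn_, p_value = p,
                     call = if (p < alpha && fp > fn_) "enriched"
                            else if (p < alpha && fp < fn_) "depleted"
                            else "neither")
    })
  })
  class(rows) <- c("enrichment_table", class(rows))
  attr(rows, "alpha") <- alpha
  rows
}

#' Residue frequency counts over segments
#'
#' Token counts over all segment positions, padding excluded -- the counts
#' behind a word-cloud view of the positive set.
#'
#' @param segments a segments tibble.
#' @return a named integer vector of length 20.
#' @export
residue_frequencies <- function(segments) {
  if (nrow(segments) == 0) return(setNames(integer(20), AA20))
  chars <- unlist(strsplit(segments$tokens, "", fixed = TRUE), use.names = FALSE)
  setNames(tabulate(match(chars, AA20), nbins = 20), AA20)
}

#' Write a square residue matrix (relations or p-values) to TSV
#'
#' @param m a `relation_matrix` or `pvalue_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(residue = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
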