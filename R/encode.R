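# Segment -> feature-matrix encoders: concatenated embeddings (the primary
# representation) and three composition baselines (AAC, DPC, CKSAAPGP).

new_dataset <- function(X, y, feature_names, encoder_tag, chain_id = NULL,
                        center_pos = NULL) {
  assert_that(nrow(X) == length(y), "rows(X) must equal length(y)")
  assert_that(all(is.finite(X)), "features must be finite")
  colnames(X) <- feature_names
  structure(list(X = X, y = y, feature_names = feature_names,
                 encoder_tag = encoder_tag, chain_id = chain_id,
                 center_pos = center_pos),
            class = "prip_dataset")
}

#' @export
print.prip_dataset <- function(x, ...) {
  cat("<prip_dataset> ", nrow(x$X), " segments x ", ncol(x$X),
      " features (", x$encoder_tag, "); positives: ",
      sum(x$y == 1, na.rm = TRUE), "\n", sep = "")
  invisible(x)
}

#' Encode segments as concatenated embedding vectors
#'
#' Each window position contributes its token's dictionary vector, in order;
#' `'X'` (and any out-of-vocabulary token) contributes a zero block, so a
#' window of length `L` with a `dim`-dimensional dictionary yields `L * dim`
#' features.
#'
#' @param segments a segments tibble ([segment_chains()]).
#' @param dict a [train_embedding()] dictionary.
#' @return a `prip_dataset` (fields `X`, `y`, `feature_names`, `encoder_tag`).
#' @export
embed_segments <- function(segments, dict) {
  assert_that(nrow(segments) > 0, "no segments")
  L <- nchar(segments$tokens[1])
  assert_that(all(nchar(segments$tokens) == L), "unequal segment lengths")
  d <- ncol(dict$vectors)
  chars <- unlist(strsplit(segments$tokens, "", fixed = TRUE), use.names = FALSE)
  V <- rbind(dict$vectors, 0)
  idx <- match(chars, dict$vocab, nomatch = nrow(V))
  A <- t(V[idx, , drop = FALSE])          # d x (n*L), segment-major columns
  dim(A) <- c(d * L, nrow(segments))
  X <- t(A)
  names <- paste0("p", rep(seq_len(L), each = d), "_d", rep(seq_len(d), L))
  new_dataset(X, segments$label, names, paste0("embedding", d, "xL", L),
              chain_id = segments$chain_id, center_pos = segments$center_pos)
}

#' Amino-acid composition of one sequence
#'
#' Frequency of each of the 20 standard residues among standard positions;
#' `'X'` positions are excluded from numerator and denominator. Sums to 1
#' (all-zero for a window of pure padding).
#'
#' @param sequence one character string.
#' @return named numeric vector of length 20.
#' @export
aac <- function(sequence) {
  assert_that(nchar(sequence) > 0, "empty sequence")
  idx <- match(seq_chars(sequence), AA20)
  idx <- idx[!is.na(idx)]
  cnt <- tabulate(idx, nbins = 20)
  tot <- sum(cnt)
  setNames(if (tot > 0) cnt / tot else rep(0, 20), AA20)
}

#' Dipeptide composition of one sequence
#'
#' Frequency of each ordered adjacent standard-residue pair, over all
#' adjacent pairs with both members standard.
#'
#' @param sequence one character string, length >= 2.
#' @return named numeric vector of length 400 (first residue varies slowest).
#' @export
dpc <- function(sequence) {
  assert_that(nchar(sequence) >= 2, "dpc needs length >= 2")
  ch <- seq_chars(sequence)
  i1 <- match(ch[-length(ch)], AA20)
  i2 <- match(ch[-1], AA20)
  ok <- !is.na(i1) & !is.na(i2)
  cnt <- tabulate((i1[ok] - 1L) * 20L + i2[ok], nbins = 400)
  tot <- sum(cnt)
  nm <- paste0(rep(AA20, each = 20), rep(AA20, 20))
  setNames(if (tot > 0) cnt / tot else rep(0, 400), nm)
}

#' Composition of k-spaced amino-acid group pairs
#'
#' Residues are mapped to five physicochemical groups (aliphatic GAVLMI,
#' aromatic FYW, positively charged KRH, negatively charged DE, uncharged
#' STCPNQ). For each spacing `k = 0..kmax` the 25 ordered group-pair
#' frequencies over position pairs `(i, i + k + 1)` form one block, each
#' block normalized to sum 1; blocks are concatenated, giving
#' `25 * (kmax + 1)` features (100 at the default `kmax = 3`). Pairs touching
#' an `'X'` are skipped and excluded from the block denominator.
#'
#' @param sequence one character string, length >= `kmax + 2`.
#' @param kmax maximum spacing (default 3).
#' @return named numeric vector of length `25 * (kmax + 1)`.
#' @export
cksaapgp <- function(sequence, kmax = 3) {
  assert_that(nchar(sequence) >= kmax + 2, "sequence shorter than kmax + 2")
  ch <- seq_chars(sequence)
  grp_of <- setNames(rep(seq_along(AA_GROUPS), lengths(AA_GROUPS)),
                     unlist(AA_GROUPS))
  g <- unname(grp_of[ch])                 # NA for 'X' / nonstandard
  L <- length(g)
  gn <- names(AA_GROUPS)
  out <- numeric(0)
  for (k in 0:kmax) {
    i1 <- g[seq_len(L - k - 1)]
    i2 <- g[seq_len(L - k - 1) + k + 1L]
    ok <- !is.na(i1) & !is.na(i2)
    cnt <- tabulate((i1[ok] - 1L) * 5L + i2[ok], nbins = 25)
    tot <- sum(cnt)
    blk <- if (tot > 0) cnt / tot else rep(0, 25)
    names(blk) <- paste0(rep(gn, each = 5), ".", rep(gn, 5), ".k", k)
    out <- c(out, blk)
  }
  out
}

#' Encode segments with a composition baseline
#'
#' @param segments a segments tibble.
#' @param encoder `"aac"`, `"dpc"` or `"cksaapgp"`.
#' @param kmax spacing bound for `"cksaapgp"`.
#' @return a `prip_dataset`.
#' @export
encode_composition <- function(segments, encoder = c("aac", "dpc", "cksaapgp"),
                               kmax = 3) {
  encoder <- match.arg(encoder)
  fn <- switch(encoder, aac = aac, dpc = dpc,
               cksaapgp = function(s) cksaapgp(s, kmax))
  proto <- fn(segments$tokens[1])
  X <- t(vapply(segments$tokens, fn, proto, USE.NAMES = FALSE))
  new_dataset(X, segments$label, names(proto), encoder,
              chain_id = segments$chain_id, center_pos = segments$center_pos)
}
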