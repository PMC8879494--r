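# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (exhaustive loops) so they cannot share a defect with
# the implementation they check.

# exhaustive scan of all (feature, midpoint-threshold) splits
oracle_best_split <- function(X, g, h, lambda, gamma, mch = 0) {
  best <- list(gain = 0, feature = NA, threshold = NA)
  G <- sum(g); H <- sum(h)
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    thrs <- (head(vals, -1) + tail(vals, -1)) / 2
    for (thr in thrs) {
      L <- X[, j] < thr
      GL <- sum(g[L]); HL <- sum(h[L])
      GR <- G - GL; HR <- H - HL
      if (HL < mch || HR < mch) next
      gain <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
                       G^2 / (H + lambda)) - gamma
      if (gain > best$gain + 1e-12)
        best <- list(gain = gain, feature = j, threshold = thr)
    }
  }
  best
}

# concordant-pair rank statistic with ties counted 1/2
auc_rank_oracle <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
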