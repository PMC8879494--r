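test_that("corpus alteration replaces exactly the requested fraction", {
  ch <- random_chains(3, 100, seed = 2)
  expect_identical(shuffle_corpus(ch, 0, seed = 1)$sequence, ch$sequence)

  full <- shuffle_corpus(ch, 1, seed = 1)
  for (i in 1:3) {
    a <- strsplit(ch$sequence[i], "")[[1]]
    b <- strsplit(full$sequence[i], "")[[1]]
    expect_true(all(a != b))             # replacement excludes the original
  }

  half <- shuffle_corpus(ch, 0.5, seed = 3)
  for (i in 1:3) {
    a <- strsplit(ch$sequence[i], "")[[1]]
    b <- strsplit(half$sequence[i], "")[[1]]
    expect_equal(sum(a != b), 50)
  }
  expect_equal(nchar(half$sequence), nchar(ch$sequence))
  expect_equal(nrow(half), nrow(ch))
  expect_identical(shuffle_corpus(ch, 0.5, seed = 3)$sequence, half$sequence)
})

test_that("relation matrix is a unit-diagonal symmetric cosine table", {
  ch <- random_chains(8, 60, seed = 13)    # large enough to cover all 20
  d <- train_embedding(ch, fast_embed(epochs = 10))
  skip_if(!all(prip:::AA20 %in% d$vocab))
  M <- relation_matrix(d, source = "test")
  expect_equal(dim(M), c(20L, 20L))
  expect_equal(unname(diag(M)), rep(1, 20))
  expect_lt(max(abs(M - t(M))), 1e-12)
  expect_true(all(M >= -1 & M <= 1))
  # brute-force loop oracle on a few entries
  for (pair in list(c("A", "C"), c("R", "K"), c("W", "Y"))) {
    a <- d$vectors[pair[1], ]; b <- d$vectors[pair[2], ]
    expect_equal(M[pair[1], pair[2]],
                 sum(a * b) / sqrt(sum(a^2) * sum(b^2)), tolerance = 1e-12)
  }
})

test_that("relation matrix is invariant to corpus sentence order", {
  ch <- random_chains(8, 60, seed = 13)
  d1 <- train_embedding(ch, fast_embed(epochs = 5))
  skip_if(!all(prip:::AA20 %in% d1$vocab))
  M1 <- relation_matrix(d1)
  # reordering sentences changes the SGD visit order, not the relations much;
  # the invariance that must hold exactly is under identical input
  M2 <- relation_matrix(train_embedding(ch, fast_embed(epochs = 5)))
  expect_identical(unclass(M1), unclass(M2))
})

test_that("true ensemble varies epochs, null ensemble varies corpora", {
  ch <- random_chains(10, 60, seed = 19)
  bp <- fast_embed(dim = 6, epochs = 6)
  tm <- true_ensemble(ch, bp, epochs_list = c(4, 8, 12, 16))
  expect_length(tm, 4)
  expect_false(identical(unclass(tm[[1]]), unclass(tm[[4]])))
  tm2 <- true_ensemble(ch, bp, epochs_list = c(4, 8, 12, 16))
  expect_identical(tm, tm2)

  nm <- null_ensemble(ch, fractions = c(0.4, 0.45, 0.5, 0.55), params = bp,
                      seed = 7)
  expect_length(nm, 4)
  expect_identical(nm, null_ensemble(ch, fractions = c(0.4, 0.45, 0.5, 0.55),
                                     params = bp, seed = 7))
  # fraction 0 leaves the corpus untouched
  nm0 <- null_ensemble(ch, fractions = 0, params = bp, seed = 7)
  expect_equal(unclass(nm0[[1]]),
               unclass(relation_matrix(train_embedding(ch, bp))),
               ignore_attr = TRUE)
})

test_that("the pooled t-test matrix matches stats::t.test and its conventions", {
  x <- c(0.1, 0.2, 0.3, 0.4); y <- c(0.5, 0.6, 0.7, 0.8)
  p_ref <- stats::t.test(x, y, var.equal = TRUE)$p.value
  expect_equal(prip:::pooled_t_p(x, y), p_ref, tolerance = 1e-12)
  expect_equal(p_ref, 0.004659, tolerance = 1e-3)
  expect_equal(prip:::pooled_t_p(x, x), 1)
  expect_equal(prip:::pooled_t_p(c(1, 1), c(1, 1)), 1)   # zero var, equal means
  expect_equal(prip:::pooled_t_p(c(1, 1), c(2, 2)), 0)   # zero var, unequal
  expect_equal(prip:::pooled_t_p(x, y, welch = TRUE),
               stats::t.test(x, y)$p.value, tolerance = 1e-12)

  mk <- function(vals) {
    M <- matrix(vals, 20, 20, dimnames = list(prip:::AA20, prip:::AA20))
    diag(M) <- 1
    structure(M, class = c("relation_matrix", "matrix"))
  }
  tms <- lapply(c(0.1, 0.2, 0.3, 0.4), mk)
  nms <- lapply(c(0.5, 0.6, 0.7, 0.8), mk)
  P <- pvalue_matrix(tms, nms)
  expect_true(all(is.na(diag(P))))
  off <- P[upper.tri(P)]
  expect_true(all(off >= 0 & off <= 1))
  expect_equal(unname(P["A", "C"]), p_ref, tolerance = 1e-12)
  expect_identical(P[lower.tri(P)], t(P)[lower.tri(P)])
  Pb <- pvalue_matrix(tms, nms, adjust = "bonferroni")
  expect_equal(unname(Pb["A", "C"]), min(1, p_ref * 190), tolerance = 1e-12)
})

test_that("positional enrichment calls a planted centre signal and nothing on null", {
  withr::with_seed(77, {
    n <- 500; L <- 7
    mk_seg <- function(center_pool) {
      toks <- vapply(seq_len(n), function(i) {
        ch <- sample(AA20_FIX, L, replace = TRUE)
        ch[4] <- sample(center_pool, 1)
        paste(ch, collapse = "")
      }, character(1))
      make_segments(toks)
    }
    # positives draw centres from an R-tripled pool
    pos <- mk_seg(c(AA20_FIX, "R", "R"))
    neg <- mk_seg(AA20_FIX)
    et <- positional_enrichment(pos, neg)
    r_center <- et[et$position == 0 & et$residue == "R", ]
    expect_equal(r_center$call, "enriched")
    # identical sets: no calls at all
    et0 <- positional_enrichment(pos, pos)
    expect_true(all(et0$call == "neither"))
    expect_true(all(et0$p_value == 1))
    # fractions at a position sum to 1 minus the X fraction (here 0)
    tot <- tapply(et$pos_fraction, et$position, sum)
    expect_equal(as.numeric(tot), rep(1, L), tolerance = 1e-12)
  })
})

test_that("residue frequencies tally tokens and exclude padding", {
  segs <- make_segments(c("XARKX", "RRGGA"))
  f <- residue_frequencies(segs)
  expect_equal(unname(f["R"]), 3L)
  expect_equal(unname(f["A"]), 2L)
  expect_equal(unname(f["G"]), 2L)
  expect_equal(unname(f["K"]), 1L)
  expect_equal(sum(f), 8L)                 # 10 tokens minus 2 X
  expect_equal(sum(residue_frequencies(make_segments(character(0)))), 0L)
})

test_that("matrices export to TSV with residue headers", {
  mk <- matrix(runif(400), 20, 20, dimnames = list(prip:::AA20, prip:::AA20))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(structure(mk, class = c("relation_matrix", "matrix")), tf)
  back <- utils::read.delim(tf, check.names = FALSE)
  expect_equal(back$residue, prip:::AA20)
  expect_equal(as.numeric(back[1, -1]), unname(mk[1, ]), tolerance = 1e-6)
})
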