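#' Divide one sequence into fixed-length X-padded windows
#'
#' One window per residue, centred on it, with `n` residues up- and
#' downstream; positions past either terminus are filled with `'X'`.
#'
#' @param sequence a single character string.
#' @param n half-window size (window length is `2n + 1`).
#' @return character vector of `nchar(sequence)` windows.
#' @export
#' @examples
#' divide_chain("TGDFPLO", 3)
divide_chain <- function(sequence, n) {
  assert_that(length(sequence) == 1 && is.character(sequence) &&
                nchar(sequence) > 0, "`sequence` must be one non-empty string")
  assert_that(is.numeric(n) && n >= 1 && n == as.integer(n),
              "`n` must be an integer >= 1")
  L <- nchar(sequence)
  padded <- paste0(strrep(PAD, n), sequence, strrep(PAD, n))
  substring(padded, seq_len(L), seq_len(L) + 2L * n)
}

#' Divide chains into centred segments
#'
#' @param chains a chains tibble ([read_fasta()]); labels, when present, are
#'   copied from the centre residue.
#' @param n half-window size.
#' @return a tibble `chain_id`, `center_pos`, `tokens`, `label` (NA when the
#'   chain is unlabelled), with attribute `window_n = n`.
#' @export
segment_chains <- function(chains, n) {
  chains <- check_chains(chains)
  out <- purrr::pmap_dfr(
    list(chains$chain_id, chains$sequence, chains$labels),
    function(id, s, lab) {
      L <- nchar(s)
      tibble::tibble(chain_id = rep(id, L),
                     center_pos = seq_len(L),
                     tokens = divide_chain(s, n),
                     label = if (is.null(lab)) rep(NA_integer_, L)
                             else as.integer(lab))
    })
  attr(out, "window_n") <- as.integer(n)
  out
}

#' Split segments into positive and negative sets by centre label
#'
#' @param chains a labelled chains tibble.
#' @param n half-window size.
#' @return list with tibbles `pos` and `neg` ([segment_chains()] layout);
#'   `|pos| + |neg|` equals the total residue count.
#' @export
build_dataset <- function(chains, n) {
  check_chains(chains, labelled = TRUE)
  seg <- segment_chains(chains, n)
  list(pos = seg[seg$label == 1L, , drop = FALSE],
       neg = seg[seg$label == 0L, , drop = FALSE])
}

#' Disrupt negative segments
#'
#' Implements the negative-disruption variant (PRIP*): every negative
#' segment's window is scrambled so that near-duplicates of positive windows
#' lose their local ordering. The default method permutes each window's own
#' letters (composition preserved); `method = "replace"` substitutes every
#' position by a uniform standard residue instead.
#'
#' @param segments a segments tibble whose rows are all negatives (label 0).
#' @param seed integer seed; output is deterministic given the seed.
#' @param method `"shuffle"` (composition-preserving permutation, default) or
#'   `"replace"` (uniform random residues).
#' @return the segments tibble with `tokens` rewritten.
#' @export
disrupt_negatives <- function(segments, seed, method = c("shuffle", "replace")) {
  method <- match.arg(method)
  assert_that(all(segments$label == 0L | is.na(segments$label)),
              "disrupt_negatives expects negative segments only")
  withr::with_seed(seed, {
    segments$tokens <- vapply(segments$tokens, function(tok) {
      ch <- seq_chars(tok)
      if (method == "shuffle") paste(sample(ch), collapse = "")
      else paste(sample(AA20, length(ch), replace = TRUE), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  segments
}

#' Write segments to TSV for inspection
#'
#' @param segments a segments tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments[, c("chain_id", "center_pos", "tokens", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
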