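# Shared constants and small helpers.

# The 20 standard amino acids, alphabetical one-letter order. 'X' marks an
# unknown residue or terminal padding and is excluded from every composition
# denominator and embedded as the zero vector.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PAD <- "X"
AA21 <- c(AA20, PAD)

# Physicochemical groups used by the CKSAAPGP encoder.
AA_GROUPS <- list(
  aliphatic = c("G", "A", "V", "L", "M", "I"),
  aromatic  = c("F", "Y", "W"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  uncharged = c("S", "T", "C", "P", "N", "Q")
)

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomized stages (corpus shuffling, fold assignment, embedding and
#' classifier training, synthetic data) draw their seeds from one master seed
#' through this documented scheme, so a single `--seed` reproduces a whole run.
#'
#' @param seed master seed (integer).
#' @param offset integer stage offset; distinct stages use distinct offsets.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
fanout_seed <- function(seed, offset = 0L) {
  s <- (as.double(seed) * 48271 + as.double(offset) * 2654435) %% 2147483646
  as.integer(s) + 1L
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# chains tibble contract: chain_id (chr), sequence (chr), labels (list of
# integer vectors or NULL)
check_chains <- function(chains, labelled = FALSE) {
  assert_that(is.data.frame(chains) &&
                all(c("chain_id", "sequence") %in% names(chains)),
              "`chains` must be a data frame with columns chain_id, sequence")
  assert_that(all(nchar(chains$sequence) > 0), "empty sequence in `chains`")
  if (!"labels" %in% names(chains)) chains$labels <- vector("list", nrow(chains))
  if (labelled) {
    ok <- purrr::map2_lgl(chains$labels, nchar(chains$sequence),
                          ~ !is.null(.x) && length(.x) == .y)
    assert_that(all(ok), "all chains must carry per-residue labels")
    assert_that(all(unlist(chains$labels) %in% c(0L, 1L)),
                "labels must be 0/1")
  }
  invisible(chains)
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
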