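#' Read protein chains from a FASTA file
#'
#' Letters outside the 20 standard amino-acid codes are mapped to `'X'`
#' (unknown). Each record becomes one chain; labels are absent after reading
#' and can be attached with [read_labels()] / [attach_labels()].
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `chain_id`, `sequence` and a `labels`
#'   list-column (all `NULL`).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", "TGDFPLO"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  assert_that(length(nonblank) > 0, paste0("empty FASTA file: ", path))
  first <- nonblank[1]
  if (!startsWith(lines[first], ">"))
    stop("not FASTA: line ", first, " of ", path,
         " does not start with '>'", call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  dup <- ids[duplicated(ids)]
  assert_that(length(dup) == 0,
              paste0("duplicate FASTA ids: ", paste(unique(dup), collapse = ", ")))
  seqs <- toupper(as.character(aa))
  assert_that(all(nchar(seqs) > 0), "FASTA record with empty sequence")
  seqs <- gsub(paste0("[^", paste(AA20, collapse = ""), "]"), PAD, seqs)
  tibble::tibble(chain_id = unname(ids), sequence = unname(seqs),
                 labels = vector("list", length(ids)))
}

#' Write protein chains to a FASTA file
#'
#' @param chains a chains tibble (see [read_fasta()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chains, path) {
  check_chains(chains)
  aa <- Biostrings::AAStringSet(setNames(chains$sequence, chains$chain_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read per-residue interface labels from a TSV file
#'
#' The file has a header and columns `chain_id`, `position` (1-based),
#' `label` (0/1). Positions not listed default to 0 when the labels are
#' attached to chains.
#'
#' @param path path to the TSV.
#' @param chains optional chains tibble; when given, dense label vectors are
#'   attached (via [attach_labels()]) and the chains tibble is returned.
#' @return a tibble of raw rows, or `chains` with filled `labels`.
#' @export
read_labels <- function(path, chains = NULL) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer"))
  assert_that(all(c("chain_id", "position", "label") %in% names(raw)),
              "labels TSV needs columns chain_id, position, label")
  raw <- tibble::as_tibble(raw)
  if (nrow(raw) > 0) {
    assert_that(all(raw$label %in% c(0L, 1L)), "labels must be 0 or 1")
    assert_that(all(raw$position >= 1L), "positions are 1-based")
    key <- paste(raw$chain_id, raw$position)
    if (anyDuplicated(key)) {
      conflicts <- tapply(raw$label, key, function(v) length(unique(v)) > 1)
      assert_that(!any(conflicts), "conflicting duplicate (chain, position) labels")
      raw <- raw[!duplicated(key), ]
    }
  }
  if (is.null(chains)) raw else attach_labels(chains, raw)
}

#' Attach sparse label rows to chains as dense 0/1 vectors
#'
#' @param chains a chains tibble.
#' @param label_rows tibble with `chain_id`, `position`, `label`.
#' @return `chains` with the `labels` list-column filled; unlisted positions 0.
#' @export
attach_labels <- function(chains, label_rows) {
  check_chains(chains)
  by_chain <- split(label_rows, label_rows$chain_id)
  chains$labels <- purrr::map2(chains$chain_id, nchar(chains$sequence),
    function(id, len) {
      v <- integer(len)
      rows <- by_chain[[id]]
      if (!is.null(rows)) {
        assert_that(all(rows$position <= len),
                    paste0("label position out of range for chain ", id))
        v[rows$position] <- rows$label
      }
      v
    })
  chains
}

#' Write interface labels to TSV
#'
#' Only interface (label 1) rows are written; absent rows read back as 0.
#'
#' @param chains labelled chains tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(chains, path) {
  check_chains(chains, labelled = TRUE)
  rows <- purrr::map2_dfr(chains$chain_id, chains$labels, function(id, lab) {
    pos <- which(lab == 1L)
    tibble::tibble(chain_id = rep(id, length(pos)), position = pos,
                   label = rep(1L, length(pos)))
  })
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- protein--RNA complexes -------------------------------------------------

RNA_RESIDUES <- c("A", "C", "G", "U", "I",
                  "RA", "RC", "RG", "RU",
                  "1MA", "5MC", "7MG", "H2U", "M2G", "OMC", "OMG",
                  "PSU", "4SU", "5MU", "YG")

AA3 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
         HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
         PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
         TRP = "W", TYR = "Y")

#' Read a protein--RNA complex from a PDB file
#'
#' Atoms are classified by residue name: ribonucleotide codes (A, C, G, U and
#' common modified bases) go to the RNA side, everything else to the protein
#' side. Nonstandard protein residues keep their coordinates and map to 'X'
#' in derived sequences.
#'
#' @param path path to a PDB file.
#' @return an object of class `prip_complex`: a list with tibbles
#'   `protein_atoms` and `rna_atoms` (columns `chain_id`, `residue_index`,
#'   `residue_name`, `atom_name`, `element`, `x`, `y`, `z`).
#' @export
read_complex_pdb <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  tb <- tibble::tibble(chain_id = as.character(at$chain),
                       residue_index = as.integer(at$resno),
                       residue_name = toupper(trimws(at$resid)),
                       atom_name = trimws(at$elety),
                       element = toupper(trimws(at$elesy %||% "")),
                       x = at$x, y = at$y, z = at$z)
  assert_that(all(is.finite(tb$x)) && all(is.finite(tb$y)) && all(is.finite(tb$z)),
              "non-finite coordinates in PDB")
  is_rna <- tb$residue_name %in% RNA_RESIDUES
  is_water <- tb$residue_name %in% c("HOH", "WAT")
  new_complex(protein_atoms = tb[!is_rna & !is_water, , drop = FALSE],
              rna_atoms = tb[is_rna, , drop = FALSE])
}

new_complex <- function(protein_atoms, rna_atoms) {
  structure(list(protein_atoms = tibble::as_tibble(protein_atoms),
                 rna_atoms = tibble::as_tibble(rna_atoms)),
            class = "prip_complex")
}

#' @export
print.prip_complex <- function(x, ...) {
  cat("<prip_complex> ", nrow(x$protein_atoms), " protein atoms, ",
      nrow(x$rna_atoms), " RNA atoms\n", sep = "")
  invisible(x)
}

#' Label interface residues by the 5 angstrom rule
#'
#' A protein residue is an interface residue when at least one of its atoms
#' lies strictly closer than `cutoff` to any RNA atom. The boundary (exactly
#' `cutoff`) is non-interface. With no RNA atoms every residue is labelled 0
#' and a warning is raised.
#'
#' @param structure a `prip_complex`.
#' @param cutoff distance cutoff in angstrom (default 5).
#' @param atoms `"all"` (default) uses every atom present, `"heavy"` drops
#'   hydrogens.
#' @return a tibble `chain_id`, `residue_index`, `label`, one row per protein
#'   residue, in coordinate order.
#' @export
label_interfaces <- function(structure, cutoff = 5.0, atoms = c("all", "heavy")) {
  atoms <- match.arg(atoms)
  assert_that(inherits(structure, "prip_complex"), "need a prip_complex")
  assert_that(cutoff > 0, "cutoff must be positive")
  pa <- structure$protein_atoms
  ra <- structure$rna_atoms
  assert_that(nrow(pa) > 0, "structure has no protein atoms")
  if (atoms == "heavy") {
    drop_h <- function(tb) tb[!(tb$element == "H" |
                                  grepl("^[0-9]*H", tb$atom_name)), , drop = FALSE]
    pa <- drop_h(pa); ra <- drop_h(ra)
  }
  res_key <- paste(pa$chain_id, pa$residue_index, sep = "\r")
  res_order <- unique(res_key)
  if (nrow(ra) == 0) {
    warning("no RNA atoms in structure; all residues labelled non-interface")
    min_d <- rep(Inf, length(res_order))
  } else {
    R <- as.matrix(ra[, c("x", "y", "z")])
    rn2 <- rowSums(R^2)
    P <- as.matrix(pa[, c("x", "y", "z")])
    # min distance of each protein atom to any RNA atom, chunked to bound memory
    atom_min <- numeric(nrow(P))
    chunk <- 2000L
    for (s in seq(1L, nrow(P), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(P))
      Pc <- P[s:e, , drop = FALSE]
      d2 <- outer(rowSums(Pc^2), rn2, "+") - 2 * (Pc %*% t(R))
      atom_min[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
    }
    min_d <- as.numeric(tapply(atom_min, factor(res_key, levels = res_order), min))
  }
  parts <- strsplit(res_order, "\r", fixed = TRUE)
  tibble::tibble(chain_id = purrr::map_chr(parts, 1),
                 residue_index = as.integer(purrr::map_chr(parts, 2)),
                 label = as.integer(min_d < cutoff))
}

#' Derive labelled chains from a protein--RNA complex
#'
#' Sequences are taken from observed protein residues in coordinate order
#' (one letter per residue; nonstandard residues become 'X'); labels come
#' from [label_interfaces()].
#'
#' @inheritParams label_interfaces
#' @return a labelled chains tibble.
#' @export
chains_from_complex <- function(structure, cutoff = 5.0, atoms = c("all", "heavy")) {
  lab <- label_interfaces(structure, cutoff, atoms)
  pa <- structure$protein_atoms
  res <- pa[!duplicated(paste(pa$chain_id, pa$residue_index, sep = "\r")), ]
  letter <- unname(AA3[res$residue_name])
  letter[is.na(letter)] <- PAD
  res$letter <- letter
  res$label <- lab$label
  out <- dplyr::group_by(res, .data$chain_id)
  out <- dplyr::summarise(out,
                          sequence = paste(.data$letter, collapse = ""),
                          labels = list(as.integer(.data$label)),
                          .groups = "drop")
  tibble::as_tibble(out)
}
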