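# Peptide windows around candidate residues, their binary encodings, and
# identity-based homology reduction.
#
# Encoding layout for a window of half-width h (default 4, i.e. 9-mers):
#   * sequence block: 20 bits per window residue (canonical order
#     ACDEFGHIKLMNPQRSTVWY); 'X'/padding encodes as all zeros -> 20*(2h+1);
#   * coil flags: 1 bit per residue, 1 iff the secondary structure is coil
#     (helix and strand are 0) -> (2h+1);
#   * accessibility: 7 bits per residue, one-hot at index min(score, 6);
#     scores are reported on a 0 (buried) .. 9 (exposed) scale but candidate
#     residues essentially never exceed 6, so 7..9 clamp to the top bin
#     -> 7*(2h+1).
# Total for h = 4 with structure: 180 + 9 + 63 = 252.

#' Extract a peptide window around a position
#'
#' Returns the `2h+1`-mer centered at `position`, padded with `X` where the
#' window overruns a terminus.
#'
#' @param sequence A protein sequence.
#' @param position 1-based center position.
#' @param h Half-width of the window (default 4, giving 9-mers).
#' @return A character scalar of length `2h+1`.
#' @export
#' @examples
#' extract_window("MASTQPLVK", 4)  # "XMASTQPLV"
extract_window <- function(sequence, position, h = 4) {
  check_that(length(sequence) == 1 && length(position) == 1,
             "extract_window is scalar; use peptide_windows() for tables")
  check_that(position >= 1 && position <= nchar(sequence),
             paste0("position ", position, " out of range 1..", nchar(sequence)))
  padded <- paste0(strrep("X", h), sequence, strrep("X", h))
  substr(padded, position, position + 2 * h)
}

#' Extract peptide windows for a table of positions
#'
#' @param positions Tibble with columns `protein_id` and `position` (other
#'   columns are carried through).
#' @param proteins Proteome tibble (`id`, `sequence`).
#' @inheritParams extract_window
#' @return `positions` with an added `peptide` column.
#' @export
peptide_windows <- function(positions, proteins, h = 4) {
  if (nrow(positions) == 0) {
    return(mutate(positions, peptide = character(0)))
  }
  idx <- match(positions$protein_id, proteins$id)
  check_that(!anyNA(idx),
             paste0("unknown proteins: ",
                    some_of(unique(positions$protein_id[is.na(idx)]))))
  len <- nchar(proteins$sequence)[idx]
  bad <- which(positions$position < 1 | positions$position > len)
  check_that(length(bad) == 0,
             paste0("positions out of range: ",
                    some_of(paste0(positions$protein_id[bad], ":",
                                   positions$position[bad]))))
  padded <- paste0(strrep("X", h), proteins$sequence[idx], strrep("X", h))
  mutate(positions,
         peptide = substr(padded, positions$position, positions$position + 2 * h))
}

#' One-hot encode a peptide
#'
#' Each residue becomes a 20-bit indicator block in the canonical order
#' returned by [aa_alphabet()]; `X` (unknown or padding) yields an all-zero
#' block.
#'
#' @param peptide A peptide string.
#' @return Integer vector of length `20 * nchar(peptide)`.
#' @export
#' @examples
#' length(onehot_encode("MASTQPLVK"))  # 180
onehot_encode <- function(peptide) {
  chars <- strsplit(peptide, "")[[1]]
  idx <- match(chars, AA_STANDARD)
  bad <- which(is.na(idx) & chars != "X")
  check_that(length(bad) == 0,
             paste0("unknown residue(s): ", some_of(unique(chars[bad]))))
  v <- integer(20L * length(chars))
  hit <- which(!is.na(idx))
  v[(hit - 1L) * 20L + idx[hit]] <- 1L
  v
}

#' Encode secondary structure and accessibility
#'
#' Coil flags are 1 for coil (`C`) and 0 for helix/strand (`H`/`E`);
#' accessibility scores one-hot into 7 bins at index `min(score, 6)`.
#' `NA` entries (missing or padded positions) encode as zeros.
#'
#' @param ss_labels Character vector of `H`/`E`/`C` labels (`NA` allowed).
#' @param acc_scores Integer vector of accessibility scores 0..9 (`NA`
#'   allowed), parallel to `ss_labels`.
#' @return A list with `coil` (integer vector, one flag per residue) and
#'   `acc` (integer vector of 7 bits per residue).
#' @export
#' @examples
#' encode_structure(c("H", "E", "C"), c(0L, 1L, 6L))
encode_structure <- function(ss_labels, acc_scores) {
  check_that(length(ss_labels) == length(acc_scores),
             "ss_labels and acc_scores must have the same length")
  check_that(all(ss_labels %in% c("H", "E", "C") | is.na(ss_labels)),
             "ss_labels must be H, E, C or NA")
  check_that(all((acc_scores >= 0 & acc_scores <= 9) | is.na(acc_scores)),
             "acc_scores must be in 0..9 or NA")
  n <- length(ss_labels)
  coil <- ifelse(!is.na(ss_labels) & ss_labels == "C", 1L, 0L)
  acc <- integer(7L * n)
  hit <- which(!is.na(acc_scores))
  acc[(hit - 1L) * 7L + pmin(acc_scores[hit], 6L) + 1L] <- 1L
  list(coil = coil, acc = acc)
}

#' Encode a table of peptide windows as a binary feature matrix
#'
#' Produces one row per window: the sequence one-hot block followed by
#' per-residue coil flags and accessibility one-hots.  When `structure` is
#' `NULL`, or a residue has no structure record, its structure bits are zero
#' (a single warning summarises missing in-sequence records).
#'
#' @param windows Tibble with columns `protein_id`, `position`, `peptide`
#'   (as from [peptide_windows()]).
#' @param structure Optional structure tibble (see [read_structure()]).
#' @inheritParams extract_window
#' @return Integer matrix with `28 * (2h+1)` named columns.
#' @export
encode_windows <- function(windows, structure = NULL, h = 4) {
  n <- nrow(windows)
  L <- 2L * h + 1L
  check_that(all(nchar(windows$peptide) == L),
             paste0("all peptides must have length ", L))
  chars <- matrix(unlist(strsplit(windows$peptide, "")), nrow = n, byrow = TRUE)
  idx <- match(chars, AA_STANDARD)  # column-major over the n x L matrix
  bad <- which(is.na(idx) & chars != "X")
  check_that(length(bad) == 0,
             paste0("unknown residue(s): ", some_of(unique(chars[bad]))))
  seq_block <- matrix(0L, n, 20L * L)
  hit <- which(!is.na(idx))
  if (length(hit) > 0) {
    rows <- ((hit - 1L) %% n) + 1L
    offs <- ((hit - 1L) %/% n) + 1L
    seq_block[cbind(rows, (offs - 1L) * 20L + idx[hit])] <- 1L
  }
  coil <- matrix(0L, n, L)
  acc <- matrix(0L, n, 7L * L)
  if (!is.null(structure) && nrow(structure) > 0 && n > 0) {
    key <- paste(structure$protein_id, structure$position)
    n_missing <- 0L
    for (o in seq_len(L)) {
      pos_o <- windows$position + (o - h - 1L)
      mi <- match(paste(windows$protein_id, pos_o), key)
      found <- !is.na(mi)
      # A residue drawn from inside the sequence (not 'X' padding) should
      # normally have a structure record; count silent degradations.
      n_missing <- n_missing + sum(!found & chars[, o] != "X")
      if (any(found)) {
        coil[found, o] <- as.integer(structure$ss_label[mi[found]] == "C")
        acc[cbind(which(found),
                  (o - 1L) * 7L + pmin(structure$acc_score[mi[found]], 6L) + 1L)] <- 1L
      }
    }
    if (n_missing > 0) {
      warn(paste0(n_missing, " window residue(s) without structure records ",
                  "encoded as zeros"))
    }
  }
  out <- cbind(seq_block, coil, acc)
  colnames(out) <- c(
    sprintf("seq%02d_%s", rep(seq_len(L), each = 20), AA_STANDARD),
    sprintf("coil%02d", seq_len(L)),
    sprintf("acc%02d_%d", rep(seq_len(L), each = 7), 0:6)
  )
  out
}

#' Ungapped sequence identity between two equal-length peptides
#'
#' The fraction of positions with equal characters.  `X` (unknown/padding)
#' matches nothing, including another `X`.
#'
#' @param a,b Equal-length peptide strings.
#' @return Identity in \[0, 1\].
#' @export
#' @examples
#' pairwise_identity("AAAASAAAA", "AAAASAAAT")  # 8/9
pairwise_identity <- function(a, b) {
  check_that(nchar(a) == nchar(b), "peptides must have equal length")
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  mean(va == vb & va != "X")
}

# Logical keep-vector for greedy first-come-first-kept homology reduction.
homology_keep <- function(peptides, threshold = 0.7) {
  n <- length(peptides)
  if (n == 0) return(logical(0))
  L <- nchar(peptides[1])
  check_that(all(nchar(peptides) == L), "peptides must have equal length")
  M <- matrix(unlist(strsplit(peptides, "")), nrow = n, byrow = TRUE)
  keep <- logical(n)
  kept_rows <- NULL
  for (i in seq_len(n)) {
    vi <- M[i, ]
    if (is.null(kept_rows)) {
      keep[i] <- TRUE
      kept_rows <- M[i, , drop = FALSE]
      next
    }
    eq <- kept_rows == matrix(vi, nrow(kept_rows), L, byrow = TRUE) &
      matrix(vi != "X", nrow(kept_rows), L, byrow = TRUE)
    if (max(rowSums(eq)) / L <= threshold) {
      keep[i] <- TRUE
      kept_rows <- rbind(kept_rows, vi)
    }
  }
  keep
}

#' Greedy homology filter
#'
#' Scans windows in input order and keeps one iff its identity to every
#' previously kept window is at most `threshold` (strictly greater is
#' discarded).  Removing near-duplicate peptides prevents trivially similar
#' sequences from straddling training and test sets.
#'
#' @param windows Either a character vector of equal-length peptides or a
#'   tibble with a `peptide` column.
#' @param threshold Identity threshold (default 0.7: over 70% identity is
#'   discarded).
#' @return The kept subset, same type as the input, original order preserved.
#' @export
#' @examples
#' homology_filter(c("AAAASAAAA", "AAAASAAAT", "TTTTSTTTT"))
homology_filter <- function(windows, threshold = 0.7) {
  if (is.character(windows)) {
    windows[homology_keep(windows, threshold)]
  } else {
    check_that("peptide" %in% names(windows), "windows must have a peptide column")
    windows[homology_keep(windows$peptide, threshold), , drop = FALSE]
  }
}

#' Enumerate the background peptide pool
#'
#' Every S/T-centered (by default) window in the proteome, excluding positions
#' recorded as known phosphosites of any family.  This pool is the source of
#' negative training examples and of scan candidates.
#'
#' @param proteins Proteome tibble.
#' @param sites Optional known-site tibble; matching (protein, position) pairs
#'   are excluded whatever their family.
#' @param residues Center residues to enumerate (default S and T).
#' @inheritParams extract_window
#' @return Tibble with columns `protein_id`, `position`, `residue`, `peptide`.
#' @export
build_background_pool <- function(proteins, sites = NULL,
                                  residues = c("S", "T"), h = 4) {
  pat <- paste0("[", paste(residues, collapse = ""), "]")
  loc <- stringr::str_locate_all(proteins$sequence, pat)
  counts <- vapply(loc, nrow, 0L)
  pool <- tibble(
    protein_id = rep(proteins$id, counts),
    position = as.integer(unlist(lapply(loc, function(m) m[, 1])))
  )
  if (!is.null(sites) && nrow(sites) > 0) {
    pool <- anti_join(pool, sites, by = c("protein_id", "position"))
  }
  pool <- peptide_windows(pool, proteins, h)
  mutate(pool, residue = substr(pool$peptide, h + 1, h + 1), .before = "peptide")
}

#' Sample negative windows from the background pool
#'
#' Sequential uniform draws without replacement; a draw is rejected if its
#' identity to any previously accepted window exceeds `threshold`.  Sampling
#' stops once `n` windows are accepted and errors (reporting the shortfall) if
#' the pool is exhausted first.
#'
#' @param pool Background pool tibble (see [build_background_pool()]).
#' @param n Number of negatives required.
#' @param threshold Identity threshold for rejection (default 0.7).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Tibble of `n` accepted pool rows, in acceptance order.
#' @export
sample_negatives <- function(pool, n, threshold = 0.7, seed = NULL) {
  draw <- function() {
    if (n == 0) return(pool[0, , drop = FALSE])
    check_that(n <= nrow(pool),
               paste0("pool of ", nrow(pool), " windows cannot supply ", n))
    ord <- sample.int(nrow(pool))
    L <- nchar(pool$peptide[1])
    accepted <- integer(0)
    kept_rows <- NULL
    for (i in ord) {
      vi <- strsplit(pool$peptide[i], "")[[1]]
      ok <- if (is.null(kept_rows)) TRUE else {
        eq <- kept_rows == matrix(vi, nrow(kept_rows), L, byrow = TRUE) &
          matrix(vi != "X", nrow(kept_rows), L, byrow = TRUE)
        max(rowSums(eq)) / L <= threshold
      }
      if (ok) {
        accepted <- c(accepted, i)
        kept_rows <- rbind(kept_rows, vi)
        if (length(accepted) == n) break
      }
    }
    check_that(length(accepted) == n,
               paste0("background pool exhausted: ", length(accepted), " of ",
                      n, " negatives accepted (shortfall ",
                      n - length(accepted), ")"))
    pool[accepted, , drop = FALSE]
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
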