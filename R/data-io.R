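# Domain types and readers/writers for every on-disk format the pipeline
# touches.  All tabular formats are tab-delimited UTF-8 with a header line;
# lines starting with '#' are ignored.  Positions are 1-based everywhere,
# on disk and in memory.

#' Read a proteome from a FASTA file
#'
#' The first whitespace-delimited token of each header is taken as the protein
#' id.  Sequences are uppercased; characters outside the 20 standard residue
#' codes (plus `X`) are replaced by `X` with a warning, so proteomes containing
#' rare codes (U, B, Z, ...) load rather than fail.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MASTQPLVK", ">P2", "mstpr"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  check_that(file.exists(path), paste0("FASTA file not found: ", path))
  recs <- Biostrings::readBStringSet(path)
  check_that(length(recs) > 0, paste0("FASTA file is empty: ", path))
  ids <- sub("\\s.*$", "", names(recs))
  check_that(all(nzchar(ids)), "FASTA records with empty ids are not allowed")
  dup <- unique(ids[duplicated(ids)])
  check_that(length(dup) == 0,
             paste0("duplicate protein ids in FASTA: ", some_of(dup)))
  seqs <- toupper(as.character(recs))
  check_that(all(nchar(seqs) >= 1), "zero-length sequences are not allowed")
  n_bad <- sum(nchar(gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", seqs)))
  if (n_bad > 0) {
    warn(paste0(n_bad, " non-standard residue(s) replaced by 'X'"))
    seqs <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", seqs)
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write a proteome to a FASTA file
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::BStringSet(stats::setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read known phosphorylation sites
#'
#' Expects a TSV with columns `protein_id`, `position` (1-based), `residue`
#' (S/T/Y) and `family` (kinase-family label).  Duplicate
#' (protein, position, family) rows collapse to one with a warning.  When a
#' proteome is supplied every site is validated against it.
#'
#' @param path Path to the sites TSV.
#' @param proteins Optional proteome tibble (as from [read_fasta()]) used to
#'   validate positions and residues.
#' @return Tibble with columns `protein_id`, `position`, `residue`, `family`.
#' @export
read_sites <- function(path, proteins = NULL) {
  sites <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             protein_id = readr::col_character(),
                             position = readr::col_integer(),
                             residue = readr::col_character(),
                             family = readr::col_character()
                           ))
  needed <- c("protein_id", "position", "residue", "family")
  check_that(all(needed %in% names(sites)),
             paste0("sites file must have columns: ", paste(needed, collapse = ", ")))
  sites <- sites[needed]
  n0 <- nrow(sites)
  sites <- distinct(sites, .data$protein_id, .data$position, .data$family,
                    .keep_all = TRUE)
  if (nrow(sites) < n0) {
    warn(paste0(n0 - nrow(sites), " duplicate site row(s) dropped"))
  }
  if (!is.null(proteins)) validate_sites(sites, proteins)
  sites
}

#' Validate phosphorylation sites against a proteome
#'
#' Checks that every site's protein exists, its position is within the
#' sequence, its residue is one of S/T/Y and matches the sequence character at
#' that position.  Fails with a message listing the offending rows.
#'
#' @inheritParams read_sites
#' @param sites Site tibble.
#' @return `sites`, invisibly.
#' @export
validate_sites <- function(sites, proteins) {
  idx <- match(sites$protein_id, proteins$id)
  bad_prot <- which(is.na(idx))
  check_that(length(bad_prot) == 0,
             paste0("sites reference unknown proteins: ",
                    some_of(unique(sites$protein_id[bad_prot]))))
  len <- nchar(proteins$sequence)[idx]
  bad_pos <- which(is.na(sites$position) | sites$position < 1 | sites$position > len)
  bad_res <- which(!sites$residue %in% c("S", "T", "Y") |
                     substr(proteins$sequence[idx], sites$position, sites$position) !=
                       sites$residue)
  bad <- sort(unique(c(bad_pos, bad_res)))
  if (length(bad) > 0) {
    rows <- paste0(sites$protein_id[bad], ":", sites$position[bad],
                   sites$residue[bad])
    abort(paste0("invalid sites (position out of range or residue mismatch): ",
                 some_of(rows)))
  }
  invisible(sites)
}

# ---------------------------------------------------------------------------
# Feature matrices: binary protein-by-term incidence for one namespace.

#' Build a binary protein-by-term feature matrix
#'
#' @param pairs Tibble with columns `protein_id` and `term_id`; one row per
#'   annotation.  Repeated pairs collapse to a single 1.
#' @param namespace Namespace label, one of `kegg`, `go_bp`, `go_cc`, `go_mf`,
#'   `pfam`, `interpro`, `string_ppi`.
#' @param protein_ids Optional ordered protein universe the matrix is aligned
#'   to; proteins without annotations get all-zero rows, and annotations for
#'   proteins outside the universe are dropped with a warning.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(pairs, namespace, protein_ids = NULL) {
  check_that(namespace %in% NAMESPACES,
             paste0("unknown namespace '", namespace, "'; expected one of: ",
                    paste(NAMESPACES, collapse = ", ")))
  check_that(all(c("protein_id", "term_id") %in% names(pairs)),
             "pairs must have columns protein_id and term_id")
  bad <- is.na(pairs$term_id) | !nzchar(pairs$term_id)
  check_that(!any(bad), "empty term ids are not allowed")
  bad <- is.na(pairs$protein_id) | !nzchar(pairs$protein_id)
  check_that(!any(bad), "empty protein ids are not allowed")
  pairs <- distinct(pairs, .data$protein_id, .data$term_id)
  if (is.null(protein_ids)) {
    protein_ids <- sort(unique(pairs$protein_id))
  } else {
    check_that(!anyDuplicated(protein_ids), "duplicate protein ids in universe")
    unknown <- setdiff(pairs$protein_id, protein_ids)
    if (length(unknown) > 0) {
      warn(paste0("dropping annotations for ", length(unknown),
                  " protein(s) outside the proteome: ", some_of(unknown)))
      pairs <- filter(pairs, .data$protein_id %in% protein_ids)
    }
  }
  term_ids <- sort(unique(pairs$term_id))
  inc <- matrix(0L, nrow = length(protein_ids), ncol = length(term_ids),
                dimnames = list(protein_ids, term_ids))
  if (nrow(pairs) > 0) {
    inc[cbind(match(pairs$protein_id, protein_ids),
              match(pairs$term_id, term_ids))] <- 1L
  }
  structure(list(namespace = namespace, incidence = inc),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> namespace:", x$namespace,
      "|", nrow(x$incidence), "proteins x", ncol(x$incidence), "terms |",
      sum(x$incidence), "annotations\n")
  invisible(x)
}

#' @export
as_tibble.feature_matrix <- function(x, ...) {
  idx <- which(x$incidence == 1L, arr.ind = TRUE)
  tibble(protein_id = rownames(x$incidence)[idx[, 1]],
         term_id = colnames(x$incidence)[idx[, 2]]) |>
    arrange(.data$protein_id, .data$term_id)
}

#' @export
dim.feature_matrix <- function(x) dim(x$incidence)

# Re-align a feature matrix to a protein universe (all-zero rows for
# proteins without annotations).
align_feature_matrix <- function(fm, protein_ids) {
  if (identical(rownames(fm$incidence), protein_ids)) return(fm)
  feature_matrix(as_tibble(fm), fm$namespace, protein_ids)
}

#' Read functional annotations for one namespace
#'
#' Reads a long-format TSV with columns `protein_id` and `term_id`.  For the
#' `string_ppi` namespace a 3-column interaction dialect
#' (`protein_a`, `protein_b`, `score`) is also accepted: every pair with
#' `score >= ppi_score_cutoff` contributes reciprocal binary partner-presence
#' terms (`partner:<id>`), mirroring how interaction partners act as protein
#' features.
#'
#' @inheritParams feature_matrix
#' @param path Path to the annotation TSV.
#' @param ppi_score_cutoff Minimum interaction score for the PPI dialect
#'   (default 400, a medium-confidence link).
#' @return A `feature_matrix`.
#' @export
read_annotations <- function(path, namespace, protein_ids = NULL,
                             ppi_score_cutoff = 400) {
  check_that(namespace %in% NAMESPACES,
             paste0("unknown namespace '", namespace, "'; expected one of: ",
                    paste(NAMESPACES, collapse = ", ")))
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (namespace == "string_ppi" &&
      all(c("protein_a", "protein_b", "score") %in% names(tb))) {
    tb <- filter(tb, .data$score >= ppi_score_cutoff)
    tb <- tibble(
      protein_id = c(tb$protein_a, tb$protein_b),
      term_id = c(paste0("partner:", tb$protein_b),
                  paste0("partner:", tb$protein_a))
    )
  }
  check_that(all(c("protein_id", "term_id") %in% names(tb)),
             "annotation file must have columns protein_id and term_id")
  feature_matrix(tb[c("protein_id", "term_id")], namespace, protein_ids)
}

#' Write a feature matrix as a long-format annotation TSV
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(fm, path) {
  readr::write_tsv(as_tibble(fm), path, progress = FALSE)
  invisible(path)
}

#' Read per-residue structure annotations
#'
#' Expects a TSV with columns `protein_id`, `position` (1-based), `ss_label`
#' (H/E/C) and `acc_score` (integer solvent-accessibility score, 0 buried to
#' 9 exposed).  At most one record per (protein, position) is allowed.
#'
#' @inheritParams read_sites
#' @return Tibble with columns `protein_id`, `position`, `ss_label`,
#'   `acc_score`.
#' @export
read_structure <- function(path, proteins = NULL) {
  st <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(
                          protein_id = readr::col_character(),
                          position = readr::col_integer(),
                          ss_label = readr::col_character(),
                          acc_score = readr::col_integer()
                        ))
  needed <- c("protein_id", "position", "ss_label", "acc_score")
  check_that(all(needed %in% names(st)),
             paste0("structure file must have columns: ",
                    paste(needed, collapse = ", ")))
  st <- st[needed]
  validate_structure(st, proteins)
  st
}

validate_structure <- function(st, proteins = NULL) {
  check_that(all(st$ss_label %in% c("H", "E", "C")),
             "ss_label must be one of H, E, C")
  check_that(all(st$acc_score >= 0 & st$acc_score <= 9),
             "acc_score must be an integer in 0..9")
  key <- paste(st$protein_id, st$position)
  dup <- unique(key[duplicated(key)])
  check_that(length(dup) == 0,
             paste0("duplicate structure records for: ", some_of(dup)))
  if (!is.null(proteins)) {
    idx <- match(st$protein_id, proteins$id)
    check_that(!anyNA(idx),
               paste0("structure references unknown proteins: ",
                      some_of(unique(st$protein_id[is.na(idx)]))))
    len <- nchar(proteins$sequence)[idx]
    bad <- which(st$position < 1 | st$position > len)
    check_that(length(bad) == 0,
               paste0("structure positions out of range: ",
                      some_of(paste0(st$protein_id[bad], ":", st$position[bad]))))
  }
  invisible(st)
}

# ---------------------------------------------------------------------------
# Predicted-site tables.

#' Write a predicted-site table
#'
#' Writes a TSV with header `protein_id`, `position`, `residue`, `family`,
#' `decision_value`, `protein_score`.  Positions are 1-based; numeric columns
#' are printed at full precision (well beyond 6 significant digits).
#'
#' @param predictions Tibble carrying the six columns above.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  needed <- c("protein_id", "position", "residue", "family",
              "decision_value", "protein_score")
  check_that(all(needed %in% names(predictions)),
             paste0("predictions must have columns: ",
                    paste(needed, collapse = ", ")))
  readr::write_tsv(predictions[needed], path, progress = FALSE)
  invisible(path)
}

#' Read a predicted-site table written by [write_predictions()]
#'
#' @param path Path to the predictions TSV.
#' @return Tibble with the prediction columns.
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    protein_id = readr::col_character(),
                    position = readr::col_integer(),
                    residue = readr::col_character(),
                    family = readr::col_character(),
                    decision_value = readr::col_double(),
                    protein_score = readr::col_double()
                  ))
}

# ---------------------------------------------------------------------------
# The dataset container: proteome + sites + annotation matrices + structure.

#' Assemble a validated phosphorylation dataset
#'
#' Bundles a proteome, known phosphorylation sites, one feature matrix per
#' annotation namespace and optional per-residue structure annotations, and
#' enforces referential integrity: every site resolves to its protein and
#' residue, every matrix is aligned to the proteome (proteins without
#' annotations get all-zero rows), and structure records stay within their
#' sequences.
#'
#' @param proteins Proteome tibble (`id`, `sequence`).
#' @param sites Site tibble (`protein_id`, `position`, `residue`, `family`).
#' @param annotations Named list of `feature_matrix` objects, one per
#'   namespace.
#' @param structure Optional structure tibble (see [read_structure()]).
#' @return A `phospho_dataset` object (a named list with elements `proteins`,
#'   `sites`, `annotations`, `structure`).
#' @export
phospho_dataset <- function(proteins, sites, annotations = list(),
                            structure = NULL) {
  check_that(all(c("id", "sequence") %in% names(proteins)),
             "proteins must have columns id and sequence")
  check_that(!anyDuplicated(proteins$id), "duplicate protein ids")
  check_that(all(nchar(proteins$sequence) >= 1), "zero-length sequences")
  validate_sites(sites, proteins)
  check_that(is.list(annotations), "annotations must be a list of feature matrices")
  annotations <- lapply(annotations, function(fm) {
    check_that(inherits(fm, "feature_matrix"), "annotations must be feature_matrix objects")
    check_that(all(rownames(fm$incidence) %in% proteins$id),
               paste0("matrix '", fm$namespace, "' has proteins outside the proteome"))
    align_feature_matrix(fm, proteins$id)
  })
  if (length(annotations) > 0) {
    names(annotations) <- vapply(annotations, function(fm) fm$namespace, "")
    check_that(!anyDuplicated(names(annotations)), "duplicate namespaces")
  }
  if (!is.null(structure)) validate_structure(structure, proteins)
  structure(list(proteins = proteins, sites = sites,
                 annotations = annotations, structure = structure),
            class = "phospho_dataset")
}

#' @export
print.phospho_dataset <- function(x, ...) {
  cat("<phospho_dataset>\n")
  cat("  proteins:   ", nrow(x$proteins), "\n")
  cat("  sites:      ", nrow(x$sites), " (families: ",
      paste(sort(unique(x$sites$family)), collapse = ", "), ")\n", sep = "")
  cat("  namespaces: ", if (length(x$annotations)) {
    paste(names(x$annotations), collapse = ", ")
  } else "none", "\n")
  cat("  structure:  ", if (is.null(x$structure)) "absent" else
    paste0(nrow(x$structure), " records"), "\n")
  invisible(x)
}

#' Write a dataset to a directory of plain-text files
#'
#' Writes `proteome.fasta`, `sites.tsv`, one `annotations_<namespace>.tsv` per
#' namespace and, if present, `structure.tsv`.
#'
#' @param dataset A `phospho_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$proteins, file.path(dir, "proteome.fasta"))
  readr::write_tsv(dataset$sites, file.path(dir, "sites.tsv"), progress = FALSE)
  for (fm in dataset$annotations) {
    write_annotations(fm, file.path(dir, paste0("annotations_", fm$namespace, ".tsv")))
  }
  if (!is.null(dataset$structure)) {
    readr::write_tsv(dataset$structure, file.path(dir, "structure.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Read a dataset from a directory written by [write_dataset()]
#'
#' @param dir Directory holding the dataset files.
#' @return A validated `phospho_dataset`.
#' @export
read_dataset <- function(dir) {
  fa <- file.path(dir, "proteome.fasta")
  st <- file.path(dir, "sites.tsv")
  check_that(file.exists(fa) && file.exists(st),
             paste0("not a dataset directory (missing proteome.fasta/sites.tsv): ", dir))
  proteins <- read_fasta(fa)
  sites <- read_sites(st, proteins)
  ann_files <- list.files(dir, pattern = "^annotations_.*\\.tsv$", full.names = TRUE)
  annotations <- lapply(ann_files, function(f) {
    ns <- sub("^annotations_(.*)\\.tsv$", "\\1", basename(f))
    read_annotations(f, ns, protein_ids = proteins$id)
  })
  struct_file <- file.path(dir, "structure.tsv")
  structure_tb <- if (file.exists(struct_file)) {
    read_structure(struct_file, proteins)
  } else NULL
  phospho_dataset(proteins, sites, annotations, structure_tb)
}
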