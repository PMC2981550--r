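# Readers/writers and the dataset container.

test_that("FASTA reading normalizes case, maps odd residues to X, round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MASTQPLVK", ">P2", "mst"), f)
  p <- read_fasta(f)
  expect_equal(p$id, c("P1", "P2"))
  expect_equal(p$sequence, c("MASTQPLVK", "MST"))

  writeLines(c(">P1", "MAUST"), f)  # selenocysteine U is outside the alphabet
  expect_warning(p <- read_fasta(f), "replaced by 'X'")
  expect_equal(p$sequence, "MAXST")

  f2 <- withr::local_tempfile(fileext = ".fasta")
  orig <- tiny_proteome()
  write_fasta(orig, f2)
  expect_equal(read_fasta(f2), orig)
})

test_that("FASTA reading rejects duplicates and empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MAST", ">P1", "MSTT"), f)
  expect_error(read_fasta(f), "duplicate.*P1")
  writeLines(character(0), f)
  expect_error(read_fasta(f))
  expect_error(read_fasta(file.path(tempdir(), "no-such-file.fasta")),
               "not found")
})

test_that("site tables parse, deduplicate, and validate against the proteome", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tresidue\tfamily",
               "# a comment line",
               "P1\t4\tT\tCDK", "P1\t10\tS\tCDK", "P2\t2\tS\tPKA"), f)
  s <- read_sites(f, tiny_proteome())
  expect_equal(nrow(s), 3)
  expect_equal(sort(table(s$family), decreasing = TRUE) |> as.integer(), c(2, 1))

  writeLines(c("protein_id\tposition\tresidue\tfamily",
               "P1\t4\tT\tCDK", "P1\t4\tT\tCDK"), f)
  expect_warning(s <- read_sites(f, tiny_proteome()), "duplicate")
  expect_equal(nrow(s), 1)

  # residue mismatch: P3 position 2 is 'A'
  writeLines(c("protein_id\tposition\tresidue\tfamily", "P3\t2\tS\tCDK"), f)
  expect_error(read_sites(f, tiny_proteome()), "residue mismatch")
  writeLines(c("protein_id\tposition\tresidue\tfamily", "P1\t99\tS\tCDK"), f)
  expect_error(read_sites(f, tiny_proteome()), "out of range")
})

test_that("long-format annotations become binary incidence", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tterm_id",
               "P1\tgo:1", "P1\tgo:2", "P2\tgo:2", "P2\tgo:3"), f)
  fm <- read_annotations(f, "go_bp")
  expect_s3_class(fm, "feature_matrix")
  expect_equal(dim(fm), c(2L, 3L))
  expect_equal(sum(fm$incidence), 4)

  # repeated annotation is a single 1, not 2
  writeLines(c("protein_id\tterm_id", "P1\tgo:1", "P1\tgo:1"), f)
  fm <- read_annotations(f, "go_bp")
  expect_equal(sum(fm$incidence), 1)

  writeLines(c("protein_id\tterm_id", "P1\t"), f)
  expect_error(read_annotations(f, "go_bp"), "empty term")
  expect_error(read_annotations(f, "go_zz"), "unknown namespace")
})

test_that("PPI dialect converts score-filtered pairs to partner terms", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tscore", "A\tB\t700", "A\tC\t300"), f)
  fm <- read_annotations(f, "string_ppi", ppi_score_cutoff = 400)
  # A gains exactly one partner term, and the link is reciprocal
  expect_equal(sum(fm$incidence["A", ]), 1)
  expect_equal(fm$incidence["A", "partner:B"], 1L)
  expect_equal(fm$incidence["B", "partner:A"], 1L)
  expect_false("partner:C" %in% colnames(fm$incidence))
})

test_that("feature matrices align to a proteome with all-zero rows", {
  pairs <- tibble::tibble(protein_id = "P1", term_id = "kegg:1")
  fm <- feature_matrix(pairs, "kegg", protein_ids = c("P1", "P2", "P3"))
  expect_equal(dim(fm), c(3L, 1L))
  expect_equal(unname(fm$incidence[, 1]), c(1L, 0L, 0L))
  expect_warning(
    feature_matrix(tibble::tibble(protein_id = "P9", term_id = "kegg:1"),
                   "kegg", protein_ids = c("P1")),
    "outside the proteome"
  )
  expect_equal(as_tibble(fm), pairs)
})

test_that("prediction tables round-trip and handle the empty case", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- tibble::tibble(protein_id = character(), position = integer(),
                          residue = character(), family = character(),
                          decision_value = double(), protein_score = double())
  write_predictions(empty, f)
  expect_length(readLines(f), 1)  # header only

  recs <- tibble::tibble(protein_id = c("P1", "P2"), position = c(4L, 2L),
                         residue = c("T", "S"), family = "CDK",
                         decision_value = c(1.2345678, -0.87654321),
                         protein_score = c(3.14159, -1.5))
  write_predictions(recs, f)
  expect_length(readLines(f), 3)
  expect_equal(read_predictions(f), recs, tolerance = 1e-12)
})

test_that("dataset construction enforces referential integrity", {
  p <- tiny_proteome()
  s <- tibble::tibble(protein_id = "P1", position = 4L, residue = "T",
                      family = "CDK")
  fm <- feature_matrix(tibble::tibble(protein_id = "P2", term_id = "kegg:1"),
                       "kegg")
  ds <- phospho_dataset(p, s, list(fm))
  # matrix re-aligned to the full proteome
  expect_equal(rownames(ds$annotations$kegg$incidence), p$id)

  bad <- tibble::tibble(protein_id = "P9", position = 1L, residue = "S",
                        family = "CDK")
  expect_error(phospho_dataset(p, bad, list()), "unknown proteins")
  bad_fm <- feature_matrix(tibble::tibble(protein_id = "ZZ", term_id = "t"),
                           "kegg")
  expect_error(phospho_dataset(p, s, list(bad_fm)), "outside the proteome")
})

test_that("datasets round-trip through a directory of text files", {
  ds <- simulate_dataset(small_config(seed = 4))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$proteins, ds$proteins)
  expect_equal(back$sites, ds$sites)
  expect_setequal(names(back$annotations), names(ds$annotations))
  for (ns in names(ds$annotations)) {
    expect_equal(back$annotations[[ns]]$incidence[, colnames(ds$annotations[[ns]]$incidence)],
                 ds$annotations[[ns]]$incidence)
  }
  expect_equal(dplyr::arrange(back$structure, protein_id, position),
               dplyr::arrange(ds$structure, protein_id, position))
})
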