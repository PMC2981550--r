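# Peptide windows, binary encodings, identity and homology filtering.

test_that("window extraction pads termini with X", {
  expect_equal(extract_window("MASTQPLVK", 4), "XMASTQPLV")
  expect_equal(nchar(extract_window("MASTQPLVK", 5)), 9)
  # position 1: four leading X
  expect_equal(substr(extract_window("MASTQPLVK", 1), 1, 4), "XXXX")
  expect_equal(extract_window("MASTQPLVK", 9), "QPLVKXXXX")
  expect_error(extract_window("MAST", 5), "out of range")
  w <- peptide_windows(tibble::tibble(protein_id = "P1", position = 4L),
                       tiny_proteome())
  expect_equal(w$peptide, "XMASTQPLV")
})

test_that("one-hot encoding has indicator structure with all-zero X blocks", {
  v <- onehot_encode("MASTQPLVK")
  expect_length(v, 180)
  expect_equal(sum(v), 9)

  v <- onehot_encode("SSSSSSSSS")
  s_col <- which(aa_alphabet() == "S")
  expect_equal(which(v == 1), (0:8) * 20 + s_col)

  expect_equal(sum(onehot_encode("XXXXSXXXX")), 1)
  expect_error(onehot_encode("MAST*QPLV"), "unknown residue")

  # single residue is a 20-dimensional indicator
  expect_length(onehot_encode("S"), 20)
})

test_that("structure encodes as coil flags and clamped accessibility one-hots", {
  enc <- encode_structure(c("H", "E", "C"), c(0L, 1L, 6L))
  expect_equal(enc$coil, c(0L, 0L, 1L))
  expect_equal(enc$acc, c(1L, rep(0L, 6),      # 0 -> bit at index 0
                          0L, 1L, rep(0L, 5),  # 1 -> bit at index 1
                          rep(0L, 6), 1L))     # 6 -> bit at index 6
  # exhaustive sweep: scores 0..9 set the bit at min(score, 6)
  for (s in 0:9) {
    a <- encode_structure("C", s)$acc
    expect_equal(which(a == 1) - 1L, min(s, 6L))
  }
  # missing data degrades to zeros
  enc <- encode_structure(c(NA, "C"), c(NA, 3L))
  expect_equal(enc$coil, c(0L, 1L))
  expect_equal(sum(enc$acc[1:7]), 0)
})

test_that("window encoding concatenates sequence, coil and accessibility blocks", {
  prot <- tiny_proteome()
  wins <- peptide_windows(
    tibble::tibble(protein_id = c("P1", "P2"), position = c(4L, 2L)), prot)
  st <- tibble::tibble(protein_id = "P1", position = 1:12,
                       ss_label = rep(c("C", "H", "E"), 4),
                       acc_score = rep(c(0L, 3L, 9L), 4))
  expect_warning(M <- encode_windows(wins, st), "without structure")
  expect_equal(dim(M), c(2L, 252L))
  # P1 window XMASTQPLV: 8 sequence bits (X is zero)
  expect_equal(sum(M[1, 1:180]), 8)
  # coil flags for P1 positions 0..8 (position 0 padded): C at 1,4,7
  expect_equal(unname(M[1, 181:189]), c(0, 1, 0, 0, 1, 0, 0, 1, 0))
  # accessibility present for the 8 in-sequence residues, clamped to bin 6
  expect_equal(sum(M[1, 190:252]), 8)
  acc9 <- M[1, 190 + 7 * 3 + 0:6]  # window offset 4 = protein position 3, score 9
  expect_equal(unname(acc9), c(0, 0, 0, 0, 0, 0, 1))
  # P2 has no structure records at all -> structure blocks zero
  expect_equal(sum(M[2, 181:252]), 0)
  # without structure the blocks are zero and no warning fires
  M0 <- encode_windows(wins, NULL)
  expect_equal(sum(M0[, 181:252]), 0)
})

test_that("identity counts matching positions and X matches nothing", {
  expect_equal(pairwise_identity("AAAASAAAA", "AAAASAAAA"), 1)
  expect_equal(pairwise_identity("AAAASAAAA", "AAAASAAAT"), 8 / 9)
  expect_equal(pairwise_identity("XXXXSXXXX", "XXXXSXXXX"), 1 / 9)
  expect_error(pairwise_identity("AST", "AS"), "equal length")
})

test_that("greedy homology filtering keeps first-come representatives", {
  kept <- homology_filter(c("AAAASAAAA", "AAAASAAAT", "TTTTSTTTT"))
  expect_equal(kept, c("AAAASAAAA", "TTTTSTTTT"))
  expect_equal(homology_filter(rep("AAAASAAAA", 5)), "AAAASAAAA")
  # 6/9 = 0.667 <= 0.7 is kept (identity exactly 0.7 impossible for 9-mers)
  expect_equal(homology_filter(c("AAAASAAAA", "AAARSRRAA")),
               c("AAAASAAAA", "AAARSRRAA"))
  # tibble input filters rows
  tb <- tibble::tibble(peptide = c("AAAASAAAA", "AAAASAAAT"), x = 1:2)
  expect_equal(homology_filter(tb)$x, 1L)
})

test_that("no kept pair exceeds the identity threshold (property)", {
  withr::with_seed(99, {
    for (rep in 1:3) {
      w <- random_homologous_windows(150)
      kept <- homology_filter(w, threshold = 0.7)
      expect_gt(length(kept), 0)
      if (length(kept) > 1) {
        pairs <- utils::combn(length(kept), 2)
        ids <- apply(pairs, 2, function(p) {
          pairwise_identity(kept[p[1]], kept[p[2]])
        })
        expect_lte(max(ids), 0.7)
      }
    }
  })
})

test_that("the background pool is every S/T window minus known sites", {
  prot <- tibble::tibble(id = "P", sequence = "MSTA")
  sites <- tibble::tibble(protein_id = "P", position = 2L, residue = "S",
                          family = "CDK")
  pool <- build_background_pool(prot, sites)
  expect_equal(nrow(pool), 1)
  expect_equal(pool$position, 3L)
  expect_equal(pool$residue, "T")
  expect_equal(pool$peptide, "XXMSTAXXX")
  # no S/T at all -> empty pool
  expect_equal(nrow(build_background_pool(tibble::tibble(id = "Q",
                                                         sequence = "MARK"))), 0)
  # count bookkeeping on a generated proteome
  ds <- simulate_dataset(small_config(seed = 8))
  pool <- build_background_pool(ds$proteins, ds$sites)
  n_st <- sum(stringr::str_count(ds$proteins$sequence, "[ST]"))
  expect_equal(nrow(pool), n_st - nrow(ds$sites))
})

test_that("negative sampling respects the homology guard and determinism", {
  ds <- simulate_dataset(small_config(seed = 5))
  pool <- build_background_pool(ds$proteins, ds$sites)
  expect_equal(nrow(sample_negatives(pool, 0)), 0)
  neg <- sample_negatives(pool, 30, seed = 123)
  expect_equal(nrow(neg), 30)
  pairs <- utils::combn(30, 2)
  ids <- apply(pairs, 2, function(p) {
    pairwise_identity(neg$peptide[p[1]], neg$peptide[p[2]])
  })
  expect_lte(max(ids), 0.7)
  expect_identical(sample_negatives(pool, 30, seed = 123), neg)
  expect_error(sample_negatives(pool[1:3, ], 10), "cannot supply|exhausted")
})
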