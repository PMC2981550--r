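# Probability estimation, Jaccard weighting, and the weighted log-odds score.

test_that("probability estimates use additive smoothing", {
  ids <- c("a", "b", "c", "d", "e", "f")
  pairs <- tibble::tibble(protein_id = c("a", "b", "c"), term_id = "t1")
  fm <- feature_matrix(pairs, "kegg", protein_ids = ids)
  p <- estimate_probs(fm, "t1", positive_ids = c("a", "b", "c"))
  expect_equal(p$f1, 4 / 5)          # 3 of 3 positives, pseudocount 1
  expect_equal(p$g1, 4 / 8)          # 3 of 6 background
  p0 <- estimate_probs(fm, "t1", positive_ids = c("d", "e", "f"))
  expect_equal(p0$f1, 1 / 5)         # 0 of 3: smoothing keeps it off 0
  plain <- estimate_probs(fm, "t1", positive_ids = c("a", "b"),
                          pseudocount = 0)
  expect_equal(plain$f1, 1)          # plain empirical frequency at c = 0
  expect_error(estimate_probs(fm, "t1", character(0)), "empty")
})

test_that("Jaccard distance counts differing coordinates over the union", {
  expect_equal(jaccard_distance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(jaccard_distance(c(1, 0, 0), c(0, 1, 1)), 1)
  expect_equal(jaccard_distance(c(1, 1, 0, 0), c(1, 0, 1, 0)), 2 / 3)
  expect_message(d0 <- jaccard_distance(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(d0, 0)
  expect_error(jaccard_distance(1, c(1, 0)), "equal length")
})

test_that("redundancy weights are self-inclusive similarity sums", {
  X1 <- matrix(c(1, 0, 1, 0), ncol = 1)
  expect_equal(unname(feature_weights(X1)), 1)
  Xdup <- cbind(a = c(1, 0, 1, 0), b = c(1, 0, 1, 0))
  expect_equal(feature_weights(Xdup), c(a = 2, b = 2))
  Xdisj <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  expect_equal(feature_weights(Xdisj), c(a = 1, b = 1))
  # correlated columns: Jaccard distance 2/3, similarity 1/3 -> weights 4/3
  Xcor <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  expect_equal(feature_weights(Xcor), c(a = 4 / 3, b = 4 / 3))
})

test_that("the weighted log-odds score behaves as designed", {
  model1 <- structure(list(
    features = tibble::tibble(namespace = "kegg", term_id = "t",
                              f1 = 0.75, g1 = 0.25, w = 1),
    positive_ids = "a", family = NULL, n_background = 4,
    pseudocount = 1, weighted = TRUE), class = "logodds_model")
  expect_equal(score_protein(1, model1), log(3), tolerance = 1e-12)
  expect_equal(score_protein(0, model1), log(1 / 3), tolerance = 1e-12)

  # duplicating the lone feature splits its weight: total unchanged
  model2 <- model1
  model2$features <- model2$features[c(1, 1), ]
  model2$features$w <- c(2, 2)
  expect_equal(score_protein(c(1, 1), model2), log(3), tolerance = 1e-12)

  # f == g scores 0 whatever the input
  modelfg <- model1
  modelfg$features$g1 <- 0.75
  expect_equal(score_protein(1, modelfg), 0)
  expect_equal(score_protein(0, modelfg), 0)
})

test_that("scores are additive over Jaccard-orthogonal feature blocks", {
  withr::with_seed(42, {
    j <- 40
    mk_cols <- function(p, rows) {
      X <- matrix(0L, j, p)
      for (i in seq_len(p)) X[sample(rows, 5), i] <- 1L
      X
    }
    # block A on rows 1..20, block B on rows 21..40: cross-similarities 0
    XA <- mk_cols(3, 1:20)
    XB <- mk_cols(4, 21:40)
    f <- runif(7, 0.1, 0.9); g <- runif(7, 0.1, 0.9); x <- rbinom(7, 1, 0.5)
    mk_model <- function(X, f1, g1) {
      structure(list(
        features = tibble::tibble(namespace = "kegg",
                                  term_id = paste0("t", seq_along(f1)),
                                  f1 = f1, g1 = g1,
                                  w = unname(feature_weights(X))),
        positive_ids = "a", family = NULL, n_background = j,
        pseudocount = 1, weighted = TRUE), class = "logodds_model")
    }
    sA <- score_protein(x[1:3], mk_model(XA, f[1:3], g[1:3]))
    sB <- score_protein(x[4:7], mk_model(XB, f[4:7], g[4:7]))
    sAB <- score_protein(x, mk_model(cbind(XA, XB), f, g))
    expect_equal(sAB, sA + sB, tolerance = 1e-12)
  })
})

test_that("KS comparison matches stepwise CDF enumeration", {
  same <- ks_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 3, 10))$statistic, 1 / 4)
  expect_error(ks_compare(numeric(0), 1), "nonempty")
})

test_that("candidate selection is strictly above the substrate median", {
  scores <- tibble::tibble(
    protein_id = c("s1", "s2", "s3", "s4", "s5", "a", "b", "c", "d"),
    score = c(1, 2, 3, 4, 5, 0, 2.5, 3.5, 10),
    is_substrate = c(rep(TRUE, 5), rep(FALSE, 4))
  )
  expect_equal(candidate_set(scores), c("c", "d"))
  # a background protein exactly at the median is excluded
  scores$score[scores$protein_id == "b"] <- 3
  expect_equal(candidate_set(scores), c("c", "d"))
  # even-count median is the mean of the central values
  sc2 <- tibble::tibble(protein_id = c("s1", "s2", "x"),
                        score = c(1, 2, 1.5),
                        is_substrate = c(TRUE, TRUE, FALSE))
  expect_equal(candidate_set(sc2), character(0))
  sc2$score[3] <- 1.6
  expect_equal(candidate_set(sc2), "x")
  expect_error(candidate_set(dplyr::filter(scores, !is_substrate)),
               "no substrate scores")
})

test_that("planted signal separates medians; null data does not", {
  planted_gap <- vapply(1:10, function(s) {
    ds <- simulate_dataset(calib_config(seed = 900 + s, n_terms = 50))
    sc <- score_proteins(ds, fit_logodds(ds, "CDK"))
    median(sc$score[sc$is_substrate]) - median(sc$score[!sc$is_substrate])
  }, 0)
  expect_true(all(planted_gap > 0))
  null_gap <- vapply(1:10, function(s) {
    ds <- null_dataset(calib_config(seed = 950 + s, n_terms = 50))
    sc <- score_proteins(ds, fit_logodds(ds, "CDK"))
    median(sc$score[sc$is_substrate]) - median(sc$score[!sc$is_substrate])
  }, 0)
  expect_gte(mean(abs(null_gap) < 0.1), 0.9)
})

test_that("model fitting produces tidy and glance summaries", {
  ds <- simulate_dataset(small_config(seed = 31))
  m <- fit_logodds(ds, "CDK")
  td <- tidy(m)
  expect_true(all(c("namespace", "term_id", "f1", "g1", "w",
                    "logodds_present") %in% names(td)))
  expect_true(all(td$f1 > 0 & td$f1 < 1))
  expect_true(all(td$w >= 1))
  gl <- glance(m)
  expect_equal(gl$n_features, nrow(td))
  sc <- score_proteins(ds, m)
  expect_equal(nrow(sc), nrow(ds$proteins))
  expect_equal(sum(sc$is_substrate), dplyr::n_distinct(ds$sites$protein_id))
  # a model with no features scores everything 0
  m0 <- fit_logodds(ds, "CDK", features = tidy(m)[0, ])
  expect_true(all(score_proteins(ds, m0)$score == 0))
})
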