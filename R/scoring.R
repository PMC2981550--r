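# Redundancy-weighted log-odds scoring of candidate proteins over the
# significant binary functional features.
#
# For feature i with value x_i in {0,1}, f(x_i) is its probability among the
# known substrates and g(x_i) among the whole proteome (both Laplace
# smoothed).  Correlated features (e.g. near-synonymous pathway and process
# terms) would otherwise be double counted, so each feature's log-odds
# contribution is divided by a weight w_i equal to the sum of its Jaccard
# similarities to all features (including its own self-similarity of 1, which
# also makes a lone feature well defined):
#
#   score(protein) = sum_i (1 / w_i) * ln( f(x_i) / g(x_i) )
#
# Duplicating a feature column leaves the score unchanged: the duplicate pair
# each get w = 2 and the two halves add back to the original contribution.

#' Estimate per-feature class probabilities
#'
#' Laplace-smoothed frequencies of each feature among the positive
#' (substrate) proteins, `f1 = (k_pos + c) / (n_pos + 2c)`, and among the
#' background universe, `g1 = (k_bg + c) / (n_bg + 2c)`, with pseudocount
#' `c`.  Smoothing keeps every probability strictly inside (0, 1) so log-odds
#' are always finite.
#'
#' @param fm A `feature_matrix` aligned to the background proteome.
#' @param feature_ids Term ids (columns of `fm`) to estimate.
#' @param positive_ids Substrate protein ids.
#' @param background_ids Background protein ids (default: every row of `fm`).
#' @param pseudocount Additive smoothing constant (default 1).
#' @return Tibble with columns `term_id`, `f1`, `g1`.
#' @export
estimate_probs <- function(fm, feature_ids, positive_ids,
                           background_ids = NULL, pseudocount = 1) {
  inc <- fm$incidence
  check_that(all(feature_ids %in% colnames(inc)),
             paste0("unknown features: ",
                    some_of(setdiff(feature_ids, colnames(inc)))))
  positive_ids <- unique(positive_ids)
  check_that(length(positive_ids) > 0, "positive set is empty")
  check_that(all(positive_ids %in% rownames(inc)),
             "positive proteins must be rows of the matrix")
  background_ids <- background_ids %||% rownames(inc)
  check_that(all(background_ids %in% rownames(inc)),
             "background proteins must be rows of the matrix")
  X <- inc[, feature_ids, drop = FALSE]
  f1 <- (colSums(X[positive_ids, , drop = FALSE]) + pseudocount) /
    (length(positive_ids) + 2 * pseudocount)
  g1 <- (colSums(X[background_ids, , drop = FALSE]) + pseudocount) /
    (length(background_ids) + 2 * pseudocount)
  tibble(term_id = feature_ids, f1 = unname(f1), g1 = unname(g1))
}

#' Jaccard distance between two binary vectors
#'
#' The fraction of coordinates, among those nonzero in either vector, at
#' which the vectors differ.  Two all-zero vectors are treated as identical
#' (distance 0) with a message.
#'
#' @param u,v Equal-length binary vectors.
#' @return Distance in \[0, 1\]; similarity is `1 - distance`.
#' @export
#' @examples
#' jaccard_distance(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 2/3
jaccard_distance <- function(u, v) {
  check_that(length(u) == length(v), "vectors must have equal length")
  union_nz <- sum(u != 0 | v != 0)
  if (union_nz == 0) {
    inform("both vectors are all-zero; Jaccard distance defined as 0")
    return(0)
  }
  sum(u != v) / union_nz
}

#' Redundancy weights for a set of binary feature columns
#'
#' `w_i = 1 + sum over r != i of (1 - jaccard_distance(col_i, col_r))`; the
#' leading 1 is the feature's self-similarity, which guarantees `w_i >= 1`
#' and a well-defined single-feature case.  Highly redundant features get
#' large weights and hence small per-feature contributions.
#'
#' @param X Binary matrix whose columns are the feature incidence vectors
#'   over the protein sample.
#' @return Named numeric vector of weights, one per column.
#' @export
feature_weights <- function(X) {
  X <- as.matrix(X)
  check_that(ncol(X) >= 1, "at least one feature column is required")
  cs <- colSums(X != 0)
  inter <- crossprod(X != 0)
  un <- outer(cs, cs, "+") - inter
  sim <- ifelse(un == 0, 1, inter / un)  # all-zero pairs count as identical
  w <- rowSums(sim)
  stats::setNames(as.numeric(w), colnames(X))
}

#' Fit the weighted log-odds scoring model
#'
#' Estimates `f`/`g` probabilities for every significant feature and the
#' Jaccard redundancy weights of their incidence columns over the full
#' proteome, yielding a `logodds_model` usable with [score_proteins()].
#' With no features (e.g. nothing significant on null data) the model scores
#' every protein 0.
#'
#' @param dataset A `phospho_dataset`.
#' @param family Kinase-family label defining the positive set (proteins with
#'   at least one site of the family), or `NULL` for all site-bearing
#'   proteins.
#' @param features Tibble of selected features (`namespace`, `term_id`), as
#'   from [enrich_dataset()]; computed at `alpha` when `NULL`.
#' @param alpha Significance cutoff used when `features` is `NULL`.
#' @param pseudocount Smoothing constant for [estimate_probs()].
#' @param weighted When `FALSE`, all weights are fixed to 1 (plain summed
#'   log-odds).
#' @return A `logodds_model` object.
#' @export
fit_logodds <- function(dataset, family = NULL, features = NULL, alpha = 1e-2,
                        pseudocount = 1, weighted = TRUE) {
  sites <- dataset$sites
  if (!is.null(family)) sites <- filter(sites, .data$family == !!family)
  positive_ids <- unique(sites$protein_id)
  check_that(length(positive_ids) > 0, "no substrate proteins for the positive set")
  if (is.null(features)) features <- enrich_dataset(dataset, family, alpha)
  feats <- features[c("namespace", "term_id")]
  if (nrow(feats) > 0) {
    probs <- lapply(split(feats, feats$namespace), function(fs) {
      ns <- fs$namespace[1]
      check_that(ns %in% names(dataset$annotations),
                 paste0("namespace '", ns, "' not in the dataset"))
      p <- estimate_probs(dataset$annotations[[ns]], fs$term_id, positive_ids,
                          pseudocount = pseudocount)
      mutate(p, namespace = ns, .before = 1)
    })
    probs <- bind_rows(probs)
    feats <- left_join(feats, probs, by = c("namespace", "term_id"))
    X <- feature_columns(dataset, feats)
    feats$w <- if (weighted) unname(feature_weights(X)) else rep(1, nrow(feats))
  } else {
    feats <- tibble(namespace = character(), term_id = character(),
                    f1 = double(), g1 = double(), w = double())
  }
  structure(list(features = feats, positive_ids = positive_ids,
                 family = family, n_background = nrow(dataset$proteins),
                 pseudocount = pseudocount, weighted = weighted),
            class = "logodds_model")
}

#' @export
print.logodds_model <- function(x, ...) {
  cat("<logodds_model>", if (!is.null(x$family)) paste0("family: ", x$family),
      "|", nrow(x$features), "features |", length(x$positive_ids),
      "positives /", x$n_background, "background\n")
  invisible(x)
}

#' @export
tidy.logodds_model <- function(x, ...) {
  mutate(x$features,
         logodds_present = log(.data$f1 / .data$g1) / .data$w,
         logodds_absent = log((1 - .data$f1) / (1 - .data$g1)) / .data$w)
}

#' @export
glance.logodds_model <- function(x, ...) {
  tibble(n_features = nrow(x$features),
         n_positive = length(x$positive_ids),
         n_background = x$n_background,
         pseudocount = x$pseudocount,
         weighted = x$weighted)
}

# Extract the binary incidence columns of a feature table (namespace,
# term_id) over the whole proteome; rows are proteome ids.
feature_columns <- function(dataset, features) {
  cols <- lapply(seq_len(nrow(features)), function(i) {
    ns <- features$namespace[i]
    check_that(ns %in% names(dataset$annotations),
               paste0("model/feature mismatch: namespace '", ns,
                      "' not in the dataset"))
    inc <- dataset$annotations[[ns]]$incidence
    check_that(features$term_id[i] %in% colnames(inc),
               paste0("model/feature mismatch: term '", features$term_id[i],
                      "' not in namespace '", ns, "'"))
    inc[, features$term_id[i]]
  })
  X <- do.call(cbind, cols)
  colnames(X) <- paste(features$namespace, features$term_id, sep = "/")
  X
}

#' Score a single feature-value vector
#'
#' @param x Binary vector of the protein's feature values, aligned to
#'   `model$features`.
#' @param model A `logodds_model`.
#' @return The weighted log-odds score.
#' @export
score_protein <- function(x, model) {
  feats <- model$features
  check_that(length(x) == nrow(feats),
             "x must have one value per model feature")
  if (nrow(feats) == 0) return(0)
  f <- ifelse(x == 1, feats$f1, 1 - feats$f1)
  g <- ifelse(x == 1, feats$g1, 1 - feats$g1)
  sum(log(f / g) / feats$w)
}

#' Score proteins of a dataset
#'
#' @param dataset A `phospho_dataset` carrying the annotation namespaces the
#'   model's features come from.
#' @param model A `logodds_model`.
#' @param ids Protein ids to score (default: the whole proteome).
#' @return Tibble with columns `protein_id`, `score`, `is_substrate` (whether
#'   the protein is in the model's positive set).
#' @export
score_proteins <- function(dataset, model, ids = NULL) {
  ids <- ids %||% dataset$proteins$id
  check_that(all(ids %in% dataset$proteins$id), "unknown protein ids")
  feats <- model$features
  if (nrow(feats) == 0) {
    return(tibble(protein_id = ids, score = 0,
                  is_substrate = ids %in% model$positive_ids))
  }
  X <- feature_columns(dataset, feats)[ids, , drop = FALSE]
  lo1 <- log(feats$f1 / feats$g1) / feats$w
  lo0 <- log((1 - feats$f1) / (1 - feats$g1)) / feats$w
  score <- as.numeric(X %*% lo1 + (1 - X) %*% lo0)
  tibble(protein_id = ids, score = score,
         is_substrate = ids %in% model$positive_ids)
}

#' Two-sample Kolmogorov-Smirnov comparison of score distributions
#'
#' @param x,y Numeric score samples (e.g. substrate vs background protein
#'   scores).
#' @return Tibble with `statistic` (D), `p_value` (asymptotic), `n_x`, `n_y`.
#' @export
ks_compare <- function(x, y) {
  check_that(length(x) > 0 && length(y) > 0, "both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  tibble(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
         n_x = length(x), n_y = length(y))
}

#' Above-median candidate proteins
#'
#' Background proteins whose score strictly exceeds the median score of the
#' known substrates; the even-count median is the mean of the two central
#' values.
#'
#' @param scores Score tibble from [score_proteins()] (columns `protein_id`,
#'   `score`, `is_substrate`).
#' @return Character vector of candidate protein ids.
#' @export
candidate_set <- function(scores) {
  sub <- scores$score[scores$is_substrate]
  check_that(length(sub) > 0, "no substrate scores")
  med <- median(sub)
  scores$protein_id[!scores$is_substrate & scores$score > med]
}

#' Histogram of substrate versus background score distributions
#'
#' Within-group percentage histograms of the weighted log-odds scores,
#' substrates overlaid on the background.
#'
#' @param scores Score tibble from [score_proteins()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(scores, bins = 30) {
  grp <- ifelse(scores$is_substrate, "substrates", "background")
  df <- tibble(score = scores$score, set = grp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$set)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      bins = bins, position = "identity", alpha = 0.6, colour = "grey30"
    ) +
    ggplot2::scale_fill_manual(values = c(background = "white",
                                          substrates = "grey55")) +
    ggplot2::labs(x = "weighted log-odds score", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}
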