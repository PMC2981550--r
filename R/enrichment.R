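# Over/under-represented annotation terms among a kinase family's substrates
# versus the background proteome: exact two-sided hypergeometric tests with
# Bonferroni control.  The selected terms are the functional features used by
# the scoring and classification stages.

check_hyper_args <- function(k, K, n, N) {
  ok <- all(c(k, K, n, N) == floor(c(k, K, n, N))) &&
    K >= 0 && K <= N && n >= 0 && n <= N &&
    k >= max(0, n - (N - K)) && k <= min(n, K)
  check_that(ok, paste0("arguments outside the hypergeometric support: k=", k,
                        " K=", K, " n=", n, " N=", N))
}

#' Hypergeometric probability mass
#'
#' Probability of drawing exactly `k` annotated proteins in a study set of
#' size `n` from a background of `N` proteins of which `K` carry the term:
#' `choose(K, k) * choose(N - K, n - k) / choose(N, n)`, evaluated in log
#' space for stability.
#'
#' @param k Annotated proteins in the study set.
#' @param K Annotated proteins in the background.
#' @param n Study-set size.
#' @param N Background size.
#' @return The probability mass at `k`.
#' @export
#' @examples
#' hypergeom_pmf(1, K = 2, n = 2, N = 4)  # 2/3
hypergeom_pmf <- function(k, K, n, N) {
  check_hyper_args(k, K, n, N)
  exp(stats::dhyper(k, K, N - K, n, log = TRUE))
}

#' Two-sided hypergeometric p-value
#'
#' Minimum-likelihood two-sided p (the standard two-sided rule of Fisher's
#' exact test): the sum of the probability mass over every outcome in the
#' support no more likely than the observed one.  A relative tie tolerance
#' guards against floating-point differences between equally likely outcomes.
#'
#' @inheritParams hypergeom_pmf
#' @param tie_tol Relative tolerance when comparing masses (default `1e-7`).
#' @return A p-value in (0, 1].
#' @export
#' @examples
#' two_sided_p(4, K = 4, n = 5, N = 10)  # 12/252
two_sided_p <- function(k, K, n, N, tie_tol = 1e-7) {
  check_hyper_args(k, K, n, N)
  lo <- max(0, n - (N - K))
  support <- lo:min(n, K)
  pmf <- stats::dhyper(support, K, N - K, n)
  pk <- pmf[k - lo + 1]
  min(max(sum(pmf[pmf <= pk * (1 + tie_tol)]), pk), 1)
}

# Doubled single-tail alternative (configurable, not the default).
two_sided_p_double <- function(k, K, n, N) {
  check_hyper_args(k, K, n, N)
  lower <- stats::phyper(k, K, N - K, n)
  upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Bonferroni correction
#'
#' @param p_raw Raw p-value(s) in \[0, 1\].
#' @param m Number of tests (>= 1).
#' @return `min(1, m * p_raw)`, vectorised over `p_raw`.
#' @export
#' @examples
#' bonferroni(0.001, 20)  # 0.02
bonferroni <- function(p_raw, m) {
  check_that(m >= 1, "m must be >= 1")
  check_that(all(p_raw >= 0 & p_raw <= 1), "p_raw must be in [0,1]")
  pmin(1, m * p_raw)
}

#' Select over/under-represented terms for a study set
#'
#' Tests every term of one namespace for over- or under-representation in the
#' study set (e.g. the substrates of a kinase family) against the full
#' protein universe of the matrix, using [two_sided_p()].  Terms absent from
#' the background (`K = 0`) are untestable and excluded both from testing and
#' from the Bonferroni test count `m`, which is per namespace.  Results with
#' corrected p below `alpha` are returned, each labelled `over` when the
#' study-set frequency exceeds the background frequency and `under`
#' otherwise.
#'
#' @param study_ids Protein ids of the study set (must be rows of the
#'   matrix).
#' @param fm A `feature_matrix` aligned to the background proteome.
#' @param alpha Significance cutoff on the Bonferroni-corrected p
#'   (default 1e-2).
#' @param tail Two-sided rule: `"min_likelihood"` (default) or `"double"`
#'   (doubled smaller tail).
#' @return Tibble with columns `namespace`, `term_id`, `k`, `n`, `K`, `N`,
#'   `p_raw`, `p_corrected`, `direction`, sorted by `p_corrected` then
#'   `term_id`.
#' @export
select_features <- function(study_ids, fm, alpha = 1e-2,
                            tail = c("min_likelihood", "double")) {
  tail <- match.arg(tail)
  check_that(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  study <- unique(study_ids)
  check_that(length(study) > 0, "study set is empty")
  inc <- fm$incidence
  missing <- setdiff(study, rownames(inc))
  check_that(length(missing) == 0,
             paste0("study proteins not in the matrix: ", some_of(missing)))
  N <- nrow(inc)
  n <- length(study)
  K <- colSums(inc)
  k <- colSums(inc[study, , drop = FALSE])
  testable <- which(K > 0)
  m <- length(testable)
  if (m == 0) {
    return(tibble(namespace = character(), term_id = character(),
                  k = integer(), n = integer(), K = integer(), N = integer(),
                  p_raw = double(), p_corrected = double(),
                  direction = character()))
  }
  pfun <- if (tail == "min_likelihood") two_sided_p else two_sided_p_double
  p_raw <- unname(vapply(testable, function(j) pfun(k[j], K[j], n, N), 0))
  res <- tibble(
    namespace = fm$namespace,
    term_id = colnames(inc)[testable],
    k = as.integer(k[testable]),
    n = as.integer(n),
    K = as.integer(K[testable]),
    N = as.integer(N),
    p_raw = p_raw,
    p_corrected = bonferroni(p_raw, m),
    direction = ifelse(k[testable] / n > K[testable] / N, "over", "under")
  )
  res <- filter(res, .data$p_corrected < alpha)
  arrange(res, .data$p_corrected, .data$term_id)
}

#' Select significant terms across all namespaces of a dataset
#'
#' Convenience wrapper: the study set is the set of proteins carrying at
#' least one known site of `family` (all families when `NULL`), and
#' [select_features()] runs per namespace with its own Bonferroni count.
#'
#' @param dataset A `phospho_dataset`.
#' @param family Kinase-family label, or `NULL` for all sites.
#' @inheritParams select_features
#' @return Tibble of significant terms across namespaces (see
#'   [select_features()]).
#' @export
enrich_dataset <- function(dataset, family = NULL, alpha = 1e-2,
                           tail = c("min_likelihood", "double")) {
  tail <- match.arg(tail)
  sites <- dataset$sites
  if (!is.null(family)) sites <- filter(sites, .data$family == !!family)
  study <- unique(sites$protein_id)
  check_that(length(study) > 0,
             paste0("no substrates found", if (!is.null(family))
               paste0(" for family '", family, "'")))
  res <- lapply(dataset$annotations, function(fm) {
    select_features(study, fm, alpha = alpha, tail = tail)
  })
  bind_rows(res)
}
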