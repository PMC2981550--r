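# Shared fixtures and independent oracles used across the suite.

# A tiny literal proteome for IO and window tests.
tiny_proteome <- function() {
  tibble::tibble(
    id = c("P1", "P2", "P3"),
    sequence = c("MASTQPLVKSAR", "MSTPRKKSTAGH", "AAAASAAAATTT")
  )
}

# Small, fast generator configuration: 15 substrates x 2 sites over a
# 120-protein background, two namespaces.  Arguments override the defaults.
small_config <- function(seed = 1, ...) {
  args <- list(
    n_background = 120, n_substrates = 15, protein_length = 80,
    namespaces = lapply(c("kegg", "go_cc"),
                        function(n) synth_namespace(n, n_terms = 20)),
    seed = seed
  )
  args <- utils::modifyList(args, list(...))
  do.call(synth_config, args)
}

# Planted-recovery configuration: 30 substrates / 500 background, one
# namespace of 30 terms with three terms planted at odds ratio 10.
recovery_config <- function(seed) {
  synth_config(
    n_background = 500, n_substrates = 30, protein_length = 60,
    sites_per_substrate = 1,
    namespaces = list(synth_namespace("kegg", n_terms = 30,
                                      background_term_prob = 0.1,
                                      n_enriched = 3, n_depleted = 0,
                                      enriched_odds_ratio = 10)),
    seed = seed
  )
}

# Configuration for the enrichment calibration experiments: 50 substrates /
# 500 background / one namespace of 200 terms at background rate 0.1.
# Sequence length is irrelevant to term calibration, so proteins are short.
calib_config <- function(seed, n_substrates = 50, n_terms = 200) {
  synth_config(
    n_background = 500, n_substrates = n_substrates, protein_length = 60,
    sites_per_substrate = 1,
    namespaces = list(synth_namespace("kegg", n_terms = n_terms,
                                      background_term_prob = 0.1,
                                      n_enriched = 3, n_depleted = 0)),
    seed = seed
  )
}

# Proteome-scan study configuration: sharp proline-directed consensus motif
# (P at +1, R at +3) at strength 0.9 and sparse functional signal (one
# enriched term in each of three namespaces), emulating the regime where a
# scan makes sparse predictions on prioritized candidates.
scan_config <- function(seed) {
  synth_config(
    seed = seed, motif = list(`1` = "P", `3` = "R"), motif_strength = 0.9,
    namespaces = lapply(c("kegg", "go_cc", "string_ppi"), function(n) {
      synth_namespace(n, n_terms = 30, n_enriched = 1, n_depleted = 0)
    })
  )
}

# Independent brute-force oracle for the two-sided hypergeometric p-value:
# enumerate the whole support with explicit binomial coefficients.
oracle_two_sided <- function(k, K, n, N) {
  supp <- max(0, n - (N - K)):min(n, K)
  mass <- choose(K, supp) * choose(N - K, n - supp) / choose(N, n)
  pk <- mass[supp == k]
  min(sum(mass[mass <= pk * (1 + 1e-7)]), 1)
}

# Rank-based AUC oracle (probability a positive outranks a negative).
oracle_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))[seq_along(pos)]
  (sum(r) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Windows drawn from a 3-letter alphabet are highly homologous by
# construction; handy for exercising the identity filter.
random_homologous_windows <- function(n, letters = c("A", "S", "T"), L = 9) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, L, replace = TRUE), collapse = "")
  }, "")
}
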