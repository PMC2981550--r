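# Synthetic datasets with the statistical structure the method assumes:
# a planted sequence motif around true phosphosites and planted over/under-
# represented annotation terms among substrate proteins.  Everything is a
# pure function of the configuration and its seed.

#' Describe one synthetic annotation namespace
#'
#' Terms are independent Bernoulli flags.  Background proteins carry each term
#' with probability `background_term_prob`; for substrate proteins the
#' probability of an enriched (depleted) term is tilted by the odds ratio:
#' `p' = OR * p / (1 - p + OR * p)`, which keeps the background probability
#' interpretable and the hypergeometric alternative well defined.
#'
#' @param name Namespace label (see [feature_matrix()]).
#' @param n_terms Number of terms in the namespace.
#' @param background_term_prob Per-protein Bernoulli probability of each term
#'   in the background.
#' @param n_enriched Number of terms over-represented among substrates.
#' @param enriched_odds_ratio Odds ratio (> 0) applied to enriched terms for
#'   substrate proteins.
#' @param n_depleted Number of terms under-represented among substrates.
#' @param depleted_odds_ratio Odds ratio (> 0, typically < 1) applied to
#'   depleted terms for substrate proteins.
#' @return A `synth_namespace` list.
#' @export
synth_namespace <- function(name, n_terms = 30, background_term_prob = 0.1,
                            n_enriched = 3, enriched_odds_ratio = 8,
                            n_depleted = 2, depleted_odds_ratio = 1 / 8) {
  check_that(name %in% NAMESPACES, paste0("unknown namespace '", name, "'"))
  check_that(n_terms >= 1, "n_terms must be positive")
  check_that(background_term_prob > 0 && background_term_prob < 1,
             "background_term_prob must be in (0,1)")
  check_that(enriched_odds_ratio > 0 && depleted_odds_ratio > 0,
             "odds ratios must be > 0")
  check_that(n_enriched >= 0 && n_depleted >= 0, "term counts must be >= 0")
  check_that(n_enriched + n_depleted <= n_terms,
             paste0("namespace '", name, "': n_enriched + n_depleted exceeds n_terms"))
  structure(list(name = name, n_terms = as.integer(n_terms),
                 background_term_prob = background_term_prob,
                 n_enriched = as.integer(n_enriched),
                 enriched_odds_ratio = enriched_odds_ratio,
                 n_depleted = as.integer(n_depleted),
                 depleted_odds_ratio = depleted_odds_ratio),
            class = "synth_namespace")
}

default_namespaces <- function() {
  lapply(NAMESPACES, synth_namespace)
}

#' Configure the synthetic-data generator
#'
#' The defaults describe the study conditions the rest of the package is
#' calibrated against: 50 substrate proteins with 2 true sites each (100
#' positive sites) over a 500-protein background, a proline-directed motif
#' (`P` at offset +1, as for CDK/MAPK-class kinases) mixed with uniform
#' residues at strength 0.8, and seven annotation namespaces each planting a
#' few terms at odds ratio 8 (enriched) and 1/8 (depleted) over a 10% term
#' background rate.
#'
#' @param n_background Number of background proteins.
#' @param n_substrates Number of substrate proteins.
#' @param protein_length Length of every generated protein.
#' @param family Kinase-family label attached to the planted sites.
#' @param motif Named list mapping window offsets (as names, `"-4"` .. `"4"`,
#'   excluding `"0"`) to either a single residue or a named probability vector
#'   over residues.
#' @param motif_strength Mixing weight in \[0, 1\]: each motif offset follows
#'   the motif distribution with this probability and is uniform otherwise.
#' @param namespaces List of [synth_namespace()] descriptions.
#' @param sites_per_substrate True sites planted per substrate protein.
#' @param seed Integer seed; the generator is a pure function of the
#'   configuration including this seed.
#' @return A `synth_config` list.
#' @export
#' @examples
#' cfg <- synth_config(n_background = 50, n_substrates = 5, seed = 1)
#' ds <- simulate_dataset(cfg)
#' ds
synth_config <- function(n_background = 500, n_substrates = 50,
                         protein_length = 300, family = "CDK",
                         motif = list(`1` = "P"), motif_strength = 0.8,
                         namespaces = default_namespaces(),
                         sites_per_substrate = 2, seed = 1) {
  check_that(n_background >= 1 && n_substrates >= 1, "counts must be positive")
  check_that(sites_per_substrate >= 1, "sites_per_substrate must be >= 1")
  check_that(motif_strength >= 0 && motif_strength <= 1,
             "motif_strength must be in [0,1]")
  # Sites are planted at least 5 residues from either terminus with centers at
  # least 9 apart, so windows are unpadded and non-overlapping.
  check_that(protein_length >= 10 + 9 * sites_per_substrate,
             "protein_length too short for the requested sites_per_substrate")
  offs <- suppressWarnings(as.integer(names(motif)))
  check_that(!anyNA(offs) && all(offs >= -4 & offs <= 4 & offs != 0),
             "motif offsets must be integers in -4..4 excluding 0")
  motif <- lapply(motif, function(m) {
    if (is.character(m) && length(m) == 1) {
      m <- stats::setNames(1, m)
    }
    check_that(is.numeric(m) && all(m >= 0) && sum(m) > 0 &&
                 all(names(m) %in% AA_STANDARD),
               "motif entries must be residues or named probability vectors")
    m / sum(m)
  })
  namespaces <- lapply(namespaces, function(ns) {
    check_that(inherits(ns, "synth_namespace"),
               "namespaces must be synth_namespace objects")
    ns
  })
  check_that(!anyDuplicated(vapply(namespaces, `[[`, "", "name")),
             "duplicate namespace names")
  structure(list(n_background = as.integer(n_background),
                 n_substrates = as.integer(n_substrates),
                 protein_length = as.integer(protein_length),
                 family = family, motif = motif,
                 motif_strength = motif_strength, namespaces = namespaces,
                 sites_per_substrate = as.integer(sites_per_substrate),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Odds-ratio tilt of a Bernoulli probability.
tilt_prob <- function(p, odds_ratio) {
  odds_ratio * p / (1 - p + odds_ratio * p)
}

# n i.i.d. uniform sequences of length len, each guaranteed >= 1 S/T.
draw_sequences <- function(n, len) {
  chars <- matrix(sample(AA_STANDARD, n * len, replace = TRUE), nrow = len)
  seqs <- apply(chars, 2, paste, collapse = "")
  redo <- which(!grepl("[ST]", seqs))
  while (length(redo) > 0) {
    for (i in redo) {
      seqs[i] <- paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
    }
    redo <- redo[!grepl("[ST]", seqs[redo])]
  }
  seqs
}

# Sample k site centers in [6, len - 5], pairwise at least 9 apart.
draw_site_positions <- function(len, k) {
  lo <- 6L
  hi <- len - 5L
  repeat {
    pos <- sort(sample(lo:hi, k))
    if (k == 1 || all(diff(pos) >= 9)) return(pos)
  }
}

#' Generate a synthetic dataset
#'
#' Background proteins have i.i.d. uniform residues (resampled to guarantee at
#' least one S/T).  Each substrate protein carries `sites_per_substrate` true
#' sites whose -4..+4 windows follow the configured motif mixed with uniform
#' residues at `motif_strength`; site centers are S or T with equal
#' probability.  Annotation terms are independent Bernoulli flags, with
#' enriched/depleted terms tilted for substrates by their odds ratios.
#' Structure labels are uniform over \{H, E, C\} and accessibility scores
#' uniform over 0..6 for every residue.
#'
#' The returned dataset carries an attribute `planted`: a named list per
#' namespace with the ids of the enriched and depleted terms, for use as
#' ground truth in calibration experiments.
#'
#' @param config A [synth_config()].
#' @return A `phospho_dataset`.
#' @export
simulate_dataset <- function(config) {
  check_that(inherits(config, "synth_config"), "config must be a synth_config")
  len <- config$protein_length
  sub_ids <- sprintf("SUB%04d", seq_len(config$n_substrates))
  bg_ids <- sprintf("BG%05d", seq_len(config$n_background))
  ids <- c(sub_ids, bg_ids)

  # Component sub-streams are seeded independently so that, e.g., adding a
  # namespace leaves the generated sequences untouched.
  seqs <- withr::with_seed(child_seed(config$seed, 1L), {
    draw_sequences(length(ids), len)
  })

  sites <- withr::with_seed(child_seed(config$seed, 2L), {
    rows <- vector("list", config$n_substrates)
    for (i in seq_len(config$n_substrates)) {
      pos <- draw_site_positions(len, config$sites_per_substrate)
      chars <- strsplit(seqs[i], "")[[1]]
      centers <- sample(c("S", "T"), length(pos), replace = TRUE)
      chars[pos] <- centers
      for (off_name in names(config$motif)) {
        off <- as.integer(off_name)
        pref <- config$motif[[off_name]]
        use_motif <- runif(length(pos)) < config$motif_strength
        drawn <- ifelse(use_motif,
                        sample(names(pref), length(pos), replace = TRUE, prob = pref),
                        sample(AA_STANDARD, length(pos), replace = TRUE))
        chars[pos + off] <- drawn
      }
      seqs[i] <- paste(chars, collapse = "")
      rows[[i]] <- tibble(protein_id = sub_ids[i], position = pos,
                          residue = centers, family = config$family)
    }
    bind_rows(rows)
  })

  annotations <- lapply(seq_along(config$namespaces), function(j) {
    ns <- config$namespaces[[j]]
    withr::with_seed(child_seed(config$seed, 100L + j), {
      terms <- sprintf("%s:T%04d", ns$name, seq_len(ns$n_terms))
      p_bg <- rep(ns$background_term_prob, ns$n_terms)
      p_sub <- p_bg
      if (ns$n_enriched > 0) {
        p_sub[seq_len(ns$n_enriched)] <-
          tilt_prob(ns$background_term_prob, ns$enriched_odds_ratio)
      }
      if (ns$n_depleted > 0) {
        p_sub[ns$n_enriched + seq_len(ns$n_depleted)] <-
          tilt_prob(ns$background_term_prob, ns$depleted_odds_ratio)
      }
      inc_sub <- matrix(runif(config$n_substrates * ns$n_terms) <
                          rep(p_sub, each = config$n_substrates),
                        nrow = config$n_substrates)
      inc_bg <- matrix(runif(config$n_background * ns$n_terms) <
                         rep(p_bg, each = config$n_background),
                       nrow = config$n_background)
      inc <- rbind(inc_sub, inc_bg) * 1L
      dimnames(inc) <- list(ids, terms)
      fm <- structure(list(namespace = ns$name, incidence = inc),
                      class = "feature_matrix")
      attr(fm, "planted") <- list(
        enriched = terms[seq_len(ns$n_enriched)],
        depleted = terms[ns$n_enriched + seq_len(ns$n_depleted)]
      )
      fm
    })
  })

  structure_tb <- withr::with_seed(child_seed(config$seed, 50L), {
    n_res <- length(ids) * len
    tibble(protein_id = rep(ids, each = len),
           position = rep(seq_len(len), times = length(ids)),
           ss_label = sample(c("H", "E", "C"), n_res, replace = TRUE),
           acc_score = sample(0:6, n_res, replace = TRUE))
  })

  planted <- lapply(annotations, attr, "planted")
  names(planted) <- vapply(config$namespaces, `[[`, "", "name")
  ds <- phospho_dataset(tibble(id = ids, sequence = seqs), sites,
                        annotations, structure_tb)
  attr(ds, "planted") <- planted
  attr(ds, "config") <- config
  ds
}

#' Generate a matched no-signal dataset
#'
#' Runs [simulate_dataset()] on the same configuration with every odds ratio
#' forced to 1 and `motif_strength` forced to 0, so neither the sequences nor
#' the annotations carry any substrate signal.  Used for null calibration of
#' the enrichment, scoring and classification stages.
#'
#' @inheritParams simulate_dataset
#' @return A `phospho_dataset` with no planted signal.
#' @export
null_dataset <- function(config) {
  check_that(inherits(config, "synth_config"), "config must be a synth_config")
  config$motif_strength <- 0
  config$namespaces <- lapply(config$namespaces, function(ns) {
    ns$enriched_odds_ratio <- 1
    ns$depleted_odds_ratio <- 1
    ns
  })
  simulate_dataset(config)
}
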