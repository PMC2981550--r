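# End-to-end proteome scan: restrict to above-median candidate proteins,
# classify every non-known S/T window in them with the trained model, and
# tally predictions.  run_pipeline() chains every stage and writes all
# intermediate artifacts as plain text.

#' Scan candidate proteins for predicted phosphorylation sites
#'
#' Candidate proteins are the background proteins whose weighted log-odds
#' score exceeds the median score of the known substrates
#' (see [candidate_set()]).  Every S/T-centered window in a candidate protein
#' that is not a known site (of any family) is encoded with the model's
#' feature group and classified; windows with positive decision values
#' become predicted sites.
#'
#' @param dataset A `phospho_dataset`.
#' @param family Kinase-family label for the output table.
#' @param model A `phospho_svm` from [train_final()].
#' @param scores Score tibble from [score_proteins()] for the same dataset
#'   and family.
#' @param include_known Also scan known sites, flagged in a `known` column
#'   (default `FALSE`: known sites are training data and excluded).
#' @return A `phospho_scan` object: list with `predictions` (tibble
#'   `protein_id`, `position`, `residue`, `family`, `decision_value`,
#'   `protein_score`) and `summary` (tibble `family`, `n_candidate_sites`,
#'   `n_predicted_proteins`, `n_predicted_sites`).
#' @export
scan_proteome <- function(dataset, family, model, scores,
                          include_known = FALSE) {
  check_that(inherits(model, "phospho_svm"), "model must be a phospho_svm")
  cand <- candidate_set(scores)
  empty_pred <- tibble(protein_id = character(), position = integer(),
                       residue = character(), family = character(),
                       decision_value = double(), protein_score = double())
  if (length(cand) == 0) {
    return(structure(list(
      predictions = empty_pred,
      summary = tibble(family = family, n_candidate_sites = 0L,
                       n_predicted_proteins = 0L, n_predicted_sites = 0L),
      scanned = empty_pred
    ), class = "phospho_scan"))
  }
  prot <- filter(dataset$proteins, .data$id %in% cand)
  wins <- build_background_pool(prot,
                                sites = if (include_known) NULL else dataset$sites,
                                residues = c("S", "T"), h = model$h)
  if (include_known) {
    known <- dataset$sites[c("protein_id", "position")]
    wins <- mutate(wins, known = paste(wins$protein_id, wins$position) %in%
                     paste(known$protein_id, known$position))
  }
  pred <- predict_sites(model, wins, dataset)
  pred <- mutate(pred, family = family,
                 protein_score = scores$score[match(pred$protein_id,
                                                    scores$protein_id)])
  hits <- filter(pred, .data$predicted)
  predictions <- hits[c("protein_id", "position", "residue", "family",
                        "decision_value", "protein_score")]
  structure(list(
    predictions = predictions,
    summary = tibble(family = family,
                     n_candidate_sites = nrow(pred),
                     n_predicted_proteins = n_distinct(predictions$protein_id),
                     n_predicted_sites = nrow(predictions)),
    scanned = pred
  ), class = "phospho_scan")
}

#' @export
print.phospho_scan <- function(x, ...) {
  cat("<phospho_scan> family:", x$summary$family, "|",
      x$summary$n_candidate_sites, "candidate sites ->",
      x$summary$n_predicted_sites, "predicted sites on",
      x$summary$n_predicted_proteins, "proteins\n")
  invisible(x)
}

#' @export
tidy.phospho_scan <- function(x, ...) x$predictions

#' @export
glance.phospho_scan <- function(x, ...) x$summary

# One log line per event; no timestamps so identical runs produce identical
# logs.
pipeline_log <- function(path, ...) {
  cat(paste0(paste0(..., collapse = ""), "\n"), file = path, append = TRUE)
}

#' Run the full pipeline and write all artifacts
#'
#' Executes the requested stages in order -- `simulate` (or load an existing
#' dataset from `out_dir`), `enrich`, `score`, `cv`, `train`, `scan` -- and
#' writes every intermediate as plain text under `out_dir`, plus a
#' `pipeline.log` recording parameters and seeds.  Outputs are a pure
#' function of the configuration and seed, so re-running with identical
#' inputs reproduces identical files.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [synth_config()] used by the `simulate` stage and as the
#'   default source of `family` and `seed`.
#' @param stages Character vector of stages to run, in pipeline order.
#' @param family Kinase-family label (default: the config's family).
#' @param seed Master seed (default: the config's seed).
#' @param reps,folds,split_mode,alpha Cross-validation settings (see
#'   [run_cv()]).
#' @param cv_groups Feature groups evaluated by the `cv` stage.
#' @return Invisibly, a named list of in-memory stage results.
#' @export
run_pipeline <- function(out_dir, config = synth_config(),
                         stages = c("simulate", "enrich", "score", "cv",
                                    "train", "scan"),
                         family = config$family, seed = config$seed,
                         reps = 10, folds = 5, split_mode = "site",
                         alpha = 1e-2,
                         cv_groups = names(feature_groups())) {
  all_stages <- c("simulate", "enrich", "score", "cv", "train", "scan")
  check_that(all(stages %in% all_stages),
             paste0("unknown stage(s): ", some_of(setdiff(stages, all_stages))))
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out_dir, "pipeline.log")
  unlink(log)
  pipeline_log(log, "hetphos pipeline | stages: ", paste(stages, collapse = ","),
               " | family: ", family, " | seed: ", seed)
  res <- list()

  if ("simulate" %in% stages) {
    res$dataset <- simulate_dataset(config)
    write_dataset(res$dataset, out_dir)
    pipeline_log(log, "simulate: ", nrow(res$dataset$proteins), " proteins, ",
                 nrow(res$dataset$sites), " sites, ",
                 length(res$dataset$annotations), " namespaces")
  } else if (length(stages) > 0) {
    ok <- file.exists(file.path(out_dir, "proteome.fasta"))
    check_that(ok, paste0("stage '", stages[1], "' needs a dataset: run the ",
                          "'simulate' stage or place dataset files in ", out_dir))
    res$dataset <- read_dataset(out_dir)
    pipeline_log(log, "load: dataset read from ", out_dir)
  }

  if ("enrich" %in% stages) {
    res$enrichment <- enrich_dataset(res$dataset, family, alpha)
    readr::write_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
    pipeline_log(log, "enrich: ", nrow(res$enrichment),
                 " significant terms at alpha ", alpha)
  }

  if ("score" %in% stages) {
    check_that(!is.null(res$enrichment),
               "stage 'score' needs the 'enrich' stage")
    res$model_logodds <- fit_logodds(res$dataset, family,
                                     features = res$enrichment)
    res$scores <- score_proteins(res$dataset, res$model_logodds)
    readr::write_tsv(res$scores, file.path(out_dir, "scores.tsv"),
                     progress = FALSE)
    sub <- res$scores$score[res$scores$is_substrate]
    bg <- res$scores$score[!res$scores$is_substrate]
    res$ks <- ks_compare(sub, bg)
    readr::write_tsv(res$ks, file.path(out_dir, "ks.tsv"), progress = FALSE)
    pipeline_log(log, "score: KS D = ", signif(res$ks$statistic, 4),
                 ", p = ", signif(res$ks$p_value, 4))
  }

  if ("cv" %in% stages) {
    res$cv <- run_cv(res$dataset, family, split_mode = split_mode,
                     folds = folds, reps = reps, seed = seed,
                     groups = cv_groups, alpha = alpha)
    readr::write_tsv(tidy(res$cv), file.path(out_dir, "cv_report.tsv"),
                     progress = FALSE)
    pipeline_log(log, "cv: ", reps, " reps x ", folds, " folds (", split_mode,
                 " splits), minus = ",
                 if (is.na(res$cv$minus)) "NA" else signif(res$cv$minus, 4))
  }

  if ("train" %in% stages) {
    res$model <- train_final(res$dataset, family, group = "all", seed = seed,
                             alpha = alpha)
    saveRDS(res$model, file.path(out_dir, "model.rds"))
    pipeline_log(log, "train: group all, ", res$model$n_features,
                 " features, ", res$model$n_pos, " positive sites")
  }

  if ("scan" %in% stages) {
    if (is.null(res$model)) {
      mf <- file.path(out_dir, "model.rds")
      check_that(file.exists(mf), "stage 'scan' needs the 'train' stage")
      res$model <- readRDS(mf)
    }
    if (is.null(res$scores)) {
      sf <- file.path(out_dir, "scores.tsv")
      check_that(file.exists(sf), "stage 'scan' needs the 'score' stage")
      res$scores <- readr::read_tsv(sf, show_col_types = FALSE,
                                    progress = FALSE)
    }
    res$scan <- scan_proteome(res$dataset, family, res$model, res$scores)
    write_predictions(res$scan$predictions,
                      file.path(out_dir, "predictions.tsv"))
    readr::write_tsv(res$scan$summary, file.path(out_dir, "scan_summary.tsv"),
                     progress = FALSE)
    pipeline_log(log, "scan: ", res$scan$summary$n_candidate_sites,
                 " candidate sites -> ", res$scan$summary$n_predicted_sites,
                 " predicted on ", res$scan$summary$n_predicted_proteins,
                 " proteins")
  }

  invisible(res)
}
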