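# Site-level classification with RBF-kernel SVMs over nine feature groups,
# evaluated by repeated, leakage-safe five-fold cross-validation.
#
# Each feature group is the 252-bit sequence+structure block plus the
# significant terms of zero or more annotation namespaces.  Significant terms
# are re-selected inside every training fold from the training positives
# only, so no information from test-fold substrates leaks into feature
# selection.  Negatives are drawn fresh from the background peptide pool with
# the same homology guard as the positives and the same sample size, so every
# fold is class balanced by construction (site-level splits).

#' The nine feature groups
#'
#' Named list mapping each group to the annotation namespaces added on top of
#' the sequence+structure block: `sequence` adds none, `all` adds every
#' namespace, the remaining seven add their single namespace.
#'
#' @return Named list of character vectors.
#' @export
feature_groups <- function() {
  list(
    sequence = character(0),
    kegg = "kegg",
    bp = "go_bp",
    cc = "go_cc",
    mf = "go_mf",
    pfam = "pfam",
    ipr = "interpro",
    string = "string_ppi",
    all = NAMESPACES
  )
}

#' Assemble feature vectors for a set of windows
#'
#' Concatenates the sequence+structure encoding of each window with one
#' binary indicator per selected functional feature of the group's
#' namespaces, looked up from the window's source protein (background
#' windows therefore use their own protein's annotations).
#'
#' @param windows Window tibble (`protein_id`, `position`, `peptide`).
#' @param group Feature-group name (see [feature_groups()]).
#' @param features Tibble of selected features (`namespace`, `term_id`);
#'   only those in the group's namespaces are used.
#' @param dataset The `phospho_dataset` supplying annotations and structure.
#' @inheritParams extract_window
#' @return Numeric matrix, one row per window.
#' @export
assemble_vectors <- function(windows, group, features, dataset, h = 4) {
  check_that(group %in% names(feature_groups()),
             paste0("unknown feature group '", group, "'"))
  ss <- encode_windows(windows, dataset$structure, h)
  namespaces <- feature_groups()[[group]]
  feats <- features[features$namespace %in% namespaces, , drop = FALSE]
  if (nrow(feats) == 0) return(ss)
  X <- feature_columns(dataset, feats)[windows$protein_id, , drop = FALSE]
  rownames(X) <- NULL
  cbind(ss, X)
}

# Fit one RBF-SVM and return test accuracy (%).  Binary features are left
# unscaled; cost 1 and kernel width 1/ncol are the only hyperparameters.
svm_fold_accuracy <- function(M, y, train, test) {
  fit <- e1071::svm(M[train, , drop = FALSE], y[train], kernel = "radial",
                    cost = 1, gamma = 1 / ncol(M), scale = FALSE)
  pred <- predict(fit, M[test, , drop = FALSE])
  100 * mean(pred == y[test])
}

#' Repeated cross-validation over feature groups
#'
#' For each repetition: homology-filter the family's positive windows, draw
#' an equal number of homology-guarded negatives from the background pool,
#' split five-fold, re-select significant terms per namespace from the
#' training positives of each fold, and train/test one RBF-SVM per feature
#' group on identical partitions.  Accuracy is the percentage of correct
#' predictions over the pooled positive and negative test samples.
#'
#' `split_mode = "site"` splits sites directly; `"protein"` splits source
#' proteins first (no protein contributes sites to both train and test, and
#' negatives are likewise grouped by source protein).
#'
#' @param dataset A `phospho_dataset`.
#' @param family Kinase-family label.
#' @param split_mode `"site"` or `"protein"`.
#' @param folds Number of folds (default 5).
#' @param reps Number of repetitions of the full cross-validation
#'   (default 10).
#' @param seed Master seed; repetition `r` uses the derived child seed
#'   `seed + r`.
#' @param groups Feature groups to evaluate (default all nine).
#' @param alpha In-fold significance cutoff for term selection.
#' @param identity_threshold Homology threshold for positives and negatives.
#' @param resample_negatives Draw a fresh negative set each repetition
#'   (default); when `FALSE` one fixed set is reused.
#' @param collect_diagnostics Record per-fold selected features and
#'   train/test protein sets (used for leakage audits).
#' @inheritParams extract_window
#' @return A `phospho_cv` report.
#' @export
run_cv <- function(dataset, family, split_mode = c("site", "protein"),
                   folds = 5, reps = 10, seed = 1,
                   groups = names(feature_groups()), alpha = 1e-2,
                   identity_threshold = 0.7, resample_negatives = TRUE,
                   collect_diagnostics = FALSE, h = 4) {
  split_mode <- match.arg(split_mode)
  check_that(all(groups %in% names(feature_groups())),
             "unknown feature group(s)")
  fam_sites <- filter(dataset$sites, .data$family == !!family)
  check_that(nrow(fam_sites) >= folds,
             paste0("family '", family, "' has fewer than ", folds, " sites"))
  pos_all <- peptide_windows(fam_sites, dataset$proteins, h)
  pos_all <- homology_filter(pos_all, identity_threshold)
  n_pos <- nrow(pos_all)
  check_that(n_pos >= folds,
             paste0("family '", family, "' has fewer than ", folds,
                    " sites after homology filtering"))
  pool <- build_background_pool(dataset$proteins, dataset$sites,
                                c("S", "T"), h)
  need_ns <- unique(unlist(feature_groups()[groups]))
  acc <- array(NA_real_, c(reps, folds, length(groups)),
               dimnames = list(NULL, NULL, groups))
  diag_features <- list()
  diag_folds <- list()
  neg <- NULL
  for (r in seq_len(reps)) {
    withr::with_seed(child_seed(seed, r), {
      if (is.null(neg) || resample_negatives) {
        neg <- sample_negatives(pool, n_pos, identity_threshold)
      }
      if (split_mode == "site") {
        fold_pos <- sample(rep(seq_len(folds), length.out = n_pos))
        fold_neg <- sample(rep(seq_len(folds), length.out = n_pos))
      } else {
        # one fold per source protein, shared across roles: a protein that
        # contributes both positive sites and negative windows stays on one
        # side of every split
        prots <- unique(c(pos_all$protein_id, neg$protein_id))
        fp <- sample(rep(seq_len(folds), length.out = length(prots)))
        fold_pos <- fp[match(pos_all$protein_id, prots)]
        fold_neg <- fp[match(neg$protein_id, prots)]
      }
      allw <- bind_rows(pos_all[c("protein_id", "position", "peptide")],
                        neg[c("protein_id", "position", "peptide")])
      y <- factor(rep(c("site", "bg"), c(n_pos, nrow(neg))),
                  levels = c("bg", "site"))
      foldid <- c(fold_pos, fold_neg)
      ss <- encode_windows(allw, dataset$structure, h)
      fun_all <- dataset$annotations[intersect(names(dataset$annotations),
                                               need_ns)]
      for (f in seq_len(folds)) {
        test <- foldid == f
        train <- !test
        study <- unique(pos_all$protein_id[fold_pos != f])
        sel <- bind_rows(lapply(fun_all, function(fm) {
          select_features(study, fm, alpha = alpha)
        }))
        if (collect_diagnostics) {
          diag_folds[[length(diag_folds) + 1L]] <- tibble(
            rep = r, fold = f,
            n_train_pos = sum(train & y == "site"),
            n_train_neg = sum(train & y == "bg"),
            n_test_pos = sum(test & y == "site"),
            n_test_neg = sum(test & y == "bg"),
            train_proteins = list(sort(unique(allw$protein_id[train]))),
            test_proteins = list(sort(unique(allw$protein_id[test]))),
            train_study = list(study)
          )
          if (nrow(sel) > 0) {
            diag_features[[length(diag_features) + 1L]] <- mutate(
              sel[c("namespace", "term_id", "k", "n", "direction")], rep = r, fold = f,
              .before = 1
            )
          }
        }
        for (g in groups) {
          namespaces <- feature_groups()[[g]]
          feats <- sel[sel$namespace %in% namespaces, , drop = FALSE]
          M <- if (nrow(feats) > 0) {
            Xf <- feature_columns(dataset, feats)[allw$protein_id, ,
                                                  drop = FALSE]
            rownames(Xf) <- NULL
            cbind(ss, Xf)
          } else ss
          acc[r, f, g] <- svm_fold_accuracy(M, y, train, test)
        }
      }
    })
  }
  rep_acc <- apply(acc, c(1, 3), mean)
  accuracy <- tibble(
    group = groups,
    mean = as.numeric(colMeans(rep_acc)),
    sd = as.numeric(apply(rep_acc, 2, sd))
  )
  minus <- if (all(c("all", "sequence") %in% groups)) {
    accuracy$mean[accuracy$group == "all"] -
      accuracy$mean[accuracy$group == "sequence"]
  } else NA_real_
  structure(list(
    family = family, accuracy = accuracy, minus = minus,
    rep_accuracy = as_tibble(cbind(tibble(rep = seq_len(reps)),
                                   as.data.frame(rep_acc))),
    n_pos = n_pos, n_neg = n_pos, folds = folds, reps = reps, seed = seed,
    split_mode = split_mode, alpha = alpha,
    diagnostics = if (collect_diagnostics) {
      list(folds = bind_rows(diag_folds), features = bind_rows(diag_features))
    } else NULL
  ), class = "phospho_cv")
}

#' @export
print.phospho_cv <- function(x, ...) {
  cat("<phospho_cv> family:", x$family, "| split:", x$split_mode,
      "|", x$folds, "folds x", x$reps, "reps |", x$n_pos, "pos /",
      x$n_neg, "neg\n")
  print(x$accuracy)
  if (!is.na(x$minus)) cat("minus (all - sequence):", round(x$minus, 2), "\n")
  invisible(x)
}

#' @export
tidy.phospho_cv <- function(x, ...) {
  mutate(x$accuracy, family = x$family, .before = 1)
}

#' @export
glance.phospho_cv <- function(x, ...) {
  tibble(family = x$family, minus = x$minus, n_pos = x$n_pos,
         n_neg = x$n_neg, folds = x$folds, reps = x$reps,
         split_mode = x$split_mode, seed = x$seed)
}

#' @export
autoplot.phospho_cv <- function(object, ...) {
  df <- mutate(object$accuracy,
               group = factor(.data$group, levels = object$accuracy$group))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.25
    ) +
    ggplot2::coord_cartesian(ylim = c(40, 100)) +
    ggplot2::labs(x = "feature group", y = "accuracy (%)",
                  title = paste0(object$family, " (", object$split_mode,
                                 "-level splits)")) +
    ggplot2::theme_minimal()
}

#' Train the final site classifier
#'
#' Trains one RBF-SVM on all (homology-filtered) known sites of the family
#' plus an equal-size fresh negative sample, with functional features
#' selected on the full positive set.  The returned model records its feature
#' list, group and seed; decision values are oriented so that positive values
#' favour the phosphosite class.
#'
#' @inheritParams run_cv
#' @param group Feature group to train on (default `"all"`).
#' @return A `phospho_svm` model handle.
#' @export
train_final <- function(dataset, family, group = "all", seed = 1,
                        alpha = 1e-2, identity_threshold = 0.7, h = 4) {
  check_that(group %in% names(feature_groups()),
             paste0("unknown feature group '", group, "'"))
  fam_sites <- filter(dataset$sites, .data$family == !!family)
  check_that(nrow(fam_sites) > 0, paste0("no sites for family '", family, "'"))
  withr::with_seed(child_seed(seed, 0L), {
    pos <- peptide_windows(fam_sites, dataset$proteins, h)
    pos <- homology_filter(pos, identity_threshold)
    pool <- build_background_pool(dataset$proteins, dataset$sites,
                                  c("S", "T"), h)
    neg <- sample_negatives(pool, nrow(pos), identity_threshold)
    study <- unique(pos$protein_id)
    namespaces <- feature_groups()[[group]]
    sel <- bind_rows(lapply(
      dataset$annotations[intersect(names(dataset$annotations), namespaces)],
      function(fm) select_features(study, fm, alpha = alpha)
    ))
    if (nrow(sel) == 0) {
      sel <- tibble(namespace = character(), term_id = character(),
                    direction = character())
    }
    allw <- bind_rows(pos[c("protein_id", "position", "peptide")],
                      neg[c("protein_id", "position", "peptide")])
    y <- factor(rep(c("site", "bg"), c(nrow(pos), nrow(neg))),
                levels = c("bg", "site"))
    M <- assemble_vectors(allw, group, sel, dataset, h)
    fit <- e1071::svm(M, y, kernel = "radial", cost = 1, gamma = 1 / ncol(M),
                      scale = FALSE)
    dv <- as.numeric(attr(predict(fit, M, decision.values = TRUE),
                          "decision.values"))
    dv_sign <- if (mean(dv[y == "site"]) >= mean(dv[y == "bg"])) 1 else -1
    structure(list(fit = fit, features = sel[c("namespace", "term_id")],
                   group = group, family = family, h = h,
                   n_features = ncol(M), n_pos = nrow(pos),
                   seed = seed, alpha = alpha, dv_sign = dv_sign),
              class = "phospho_svm")
  })
}

#' @export
print.phospho_svm <- function(x, ...) {
  cat("<phospho_svm> family:", x$family, "| group:", x$group, "|",
      x$n_features, "features |", x$n_pos, "positive sites | seed:",
      x$seed, "\n")
  invisible(x)
}

#' @export
tidy.phospho_svm <- function(x, ...) x$features

#' @export
glance.phospho_svm <- function(x, ...) {
  tibble(family = x$family, group = x$group, n_features = x$n_features,
         n_selected_terms = nrow(x$features), n_pos = x$n_pos,
         alpha = x$alpha, seed = x$seed)
}

#' Classify peptide windows with a trained model
#'
#' Encodes the windows with the model's feature group and selected features
#' (erroring if the dataset lacks any of them) and returns signed decision
#' values; windows with positive decision values are predicted sites.
#'
#' @param model A `phospho_svm` from [train_final()].
#' @param windows Window tibble (`protein_id`, `position`, `peptide`).
#' @param dataset The `phospho_dataset` supplying annotations and structure.
#' @return `windows` with added columns `decision_value` and `predicted`.
#' @export
predict_sites <- function(model, windows, dataset) {
  check_that(inherits(model, "phospho_svm"), "model must be a phospho_svm")
  if (nrow(windows) == 0) {
    return(mutate(windows, decision_value = double(0), predicted = logical(0)))
  }
  M <- assemble_vectors(windows, model$group, model$features, dataset,
                        model$h)
  check_that(ncol(M) == model$n_features,
             paste0("model/feature mismatch: model expects ", model$n_features,
                    " features, dataset provides ", ncol(M)))
  dv <- model$dv_sign *
    as.numeric(attr(predict(model$fit, M, decision.values = TRUE),
                    "decision.values"))
  mutate(windows, decision_value = dv, predicted = dv > 0)
}
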