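#' Stratified fold assignment
#'
#' Deals each class's (shuffled) rows round-robin over `k` folds, so every
#' fold approximately preserves the class proportions. Uses the current
#' RNG state; seed upstream for determinism.
#'
#' @param y Label vector.
#' @param k Number of folds.
#' @return Integer fold id per row.
#' @export
stratified_folds <- function(y, k) {
  if (min(table(y)) < k)
    stop("smallest class has fewer sessions (", min(table(y)),
         ") than folds (", k, "); cannot stratify")
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Region-of-interest channel map
#'
#' `left_motor` is the fixed six-channel set over left M1; `central` is
#' the midline central strip present in the montage; `whole_scalp` is
#' every channel.
#'
#' @param channels Montage channel names.
#' @return Named list of channel vectors.
#' @export
roi_definitions <- function(channels) {
  list(left_motor = intersect(left_motor_channels(), channels),
       central = intersect(c("FC1", "FCz", "FC2", "C1", "Cz", "C2",
                             "CP1", "CPz", "CP2"), channels),
       whole_scalp = channels)
}

#' Build the candidate feature groups
#'
#' Deterministically ordered Cartesian product of feature families, ROIs
#' and data transformations. A family is either a channel-wise feature
#' base name (columns `<family>_<channel>`) or a session-level column
#' name. Pre-TBS features and the visit-type code are appended per group
#' according to the flags.
#'
#' @param families Character vector of family names.
#' @param rois Character vector of ROI names (see [roi_definitions()]).
#' @param transformations Subset of `"normalization"`,
#'   `"log_distance_to_median"`, `"none"`.
#' @param include_pretbs Append `pre_*` columns to every group.
#' @param include_visit_type Append the visit-type code to every group.
#' @return List of `feature_group` objects.
#' @export
build_feature_groups <- function(families,
                                 rois = c("left_motor", "central",
                                          "whole_scalp"),
                                 transformations = c("normalization",
                                   "log_distance_to_median"),
                                 include_pretbs = FALSE,
                                 include_visit_type = FALSE) {
  if (length(families) == 0) return(list())
  known <- c("normalization", "log_distance_to_median", "none")
  if (length(bad <- setdiff(transformations, known)))
    stop("unknown transformation(s): ", paste(bad, collapse = ", "))
  groups <- list()
  for (fam in families)
    for (roi in rois)
      for (tr in transformations)
        groups[[length(groups) + 1L]] <- structure(
          list(family = fam, roi = roi, transformation = tr,
               include_pretbs = include_pretbs,
               include_visit_type = include_visit_type),
          class = "feature_group")
  groups
}

#' @export
format.feature_group <- function(x, ...)
  paste(x$family, x$roi, x$transformation, sep = "|")

#' Design matrix for one feature group
#'
#' @param group A `feature_group`.
#' @param features Wide feature data frame (meta columns `session_id`,
#'   `subject_id`, `cohort`, `visit` plus feature columns).
#' @param roi_map As from [roi_definitions()].
#' @return Numeric matrix, rows aligned with `features`.
#' @export
group_matrix <- function(group, features, roi_map) {
  if (!group$roi %in% names(roi_map))
    stop("unknown ROI: ", group$roi)
  chan_cols <- paste0(group$family, "_", roi_map[[group$roi]])
  cols <- intersect(chan_cols, colnames(features))
  if (length(cols) == 0) {
    if (group$family %in% colnames(features)) cols <- group$family
    else stop("feature family '", group$family,
              "' matches no columns in the feature table")
  }
  if (group$include_pretbs)
    cols <- c(cols, grep("^pre_", colnames(features), value = TRUE))
  X <- as.matrix(features[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  if (group$include_visit_type)
    X <- cbind(X, visit_type = as.integer(features$visit == "retest"))
  X
}

#' Train-fitted feature transformation
#'
#' `normalization` is a per-feature z-score; `log_distance_to_median` is
#' `log(|x - median| + eps)`. All parameters (mean, SD, median) are fit on
#' the training matrix only and applied unchanged to the evaluation
#' matrix, so no evaluation information leaks into the fit. Zero-SD
#' training features are dropped with a warning under `normalization`.
#' A `visit_type` column is passed through untransformed.
#'
#' @param train,eval_ Numeric matrices with identical columns.
#' @param kind `"normalization"`, `"log_distance_to_median"` or `"none"`.
#' @param eps Offset inside the log distance.
#' @return List `train`, `eval` (transformed), `dropped` (column names).
#' @export
apply_transformation <- function(train, eval_, kind = "none", eps = 1e-6) {
  if (nrow(train) == 0) stop("empty training matrix")
  keep_as_is <- colnames(train) %in% "visit_type"
  dropped <- character(0)
  if (kind == "none") return(list(train = train, eval = eval_,
                                  dropped = dropped))
  tr <- train; ev <- eval_
  for (j in which(!keep_as_is)) {
    x <- train[, j]
    if (kind == "normalization") {
      m <- mean(x); s <- stats::sd(x)
      if (is.na(s) || s == 0) {
        dropped <- c(dropped, colnames(train)[j])
        next
      }
      tr[, j] <- (train[, j] - m) / s
      ev[, j] <- (eval_[, j] - m) / s
    } else if (kind == "log_distance_to_median") {
      md <- stats::median(x)
      tr[, j] <- log(abs(train[, j] - md) + eps)
      ev[, j] <- log(abs(eval_[, j] - md) + eps)
    } else stop("unknown transformation: ", kind)
  }
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    keep <- !colnames(train) %in% dropped
    tr <- tr[, keep, drop = FALSE]
    ev <- ev[, keep, drop = FALSE]
  }
  list(train = tr, eval = ev, dropped = dropped)
}

#' Repeated stratified cross-validation of one model
#'
#' `reps` repetitions of `folds`-fold stratified CV. Transformation
#' parameters and any hyperparameter tuning are fit inside each training
#' fold; the evaluation fold only ever receives train-fitted parameters.
#' The 95% confidence interval uses the t-distribution over the
#' `reps * folds` per-fold values.
#'
#' @param classifier_id One of [classifier_ids()].
#' @param X Feature matrix.
#' @param y Labels (`positive`/`negative`).
#' @param transformation Transformation kind (see
#'   [apply_transformation()]).
#' @param reps,folds CV geometry (default 10 x 5).
#' @param seed Seed; same seed gives identical results.
#' @param params Classifier parameters.
#' @param eval_mutator Optional diagnostic hook
#'   `function(X_eval, y_eval, rep, fold)` returning a modified evaluation
#'   matrix. Used by leakage canaries; leave `NULL` in normal use.
#' @return A `cv_result`: `per_fold` (matrix folds x metrics), `mean`,
#'   `ci_half` (95% half-widths), `reps`, `folds`.
#' @export
cross_validate <- function(classifier_id, X, y, transformation = "none",
                           reps = 10L, folds = 5L, seed = 1L,
                           params = list(), eval_mutator = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  set.seed(seed)
  rows <- list()
  for (rep in seq_len(reps)) {
    foldid <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      tr <- foldid != f
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      Xev <- X[!tr, , drop = FALSE]; yev <- y[!tr]
      if (!is.null(eval_mutator)) Xev <- eval_mutator(Xev, yev, rep, f)
      tx <- suppressWarnings(
        apply_transformation(Xtr, Xev, transformation))
      model <- fit_classifier(classifier_id, tx$train, ytr, params,
                              seed = seed + 1000L * rep + f)
      sc <- score_classifier(model, tx$eval)
      pred <- predict_classifier(model, tx$eval)
      rows[[length(rows) + 1L]] <- evaluate_metrics(yev, pred, sc)
    }
  }
  per_fold <- do.call(rbind, rows)
  mu <- colMeans(per_fold, na.rm = TRUE)
  nf <- nrow(per_fold)
  half <- apply(per_fold, 2, function(v)
    stats::qt(0.975, nf - 1) * stats::sd(v, na.rm = TRUE) / sqrt(nf))
  structure(list(per_fold = per_fold, mean = mu, ci_half = half,
                 reps = reps, folds = folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "CV (%d x %d): ROC-AUC %.3f +/- %.3f, acc %.3f, sens %.3f, spec %.3f\n",
    x$reps, x$folds, x$mean["roc_auc"], x$ci_half["roc_auc"],
    x$mean["accuracy"], x$mean["sensitivity"], x$mean["specificity"]))
  invisible(x)
}

#' Select the winning model from CV candidates
#'
#' Candidates whose mean CV sensitivity or specificity falls below 0.60
#' are excluded; among the admissible ones the highest mean ROC-AUC wins.
#' Ties break deterministically: fewest features, then lexicographically
#' smallest candidate id.
#'
#' @param candidates List of lists, each with fields `id`, `n_features`
#'   and `cv` (a `cv_result`).
#' @param min_sens,min_spec Admissibility floors.
#' @return The winning candidate, or an object of class
#'   `no_admissible_model` if every candidate is excluded.
#' @export
select_model <- function(candidates, min_sens = 0.60, min_spec = 0.60) {
  if (length(candidates) == 0) stop("no candidates")
  ok <- vapply(candidates, function(cand) {
    m <- cand$cv$mean
    !is.na(m["sensitivity"]) && !is.na(m["specificity"]) &&
      m["sensitivity"] >= min_sens && m["specificity"] >= min_spec
  }, logical(1))
  if (!any(ok))
    return(structure(list(n_candidates = length(candidates)),
                     class = "no_admissible_model"))
  adm <- candidates[ok]
  key <- vapply(adm, function(cand)
    sprintf("%018.12f|%09d|%s", 1 - cand$cv$mean["roc_auc"],
            cand$n_features, cand$id), character(1))
  adm[[order(key)[1]]]
}

#' External validation with stratified bootstrap intervals
#'
#' Retrains the classifier on the whole training set (transformation
#' refit on it), scores the held-out external set once, and derives 95%
#' percentile confidence intervals from `n_boot` class-stratified
#' resamples of the external rows. Chance levels: majority-class rate for
#' accuracy, 0.5 for ROC-AUC, positive prevalence for PR-AUC.
#'
#' @param classifier_id,params,transformation Model description.
#' @param X_train,y_train Training data.
#' @param X_ext,y_ext External validation data.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @param subjects_train,subjects_ext Optional subject ids; any overlap is
#'   an error (cross-subject designs must keep subjects on one side).
#' @return A `validation_result`: `point`, `ci` (2 x metrics), `chance`,
#'   `n_boot`, `model`.
#' @export
external_validate <- function(classifier_id, X_train, y_train, X_ext,
                              y_ext, transformation = "none",
                              params = list(), n_boot = 2000L, seed = 1L,
                              subjects_train = NULL, subjects_ext = NULL) {
  if (!is.null(subjects_train) && !is.null(subjects_ext)) {
    ov <- intersect(unique(subjects_train), unique(subjects_ext))
    if (length(ov))
      stop("subject(s) present in both training and external sets: ",
           paste(ov, collapse = ", "))
  }
  y_train <- as.character(y_train); y_ext <- as.character(y_ext)
  tx <- suppressWarnings(
    apply_transformation(as.matrix(X_train), as.matrix(X_ext),
                         transformation))
  model <- fit_classifier(classifier_id, tx$train, y_train, params,
                          seed = seed)
  sc <- score_classifier(model, tx$eval)
  pred <- predict_classifier(model, tx$eval)
  point <- evaluate_metrics(y_ext, pred, sc)
  set.seed(seed)
  idx_pos <- which(y_ext == "positive")
  idx_neg <- which(y_ext == "negative")
  boot <- t(vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(idx_pos, length(idx_pos), replace = TRUE),
             sample(idx_neg, length(idx_neg), replace = TRUE))
    evaluate_metrics(y_ext[idx], pred[idx], sc[idx])
  }, numeric(length(point))))
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  chance <- c(accuracy = max(mean(y_ext == "positive"),
                             mean(y_ext == "negative")),
              roc_auc = 0.5,
              pr_auc = mean(y_ext == "positive"))
  structure(list(point = point, ci = ci, chance = chance,
                 n_boot = n_boot, model = model),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("External validation (", x$n_boot, " stratified resamples)\n",
      sep = "")
  for (m in names(x$point))
    cat(sprintf("  %-12s %.3f [%.3f, %.3f]\n", m, x$point[m],
                x$ci[1, m], x$ci[2, m]))
  invisible(x)
}

#' Run a full model-generation/selection/validation experiment
#'
#' The three designs split sessions as follows. `cross_session`: all
#' initial visits train, all retest visits validate externally.
#' `cross_cohort`: cohort 1 (both visits) trains with the visit type
#' appended as a feature; cohort 2 validates. `cross_subject`: a seeded
#' 50/50 subject split across cohorts; both visits follow their subject.
#' Candidates are every feature group x categorization method x
#' classifier; each is assessed by [cross_validate()], the winner chosen
#' by [select_model()] and externally validated by [external_validate()].
#'
#' @param design `"cross_session"`, `"cross_cohort"` or
#'   `"cross_subject"`.
#' @param features Wide feature table (meta columns `session_id`,
#'   `subject_id`, `cohort`, `visit`).
#' @param label_sets Named list of label data frames (`session_id`,
#'   `label`), one per categorization method.
#' @param config List: `families`, `rois`, `transformations`,
#'   `classifiers`, `reps`, `folds`, `n_boot`, `seed`,
#'   `classifier_params`, `include_pretbs`.
#' @return An `experiment_report`: candidate table, selected candidate,
#'   external validation, split accounting.
#' @export
run_experiment <- function(design = c("cross_session", "cross_cohort",
                                      "cross_subject"),
                           features, label_sets, config = list()) {
  design <- match.arg(design)
  cfg <- utils::modifyList(list(
    families = NULL, rois = "left_motor",
    transformations = "normalization",
    classifiers = classifier_ids(), reps = 10L, folds = 5L,
    n_boot = 2000L, seed = 1L, classifier_params = list(),
    include_pretbs = FALSE), config)
  if (is.null(cfg$families)) stop("config$families is required")
  seed <- cfg$seed

  meta_cols <- c("session_id", "subject_id", "cohort", "visit")
  stopifnot(all(meta_cols %in% colnames(features)))
  chans <- cfg$channels %||% attr(features, "channels") %||% character()
  roi_map <- roi_definitions(chans)

  if (design == "cross_session") {
    tr_rows <- features$visit == "initial"
  } else if (design == "cross_cohort") {
    tr_rows <- features$cohort == 1
  } else {
    subjects <- sort(unique(features$subject_id))
    set.seed(seed)
    tr_sub <- sample(subjects, floor(length(subjects) / 2))
    tr_rows <- features$subject_id %in% tr_sub
  }
  groups <- build_feature_groups(
    cfg$families, cfg$rois, cfg$transformations,
    include_pretbs = cfg$include_pretbs,
    include_visit_type = design == "cross_cohort")

  candidates <- list()
  for (method in names(label_sets)) {
    lab <- label_sets[[method]]
    lab_of <- stats::setNames(as.character(lab$label), lab$session_id)
    have <- features$session_id %in% lab$session_id
    for (g in groups) {
      Xall <- group_matrix(g, features, roi_map)
      for (clf in cfg$classifiers) {
        rows <- tr_rows & have
        cv <- cross_validate(clf, Xall[rows, , drop = FALSE],
                             lab_of[features$session_id[rows]],
                             transformation = g$transformation,
                             reps = cfg$reps, folds = cfg$folds,
                             seed = seed,
                             params = cfg$classifier_params[[clf]] %||%
                               list())
        candidates[[length(candidates) + 1L]] <- list(
          id = paste(method, format(g), clf, sep = "|"),
          method = method, group = g, classifier = clf,
          n_features = ncol(Xall), cv = cv)
      }
    }
  }

  sel <- select_model(candidates)
  external <- NULL
  if (!inherits(sel, "no_admissible_model")) {
    lab <- label_sets[[sel$method]]
    lab_of <- stats::setNames(as.character(lab$label), lab$session_id)
    have <- features$session_id %in% lab$session_id
    Xall <- group_matrix(sel$group, features, roi_map)
    tr <- tr_rows & have; ex <- !tr_rows & have
    external <- external_validate(
      sel$classifier,
      Xall[tr, , drop = FALSE], lab_of[features$session_id[tr]],
      Xall[ex, , drop = FALSE], lab_of[features$session_id[ex]],
      transformation = sel$group$transformation,
      params = cfg$classifier_params[[sel$classifier]] %||% list(),
      n_boot = cfg$n_boot, seed = seed,
      subjects_train = if (design == "cross_subject")
        features$subject_id[tr] else NULL,
      subjects_ext = if (design == "cross_subject")
        features$subject_id[ex] else NULL)
  }

  cand_table <- do.call(rbind, lapply(candidates, function(cand)
    data.frame(id = cand$id, method = cand$method,
               classifier = cand$classifier,
               n_features = cand$n_features,
               roc_auc = unname(cand$cv$mean["roc_auc"]),
               accuracy = unname(cand$cv$mean["accuracy"]),
               sensitivity = unname(cand$cv$mean["sensitivity"]),
               specificity = unname(cand$cv$mean["specificity"]))))
  structure(list(design = design, candidates = candidates,
                 candidate_table = cand_table, selected = sel,
                 external = external,
                 n_train = sum(tr_rows), n_external = sum(!tr_rows),
                 train_sessions = features$session_id[tr_rows],
                 external_sessions = features$session_id[!tr_rows],
                 seed = seed),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment:", x$design, "(", x$n_train, "train /", x$n_external,
      "external sessions )\n")
  cat("Candidates:", nrow(x$candidate_table), "\n")
  if (inherits(x$selected, "no_admissible_model")) {
    cat("No admissible model (all excluded by the 0.60 ",
        "sensitivity/specificity rule)\n", sep = "")
  } else {
    cat("Selected:", x$selected$id, "\n")
    print(x$selected$cv)
    if (!is.null(x$external)) print(x$external)
  }
  invisible(x)
}
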