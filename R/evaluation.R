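#' Support-weighted multiclass scores
#'
#' Per-class F1 combined by an average weighted by class support, and
#' one-vs-rest AUC per class, also support-weighted.  A class absent from
#' the true labels (or covering all of them) has an undefined AUC and is
#' excluded from the weighted AUC mean with a warning.  The confusion
#' matrix has true labels as rows.
#'
#' @param y_true true activity labels.
#' @param y_pred predicted labels.
#' @param y_proba probability matrix, one column per class in
#'   `class_order`; rows sum to 1.
#' @param class_order class order for the confusion matrix and probability
#'   columns (default: sorted classes of `y_true`).
#' @return list with `weighted_f1`, `weighted_auc`, `per_class_f1` (named),
#'   `per_class_auc`, `confusion` (count matrix) and `support`.
#' @export
weighted_scores <- function(y_true, y_pred, y_proba,
                            class_order = sort(unique(y_true))) {
  stopifnot(length(y_true) == length(y_pred),
            nrow(y_proba) == length(y_true))
  tf <- factor(y_true, levels = class_order)
  pf <- factor(y_pred, levels = class_order)
  conf <- table(true = tf, predicted = pf)
  conf <- matrix(as.integer(conf), nrow = length(class_order),
                 dimnames = list(class_order, class_order))
  support <- rowSums(conf)
  tp <- diag(conf)
  prec_den <- colSums(conf)
  f1 <- ifelse(2 * tp + (prec_den - tp) + (support - tp) == 0, 0,
               2 * tp / (2 * tp + (prec_den - tp) + (support - tp)))
  names(f1) <- class_order
  total <- sum(support)
  weighted_f1 <- sum(f1 * support) / total

  auc <- rep(NA_real_, length(class_order))
  names(auc) <- class_order
  for (i in seq_along(class_order)) {
    cls <- class_order[i]
    pos <- y_true == cls
    if (!any(pos) || all(pos)) next
    auc[i] <- as.numeric(pROC::auc(
      response = as.integer(pos), predictor = y_proba[, cls],
      levels = c(0, 1), direction = "<", quiet = TRUE
    ))
  }
  usable <- !is.na(auc) & support > 0
  if (anyNA(auc)) {
    warning("AUC undefined for class(es): ",
            paste(class_order[is.na(auc)], collapse = ", "),
            "; excluded from the weighted mean")
  }
  weighted_auc <- if (any(usable)) {
    sum(auc[usable] * support[usable]) / sum(support[usable])
  } else NA_real_
  list(weighted_f1 = weighted_f1, weighted_auc = weighted_auc,
       per_class_f1 = f1, per_class_auc = auc, confusion = conf,
       support = support)
}

# Stratified assignment of rows to k folds (or to a test split).
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Fit standardizer + selection on the training rows of one partition and
# train a model; returns the model plus the fitted preprocessing so
# callers (and tests) can verify no test row influenced any statistic.
fit_pipeline <- function(train_fm, y_train, columns, spec, threshold) {
  std <- fit_standardizer(train_fm, columns)
  ztr <- apply_standardizer(train_fm, std)
  sel <- correlation_select(ztr, y_train, threshold, columns)
  model <- train_model(ztr[, sel$retained, drop = FALSE], y_train, spec)
  list(model = model, standardizer = std, selection = sel)
}

score_pipeline <- function(pipe, test_fm, y_test, class_order) {
  zte <- apply_standardizer(test_fm, pipe$standardizer)
  proba <- predict_proba(pipe$model, zte)
  # classes never seen in training get probability 0
  full <- matrix(0, nrow(proba), length(class_order),
                 dimnames = list(NULL, class_order))
  full[, colnames(proba)] <- proba
  pred <- class_order[max.col(full, ties.method = "first")]
  weighted_scores(y_test, pred, full, class_order)
}

#' Subject-specific (personal model) evaluation
#'
#' Stratified 80/20 train/test split of one subject's windows; the
#' standardizer and correlation-based selection are fitted on the 80%
#' only.  Stratified 10-fold cross-validation scores are recorded on the
#' training portion (folds degrade gracefully to the smallest class count,
#' with a warning), the final model is fitted on the full training portion
#' and scored on the held-out 20%.  Both the CV means and the test scores
#' are reported.
#'
#' @param features one subject's `feature_matrix`.
#' @param scenario_id early-fusion scenario (1--7).
#' @param spec a [model_spec()].
#' @param seed seed controlling the split, fold assignment and forest.
#' @param threshold selection threshold (default 0.85).
#' @param cv_folds requested number of CV folds (default 10).
#' @return list with `subject_id`, `scenario_id`, test-set `weighted_f1`,
#'   `weighted_auc`, `per_class_f1`, `confusion`, `cv_fold_scores`
#'   (per-fold weighted F1/AUC), `cv_mean_f1`, `cv_mean_auc`,
#'   `n_features`, and a `detail` element carrying the fitted
#'   preprocessing and the train/test row indices.
#' @export
subject_specific_eval <- function(features, scenario_id,
                                  spec = model_spec(), seed = 1L,
                                  threshold = 0.85, cv_folds = 10) {
  y <- features$activity
  tab <- table(y)
  if (any(tab < 2)) {
    stop("class(es) with fewer than 2 windows: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  class_order <- sort(unique(y))
  columns <- scenario_columns(scenario_id, feature_cols(features))
  seeds <- derive_seeds(seed, 3)

  # stratified 80/20 split
  set.seed(seeds[1])
  test_idx <- unlist(lapply(class_order, function(cls) {
    idx <- which(y == cls)
    n_test <- max(1, round(0.2 * length(idx)))
    sample(idx, n_test)
  }))
  train_idx <- setdiff(seq_len(nrow(features)), test_idx)
  train_fm <- features[train_idx, , drop = FALSE]
  y_train <- y[train_idx]

  # cross-validation on the training portion
  k <- min(cv_folds, min(table(y_train)))
  if (k < cv_folds) {
    warning("reducing CV folds to ", k, " (smallest class count)")
  }
  cv_scores <- data.frame(fold = integer(0), weighted_f1 = numeric(0),
                          weighted_auc = numeric(0))
  if (k >= 2) {
    set.seed(seeds[2])
    fold <- stratified_folds(y_train, k)
    for (f in seq_len(k)) {
      tr <- fold != f
      pipe <- fit_pipeline(train_fm[tr, , drop = FALSE], y_train[tr],
                           columns,
                           within_spec_seed(spec, seeds[3] + f), threshold)
      sc <- score_pipeline(pipe, train_fm[!tr, , drop = FALSE],
                           y_train[!tr], class_order)
      cv_scores <- rbind(cv_scores,
                         data.frame(fold = f, weighted_f1 = sc$weighted_f1,
                                    weighted_auc = sc$weighted_auc))
    }
  }

  # final model on the full training portion, scored on the 20%
  pipe <- fit_pipeline(train_fm, y_train, columns,
                       within_spec_seed(spec, seeds[3]), threshold)
  sc <- score_pipeline(pipe, features[test_idx, , drop = FALSE],
                       y[test_idx], class_order)
  sid <- if ("subject_id" %in% colnames(features)) {
    features$subject_id[1]
  } else NA_character_
  list(subject_id = sid, scenario_id = scenario_id,
       weighted_f1 = sc$weighted_f1, weighted_auc = sc$weighted_auc,
       per_class_f1 = sc$per_class_f1, confusion = sc$confusion,
       cv_fold_scores = cv_scores,
       cv_mean_f1 = if (nrow(cv_scores)) mean(cv_scores$weighted_f1) else NA,
       cv_mean_auc = if (nrow(cv_scores)) mean(cv_scores$weighted_auc) else NA,
       n_features = length(pipe$selection$retained),
       detail = list(pipeline = pipe, train_idx = train_idx,
                     test_idx = test_idx))
}

within_spec_seed <- function(spec, seed) {
  spec$seed <- as.integer(seed %% .Machine$integer.max)
  spec
}

# mean of per-subject results (simple mean over subjects)
cohort_mean <- function(results) {
  acts <- sort(unique(unlist(lapply(results, function(r)
    names(r$per_class_f1)))))
  pa <- sapply(acts, function(a) {
    mean(vapply(results, function(r) {
      v <- r$per_class_f1[[a]]
      if (is.null(v)) NA_real_ else v
    }, 0), na.rm = TRUE)
  })
  list(weighted_f1 = mean(vapply(results, `[[`, 0, "weighted_f1")),
       weighted_auc = mean(vapply(results, `[[`, 0, "weighted_auc")),
       per_class_f1 = pa)
}

#' Run subject-specific evaluation over a whole cohort
#'
#' @param features cohort `feature_matrix` with a `subject_id` column.
#' @inheritParams subject_specific_eval
#' @return list with `results` (one [subject_specific_eval()] result per
#'   subject) and `mean` (simple mean of weighted F1/AUC and per-activity
#'   F1 over subjects).
#' @export
subject_specific_cohort_eval <- function(features, scenario_id,
                                         spec = model_spec(), seed = 1L,
                                         threshold = 0.85, cv_folds = 10) {
  features <- features[order(features$subject_id, features$window_id), ,
                       drop = FALSE]
  subjects <- sort(unique(features$subject_id))
  seeds <- derive_seeds(seed, length(subjects))
  results <- lapply(seq_along(subjects), function(i) {
    fm <- features[features$subject_id == subjects[i], , drop = FALSE]
    subject_specific_eval(fm, scenario_id, spec, seeds[i], threshold,
                          cv_folds)
  })
  list(results = results, mean = cohort_mean(results))
}

#' Cross-subject leave-one-subject-out (LOSO) evaluation
#'
#' For each held-out subject, the standardizer, the correlation-based
#' selection and the model are fitted on the remaining subjects' windows
#' only, then scored on the held-out subject's windows.  The cohort
#' summary is the simple (unweighted) mean over subjects.
#'
#' @param features cohort `feature_matrix` with a `subject_id` column
#'   (>= 2 subjects).
#' @param scenario_id early-fusion scenario (1--7).
#' @param spec a [model_spec()].
#' @param seed master seed (per-fold forest seeds derived from it).
#' @param threshold selection threshold.
#' @return list with `results` (one per held-out subject, each carrying
#'   weighted F1/AUC, per-activity F1, confusion matrix and a `detail`
#'   element with the fitted preprocessing and training row indices) and
#'   `mean`.
#' @export
loso_eval <- function(features, scenario_id, spec = model_spec(),
                      seed = 1L, threshold = 0.85) {
  subjects <- sort(unique(features$subject_id))
  if (length(subjects) < 2) stop("LOSO needs at least 2 subjects")
  # canonical row order: results do not depend on how the cohort was stacked
  features <- features[order(features$subject_id, features$window_id), ,
                       drop = FALSE]
  class_order <- sort(unique(features$activity))
  columns <- scenario_columns(scenario_id, feature_cols(features))
  seeds <- derive_seeds(seed, length(subjects))
  results <- lapply(seq_along(subjects), function(i) {
    held <- subjects[i]
    tr <- features$subject_id != held
    train_fm <- features[tr, , drop = FALSE]
    pipe <- fit_pipeline(train_fm, train_fm$activity, columns,
                         within_spec_seed(spec, seeds[i]), threshold)
    sc <- score_pipeline(pipe, features[!tr, , drop = FALSE],
                         features$activity[!tr], class_order)
    list(subject_id = held, scenario_id = scenario_id,
         weighted_f1 = sc$weighted_f1, weighted_auc = sc$weighted_auc,
         per_class_f1 = sc$per_class_f1, confusion = sc$confusion,
         n_features = length(pipe$selection$retained),
         detail = list(pipeline = pipe, train_rows = which(tr)))
  })
  list(results = results, mean = cohort_mean(results))
}

#' Window-size sweep
#'
#' Re-runs the full pipeline (windowing, features, standardisation,
#' selection, LOSO random forest) for every combination of window size and
#' scenario, recording the mean LOSO weighted AUC.
#'
#' @param records list of `subject_record`s (raw; ACC is up-sampled
#'   internally).
#' @param sizes window sizes in seconds, each in `(0, 15]` and long enough
#'   to give >= 8 samples on every channel.
#' @param scenario_ids scenarios to sweep (default 1--3).
#' @param spec a [model_spec()].
#' @param seed master seed.
#' @param threshold selection threshold.
#' @return data frame with columns `window_seconds`, `scenario_id`,
#'   `mean_auc`, `mean_f1`.
#' @export
window_size_sweep <- function(records, sizes, scenario_ids = 1:3,
                              spec = model_spec(), seed = 1L,
                              threshold = 0.85) {
  if (any(sizes <= 0 | sizes > 15)) stop("window sizes must lie in (0, 15]")
  if (any(round(sizes * 64) < 8)) stop("window size gives < 8 samples")
  out <- data.frame()
  for (w in sizes) {
    fm <- cohort_features(records, window_seconds = w)
    for (sc in scenario_ids) {
      res <- loso_eval(fm, sc, spec, seed, threshold)
      out <- rbind(out, data.frame(window_seconds = w, scenario_id = sc,
                                   mean_auc = res$mean$weighted_auc,
                                   mean_f1 = res$mean$weighted_f1))
    }
  }
  out
}
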