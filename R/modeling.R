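# The seven early-fusion scenarios: which signals feed the classifier.
SCENARIO_SIGNALS <- list(
  `1` = "ACC",
  `2` = "ECG",
  `3` = "PPG",
  `4` = c("ACC", "ECG"),
  `5` = c("ACC", "PPG"),
  `6` = c("ECG", "PPG"),
  `7` = c("ACC", "ECG", "PPG")
)

#' Signal set of an early-fusion scenario
#'
#' @param scenario_id integer 1--7.
#' @return character vector drawn from `ACC`, `ECG`, `PPG`.
#' @export
scenario_signals <- function(scenario_id) {
  key <- as.character(scenario_id)
  if (!key %in% names(SCENARIO_SIGNALS)) {
    stop("unknown scenario_id: ", scenario_id)
  }
  SCENARIO_SIGNALS[[key]]
}

#' Feature columns belonging to a scenario
#'
#' Retains exactly the columns whose signal tag belongs to the scenario's
#' signal set; the `ACC` tag matches all three accelerometer axes.
#'
#' @param scenario_id integer 1--7.
#' @param columns feature column names following the
#'   `{signal}.{domain}.{feature}` grammar.
#' @return subset of `columns`, in input order.
#' @export
scenario_columns <- function(scenario_id, columns) {
  sigs <- scenario_signals(scenario_id)
  tags <- vapply(columns, function(cc) parse_feature_column(cc)$signal, "")
  groups <- ifelse(grepl("^ACC", tags), "ACC", tags)
  columns[groups %in% sigs]
}

#' Classifier specification
#'
#' Random forest is the headline model (300 trees, maximum depth 25);
#' k-nearest neighbours and multinomial logistic regression are available
#' behind the same interface for model comparison.  The KNN `k = 5` and
#' the unit ridge penalty of the logistic model are package defaults, not
#' values tied to any reference analysis.
#'
#' @param family `"random_forest"`, `"knn"` or `"multinomial_logistic"`.
#' @param num_trees forest size (random forest).
#' @param max_depth maximum tree depth (random forest).
#' @param k neighbourhood size (KNN).
#' @param decay ridge penalty (multinomial logistic).
#' @param seed integer seed used when growing forests.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("random_forest", "knn",
                                  "multinomial_logistic"),
                       num_trees = 300, max_depth = 25, k = 5, decay = 1,
                       seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, num_trees = num_trees,
                 max_depth = max_depth, k = k, decay = decay,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Train a classifier
#'
#' @param X numeric feature matrix / data frame (standardized features).
#' @param y activity labels (>= 2 distinct classes).
#' @param spec a [model_spec()].
#' @return object of class `har_model` exposing [predict_proba()] and
#'   [predict_labels()]; per-class probability rows sum to 1.
#' @export
train_model <- function(X, y, spec = model_spec()) {
  X <- as.data.frame(X, check.names = FALSE)
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2) stop("need at least 2 classes to train")
  if (nrow(X) < length(classes)) stop("fewer rows than classes")
  if (anyNA(X)) stop("undefined values in feature matrix")
  yf <- factor(as.character(y), levels = classes)
  fit <- switch(
    spec$family,
    random_forest = ranger::ranger(
      x = X, y = yf, num.trees = spec$num_trees, max.depth = spec$max_depth,
      probability = TRUE, importance = "impurity", seed = spec$seed,
      num.threads = 1
    ),
    knn = caret::knn3(as.matrix(X), yf, k = spec$k),
    multinomial_logistic = {
      df <- cbind(.activity = yf, X)
      nnet::multinom(.activity ~ ., data = df, decay = spec$decay,
                     trace = FALSE, maxit = 300, MaxNWts = 20000)
    }
  )
  structure(list(fit = fit, spec = spec, classes = classes,
                 features = colnames(X)),
            class = "har_model")
}

#' Per-class probability predictions
#'
#' @param model a `har_model`.
#' @param X feature matrix with the training columns.
#' @return numeric matrix, one row per input row, one column per class
#'   (training class order); rows sum to 1.
#' @export
predict_proba <- function(model, X) {
  X <- as.data.frame(X, check.names = FALSE)[, model$features, drop = FALSE]
  p <- switch(
    model$spec$family,
    random_forest = predict(model$fit, data = X,
                            num.threads = 1)$predictions,
    knn = predict(model$fit, as.matrix(X), type = "prob"),
    multinomial_logistic = {
      pr <- predict(model$fit, newdata = X, type = "probs")
      if (is.null(dim(pr))) {  # two-class case returns P(second class)
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- model$classes
      }
      pr
    }
  )
  p <- as.matrix(p)[, model$classes, drop = FALSE]
  dimnames(p) <- list(NULL, model$classes)
  p
}

#' Label predictions (argmax of class probabilities)
#'
#' @inheritParams predict_proba
#' @return character vector of predicted activity labels.
#' @export
predict_labels <- function(model, X) {
  p <- predict_proba(model, X)
  model$classes[max.col(p, ties.method = "first")]
}

#' Cross-subject feature importance ranking
#'
#' Mean-decrease-in-impurity (MDI) importance of each feature, normalised
#' per model to sum to 1, averaged across the supplied per-subject
#' (per-fold) forests and ranked in descending order.
#'
#' @param models list of random-forest `har_model`s trained on the same
#'   feature set.
#' @param top_k number of rows in the report (default 20).
#' @return data frame with columns `rank`, `domain`, `signal`, `feature`
#'   (parsed from the column name), `name` and `score`, sorted by
#'   descending mean importance.
#' @export
importance_ranking <- function(models, top_k = 20) {
  stopifnot(length(models) >= 1)
  feats <- models[[1]]$features
  for (m in models) {
    if (m$spec$family != "random_forest") {
      stop("importance ranking requires random forest models")
    }
    if (!identical(m$features, feats)) {
      stop("models were trained on heterogeneous feature sets")
    }
  }
  scores <- vapply(models, function(m) {
    imp <- m$fit$variable.importance[feats]
    imp / sum(imp)
  }, numeric(length(feats)))
  mean_score <- if (is.null(dim(scores))) scores else rowMeans(scores)
  ord <- order(-mean_score, feats)
  sel <- ord[seq_len(min(top_k, length(ord)))]
  parsed <- lapply(feats[sel], parse_feature_column)
  data.frame(
    rank = seq_along(sel),
    domain = vapply(parsed, `[[`, "", "domain"),
    signal = vapply(parsed, `[[`, "", "signal"),
    feature = vapply(parsed, `[[`, "", "feature"),
    name = feats[sel],
    score = mean_score[sel]
  )
}
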