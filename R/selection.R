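#' Fit per-column standardisation parameters on training rows
#'
#' Computes the per-feature mean and *population* standard deviation from
#' the training partition only; test partitions are always transformed
#' with these training parameters, never with their own statistics.
#'
#' @param train a `feature_matrix` (or plain data frame) of training rows
#'   (>= 2 rows).
#' @param columns feature columns to fit (default: all feature columns).
#' @return object of class `standardizer`: list with `mu`, `sigma`
#'   (named numeric vectors) and `degenerate` (names of constant columns,
#'   whose sigma is 0).
#' @export
fit_standardizer <- function(train, columns = feature_cols(train)) {
  if (nrow(train) < 2) stop("need at least 2 training rows")
  X <- as.matrix(train[, columns, drop = FALSE])
  mu <- colMeans(X)
  sigma <- sqrt(colMeans(sweep(X, 2, mu)^2))
  structure(list(mu = mu, sigma = sigma,
                 degenerate = names(sigma)[sigma == 0]),
            class = "standardizer")
}

#' Apply standardisation parameters to a feature matrix
#'
#' `z = (f - mu) / sigma` per column, with training-fitted `mu`, `sigma`.
#' Degenerate columns (training sigma of 0) map to all-zero.
#'
#' @param fm feature matrix whose feature columns include all fitted
#'   columns.
#' @param params a `standardizer` from [fit_standardizer()].
#' @return the matrix with fitted columns standardized (other columns,
#'   e.g. labels, untouched).
#' @export
apply_standardizer <- function(fm, params) {
  cols <- names(params$mu)
  if (!all(cols %in% colnames(fm))) {
    stop("feature matrix lacks columns the standardizer was fitted on")
  }
  for (cc in cols) {
    if (params$sigma[[cc]] == 0) {
      fm[[cc]] <- rep(0, nrow(fm))
    } else {
      fm[[cc]] <- (fm[[cc]] - params$mu[[cc]]) / params$sigma[[cc]]
    }
  }
  fm
}

# |Spearman| of each column against integer-coded labels (alphabetical
# label -> integer map); NA (constant column) counts as 0 relevance.
label_relevance <- function(X, labels) {
  y <- match(labels, sort(unique(labels)))
  rel <- suppressWarnings(abs(cor(X, y, method = "spearman")))[, 1]
  rel[is.na(rel)] <- 0
  rel
}

#' Correlation-based feature selection (Spearman, threshold 0.85)
#'
#' Lists every column pair whose absolute pairwise Spearman rank
#' correlation (average ranks for ties) exceeds the threshold, sorts the
#' pairs by |rho| descending (ties broken lexicographically by column
#' names), and processes them in order: a pair one of whose members was
#' already dropped is skipped; otherwise the member *less* correlated (in
#' absolute Spearman) with the integer-coded activity labels is dropped
#' (relevance ties drop the lexicographically later name).  After the
#' pass, no retained pair exceeds the threshold.  The procedure is
#' deterministic and depends only on the training rows.
#'
#' @param train feature matrix of training rows (>= 3 rows).
#' @param labels activity labels aligned to the rows.
#' @param threshold correlation threshold (default 0.85).
#' @param columns feature columns to consider.
#' @return object of class `selection_result`: list with `retained`
#'   (column names in input order), `dropped`, and `log` (data frame
#'   `kept`, `dropped`, `rho`, `relevance_kept`, `relevance_dropped`).
#' @export
correlation_select <- function(train, labels, threshold = 0.85,
                               columns = feature_cols(train)) {
  if (nrow(train) < 3) stop("need at least 3 training rows")
  if (length(labels) != nrow(train)) {
    stop("labels length does not match number of rows")
  }
  X <- as.matrix(train[, columns, drop = FALSE])
  rho <- suppressWarnings(cor(X, method = "spearman"))
  rho[is.na(rho)] <- 0
  rel <- label_relevance(X, labels)

  ut <- which(upper.tri(rho) & abs(rho) > threshold, arr.ind = TRUE)
  log_rows <- list()
  dropped <- character(0)
  if (nrow(ut) > 0) {
    a <- columns[ut[, 1]]
    b <- columns[ut[, 2]]
    # name pair in lexicographic order for the tie-break key
    lo <- ifelse(a <= b, a, b)
    hi <- ifelse(a <= b, b, a)
    r <- abs(rho[ut])
    ord <- order(-r, lo, hi)
    for (k in ord) {
      if (lo[k] %in% dropped || hi[k] %in% dropped) next
      rl <- rel[[lo[k]]]
      rh <- rel[[hi[k]]]
      if (rl < rh) {
        keep <- hi[k]; drop <- lo[k]
      } else if (rh < rl) {
        keep <- lo[k]; drop <- hi[k]
      } else {
        keep <- lo[k]; drop <- hi[k]  # relevance tie: later name goes
      }
      dropped <- c(dropped, drop)
      log_rows[[length(log_rows) + 1]] <-
        data.frame(kept = keep, dropped = drop, rho = r[k],
                   relevance_kept = rel[[keep]],
                   relevance_dropped = rel[[drop]])
    }
  }
  log_df <- if (length(log_rows) > 0) {
    do.call(rbind, log_rows)
  } else {
    data.frame(kept = character(0), dropped = character(0),
               rho = numeric(0), relevance_kept = numeric(0),
               relevance_dropped = numeric(0))
  }
  structure(list(retained = setdiff(columns, dropped),
                 dropped = dropped, log = log_df, threshold = threshold),
            class = "selection_result")
}
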