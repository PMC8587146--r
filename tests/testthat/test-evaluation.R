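test_that("weighted scores match hand-computed confusion arithmetic", {
  # perfect predictions
  y <- c("a", "a", "b", "b")
  proba <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  s <- weighted_scores(y, y, proba)
  expect_equal(s$weighted_f1, 1)
  expect_equal(s$weighted_auc, 1)
  expect_equal(unname(diag(s$confusion)), c(2, 2))

  # y_pred (a,b,b,b): per-class F1 2/3 and 4/5, supports equal
  y_pred <- c("a", "b", "b", "b")
  proba2 <- cbind(a = c(0.9, 0.4, 0.2, 0.1), b = c(0.1, 0.6, 0.8, 0.9))
  s2 <- weighted_scores(y, y_pred, proba2)
  expect_equal(unname(s2$per_class_f1), c(2 / 3, 4 / 5))
  expect_equal(s2$weighted_f1, 0.5 * 2 / 3 + 0.5 * 4 / 5)  # 0.7333...
  expect_equal(unname(s2$confusion["a", ]), c(1, 1))
  expect_equal(sum(s2$confusion), 4)
  expect_equal(unname(rowSums(s2$confusion)), unname(s2$support))
})

test_that("per-class AUC agrees with a rank-based oracle", {
  set.seed(42)
  n <- 400
  y <- sample(c("a", "b", "c"), n, replace = TRUE)
  proba <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  proba <- proba / rowSums(proba)
  pred <- colnames(proba)[max.col(proba)]
  s <- weighted_scores(y, pred, proba)
  for (cls in c("a", "b", "c")) {
    expect_equal(s$per_class_auc[[cls]],
                 oracle_auc(as.integer(y == cls), proba[, cls]),
                 tolerance = 1e-12)
  }
})

test_that("random probabilities give chance-level weighted AUC", {
  set.seed(7)
  n <- 10000
  y <- rep(c("a", "b"), n / 2)
  p_a <- runif(n)
  proba <- cbind(a = p_a, b = 1 - p_a)
  pred <- ifelse(p_a > 0.5, "a", "b")
  s <- weighted_scores(y, pred, proba)
  expect_lt(abs(s$weighted_auc - 0.5), 0.02)
})

test_that("a class absent from y_true is excluded from AUC with a warning", {
  y <- c("a", "a", "b", "b")
  proba <- cbind(a = c(0.8, 0.7, 0.2, 0.1), b = c(0.15, 0.2, 0.7, 0.8),
                 c = c(0.05, 0.1, 0.1, 0.1))
  expect_warning(
    s <- weighted_scores(y, c("a", "a", "b", "b"), proba,
                         class_order = c("a", "b", "c")),
    "AUC undefined.*c")
  expect_equal(s$weighted_auc, 1)
})

test_that("subject-specific evaluation stratifies and reports CV plus test", {
  fm <- small_cohort_features()
  one <- fm[fm$subject_id == fm$subject_id[1], ]
  res <- suppressWarnings(subject_specific_eval(one, 1, seed = 13))
  y <- one$activity
  # stratification: test takes ~20% of each class, within one window
  test_y <- y[res$detail$test_idx]
  for (cls in unique(y)) {
    expect_lte(abs(sum(test_y == cls) - 0.2 * sum(y == cls)), 1)
  }
  expect_true(res$weighted_f1 >= 0 && res$weighted_f1 <= 1)
  expect_true(res$weighted_auc >= 0 && res$weighted_auc <= 1)
  expect_gt(nrow(res$cv_fold_scores), 1)
  # well-separated synthetic data: CV mean and test score agree closely
  # (over-fitting guard)
  expect_lt(abs(res$cv_mean_f1 - res$weighted_f1), 0.1)
  # per-activity F1 recomputed from the confusion matrix matches
  conf <- res$confusion
  for (cls in rownames(conf)) {
    tp <- conf[cls, cls]
    f1 <- if (2 * tp + sum(conf[, cls]) - tp + sum(conf[cls, ]) - tp == 0) 0
          else 2 * tp / (sum(conf[, cls]) + sum(conf[cls, ]))
    expect_equal(unname(res$per_class_f1[cls]), f1)
  }
  expect_equal(sum(conf), length(res$detail$test_idx))
  # a class with < 2 windows errors by name
  bad <- one[c(which(y == "sitting")[1], which(y != "sitting")), ]
  expect_error(suppressWarnings(subject_specific_eval(bad, 1)), "sitting")
})

test_that("LOSO fits every statistic on the training subjects only", {
  fm <- small_cohort_features()
  res <- small_loso(1)
  expect_length(res$results, length(unique(fm$subject_id)))
  for (r in res$results) {
    tr_rows <- r$detail$train_rows
    expect_false(any(fm$subject_id[tr_rows] == r$subject_id))
    # standardizer provably refit-able from training rows alone
    cols <- names(r$detail$pipeline$standardizer$mu)
    refit <- fit_standardizer(fm[tr_rows, ], cols)
    expect_identical(refit$mu, r$detail$pipeline$standardizer$mu)
    expect_identical(refit$sigma, r$detail$pipeline$standardizer$sigma)
    # confusion totals equal held-out window count
    expect_equal(sum(r$confusion), sum(fm$subject_id == r$subject_id))
  }
  expect_error(loso_eval(fm[fm$subject_id == "S01", ], 1), "2 subjects")
})

test_that("cohort-level LOSO results are invariant to subject ordering", {
  fm <- small_cohort_features()
  res <- small_loso(1)
  perm <- sample(nrow(fm))
  res2 <- loso_eval(fm[perm, ], 1, seed = 99)
  expect_equal(res2$mean$weighted_f1, res$mean$weighted_f1)
  expect_equal(res2$mean$weighted_auc, res$mean$weighted_auc)
})

test_that("window-size sweep favours long windows for cardiac signals", {
  coh <- simulate_cohort(3, default_protocol(46), seed = 88)
  sw <- window_size_sweep(coh, sizes = c(1, 15), scenario_ids = 2,
                          seed = 5)
  expect_equal(nrow(sw), 2)
  expect_setequal(sw$window_seconds, c(1, 15))
  auc1 <- sw$mean_auc[sw$window_seconds == 1]
  auc15 <- sw$mean_auc[sw$window_seconds == 15]
  # heart rate needs multi-beat windows: long windows at least as good
  expect_gte(auc15, auc1)
  # deterministic under the master seed
  sw2 <- window_size_sweep(coh, sizes = c(1, 15), scenario_ids = 2,
                           seed = 5)
  expect_identical(sw, sw2)
  expect_error(window_size_sweep(coh, sizes = 16), "0, 15")
  expect_error(window_size_sweep(coh, sizes = 0.05), "8 samples")
})
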