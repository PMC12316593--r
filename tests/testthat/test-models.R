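test_that("forest training contracts: constant target, determinism, errors", {
  X <- toy_features(120L, seed = 1L)
  fn <- paste0("f", 1:6)
  m <- train_forest(X, rep(100, 120), n_trees = 20L, seed = 1L,
                    feature_names = fn) |>
    suppressWarnings()
  expect_equal(predict(m, X), rep(100, 120))
  expect_warning(train_forest(X, rep(100, 120), n_trees = 5L,
                              feature_names = fn),
                 class = "bp_degenerate")
  m1 <- train_forest(X, X$gold_sys, n_trees = 30L, seed = 7L,
                     feature_names = fn)
  m2 <- train_forest(X, X$gold_sys, n_trees = 30L, seed = 7L,
                     feature_names = fn)
  expect_identical(predict(m1, X), predict(m2, X))
  expect_error(train_forest(X[0, ], numeric(0)), class = "bp_invalid")
  expect_error(train_forest(X, c(NA, X$gold_sys[-1])), class = "bp_invalid")
  # missing features are imputed by training medians, not rejected
  X2 <- X
  X2$f1[3] <- NA
  expect_length(predict(m1, X2), 120L)
})

test_that("a linear driver dominates OOB importance", {
  ok <- 0L
  for (sd in 1:3) {
    X <- toy_features(600L, seed = sd)
    y <- 100 + 8 * X$f1
    m <- train_forest(X, y, n_trees = 40L, seed = sd,
                      feature_names = paste0("f", 1:6), importance = TRUE)
    if (names(which.max(m$oob_importance)) == "f1") ok <- ok + 1L
  }
  expect_gte(ok, 3L)
})

test_that("subject bank trains per subject and skips small ones", {
  X <- toy_features(130L, subjects = 3L, seed = 2L)
  X$subject_id[X$subject_id == "S03"][-(1:5)] <- "S01"  # S03 keeps 5 rows
  expect_warning(
    bank <- train_subject_bank(X, X$gold_sys, n_trees = 10L,
                               feature_names = paste0("f", 1:6)),
    class = "bp_small_subject")
  expect_true(all(names(bank) %in% c("S01", "S02")))
  # constant-pressure subject predicts the constant
  Xc <- toy_features(40L, seed = 3L)
  bc <- suppressWarnings(train_subject_bank(Xc, rep(90, 40), n_trees = 10L,
                                            feature_names = paste0("f", 1:6)))
  expect_equal(predict_bp(bc, Xc, mode = "subject"), rep(90, 40))
})

test_that("augmented pooling is the per-tree mean identity", {
  X <- toy_features(80L, seed = 4L)
  fn <- paste0("f", 1:6)
  # constant targets make each forest predict an exact constant
  gen <- suppressWarnings(train_forest(X, rep(110, 80), n_trees = 400L,
                                       seed = 1L, feature_names = fn))
  sub <- suppressWarnings(train_forest(X, rep(90, 80), n_trees = 100L,
                                       seed = 1L, feature_names = fn))
  bank <- structure(list(S01 = sub), class = "subject_bank")
  aug <- augmented_predictor(gen, bank)
  p <- predict_bp(aug, X, mode = "augmented")
  expect_equal(p, rep((400 * 110 + 100 * 90) / 500, 80))
  # a = b -> augmented = a
  bank2 <- structure(list(S01 = gen), class = "subject_bank")
  p2 <- predict_bp(augmented_predictor(gen, bank2), X, mode = "augmented")
  expect_equal(p2, rep(110, 80))
  # equal weighting halves instead
  p3 <- predict_bp(augmented_predictor(gen, bank, weighting = "equal"),
                   X, mode = "augmented")
  expect_equal(p3, rep(100, 80))
  # augmented prediction lies between the two model means in general
  genr <- train_forest(X, X$gold_sys, n_trees = 50L, seed = 2L,
                       feature_names = fn)
  subr <- train_forest(X, X$gold_sys + 5, n_trees = 25L, seed = 3L,
                       feature_names = fn)
  pa <- predict_bp(augmented_predictor(
    genr, structure(list(S01 = subr), class = "subject_bank")),
    X, mode = "augmented")
  pg <- predict(genr, X); ps <- predict(subr, X)
  expect_true(all(pa >= pmin(pg, ps) - 1e-9 & pa <= pmax(pg, ps) + 1e-9))
})

test_that("unknown subjects error in subject mode, fall back in augmented", {
  X <- toy_features(60L, seed = 5L)
  fn <- paste0("f", 1:6)
  gen <- train_forest(X, X$gold_sys, n_trees = 20L, seed = 1L,
                      feature_names = fn)
  bank <- structure(list(OTHER = gen), class = "subject_bank")
  expect_error(predict_bp(bank, X, mode = "subject"),
               class = "bp_unknown_subject")
  expect_warning(p <- predict_bp(augmented_predictor(gen, bank), X,
                                 mode = "augmented"),
                 class = "bp_unknown_subject")
  expect_equal(p, predict(gen, X))
})

test_that("sliding exclusions drop the 4 windows either side of the test", {
  feats <- data.frame(subject_id = "S01", run = 1L, win_index = 1:20)
  ex <- sliding_exclusions(feats, test_rows = 10L, buffer = 4L)
  expect_equal(ex, c(6:9, 11:14))  # 8 windows besides the test one
  # exhaustive audit on a 200-window toy set with a scattered test set
  feats2 <- data.frame(subject_id = rep(c("A", "B"), each = 100),
                       run = rep(c(1L, 2L), times = 100),
                       win_index = rep(1:50, 4))
  test <- c(7L, 60L, 133L, 180L)
  ex2 <- sliding_exclusions(feats2, test, buffer = 4L)
  key <- paste(feats2$subject_id, feats2$run)
  for (i in setdiff(seq_len(200L), c(ex2, test))) {
    same <- test[key[test] == key[i]]
    if (length(same))
      expect_true(all(abs(feats2$win_index[i] -
                            feats2$win_index[same]) > 4L))
  }
  for (i in ex2) {
    same <- test[key[test] == key[i]]
    expect_true(any(abs(feats2$win_index[i] -
                          feats2$win_index[same]) <= 4L))
  }
})

test_that("cv plans partition the data; sliding mode audits beat overlap", {
  X <- toy_features(200L, subjects = 4L, seed = 6L)
  plan <- make_cv_plan(X, k = 5L, seed = 1L)
  expect_setequal(unique(plan$fold), 1:5)
  expect_equal(length(plan$fold), 200L)
  expect_true(all(lengths(plan$excluded) == 0L))  # non-overlapping: none
  plan_s <- make_cv_plan(X, k = 5L, mode = "sliding", seed = 1L)
  for (f in 1:5) {
    test <- which(plan_s$fold == f)
    train <- setdiff(seq_len(200L), c(test, plan_s$excluded[[f]]))
    key <- paste(X$subject_id, X$run)
    for (i in sample(train, min(30L, length(train)))) {
      same <- test[key[test] == key[i]]
      if (length(same))
        expect_true(all(abs(X$win_index[i] - X$win_index[same]) > 4L))
    }
  }
})

test_that("cross-validation fills out-of-fold predictions for all modes", {
  X <- toy_features(250L, subjects = 2L, seed = 8L)
  plan <- make_cv_plan(X, k = 5L, seed = 2L)
  cv <- cross_validate(X, "systolic", plan, n_trees = 30L,
                       subject_trees = 15L, seed = 3L,
                       feature_names = paste0("f", 1:6))
  expect_true(all(!is.na(cv$predictions[, "general"])))
  expect_true(all(!is.na(cv$predictions[, "subject"])))
  expect_true(all(!is.na(cv$predictions[, "augmented"])))
  # f1 drives systolic strongly: CV must clearly beat predict-the-mean
  base <- mean(abs(X$gold_sys - mean(X$gold_sys)))
  expect_lt(cv$reports$general$mae, base)
  # augmented is a convex combination row-wise
  expect_true(all(
    cv$predictions[, "augmented"] >=
      pmin(cv$predictions[, "general"], cv$predictions[, "subject"]) - 1e-9 &
    cv$predictions[, "augmented"] <=
      pmax(cv$predictions[, "general"], cv$predictions[, "subject"]) + 1e-9))
  expect_error(cross_validate(X[1:10, ], "systolic", plan),
               class = "bp_invalid")
})
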