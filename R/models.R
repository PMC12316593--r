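#' Train a random-forest pressure regressor
#'
#' Bootstrap-aggregated regression trees: candidate features per split
#' `ceiling(p/3)`, minimum leaf size 5, no depth cap, prediction = mean of
#' per-tree predictions. Missing feature values are imputed with training-set
#' medians (stored in the model and reused at prediction time). Out-of-bag
#' permutation importance measures how much each tree's OOB squared error
#' grows when one feature's values are permuted among the OOB rows.
#'
#' @param features Data frame or matrix of predictors (named columns).
#' @param targets Numeric pressures in mmHg (no missing values).
#' @param n_trees Number of trees (400 for the general model by default).
#' @param seed RNG seed.
#' @param feature_names Columns to use (defaults to the default 34-feature
#'   selection intersected with the available columns).
#' @param min_leaf Minimum leaf size.
#' @param importance Compute OOB permutation importance (slower).
#' @return A `forest_model`.
#' @export
train_forest <- function(features, targets, n_trees = 400L, seed = 1L,
                         feature_names = NULL, min_leaf = 5L,
                         importance = FALSE) {
  if (NROW(features) == 0L) .bp_stop("bp_invalid", "empty training input")
  if (anyNA(targets)) .bp_stop("bp_invalid", "missing targets not allowed")
  if (NROW(features) != length(targets))
    .bp_stop("bp_invalid", "features/targets length mismatch")
  features <- as.data.frame(features)
  if (is.null(feature_names))
    feature_names <- intersect(select_features()$selected, colnames(features))
  X <- as.matrix(features[, feature_names, drop = FALSE])
  medians <- apply(X, 2L, median, na.rm = TRUE)
  medians[!is.finite(medians)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- medians[j]
  if (var(targets) == 0)
    .bp_warn("bp_degenerate", "constant target: degenerate model")
  mtry <- max(1L, ceiling(length(feature_names) / 3))
  fit <- .with_seed(seed,
    .cpp_forest_fit(X, targets, as.integer(n_trees), mtry,
                    as.integer(min_leaf), isTRUE(importance)))
  imp <- setNames(as.numeric(fit$importance), feature_names)
  structure(list(trees = fit$trees, feature_names = feature_names,
                 medians = medians,
                 oob_prediction = as.numeric(fit$oob_prediction),
                 oob_importance = if (importance) imp else NULL,
                 n_trees = as.integer(n_trees), seed = seed),
            class = "forest_model")
}

.forest_matrix <- function(model, features) {
  features <- as.data.frame(features)
  miss <- setdiff(model$feature_names, colnames(features))
  if (length(miss))
    .bp_stop("bp_schema", "missing feature columns: %s",
             paste(miss, collapse = ", "))
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  for (j in seq_len(ncol(X)))
    X[is.na(X[, j]), j] <- model$medians[j]
  X
}

#' @export
predict.forest_model <- function(object, features, ...) {
  as.numeric(.cpp_forest_predict(object$trees,
                                 .forest_matrix(object, features)))
}

#' Train one forest per subject (subject-specific bank)
#'
#' Subjects with fewer than `min_rows` training sequences are skipped with a
#' warning — too little data to span their pressure range.
#'
#' @param features Feature data frame including a `subject_id` column.
#' @param targets Numeric pressures aligned with `features`.
#' @param n_trees Trees per subject model (100 by default).
#' @param seed RNG seed (split per subject).
#' @param min_rows Minimum sequences per included subject.
#' @param feature_names Passed to [train_forest()].
#' @return A named list of `forest_model`s (class `subject_bank`).
#' @export
train_subject_bank <- function(features, targets, n_trees = 100L, seed = 1L,
                               min_rows = 20L, feature_names = NULL) {
  stopifnot("subject_id" %in% colnames(features))
  ids <- unique(features$subject_id)
  bank <- list()
  for (i in seq_along(ids)) {
    rows <- which(features$subject_id == ids[i])
    if (length(rows) < min_rows) {
      .bp_warn("bp_small_subject",
               "subject %s has %d sequences (< %d); skipped",
               ids[i], length(rows), min_rows)
      next
    }
    bank[[as.character(ids[i])]] <- train_forest(
      features[rows, , drop = FALSE], targets[rows], n_trees = n_trees,
      seed = .subject_seed(seed, i), feature_names = feature_names)
  }
  structure(bank, class = "subject_bank")
}

#' Combine a general model and a subject bank into an augmented predictor
#'
#' The augmented estimate pools the per-tree predictions of both forests —
#' equivalently a weighted mean of the two model means with weights
#' proportional to their tree counts (400:100 by default), so it always lies
#' between the general and subject estimates. Subjects absent from the bank
#' fall back to the general model.
#'
#' @param general The general `forest_model`.
#' @param bank A `subject_bank`.
#' @param weighting `"per_tree"` (weights = tree counts) or `"equal"`
#'   (both models weighted 1/2).
#' @return An `augmented_predictor`.
#' @export
augmented_predictor <- function(general, bank, weighting = c("per_tree",
                                                             "equal")) {
  structure(list(general = general, bank = bank,
                 weighting = match.arg(weighting)),
            class = "augmented_predictor")
}

#' Predict blood pressure with a general, subject or augmented model
#'
#' @param model A `forest_model` (general mode), `subject_bank` (subject
#'   mode) or `augmented_predictor` (augmented mode).
#' @param features Feature data frame (schema must cover the training
#'   features; `subject_id` column used in subject/augmented modes).
#' @param subject_id Optional vector overriding `features$subject_id`.
#' @param mode `"general"`, `"subject"` or `"augmented"`.
#' @return Numeric mmHg estimates.
#' @export
predict_bp <- function(model, features,
                       subject_id = NULL,
                       mode = c("general", "subject", "augmented")) {
  mode <- match.arg(mode)
  if (mode == "general") {
    stopifnot(inherits(model, "forest_model"))
    return(predict(model, features))
  }
  if (is.null(subject_id)) subject_id <- features$subject_id
  subject_id <- as.character(subject_id)
  if (length(subject_id) == 1L) subject_id <- rep(subject_id, NROW(features))
  if (mode == "subject") {
    stopifnot(inherits(model, "subject_bank"))
    out <- rep(NA_real_, NROW(features))
    for (id in unique(subject_id)) {
      if (is.null(model[[id]]))
        .bp_stop("bp_unknown_subject", "no subject model for %s", id)
      rows <- which(subject_id == id)
      out[rows] <- predict(model[[id]], features[rows, , drop = FALSE])
    }
    return(out)
  }
  stopifnot(inherits(model, "augmented_predictor"))
  gen <- predict(model$general, features)
  out <- gen
  for (id in unique(subject_id)) {
    rows <- which(subject_id == id)
    sm <- model$bank[[id]]
    if (is.null(sm)) {
      .bp_warn("bp_unknown_subject",
               "subject %s not in bank; falling back to the general model", id)
      next
    }
    sub <- predict(sm, features[rows, , drop = FALSE])
    if (model$weighting == "per_tree") {
      ng <- model$general$n_trees; ns <- sm$n_trees
      out[rows] <- (ng * gen[rows] + ns * sub) / (ng + ns)
    } else out[rows] <- (gen[rows] + sub) / 2
  }
  out
}

#' Build a 5-fold cross-validation plan
#'
#' Non-overlapping mode assigns sequences to folds at random, stratified
#' within subject over 5 gold-systolic quantile bins so every subject's
#' pressure range appears in each training split. Sliding mode additionally
#' records, per test fold, the training rows excluded because their window
#' index lies within `buffer` (4) windows of any test window in the same
#' contiguous run of the same subject — those windows share beats with the
#' test data.
#'
#' @param features Feature data frame with `subject_id`, `gold_sys` and (for
#'   sliding mode) `run` and `win_index` columns.
#' @param k Number of folds.
#' @param mode `"non_overlapping"` or `"sliding"`.
#' @param buffer Exclusion buffer in windows (sliding mode).
#' @param seed RNG seed.
#' @return A `cv_plan`: `fold` assignment per row, `mode`, `buffer`, and
#'   `excluded` (list over folds of row indices dropped from training).
#' @export
make_cv_plan <- function(features, k = 5L,
                         mode = c("non_overlapping", "sliding"),
                         buffer = 4L, seed = 1L) {
  mode <- match.arg(mode)
  n <- nrow(features)
  fold <- integer(n)
  .with_seed(seed, {
    for (id in unique(features$subject_id)) {
      rows <- which(features$subject_id == id)
      # stratify by gold systolic quantile bins within the subject
      q <- quantile(features$gold_sys[rows], probs = seq(0, 1, length.out = 6L))
      bin <- cut(features$gold_sys[rows], unique(q), include.lowest = TRUE,
                 labels = FALSE)
      for (b in unique(bin)) {
        br <- rows[bin == b]
        fold[br] <- sample(rep_len(seq_len(k), length(br)))
      }
    }
  })
  excluded <- vector("list", k)
  if (mode == "sliding")
    for (f in seq_len(k))
      excluded[[f]] <- sliding_exclusions(features, which(fold == f), buffer)
  structure(list(fold = fold, k = k, mode = mode, buffer = buffer,
                 excluded = excluded), class = "cv_plan")
}

#' Training rows excluded by the sliding-window overlap rule
#'
#' For a given test set, returns the indices of all rows (other than the
#' test rows themselves) whose window index lies within `buffer` windows of
#' any test window in the same contiguous run of the same subject — those
#' windows share beats with the test data and must not be trained on.
#'
#' @param features Data frame with `subject_id`, `run`, `win_index`.
#' @param test_rows Row indices of the test set.
#' @param buffer Buffer size in windows (4: a 5-beat window overlaps up to 4
#'   neighbours on each side).
#' @return Integer row indices to drop from training.
#' @export
sliding_exclusions <- function(features, test_rows, buffer = 4L) {
  n <- nrow(features)
  key <- paste(features$subject_id, features$run)
  drop <- logical(n)
  for (ky in unique(key[test_rows])) {
    rows_k <- which(key == ky)
    wt <- features$win_index[intersect(test_rows, rows_k)]
    if (!length(wt)) next
    near <- vapply(features$win_index[rows_k],
                   function(w) any(abs(w - wt) <= buffer), logical(1L))
    drop[rows_k[near]] <- TRUE
  }
  setdiff(which(drop), test_rows)
}

#' Cross-validated pressure estimation
#'
#' Runs k-fold cross-validation for the requested model modes. In sliding
#' mode, training rows inside the overlap buffer of any test window are
#' excluded. The subject bank is retrained inside every fold on training
#' rows only.
#'
#' @param features Feature data frame (`subject_id`, `gold_sys`, `gold_dia`,
#'   feature columns).
#' @param target `"systolic"` or `"diastolic"`.
#' @param plan A `cv_plan` from [make_cv_plan()].
#' @param modes Subset of `c("general", "subject", "augmented")`.
#' @param n_trees,subject_trees Tree counts for the general and subject
#'   models.
#' @param seed RNG seed.
#' @param feature_names Passed to [train_forest()].
#' @param min_rows Minimum per-subject training rows for the bank.
#' @return A `cv_result`: out-of-fold `predictions` (one column per mode),
#'   `truth`, `fold`, and per-mode [agreement_report()]s.
#' @export
cross_validate <- function(features, target = c("systolic", "diastolic"),
                           plan, modes = c("general", "subject", "augmented"),
                           n_trees = 400L, subject_trees = 100L, seed = 1L,
                           feature_names = NULL, min_rows = 20L) {
  target <- match.arg(target)
  y <- if (target == "systolic") features$gold_sys else features$gold_dia
  n <- nrow(features)
  if (n < 5L * plan$k) .bp_stop("bp_invalid", "need at least 5 rows per fold")
  preds <- matrix(NA_real_, n, length(modes),
                  dimnames = list(NULL, modes))
  need_bank <- any(modes %in% c("subject", "augmented"))
  for (f in seq_len(plan$k)) {
    test <- which(plan$fold == f)
    train <- setdiff(seq_len(n), c(test, plan$excluded[[f]]))
    gen <- train_forest(features[train, , drop = FALSE], y[train],
                        n_trees = n_trees, seed = .subject_seed(seed, f),
                        feature_names = feature_names)
    if ("general" %in% modes)
      preds[test, "general"] <- predict(gen, features[test, , drop = FALSE])
    if (need_bank) {
      bank <- suppressWarnings(train_subject_bank(
        features[train, , drop = FALSE], y[train], n_trees = subject_trees,
        seed = .subject_seed(seed, 100L + f), min_rows = min_rows,
        feature_names = feature_names))
      if ("subject" %in% modes) {
        for (id in unique(features$subject_id[test])) {
          rows <- intersect(test, which(features$subject_id == id))
          if (!is.null(bank[[id]]))
            preds[rows, "subject"] <-
              predict(bank[[id]], features[rows, , drop = FALSE])
        }
      }
      if ("augmented" %in% modes) {
        aug <- augmented_predictor(gen, bank)
        preds[test, "augmented"] <- suppressWarnings(
          predict_bp(aug, features[test, , drop = FALSE], mode = "augmented"))
      }
    }
  }
  reports <- lapply(setNames(nm = modes), function(m) {
    ok <- !is.na(preds[, m])
    if (!any(ok)) return(NULL)
    agreement_report(preds[ok, m], y[ok])
  })
  structure(list(predictions = preds, truth = y, fold = plan$fold,
                 target = target, reports = reports), class = "cv_result")
}
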