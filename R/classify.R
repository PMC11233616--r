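#' Encode a cohort feature table into a numeric design matrix
#'
#' Numeric morphological columns pass through; `sex` maps to 0 (female) /
#' 1 (male); `location` expands to a one-hot block over the six Circle of
#' Willis codes.  Encoded width is fixed at 35 + 1 (age) + 1 (sex) +
#' 6 (location) = 43 columns.
#'
#' @param table a 39-column feature table (see [read_feature_table()]).
#' @return List with `features` (n x 43 numeric matrix), `label` (integer
#'   0/1 vector or NULL), `feature_names`.
#' @export
encode_features <- function(table) {
  cols <- setdiff(feature_table_columns(), "ruptured")
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(table$sex), c("female", "male"))
  if (length(bad))
    stop("encoding error: unknown sex category: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(table$location), aneurysm_locations())
  if (length(bad))
    stop("encoding error: unknown location category: ",
         paste(bad, collapse = ", "))
  num <- setdiff(cols, c("sex", "location"))
  x <- as.matrix(table[, num])
  storage.mode(x) <- "double"
  sex <- as.numeric(table$sex == "male")
  loc <- vapply(aneurysm_locations(), function(l)
    as.numeric(table$location == l), numeric(nrow(table)))
  colnames(loc) <- paste0("location_", sub("/", "", aneurysm_locations()))
  out <- cbind(x, sex = sex, loc)
  list(features = out,
       label = if ("ruptured" %in% names(table))
         as.integer(table$ruptured) else NULL,
       feature_names = colnames(out))
}

#' Standardize features (z-score) using a fitted subset
#'
#' Column means and standard deviations are estimated on `fit_rows` only,
#' so held-out rows never leak into the transform.  Zero-variance columns
#' map to all-zeros.
#'
#' @param x numeric matrix.
#' @param fit_rows row indices used to estimate the statistics.
#' @return List with `x` (standardized matrix), `center`, `scale` (the
#'   transform record; `scale` is 0 for constant columns).
#' @export
standardize_features <- function(x, fit_rows = seq_len(nrow(x))) {
  if (length(fit_rows) == 0L) stop("validation error: fit_rows is empty")
  center <- colMeans(x[fit_rows, , drop = FALSE])
  scale <- apply(x[fit_rows, , drop = FALSE], 2, stats::sd)
  scale[!is.finite(scale)] <- 0
  list(x = apply_standardization(x, center, scale),
       center = center, scale = scale)
}

#' @rdname standardize_features
#' @param center,scale transform record from a previous fit.
#' @export
apply_standardization <- function(x, center, scale) {
  xs <- sweep(x, 2, center)
  nz <- scale > 0
  xs[, nz] <- sweep(xs[, nz, drop = FALSE], 2, scale[nz], "/")
  xs[, !nz] <- 0
  xs
}

#' @rdname standardize_features
#' @param xs standardized matrix to map back to the original scale.
#' @export
invert_standardization <- function(xs, center, scale) {
  x <- xs
  nz <- scale > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, scale[nz], "*")
  x[, !nz] <- 0
  sweep(x, 2, center, "+")
}

# stratified fold assignment using the current RNG stream
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values to produce
#' the (FPR, TPR) sequence from (0, 0) to (1, 1) and integrates it by the
#' trapezoidal rule.  The result equals the Mann-Whitney concordance
#' probability (ties counted 1/2).
#'
#' @param scores numeric scores, higher = more likely ruptured.
#' @param labels 0/1 labels, 1 = ruptured.
#' @return List with `roc_points` (data.frame `FPR`, `TPR`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("metric error: ROC needs both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)  # last row of each tie group
  tpr <- c(0, cumsum(y)[last] / sum(y))
  fpr <- c(0, cumsum(1 - y)[last] / sum(1 - y))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc_points = data.frame(FPR = fpr, TPR = tpr), auc = auc)
}

#' Classification metrics for the ruptured class
#'
#' Accuracy, precision and recall with ruptured (1) as the positive class.
#' When no positive predictions exist, precision is reported as 0 with a
#' warning flag rather than NaN.
#'
#' @param truth 0/1 true labels.
#' @param predicted 0/1 predicted labels.
#' @return List `accuracy`, `precision`, `recall`, `precision_warning`.
#' @export
evaluate_predictions <- function(truth, predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  tp <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == 0L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  prec_warn <- (tp + fp) == 0L
  list(accuracy = mean(truth == predicted),
       precision = if (prec_warn) 0 else tp / (tp + fp),
       recall = if (tp + fn == 0L) 0 else tp / (tp + fn),
       precision_warning = prec_warn)
}

## ---- model family wrappers -------------------------------------------------

#' Default hyperparameter grids
#'
#' The search grids used by [train_models()]: SVM kernel x cost, KNN
#' neighbourhood sizes, random-forest mtry, gradient-boosting depth x
#' rounds, and MLP hidden architectures.
#'
#' @return Named list of data.frames, one per model family.
#' @export
default_grids <- function() {
  list(
    svm = expand.grid(kernel = c("linear", "radial"), cost = c(0.1, 1, 10),
                      stringsAsFactors = FALSE),
    knn = data.frame(k = c(3L, 5L, 7L, 9L, 11L, 13L, 15L)),
    rf = data.frame(mtry_frac = c(0.15, 0.33), ntree = 300L),
    xgb = expand.grid(max_depth = c(2L, 4L), nrounds = c(60L, 200L),
                      eta = 0.1),
    mlp = data.frame(arch = c("16-8-4", "32-16-8"), lr = 0.05,
                     stringsAsFactors = FALSE))
}

fit_family <- function(family, x, y, params, seed) {
  set.seed(seed)
  yf <- factor(y, levels = c(0L, 1L))
  switch(family,
    svm = e1071::svm(x, yf, kernel = params$kernel, cost = params$cost,
                     scale = FALSE),
    knn = structure(list(x = x, y = yf, k = params$k), class = "knn_model"),
    rf = randomForest::randomForest(
      x, yf, ntree = params$ntree,
      mtry = max(1L, floor(params$mtry_frac * ncol(x)))),
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = params$nrounds, verbose = 0),
    mlp = fit_linear_mlp(x, y,
                         hidden = as.integer(strsplit(params$arch, "-")[[1]]),
                         lr = params$lr, seed = seed),
    stop("importance error: unknown model family: ", family))
}

# score oriented so larger = more likely ruptured
predict_scores <- function(family, fit, x, seed = 1L) {
  switch(family,
    svm = {
      pr <- stats::predict(fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      if (colnames(dv)[1] == "0/1") -dv[, 1] else dv[, 1]
    },
    knn = {
      set.seed(seed)
      pr <- class::knn(fit$x, x, fit$y, k = fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    rf = stats::predict(fit, x, type = "prob")[, "1"],
    xgb = stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1L)),
    mlp = stats::predict(fit, x))
}

predict_class <- function(family, fit, x, seed = 1L) {
  if (family == "svm") {
    as.integer(as.character(stats::predict(fit, x)))
  } else if (family == "knn") {
    set.seed(seed)
    as.integer(as.character(class::knn(fit$x, x, fit$y, k = fit$k)))
  } else if (family == "rf") {
    as.integer(as.character(stats::predict(fit, x)))
  } else {
    as.integer(predict_scores(family, fit, x) >= 0.5)
  }
}

## ---- feature importance ----------------------------------------------------

#' Signed feature importance of a fitted model
#'
#' SVM with a linear kernel reports its signed hyperplane coefficients;
#' the identity-activation MLP reports its connection-weight products
#' (signed by construction); random forest and gradient boosting report
#' their native split-gain importances; every other case (nonlinear SVM,
#' KNN) falls back to seeded permutation importance on the supplied data.
#' All importances refer to standardized features and are ordered by
#' decreasing absolute weight.
#'
#' @param family model family string.
#' @param fit fitted model from [train_models()] internals.
#' @param x standardized feature matrix (used by permutation fallback).
#' @param y 0/1 labels (permutation fallback).
#' @param seed integer seed for permutations.
#' @return data.frame with `feature` and signed `weight`, ordered by
#'   `abs(weight)` descending.
#' @export
feature_importance <- function(family, fit, x, y, seed = 1L) {
  fn <- colnames(x)
  w <- switch(family,
    svm = {
      if (fit$kernel == 0L) {  # linear
        v <- crossprod(fit$coefs, fit$SV)[1, ]
        # e1071 codes the first label it encountered as +1; orient so
        # positive weight means higher rupture risk
        if (fit$labels[1] != 2L) v <- -v
        v[fn]
      } else {
        permutation_importance(family, fit, x, y, seed)
      }
    },
    mlp = mlp_coefficients(fit)[fn],
    rf = {
      v <- fit$importance[, "MeanDecreaseGini"]
      v[fn]
    },
    xgb = {
      imp <- xgboost::xgb.importance(model = fit)
      v <- stats::setNames(rep(0, length(fn)), fn)
      v[imp$Feature] <- imp$Gain
      v
    },
    knn = permutation_importance(family, fit, x, y, seed),
    stop("importance error: unsupported model family: ", family))
  names(w) <- fn
  out <- data.frame(feature = fn, weight = unname(w),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$weight)), , drop = FALSE]
}

permutation_importance <- function(family, fit, x, y, seed, n_rep = 3L) {
  base <- mean(predict_class(family, fit, x, seed = seed) == y)
  vapply(seq_len(ncol(x)), function(j) {
    drops <- vapply(seq_len(n_rep), function(r) {
      set.seed((seed %% 100000L) * 1000L + j * 10L + r)
      xp <- x
      xp[, j] <- xp[sample.int(nrow(x)), j]
      base - mean(predict_class(family, fit, xp, seed = seed) == y)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
}

## ---- the full protocol -----------------------------------------------------

#' Train and evaluate the rupture classifiers
#'
#' The full protocol: stratified 80/20 train/test split, per-family grid
#' search scored by stratified five-fold cross-validation on the training
#' portion (with standardization refitted inside every fold so no
#' held-out information leaks), refit at the selected hyperparameters,
#' and evaluation with accuracy (train and test), precision and recall
#' for the ruptured class, the ROC curve with AUC, and signed feature
#' importance.  A gap flag marks models whose train accuracy exceeds test
#' accuracy by more than 0.10.
#'
#' @param table a 39-column feature table with a binary `ruptured` label.
#' @param families subset of `c("svm", "knn", "rf", "xgb", "mlp")`.
#' @param seed integer seed controlling the split, folds and every fit.
#' @param holdout test fraction of the stratified holdout split.
#' @param n_folds folds for the inner cross-validation.
#' @param grids hyperparameter grids, as [default_grids()].
#' @return An object of class `rupture_models`: list with `evaluation`
#'   (data.frame of per-model metrics), `roc` (per-model ROC points),
#'   `importance` (per-model importance tables), `selected` (chosen
#'   hyperparameters with their CV accuracy), `split` (train/test row
#'   indices), and `transform` (the training standardization record).
#' @export
train_models <- function(table, families = c("svm", "knn", "rf", "xgb", "mlp"),
                         seed = 1L, holdout = 0.2, n_folds = 5L,
                         grids = default_grids()) {
  families <- match.arg(families, several.ok = TRUE)
  enc <- encode_features(table)
  y <- enc$label
  if (is.null(y) || anyNA(y))
    stop("training error: table must carry a complete ruptured label")
  if (length(unique(y)) < 2L)
    stop("training error: both classes must be present")
  if (length(y) < 50L) stop("training error: need at least 50 rows")
  x <- enc$features

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test_idx <- unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(holdout * length(idx))))
  }), use.names = FALSE)
  train_idx <- setdiff(seq_along(y), test_idx)
  set.seed(seed + 1L)
  fold <- stratified_folds(y[train_idx], n_folds)

  tf <- standardize_features(x, train_idx)
  xtr <- tf$x[train_idx, , drop = FALSE]
  xte <- tf$x[test_idx, , drop = FALSE]
  ytr <- y[train_idx]
  yte <- y[test_idx]

  evaluation <- NULL
  roc <- list()
  importance <- list()
  selected <- list()
  models <- list()
  fam_id <- 0L
  for (family in families) {
    fam_id <- fam_id + 1L
    grid <- grids[[family]]
    cv_acc <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      accs <- numeric(n_folds)
      for (fd in seq_len(n_folds)) {
        tr <- train_idx[fold != fd]
        va <- train_idx[fold == fd]
        ftf <- standardize_features(x, tr)
        fseed <- (seed %% 10000L) * 100000L + fam_id * 10000L +
          gi * 100L + fd
        fit <- fit_family(family, ftf$x[tr, , drop = FALSE], y[tr],
                          grid[gi, , drop = FALSE], fseed)
        pred <- predict_class(family, fit, ftf$x[va, , drop = FALSE],
                              seed = fseed)
        accs[fd] <- mean(pred == y[va])
      }
      cv_acc[gi] <- mean(accs)
    }
    best <- which.max(cv_acc)
    fseed <- (seed %% 10000L) * 100000L + fam_id * 10000L + 99L
    fit <- fit_family(family, xtr, ytr, grid[best, , drop = FALSE], fseed)
    tr_pred <- predict_class(family, fit, xtr, seed = fseed)
    te_pred <- predict_class(family, fit, xte, seed = fseed + 1L)
    te_scores <- predict_scores(family, fit, xte, seed = fseed + 1L)
    ev <- evaluate_predictions(yte, te_pred)
    rc <- roc_auc(te_scores, yte)
    train_acc <- mean(tr_pred == ytr)
    evaluation <- rbind(evaluation, data.frame(
      model = family, train_accuracy = train_acc,
      test_accuracy = ev$accuracy, precision = ev$precision,
      recall = ev$recall, auc = rc$auc,
      cv_accuracy = cv_acc[best],
      gap_flag = (train_acc - ev$accuracy) > 0.10,
      precision_warning = ev$precision_warning,
      stringsAsFactors = FALSE))
    roc[[family]] <- rc$roc_points
    importance[[family]] <- feature_importance(family, fit, xtr, ytr,
                                               seed = fseed)
    selected[[family]] <- c(as.list(grid[best, , drop = FALSE]),
                            list(cv_accuracy = cv_acc[best]))
    models[[family]] <- fit
  }
  structure(list(evaluation = evaluation, roc = roc, importance = importance,
                 selected = selected, models = models,
                 split = list(train = train_idx, test = test_idx),
                 transform = list(center = tf$center, scale = tf$scale),
                 seed = seed),
            class = "rupture_models")
}

#' @export
print.rupture_models <- function(x, ...) {
  cat("rupture_models: evaluation\n")
  print(x$evaluation, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Pooled out-of-fold cross-validated AUC
#'
#' Stratified k-fold cross-validation of a single linear SVM over the
#' whole table; out-of-fold decision scores are pooled and summarised by
#' one AUC.  Used for null-model calibration checks.
#'
#' @param table a labelled feature table.
#' @param seed integer seed.
#' @param n_folds number of folds.
#' @param cost SVM cost parameter.
#' @return AUC scalar.
#' @export
cross_validated_auc <- function(table, seed = 1L, n_folds = 5L, cost = 1) {
  enc <- encode_features(table)
  y <- enc$label
  x <- enc$features
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- stratified_folds(y, n_folds)
  scores <- numeric(length(y))
  for (fd in seq_len(n_folds)) {
    tr <- which(fold != fd)
    va <- which(fold == fd)
    tf <- standardize_features(x, tr)
    fit <- fit_family("svm", tf$x[tr, , drop = FALSE], y[tr],
                      data.frame(kernel = "linear", cost = cost), seed + fd)
    scores[va] <- predict_scores("svm", fit, tf$x[va, , drop = FALSE])
  }
  roc_auc(scores, y)$auc
}

#' Cohort composition summary
#'
#' Location-by-sex counts and per-location rupture rates, plus the overall
#' rupture rate.
#'
#' @param table a feature table with `location`, `sex` and `ruptured`.
#' @return List with `counts` (location x sex table), `rupture_rate`
#'   (named per-location rate), `overall_rate`.
#' @export
cohort_summary <- function(table) {
  counts <- table(location = table$location, sex = table$sex)
  rate <- tapply(table$ruptured, table$location, mean)
  list(counts = counts, rupture_rate = rate,
       overall_rate = mean(table$ruptured))
}

#' Serialize a model run to disk
#'
#' Writes `evaluation.csv`, one `roc_<model>.csv` and
#' `importance_<model>.csv` per family, and `selected.json`, with stable
#' formatting so identical runs produce identical bytes.
#'
#' @param result a `rupture_models` object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(result, dir) {
  stopifnot(inherits(result, "rupture_models"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$evaluation, file.path(dir, "evaluation.csv"),
                   row.names = FALSE)
  for (fam in names(result$roc)) {
    utils::write.csv(result$roc[[fam]],
                     file.path(dir, paste0("roc_", fam, ".csv")),
                     row.names = FALSE)
    utils::write.csv(result$importance[[fam]],
                     file.path(dir, paste0("importance_", fam, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$selected, file.path(dir, "selected.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}
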