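test_that("standardization fits on the given rows only and inverts cleanly", {
  set.seed(3)
  x <- cbind(a = rnorm(100, 5, 2), b = runif(100), const = rep(7, 100))
  fit_rows <- 1:60
  tf <- standardize_features(x, fit_rows)
  expect_equal(colMeans(tf$x[fit_rows, c("a", "b")]), c(a = 0, b = 0),
               tolerance = 1e-9)
  expect_equal(apply(tf$x[fit_rows, c("a", "b")], 2, sd), c(a = 1, b = 1),
               tolerance = 1e-9)
  expect_true(all(tf$x[, "const"] == 0))
  # held-out rows use the stored statistics; transform inverts
  back <- invert_standardization(tf$x, tf$center, tf$scale)
  expect_equal(back[, c("a", "b")], x[, c("a", "b")], tolerance = 1e-9)
  expect_error(standardize_features(x, integer(0)), "empty")
})

test_that("encoding yields the documented 43-column design and decodes back", {
  tab <- make_cohort(cohort_spec(n_ruptured = 20L, n_unruptured = 30L,
                                 seed = 2L))
  enc <- encode_features(tab)
  expect_identical(ncol(enc$features), 43L)
  loc <- enc$features[, grepl("^location_", colnames(enc$features))]
  expect_identical(ncol(loc), 6L)
  expect_true(all(rowSums(loc) == 1))
  # one-hot decodes back to the category
  decoded <- aneurysm_locations()[max.col(loc)]
  expect_identical(decoded, tab$location)
  expect_identical(as.numeric(enc$features[, "sex"]),
                   as.numeric(tab$sex == "male"))
  tab$location[3] <- "XX"
  expect_error(encode_features(tab), "encoding error")
})

test_that("ROC/AUC equals pairwise concordance and stays monotone", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  set.seed(6)
  for (i in 1:20) {
    n <- sample(8:25, 1)
    scores <- sample(1:6, n, replace = TRUE)  # heavy ties
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels))
    rp <- roc_auc(scores, labels)$roc_points
    expect_true(all(diff(rp$FPR) >= 0) && all(diff(rp$TPR) >= 0))
    expect_equal(unlist(rp[1, ]), c(FPR = 0, TPR = 0))
    expect_equal(unlist(rp[nrow(rp), ]), c(FPR = 1, TPR = 1))
  }
  # independent cross-check against pROC
  set.seed(7)
  sc <- rnorm(300)
  lb <- rbinom(300, 1, plogis(sc))
  expect_equal(roc_auc(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))),
               tolerance = 1e-12)
  # label-independent scores are a coin flip
  set.seed(8)
  expect_equal(roc_auc(rnorm(4000), rep(0:1, 2000))$auc, 0.5,
               tolerance = 0.03)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("confusion metrics follow their definitions with the zero-positive rule", {
  truth <-     c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  predicted <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)  # TP 3, FP 1, FN 1, TN 5
  ev <- evaluate_predictions(truth, predicted)
  expect_equal(ev$accuracy, 0.8)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  expect_false(ev$precision_warning)

  allpos <- evaluate_predictions(rep(0:1, 5), rep(1, 10))
  expect_equal(allpos$recall, 1)
  expect_equal(allpos$accuracy, 0.5)

  nopos <- evaluate_predictions(rep(0:1, 5), rep(0, 10))
  expect_equal(nopos$precision, 0)
  expect_true(nopos$precision_warning)
})

test_that("every family separates a planted-margin table perfectly", {
  tab <- separable_table()
  res <- train_models(tab, seed = 4L)
  expect_identical(nrow(res$evaluation), 5L)
  expect_true(all(res$evaluation$test_accuracy == 1))
  expect_true(all(res$evaluation$recall == 1))
  expect_true(all(res$evaluation$auc == 1))
})

test_that("shuffled labels collapse accuracy to the majority rate", {
  tab <- make_cohort(cohort_spec(n_ruptured = 100L, n_unruptured = 150L,
                                 seed = 14L))
  set.seed(15)
  tab$ruptured <- sample(tab$ruptured)
  res <- train_models(tab, families = c("svm", "mlp"), seed = 15L)
  maj <- max(mean(tab$ruptured), 1 - mean(tab$ruptured))
  n_test <- length(res$split$test)
  # within ~4 binomial standard errors of guessing the majority class
  tol <- 4 * sqrt(0.25 / n_test)
  expect_true(all(abs(res$evaluation$test_accuracy - maj) < tol))
})

test_that("a fixed seed reproduces folds, hyperparameters and report bytes", {
  tab <- make_cohort(cohort_spec(n_ruptured = 60L, n_unruptured = 90L,
                                 seed = 19L))
  r1 <- train_models(tab, families = c("svm", "knn", "xgb"), seed = 20L)
  r2 <- train_models(tab, families = c("svm", "knn", "xgb"), seed = 20L)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$split, r2$split)
  expect_equal(r1$evaluation, r2$evaluation)
  d1 <- file.path(tempdir(), "rep1")
  d2 <- file.path(tempdir(), "rep2")
  write_reports(r1, d1)
  write_reports(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
})

test_that("train/test gap flag and input validation follow the protocol", {
  tab <- make_cohort(cohort_spec(n_ruptured = 60L, n_unruptured = 90L,
                                 seed = 23L))
  res <- train_models(tab, families = c("rf", "svm"), seed = 23L)
  ev <- res$evaluation
  expect_identical(ev$gap_flag, (ev$train_accuracy - ev$test_accuracy) > 0.10)

  one_class <- tab
  one_class$ruptured <- 0L
  expect_error(train_models(one_class), "both classes")
  expect_error(train_models(tab[1:20, ]), "50 rows")
})

test_that("holdout-only information cannot leak into grid-search scores", {
  tab <- make_cohort(cohort_spec(n_ruptured = 80L, n_unruptured = 120L,
                                 effect_coefficients = numeric(0),
                                 seed = 27L))
  base <- train_models(tab, families = "svm", seed = 28L)
  # canary: a feature equal to the label on the held-out rows only
  canary <- tab
  canary$IOR <- 0
  canary$IOR[base$split$test] <- canary$ruptured[base$split$test]
  poisoned <- train_models(canary, families = "svm", seed = 28L)
  expect_identical(poisoned$split, base$split)
  # CV selection score must not be inflated by the canary
  expect_lt(abs(poisoned$selected$svm$cv_accuracy -
                base$selected$svm$cv_accuracy), 0.08)
  expect_lt(poisoned$selected$svm$cv_accuracy, 0.75)
})

test_that("importance attribution recovers planted effects with correct sign", {
  tab <- make_cohort(cohort_spec(seed = 33L))
  enc <- encode_features(tab)
  tf <- standardize_features(enc$features)
  fit <- aneumorph:::fit_family("svm", tf$x, enc$label,
                                data.frame(kernel = "linear", cost = 1),
                                seed = 33L)
  imp <- feature_importance("svm", fit, tf$x, enc$label, seed = 33L)
  expect_setequal(imp$feature[1:3], c("EI", "SR", "I"))
  expect_true(all(imp$weight[match(c("EI", "SR", "I"), imp$feature)] > 0))
  expect_true(all(order(-abs(imp$weight)) == seq_len(nrow(imp))))
  expect_identical(nrow(imp), 43L)
})

test_that("cohort summaries count cells exactly and conserve the overall rate", {
  toy <- data.frame(location = c(rep("ICA", 4), rep("MCA", 6)),
                    sex = rep(c("female", "male"), 5),
                    ruptured = c(1, 1, 0, 0, 1, 0, 0, 0, 1, 0))
  cs <- cohort_summary(toy)
  expect_identical(as.integer(cs$counts["ICA", "female"]), 2L)
  expect_identical(as.integer(cs$counts["MCA", "male"]), 3L)
  expect_equal(cs$rupture_rate[["ICA"]], 0.5)
  expect_true(all(cs$rupture_rate >= 0 & cs$rupture_rate <= 1))
  # location-weighted mean equals the overall rate
  w <- table(toy$location)[names(cs$rupture_rate)]
  expect_equal(sum(cs$rupture_rate * w) / sum(w), cs$overall_rate)

  tab <- make_cohort(cohort_spec())
  expect_equal(cohort_summary(tab)$overall_rate, 253 / 709)
})
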