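test_that("confusion matrices add cell-wise and report exact rates", {
  m <- confusion_cells(31, 6, 10, 30)
  st <- confusion_stats(m)
  expect_equal(st$sensitivity, 31 / 37)
  expect_equal(st$specificity, 30 / 40)
  expect_equal(st$accuracy, 61 / 77)
  perfect <- confusion_cells(10, 0, 0, 12)
  stp <- confusion_stats(perfect)
  expect_equal(unlist(stp), c(sensitivity = 1, specificity = 1, accuracy = 1))
  s <- m + perfect
  expect_equal(unlist(unclass(s)), c(tp = 41, fn = 6, fp = 10, tn = 42))
  expect_error(confusion_stats(confusion_cells(0, 0, 0, 0)), "empty")
  expect_error(confusion_cells(-1, 0, 0, 0), "non-negative")
})

test_that("confusion_matrix counts labels with group 1 positive", {
  m <- confusion_matrix(predicted = c(1, 1, 2, 2, 1), actual = c(1, 2, 2, 1, 1))
  expect_equal(unlist(unclass(m)), c(tp = 2, fn = 1, fp = 1, tn = 1))
})

test_that("perfectly separated scores give a unit Youden index", {
  cut <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(2, 2, 1, 1))
  expect_equal(attr(cut, "youden"), 1)
  expect_true(cut > 0.2 && cut <= 0.8)
  expect_error(youden_cutoff(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("the Youden cutoff attains the exhaustive maximum", {
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- 20
      labels <- c(rep(1, 10), rep(2, 10))
      scores <- rnorm(n, mean = ifelse(labels == 1, 0.4, 0), sd = 0.5)
      cut <- youden_cutoff(scores, labels)
      brute <- max(vapply(c(sort(scores) - 1e-9, max(scores) + 1),
                          function(t) {
                            mean(scores[labels == 1] > t) +
                              mean(scores[labels == 2] <= t) - 1
                          }, 0))
      expect_equal(attr(cut, "youden"), brute, tolerance = 1e-12)
    }
  })
})

test_that("ROC curves are monotone in the threshold", {
  withr::with_seed(1, {
    scores <- runif(40)
    labels <- rep(1:2, 20)
    rc <- roc_curve(scores, labels)
    expect_true(all(diff(rc$threshold) < 0))
    expect_true(all(diff(rc$sens) >= 0))
    expect_true(all(diff(rc$spec) <= 0))
  })
})

test_that("cross-validation folds partition the subjects", {
  toy <- toy_feature_table(n_per_group = 15, delta = 2, seed = 3)
  cv <- crossvalidate(toy$features, toy$labels, seed = 3)
  expect_equal(length(cv$fold_ids), 30)
  expect_setequal(unique(cv$fold_ids), 1:5)
  for (k in 1:5) {
    expect_equal(sum(cv$fold_ids == k & toy$labels == 1), 3)
  }
  tot <- cv$overall$tp + cv$overall$fn + cv$overall$fp + cv$overall$tn
  expect_equal(tot, 30)
  summed <- Reduce(`+`, cv$fold_confusions)
  expect_equal(unclass(summed), unclass(cv$overall))
  expect_equal(cv$accuracy,
               (cv$overall$tp + cv$overall$tn) / tot)
})

test_that("cross-validation is deterministic given the seed", {
  toy <- toy_feature_table(n_per_group = 12, delta = 1, seed = 5)
  a <- crossvalidate(toy$features, toy$labels, seed = 11)
  b <- crossvalidate(toy$features, toy$labels, seed = 11)
  expect_identical(a$fold_cutoffs, b$fold_cutoffs)
  expect_identical(unclass(a$overall), unclass(b$overall))
})

test_that("strong signal is learned, pure noise is not", {
  strong <- toy_feature_table(n_per_group = 25, delta = 2.5, seed = 7)
  cv_s <- crossvalidate(strong$features, strong$labels, seed = 7)
  expect_gt(cv_s$accuracy, 0.8)
  null <- toy_feature_table(n_per_group = 25, k = 0, delta = 0, seed = 8)
  cv_n <- crossvalidate(null$features, null$labels, seed = 8)
  expect_gt(cv_n$accuracy, 0.3)
  expect_lt(cv_n$accuracy, 0.7)
})

test_that("small classes cannot be stratified", {
  toy <- toy_feature_table(n_per_group = 3, seed = 1)
  expect_error(crossvalidate(toy$features, toy$labels, n_folds = 5, seed = 1),
               "stratification")
})

test_that("the feature report ranks a planted signal first and never
           reports constant columns", {
  withr::with_seed(21, {
    n <- 60
    x <- matrix(rnorm(n * 10), n, 10)
    colnames(x) <- sprintf("feat_%02d__mean__phrase%02d", 1:10, 1:10)
    x[, 4] <- rnorm(n)
    labels <- stats::setNames(ifelse(x[, 4] > median(x[, 4]), 1L, 2L),
                              sprintf("S%03d", 1:n))
    x[, 7] <- 1                              # constant column
    feats <- cbind(data.frame(subject_id = names(labels)), as.data.frame(x))
    cv <- crossvalidate(feats, labels, seed = 2)
    rep_ <- feature_report(cv)
    expect_equal(rep_$feature[1], "feat_04")
    expect_false("feat_07" %in% rep_$feature)
    expect_true(all(rep_$phrase_id %in% 1:10))
    expect_true(all(rep_$statistic == "mean"))
  })
})

test_that("the alternative test-split cutoff reading is available", {
  toy <- toy_feature_table(n_per_group = 15, delta = 2, seed = 9)
  cv <- crossvalidate(toy$features, toy$labels, seed = 9, cutoff_on = "test")
  expect_length(cv$fold_cutoffs, 5)
  expect_true(is.finite(cv$accuracy))
})
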