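#' Confusion matrix for a binary symptom-group prediction
#'
#' Positive class = group 1. Construct either from counts or from
#' predicted/actual label vectors. Matrices add cell-wise with `+`.
#'
#' @param tp,fn,fp,tn non-negative counts
#' @return a `confusion_matrix`
#' @export
confusion_cells <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0)) stop("confusion counts must be non-negative")
  structure(as.list(cells), class = "confusion_matrix")
}

#' @rdname confusion_cells
#' @param predicted,actual vectors of group labels (1 = positive class)
#' @param positive the positive class label
#' @export
confusion_matrix <- function(predicted, actual, positive = 1) {
  p <- predicted == positive
  a <- actual == positive
  confusion_cells(sum(p & a), sum(!p & a), sum(p & !a), sum(!p & !a))
}

#' @export
Ops.confusion_matrix <- function(e1, e2) {
  if (.Generic != "+") stop("only `+` is defined for confusion matrices")
  confusion_cells(e1$tp + e2$tp, e1$fn + e2$fn, e1$fp + e2$fp, e1$tn + e2$tn)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("actual 1", "actual 2"),
                              c("pred 1", "pred 2")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#' `accuracy = (tp+tn)/total`.
#'
#' @param m a [confusion_cells()] object with a positive total
#' @return a list with `sensitivity`, `specificity`, `accuracy`
#' @export
confusion_stats <- function(m) {
  total <- m$tp + m$fn + m$fp + m$tn
  if (total <= 0) stop("empty confusion matrix")
  list(sensitivity = m$tp / (m$tp + m$fn),
       specificity = m$tn / (m$tn + m$fp),
       accuracy = (m$tp + m$tn) / total)
}

#' ROC curve of a score against binary labels
#'
#' @param scores predicted scores (higher = more positive)
#' @param labels actual labels
#' @param positive positive class label
#' @return a data frame with decreasing `threshold`, `sens`, `spec`
#' @export
roc_curve <- function(scores, labels, positive = 1) {
  y <- labels == positive
  thr <- sort(unique(scores), decreasing = TRUE)
  thr <- c(Inf, thr)
  sens <- vapply(thr, function(t) mean(scores[y] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!y] < t), 0)
  data.frame(threshold = thr, sens = sens, spec = spec)
}

#' Youden-index optimal cutoff
#'
#' The threshold maximizing J = sensitivity + specificity - 1, searched over
#' the midpoints of consecutive sorted unique scores plus sentinels below
#' and above the score range; a score strictly above the threshold predicts
#' the positive class. Ties in J resolve to the lowest threshold.
#'
#' @param scores predicted scores
#' @param labels actual labels (both classes must be present)
#' @param positive positive class label
#' @return the cutoff, with the achieved J in attribute `"youden"`
#' @export
youden_cutoff <- function(scores, labels, positive = 1) {
  y <- labels == positive
  if (all(y) || all(!y)) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (head(u, -1) + u[-1]) / 2, u[length(u)] + 1)
  j <- vapply(cand, function(t) {
    mean(scores[y] > t) + mean(scores[!y] <= t) - 1
  }, 0)
  best <- which(j >= max(j) - 1e-12)[1]
  structure(cand[best], youden = j[best])
}

default_learner <- function() {
  list(nrounds = 60, max_depth = 3, eta = 0.1, min_child_weight = 2,
       subsample = 1, colsample_bytree = 1, lambda = 1)
}

fit_gbt <- function(x, y, learner, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, missing = NA)
  params <- list(objective = "binary:logistic", eval_metric = "logloss",
                 max_depth = learner$max_depth, eta = learner$eta,
                 min_child_weight = learner$min_child_weight,
                 subsample = learner$subsample,
                 colsample_bytree = learner$colsample_bytree,
                 lambda = learner$lambda, nthread = 1, seed = seed)
  xgboost::xgb.train(params, dtrain, nrounds = learner$nrounds, verbose = 0)
}

# stratified fold ids, shuffled within class
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) < n_folds) {
      stop("class ", g, " too small for ", n_folds, "-fold stratification")
    }
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                  length(idx))
  }
  fold
}

#' Cross-validated symptom-group prediction
#'
#' Stratified k-fold cross-validation of a gradient-boosted decision-tree
#' classifier (positive class = group 1). Per fold the model is trained on
#' the training split, the probability cutoff is chosen by the Youden index
#' on the training-split scores (set `cutoff_on = "test"` for the
#' alternative reading), and the thresholded test-split predictions form a
#' fold confusion matrix. The five fold matrices are summed cell-wise into
#' the overall matrix, from which sensitivity, specificity and accuracy are
#' computed.
#'
#' @param features a feature data frame (`subject_id` column plus numeric
#'   registry columns; NA = missing, consumed natively by the trees)
#' @param labels named group vector (values 1/2), one entry per subject
#' @param n_folds number of folds (default 5)
#' @param seed integer seed (fold shuffle and learner)
#' @param learner learner hyperparameters, see `default_learner()`
#' @param cutoff_on "train" (default) or "test": which split's scores feed
#'   the Youden cutoff
#' @return a `cv_result`: `fold_cutoffs`, `fold_confusions`, `overall`,
#'   `sensitivity`, `specificity`, `accuracy`, `importance`, `fold_ids`,
#'   `seed`
#' @export
crossvalidate <- function(features, labels, n_folds = 5, seed = 1,
                          learner = default_learner(),
                          cutoff_on = c("train", "test")) {
  cutoff_on <- match.arg(cutoff_on)
  stopifnot(is.data.frame(features), "subject_id" %in% names(features))
  ids <- features$subject_id
  labels <- labels[ids]
  if (anyNA(labels)) stop("missing group label for some subjects")
  x <- as.matrix(features[, setdiff(names(features), "subject_id"),
                          drop = FALSE])
  storage.mode(x) <- "double"
  y <- as.integer(labels == 1)          # positive class = group 1

  with_seed(seed, {
    fold <- stratified_folds(labels, n_folds)
    cutoffs <- numeric(n_folds)
    confusions <- vector("list", n_folds)
    imp <- list()
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      model <- fit_gbt(x[tr, , drop = FALSE], y[tr], learner,
                       seed = derive_seed(seed, k))
      sc_tr <- predict(model, xgboost::xgb.DMatrix(x[tr, , drop = FALSE],
                                                   missing = NA))
      sc_te <- predict(model, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE],
                                                   missing = NA))
      cut <- if (cutoff_on == "train") {
        youden_cutoff(sc_tr, y[tr], positive = 1)
      } else {
        youden_cutoff(sc_te, y[!tr], positive = 1)
      }
      cutoffs[k] <- as.numeric(cut)
      pred <- ifelse(sc_te > cutoffs[k], 1L, 2L)
      confusions[[k]] <- confusion_matrix(pred, labels[!tr], positive = 1)
      fi <- tryCatch(xgboost::xgb.importance(model = model),
                     error = function(e) NULL)
      if (!is.null(fi) && nrow(fi) > 0) {
        imp[[k]] <- data.frame(fold = k, name = fi$Feature, gain = fi$Gain,
                               stringsAsFactors = FALSE)
      }
    }
    overall <- Reduce(`+`, confusions)
    st <- confusion_stats(overall)
    structure(list(fold_cutoffs = cutoffs, fold_confusions = confusions,
                   overall = overall, sensitivity = st$sensitivity,
                   specificity = st$specificity, accuracy = st$accuracy,
                   importance = do.call(rbind, imp), fold_ids = fold,
                   seed = seed),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  print(x$overall)
  invisible(x)
}

#' Features used by the cross-validated models
#'
#' All features with nonzero split gain in any fold, with their statistic
#' and phrase number parsed back from the registry column name, ranked by
#' total gain across folds.
#'
#' @param cv a [crossvalidate()] result
#' @return a data frame with `feature`, `statistic`, `phrase_id`,
#'   `importance`, `n_folds_used`, sorted by decreasing importance
#' @export
feature_report <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  if (is.null(cv$importance) || nrow(cv$importance) == 0) {
    return(data.frame(feature = character(0), statistic = character(0),
                      phrase_id = integer(0), importance = numeric(0),
                      n_folds_used = integer(0)))
  }
  agg <- stats::aggregate(gain ~ name, cv$importance, sum)
  nfold <- stats::aggregate(fold ~ name, cv$importance,
                            function(f) length(unique(f)))
  parts <- strsplit(agg$name, "__", fixed = TRUE)
  out <- data.frame(
    feature = vapply(parts, `[`, "", 1),
    statistic = vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, ""),
    phrase_id = vapply(parts, function(p) {
      if (length(p) >= 3) as.integer(sub("phrase", "", p[3])) else NA_integer_
    }, 0L),
    importance = agg$gain,
    n_folds_used = nfold$fold[match(agg$name, nfold$name)],
    stringsAsFactors = FALSE
  )
  out[order(-out$importance), , drop = FALSE]
}
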