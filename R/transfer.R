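#' Classifier specification for activity-type recognition
#'
#' @param feature_set `"TD"` or `"FD"` (checked against the tables' tags).
#' @param classifier only `"random_forest"` is implemented.
#' @param n_trees number of trees (>= 10; default 500).
#' @param seed integer seed; per-fold fit seeds derive from it, so
#'   same-device and cross-device cells built from one spec share their
#'   random streams and are directly comparable.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(feature_set = c("TD", "FD"),
                       classifier = "random_forest", n_trees = 500,
                       seed = 1) {
  feature_set <- match.arg(feature_set)
  if (!identical(classifier, "random_forest"))
    stop("unsupported classifier: ", classifier)
  if (n_trees < 10) stop("n_trees must be >= 10")
  structure(list(feature_set = feature_set, classifier = classifier,
                 n_trees = n_trees, seed = seed),
            class = "model_spec")
}

#' Confusion matrix with per-class recall and overall accuracy
#'
#' Rows are truth, columns are predictions, over the closed six-class
#' vocabulary. Per-class recall and overall accuracy are reported in percent
#' to one decimal.
#'
#' @param truth,predicted equal-length label vectors.
#' @param levels class vocabulary (default the six coarse activity classes).
#' @return An object of class `"confusion_matrix"`: `counts` (6x6 matrix),
#'   `per_class_recall` (%), `overall_accuracy` (%), `n_correct`, `n_total`.
#' @export
confusion_summary <- function(truth, predicted,
                              levels = activity_labels("coarse")) {
  if (length(truth) != length(predicted) || length(truth) < 1)
    stop("truth and predicted must have equal length >= 1")
  bad <- setdiff(unique(c(truth, predicted)), levels)
  if (length(bad) > 0)
    stop("label outside vocabulary: ", paste(bad, collapse = ", "))
  counts <- table(factor(truth, levels = levels),
                  factor(predicted, levels = levels))
  counts <- unclass(as.matrix(counts))
  n_total <- sum(counts)
  n_correct <- sum(diag(counts))
  rs <- rowSums(counts)
  recall <- ifelse(rs > 0, round(100 * diag(counts) / rs, 1), NA_real_)
  names(recall) <- levels
  structure(list(counts = counts, per_class_recall = recall,
                 overall_accuracy = round(100 * n_correct / n_total, 1),
                 n_correct = n_correct, n_total = n_total),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- cbind(x$counts, `%correct` = x$per_class_recall)
  print(m)
  cat(sprintf("overall accuracy: %.1f%% (%d/%d)\n",
              x$overall_accuracy, x$n_correct, x$n_total))
  invisible(x)
}

#' Leave-one-subject-out transfer evaluation of one train/test device pair
#'
#' For each subject s, a random forest is fitted on the training device's
#' feature rows excluding s and applied to the test device's rows of s; all
#' held-out predictions are pooled into one confusion matrix. Holding the
#' subject out of both tables keeps same-device and cross-device cells
#' comparable, and leave-one-SUBJECT-out (rather than window-level
#' leave-one-out) prevents same-bout windows leaking between train and test.
#'
#' @param train_table,test_table feature tables from [extract_table()] with
#'   matching `feature_set` tags and the same subject ids.
#' @param spec a [model_spec()].
#' @return An object of class `"transfer_result"`: train/test device ids,
#'   feature set, `confusion` ([confusion_summary()]), `accuracy` (%),
#'   `n_correct`, `n_total`.
#' @export
loso_transfer <- function(train_table, test_table, spec = model_spec()) {
  fs_tr <- attr(train_table, "feature_set")
  fs_te <- attr(test_table, "feature_set")
  if (!identical(fs_tr, fs_te))
    stop("feature_set mismatch between tables: ", fs_tr, " vs ", fs_te)
  if (!identical(fs_tr, spec$feature_set))
    stop("tables carry feature set ", fs_tr, " but spec requests ",
         spec$feature_set)
  subjects <- sort(unique(test_table$subject_id))
  if (length(unique(train_table$subject_id)) < 2)
    stop("need at least 2 subjects for leave-one-subject-out")
  if (!all(subjects %in% train_table$subject_id))
    stop("test subjects missing from the training table")
  fcols <- feature_cols(train_table)
  truth <- character(0); pred <- character(0)
  lev <- activity_labels("coarse")
  for (s in subjects) {
    tr <- train_table[train_table$subject_id != s, , drop = FALSE]
    te <- test_table[test_table$subject_id == s, , drop = FALSE]
    y <- factor(tr$activity, levels = lev)
    ph <- with_seed(child_seed(spec$seed, "rf", s), {
      fit <- randomForest::randomForest(x = tr[, fcols, drop = FALSE], y = y,
                                        ntree = spec$n_trees)
      as.character(predict(fit, te[, fcols, drop = FALSE]))
    })
    truth <- c(truth, te$activity)
    pred <- c(pred, ph)
  }
  cm <- confusion_summary(truth, pred)
  structure(list(train_device = train_table$device_id[1],
                 test_device = test_table$device_id[1],
                 feature_set = fs_tr, confusion = cm,
                 accuracy = cm$overall_accuracy,
                 n_correct = cm$n_correct, n_total = cm$n_total),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %s features, train %s -> test %s: %.1f%% (%d/%d)\n",
              x$feature_set, x$train_device, x$test_device, x$accuracy,
              x$n_correct, x$n_total))
  invisible(x)
}

#' Full 2x2x2 transfer grid
#'
#' Evaluates every cell {FD, TD} x {A->A, A->B, B->B, B->A} with shared fold
#' seeds, returning both the individual [loso_transfer()] results and a tidy
#' summary table (accuracies in percent to one decimal).
#'
#' @param tables named list of two devices, each a list with `TD` and `FD`
#'   feature tables.
#' @param spec a [model_spec()]; its `feature_set` field is overridden per
#'   cell.
#' @return List with `results` (named list of `transfer_result`s, names like
#'   `"TD:devA->devB"`) and `table` (data frame: feature_set, train_device,
#'   test_device, accuracy, n_correct, n_total).
#' @export
transfer_grid <- function(tables, spec = model_spec()) {
  if (length(tables) != 2)
    stop("tables must hold exactly two devices")
  devs <- names(tables)
  results <- list()
  rows <- list()
  for (fset in c("FD", "TD")) {
    for (tr in devs) {
      for (te in devs) {
        tt <- tables[[tr]][[fset]]
        et <- tables[[te]][[fset]]
        if (is.null(tt) || is.null(et))
          stop("missing ", fset, " table for a device")
        cell_spec <- spec
        cell_spec$feature_set <- fset
        res <- loso_transfer(tt, et, cell_spec)
        key <- sprintf("%s:%s->%s", fset, res$train_device, res$test_device)
        results[[key]] <- res
        rows[[key]] <- data.frame(feature_set = fset,
                                  train_device = res$train_device,
                                  test_device = res$test_device,
                                  accuracy = res$accuracy,
                                  n_correct = res$n_correct,
                                  n_total = res$n_total,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  list(results = results, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Pooled two-proportion z-test
#'
#' Compares two proportions of correct predictions with the pooled-variance
#' z statistic: `phat = (k1+k2)/(n1+n2)`,
#' `z = (k1/n1 - k2/n2) / sqrt(phat*(1-phat)*(1/n1+1/n2))`, two-sided p from
#' the standard normal. When the pooled proportion is 0 or 1 the statistic is
#' defined as z = 0 with p = 1 (the data carry no evidence either way).
#'
#' @param k1,n1 correct and total counts, group 1.
#' @param k2,n2 correct and total counts, group 2.
#' @return List with `z` and `p`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2)
    stop("counts must satisfy 0 <= k <= n, n >= 1")
  phat <- (k1 + k2) / (n1 + n2)
  if (phat <= 0 || phat >= 1) return(list(z = 0, p = 1))
  z <- (k1 / n1 - k2 / n2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Z-test report for a transfer grid
#'
#' For each feature set and training device, compares the same-device cell
#' against the cross-device cell with [two_proportion_z()], matching how
#' accuracy proportions from paired prediction runs are conventionally
#' screened.
#'
#' @param grid result of [transfer_grid()].
#' @return Data frame: feature_set, train_device, same-device and
#'   cross-device accuracy, z, p.
#' @export
transfer_ztests <- function(grid) {
  tab <- grid$table
  rows <- list()
  for (fset in unique(tab$feature_set)) {
    for (tr in unique(tab$train_device)) {
      same <- tab[tab$feature_set == fset & tab$train_device == tr &
                    tab$test_device == tr, ]
      cross <- tab[tab$feature_set == fset & tab$train_device == tr &
                     tab$test_device != tr, ]
      zt <- two_proportion_z(same$n_correct, same$n_total,
                             cross$n_correct, cross$n_total)
      rows[[length(rows) + 1]] <- data.frame(
        feature_set = fset, train_device = tr,
        same_device_accuracy = same$accuracy,
        cross_device_accuracy = cross$accuracy,
        z = zt$z, p = zt$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
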