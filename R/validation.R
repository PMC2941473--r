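# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Materialize a reproducible split plan
#'
#' Splits are planned once, with the seed stored and every fold
#' assignment made explicit, so the exact same training and test data can
#' be retrieved later without re-randomization (cross-implementation
#' reproducibility rests on the assignment table, not on PRNG parity).
#'
#' @param store an `mt_store`.
#' @param dataset an `mt_dataset` or URI.
#' @param method `"train_test"`, `"kfold"` or `"loo"`.
#' @param k number of folds (`kfold`; `loo` forces `k = n`).
#' @param stratified balance class counts across folds (requires
#'   `label_feature`); per-class fold sizes differ by at most one. A
#'   class smaller than `k` triggers a warning and best-effort balance.
#' @param seed integer random seed, stored in the plan.
#' @param label_feature URI of the nominal feature used for
#'   stratification.
#' @param test_fraction fraction assigned to the test set
#'   (`train_test` only, default 1/3).
#' @return an `mt_split_plan` with the explicit `assignment` (named
#'   vector compound URI -> fold index, or `"train"`/`"test"`).
#' @export
make_split_plan <- function(store, dataset, method = c("kfold", "train_test", "loo"),
                            k = 10L, stratified = FALSE, seed = 42L,
                            label_feature = NULL, test_fraction = 1 / 3) {
  method <- match.arg(method)
  k <- as.integer(k)
  d <- if (is.character(dataset)) get_dataset(store, dataset) else dataset
  uris <- names(d$compounds)
  n <- length(uris)
  if (n < 2L) mt_abort("need at least two compounds to split", "mt_degenerate_error")
  if (method == "loo") { k <- n; stratified <- FALSE }
  if (method == "kfold" && k > n) {
    mt_abort(sprintf("k = %d exceeds dataset size %d", k, n), "mt_param_error")
  }

  groups <- list(uris)
  if (stratified) {
    if (is.null(label_feature)) {
      mt_abort("stratified splits require label_feature", "mt_param_error")
    }
    labs <- vapply(uris, function(cu) {
      v <- d$entries[[cu]][[label_feature]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
    groups <- split(uris, labs)
    groups <- groups[sort_c(names(groups))]
    small <- vapply(groups, length, integer(1)) < (if (method == "kfold") k else 2L)
    if (any(small)) {
      warning(sprintf(
        "stratified split: class(es) %s smaller than fold count; best-effort balance",
        paste(names(groups)[small], collapse = ", ")))
    }
  }

  assignment <- with_seed(seed, {
    asg <- if (method == "train_test") character(0) else integer(0)
    for (grp in groups) {
      shuffled <- grp[sample.int(length(grp))]
      if (method == "train_test") {
        n_test <- round(length(shuffled) * test_fraction)
        lab <- c(rep("test", n_test),
                 rep("train", length(shuffled) - n_test))
        asg <- c(asg, setNames(lab, shuffled))
      } else {
        fold <- ((seq_along(shuffled) - 1L) %% k) + 1L
        asg <- c(asg, setNames(fold, shuffled))
      }
    }
    asg[uris]   # dataset entry order
  })

  structure(list(
    dataset = d$uri, method = method,
    k = if (method == "train_test") NA_integer_ else as.integer(k),
    stratified = stratified, seed = as.integer(seed),
    label_feature = label_feature,
    test_fraction = if (method == "train_test") test_fraction else NA_real_,
    assignment = assignment
  ), class = "mt_split_plan")
}

plan_folds <- function(plan) {
  if (plan$method == "train_test") {
    list(list(train = names(plan$assignment)[plan$assignment == "train"],
              test = names(plan$assignment)[plan$assignment == "test"]))
  } else {
    lapply(seq_len(plan$k), function(i) {
      list(train = names(plan$assignment)[plan$assignment != i],
           test = names(plan$assignment)[plan$assignment == i])
    })
  }
}

# ---- metrics --------------------------------------------------------------

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) pairs ranked correctly, ties counted one half.
#' ROC points are generated at each unique score threshold (descending);
#' the trapezoidal area under those points equals the pair statistic.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels logical or two-level vector; `positive` names the
#'   positive level when `labels` is not logical.
#' @param positive positive class label.
#' @return list `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) {
    mt_abort("scores and labels differ in length", "mt_param_error")
  }
  y <- if (is.logical(labels)) labels else {
    if (is.null(positive)) positive <- sort_c(unique(as.character(labels)))[1]
    as.character(labels) == positive
  }
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0L || nneg == 0L) {
    mt_abort("ROC needs at least one positive and one negative", "mt_degenerate_error")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(y & scores >= t) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!y & scores >= t) / nneg, numeric(1))
  points <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
                  data.frame(threshold = thr, fpr = fpr, tpr = tpr))
  list(points = points, auc = auc)
}

#' Classification metrics bundle
#'
#' Confusion counts, the unpredicted tally, precision, recall, the
#' F-beta measure (beta = 2 by default, switchable to the balanced
#' F-measure with `fbeta = 1`) and ROC/AUC. Unpredicted compounds
#' (missing predictions) are excluded from the confusion matrix and the
#' ROC but counted in `n_unpredicted`; `percent_unpredicted` is
#' denominated by the full test size.
#'
#' @param truth actual class labels.
#' @param predictions predicted labels; `NA` marks an unpredicted
#'   compound.
#' @param scores numeric ROC scores aligned with `truth` (may be `NA`
#'   where unpredicted).
#' @param positive positive class label (default: C-locale first level
#'   of `truth`).
#' @param fbeta beta of the F-measure (default 2).
#' @return an `mt_metrics` list: `tp`, `fp`, `tn`, `fn`,
#'   `n_unpredicted`, `percent_unpredicted`, `precision`, `recall`,
#'   `f2`, `roc`, `auc`, `n_test`.
#' @export
classification_metrics <- function(truth, predictions, scores = NULL,
                                   positive = NULL, fbeta = 2) {
  n <- length(truth)
  if (length(predictions) != n ||
      (!is.null(scores) && length(scores) != n)) {
    mt_abort("truth, predictions and scores must be aligned", "mt_param_error")
  }
  truth <- as.character(truth)
  predictions <- as.character(predictions)
  if (is.null(positive)) positive <- sort_c(unique(truth))[1]
  pred_ok <- !is.na(predictions)
  t1 <- truth[pred_ok] == positive
  p1 <- predictions[pred_ok] == positive
  tp <- sum(p1 & t1); fp <- sum(p1 & !t1)
  tn <- sum(!p1 & !t1); fn <- sum(!p1 & t1)
  nu <- sum(!pred_ok)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f2 <- if (!is.na(precision) && !is.na(recall) &&
            (fbeta^2 * precision + recall) > 0) {
    (1 + fbeta^2) * precision * recall / (fbeta^2 * precision + recall)
  } else NA_real_
  roc <- NULL; auc <- NA_real_
  if (!is.null(scores)) {
    sc <- scores[pred_ok]; yy <- truth[pred_ok]
    ok <- !is.na(sc)
    if (sum(ok) > 0 && length(unique(yy[ok])) == 2L) {
      roc <- roc_auc(sc[ok], yy[ok], positive = positive)
      auc <- roc$auc
    }
  }
  structure(list(
    task = "classification", positive = positive,
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_unpredicted = nu, percent_unpredicted = 100 * nu / n,
    precision = precision, recall = recall, f2 = f2, fbeta = fbeta,
    roc = roc$points, auc = auc, n_test = n
  ), class = "mt_metrics")
}

#' Regression metrics bundle
#'
#' Mean squared error, its square root, and the explained variance
#' `R^2 = 1 - SS_res / SS_tot`, with `SS_tot` about the truth mean of the
#' evaluated set. Zero variance in the truth leaves `R^2` missing with a
#' warning.
#'
#' @param truth,predictions aligned numeric vectors, `n >= 2`.
#' @return an `mt_metrics` list with `mse`, `rmse`, `r2`, `n_test`.
#' @export
regression_metrics <- function(truth, predictions) {
  if (length(truth) != length(predictions)) {
    mt_abort("truth and predictions differ in length", "mt_param_error")
  }
  ok <- !is.na(truth) & !is.na(predictions)
  nu <- sum(!ok)
  t <- as.numeric(truth[ok]); p <- as.numeric(predictions[ok])
  if (length(t) < 2L) mt_abort("need at least two evaluated pairs",
                               "mt_degenerate_error")
  mse <- mean((t - p)^2)
  ss_tot <- sum((t - mean(t))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero variance in truth: R^2 undefined")
    NA_real_
  } else 1 - sum((t - p)^2) / ss_tot
  structure(list(
    task = "regression",
    n_unpredicted = nu, percent_unpredicted = 100 * nu / length(truth),
    mse = mse, rmse = sqrt(mse), r2 = r2, n_test = length(truth)
  ), class = "mt_metrics")
}

#' @export
print.mt_metrics <- function(x, ...) {
  if (x$task == "classification") {
    cat(sprintf(
      "Classification metrics (n=%d): TP %d FP %d TN %d FN %d | unpredicted %d (%.1f%%)\n",
      x$n_test, x$tp, x$fp, x$tn, x$fn, x$n_unpredicted, x$percent_unpredicted))
    cat(sprintf("  precision %.4f  recall %.4f  F%g %.4f  AUC %.4f\n",
                x$precision, x$recall, x$fbeta, x$f2, x$auc))
  } else {
    cat(sprintf("Regression metrics (n=%d): MSE %.4f RMSE %.4f R2 %.4f\n",
                x$n_test, x$mse, x$rmse, x$r2))
  }
  invisible(x)
}

# ---- validation runs ------------------------------------------------------

subset_dataset <- function(store, d, uris, title_suffix) {
  sub <- structure(list(
    uri = mt_uri(store, "dataset"),
    title = paste0(d$title, title_suffix),
    created = d$created,
    compounds = d$compounds[uris],
    features = d$features,
    entries = d$entries[uris]
  ), class = "mt_dataset")
  sub$snapshot_hash <- dataset_snapshot_hash(sub)
  sub
}

#' Run a validation (train/test or cross-validation)
#'
#' For every fold of the plan the algorithm is trained on the training
#' portion only (including any per-fold feature selection: no
#' information from the test fold enters training) and the test portion
#' is predicted; per-fold and aggregate metric bundles are computed. The
#' headline aggregate pools predictions across folds (pooled confusion
#' counts, AUC on pooled scores); per-fold mean and standard deviation
#' are reported alongside. A fold whose training portion contains a
#' single class is marked failed, excluded from the aggregate and
#' recorded with a warning. The returned record stores the plan, the
#' per-fold train/test snapshot hashes and everything needed to re-run
#' the experiment.
#'
#' @param store an `mt_store`.
#' @param algorithm `"knn"` or `"ols"`.
#' @param params algorithm parameters (see [build_knn_classifier()]).
#' @param plan an `mt_split_plan`.
#' @param dependent_feature target feature URI.
#' @param independent_features predictor URIs (OLS; defaults to the six
#'   physico-chemical descriptors, computed per fold).
#' @param positive_class positive label for ROC scores (k-NN).
#' @param fbeta F-measure beta (default 2).
#' @return an `mt_validation_record`, stored in the store.
#' @export
run_validation <- function(store, algorithm, params = list(), plan,
                           dependent_feature, independent_features = NULL,
                           positive_class = NULL, fbeta = 2) {
  d <- get_dataset(store, plan$dataset)
  folds <- plan_folds(plan)
  fold_metrics <- list()
  fold_hashes <- list()
  fold_models <- character(0)
  fold_selected <- list()
  failed <- integer(0)
  pooled <- data.frame(compound = character(0), truth = character(0),
                       pred = character(0), score = numeric(0),
                       fold = integer(0), stringsAsFactors = FALSE)

  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    train_d <- subset_dataset(store, d, fold$train, sprintf(" [fold %d train]", fi))
    test_d <- subset_dataset(store, d, fold$test, sprintf(" [fold %d test]", fi))
    fold_hashes[[fi]] <- c(train = train_d$snapshot_hash,
                           test = test_d$snapshot_hash)

    truth <- vapply(fold$test, function(cu) {
      v <- d$entries[[cu]][[dependent_feature]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))

    res <- tryCatch({
      if (algorithm == "knn") {
        store_dataset(store, train_d)
        m <- build_knn_classifier(store, train_d, dependent_feature,
                                  params = params,
                                  positive_class = positive_class)
        fold_selected[[fi]] <- m$state$selected_labels
        pr <- predict_with_model(store, m, test_d)
        list(model = m$uri,
             pred = ifelse(pr$predictions$unpredicted, NA_character_,
                           pr$predictions$value),
             score = pr$predictions$score,
             positive = m$positive_class)
      } else if (algorithm == "ols") {
        store_dataset(store, train_d)
        feats <- independent_features
        if (is.null(feats)) {
          train_d <- run_descriptor_algorithm(store, train_d, "descriptors")
          alg_uri <- algorithm_by_name(store, "descriptors")$uri
          feats <- names(train_d$features)[vapply(train_d$features, function(ft)
            identical(ft$has_source, alg_uri), logical(1))]
        }
        m <- build_ols_regressor(store, train_d, feats, dependent_feature)
        pr <- predict_with_model(store, m, test_d)
        list(model = m$uri,
             pred = ifelse(pr$predictions$unpredicted, NA_character_,
                           pr$predictions$value),
             score = pr$predictions$score, positive = NULL)
      } else {
        mt_abort(sprintf("unknown validation algorithm '%s'", algorithm),
                 "mt_param_error")
      }
    }, mt_degenerate_error = function(e) e)

    if (inherits(res, "error")) {
      failed <- c(failed, fi)
      warning(sprintf("fold %d failed (%s); excluded from aggregate",
                      fi, conditionMessage(res)))
      mt_log(store, "validation_fold_failed", sprintf("fold %d", fi))
      next
    }
    fold_models <- c(fold_models, res$model)
    if (algorithm == "knn") {
      fold_metrics[[fi]] <- classification_metrics(
        truth, res$pred, res$score, positive = res$positive, fbeta = fbeta)
    } else {
      fold_metrics[[fi]] <- regression_metrics(as.numeric(truth),
                                               as.numeric(res$score))
    }
    pooled <- rbind(pooled, data.frame(
      compound = fold$test, truth = truth, pred = res$pred,
      score = res$score, fold = fi, stringsAsFactors = FALSE))
  }

  if (nrow(pooled) == 0L) {
    mt_abort("every fold failed; no aggregate metrics", "mt_degenerate_error")
  }
  aggregate <- if (algorithm == "knn") {
    classification_metrics(pooled$truth, pooled$pred, pooled$score,
                           positive = positive_class %||%
                             sort_c(unique(pooled$truth))[1],
                           fbeta = fbeta)
  } else {
    regression_metrics(as.numeric(pooled$truth), pooled$score)
  }
  per_fold_summary <- summarize_folds(fold_metrics)

  rec <- structure(list(
    uri = mt_uri(store, "validation"),
    algorithm = algorithm,
    algorithm_uri = algorithm_by_name(store, algorithm)$uri,
    params = params,
    plan = plan,
    dependent_feature = dependent_feature,
    independent_features = independent_features,
    positive_class = positive_class,
    fbeta = fbeta,
    dataset_snapshot = d$snapshot_hash,
    fold_hashes = fold_hashes,
    fold_metrics = fold_metrics,
    fold_selected = fold_selected,
    failed_folds = failed,
    models = fold_models,
    aggregate = aggregate,
    per_fold_summary = per_fold_summary
  ), class = "mt_validation_record")
  store$validations[[rec$uri]] <- rec
  mt_log(store, "run_validation", rec$uri)
  rec
}

summarize_folds <- function(fold_metrics) {
  fold_metrics <- Filter(Negate(is.null), fold_metrics)
  if (length(fold_metrics) == 0L) return(NULL)
  nums <- c("precision", "recall", "f2", "auc", "mse", "rmse", "r2")
  out <- list()
  for (nm in nums) {
    vals <- vapply(fold_metrics, function(mtr) mtr[[nm]] %||% NA_real_,
                   numeric(1))
    if (all(is.na(vals))) next
    out[[nm]] <- c(mean = mean(vals, na.rm = TRUE),
                   sd = if (sum(!is.na(vals)) > 1) sd(vals, na.rm = TRUE)
                        else NA_real_)
  }
  out
}

#' Re-execute a validation from its stored record
#'
#' Re-runs the exact experiment from the persisted plan (explicit fold
#' assignments) and parameters; for deterministic algorithms the
#' aggregate metrics reproduce identically. The training dataset's
#' snapshot hash is checked first.
#'
#' @param store an `mt_store`.
#' @param record an `mt_validation_record` or its URI.
#' @return a fresh `mt_validation_record`.
#' @export
rerun_validation <- function(store, record) {
  rec <- if (is.character(record)) store$validations[[record]] else record
  if (is.null(rec)) mt_abort("validation record not found", "mt_notfound_error")
  d <- get_dataset(store, rec$plan$dataset)
  if (!identical(d$snapshot_hash, rec$dataset_snapshot)) {
    mt_abort("training dataset changed since the validation was recorded",
             "mt_schema_error")
  }
  run_validation(store, rec$algorithm, rec$params, rec$plan,
                 rec$dependent_feature, rec$independent_features,
                 rec$positive_class, rec$fbeta)
}

#' @export
print.mt_validation_record <- function(x, ...) {
  cat(sprintf("<mt_validation_record %s: %s, %s>\n", x$uri, x$algorithm,
              x$plan$method))
  print(x$aggregate)
  invisible(x)
}
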