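balanced_csv_rows <- function() {
  c("CCO,active", "CCCO,active", "CC(C)O,active", "CCCCO,active",
    "CC(C)CO,active", "CCN,inactive", "CCCN,inactive", "CC(C)N,inactive",
    "CCCCN,inactive", "CC(C)CN,inactive")
}

test_that("split plans are explicit, stratified and reproducible", {
  tw <- tiny_store_with_csv(balanced_csv_rows())
  store <- tw$store
  d <- tw$ingest$dataset
  lab <- tw$ingest$feature$uri

  plan <- make_split_plan(store, d, "kfold", k = 5, stratified = TRUE,
                          seed = 11, label_feature = lab)
  # oracle: exhaustive per-fold class counts — every fold 1 active + 1 inactive
  labs <- vapply(names(d$entries), function(cu)
    d$entries[[cu]][[lab]], character(1))
  for (f in 1:5) {
    members <- names(plan$assignment)[plan$assignment == f]
    expect_length(members, 2L)
    expect_equal(sum(labs[members] == "active"), 1L)
    expect_equal(sum(labs[members] == "inactive"), 1L)
  }
  # folds partition the dataset
  expect_setequal(names(plan$assignment), names(d$compounds))

  # determinism contract
  plan2 <- make_split_plan(store, d, "kfold", k = 5, stratified = TRUE,
                           seed = 11, label_feature = lab)
  expect_identical(plan$assignment, plan2$assignment)
  plan3 <- make_split_plan(store, d, "kfold", k = 5, stratified = TRUE,
                           seed = 12, label_feature = lab)
  expect_false(identical(plan$assignment, plan3$assignment))

  # loo: n folds of size 1
  tw7 <- tiny_store_with_csv(head(balanced_csv_rows(), 7))
  plan_loo <- make_split_plan(tw7$store, tw7$ingest$dataset, "loo")
  expect_equal(plan_loo$k, 7L)
  expect_true(all(table(plan_loo$assignment) == 1L))

  # k > n is an error; tiny stratum warns
  expect_error(make_split_plan(store, d, "kfold", k = 11),
               class = "mt_param_error")
  expect_warning(make_split_plan(store, d, "kfold", k = 8, stratified = TRUE,
                                 seed = 1, label_feature = lab),
                 "best-effort")

  # train/test split labels
  pt <- make_split_plan(store, d, "train_test", seed = 5, test_fraction = 0.3,
                        stratified = FALSE)
  expect_setequal(unique(pt$assignment), c("train", "test"))
  expect_equal(sum(pt$assignment == "test"), 3L)
})

test_that("classification metrics match their formulas", {
  m <- classification_metrics(c("a", "a", "b", "b"), c("a", "a", "b", "b"),
                              positive = "a")
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f2, 1)
  expect_equal(m$n_unpredicted, 0L)

  # P = 0.5, R = 1.0 -> F2 = 0.8333 (F_beta formula, beta = 2)
  m2 <- classification_metrics(c("a", "b", "b"), c("a", "a", "b"),
                               positive = "a")
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$recall, 1)
  expect_equal(m2$f2, 5 * 0.5 * 1 / (4 * 0.5 + 1), tolerance = 1e-9)
  expect_equal(round(m2$f2, 4), 0.8333)
  # the fbeta switch recovers the balanced F-measure
  m2b <- classification_metrics(c("a", "b", "b"), c("a", "a", "b"),
                                positive = "a", fbeta = 1)
  expect_equal(m2b$f2, 2 * 0.5 * 1 / (0.5 + 1), tolerance = 1e-9)

  # unpredicted compounds: excluded from the matrix, counted separately
  truth <- rep(c("a", "b"), 5)
  pred <- truth
  pred[c(3, 8)] <- NA
  m3 <- classification_metrics(truth, pred, positive = "a")
  expect_equal(m3$n_unpredicted, 2L)
  expect_equal(m3$percent_unpredicted, 20)
  expect_equal(m3$tp + m3$fp + m3$tn + m3$fn, 8L)
  expect_equal(m3$tp + m3$fp + m3$tn + m3$fn + m3$n_unpredicted, m3$n_test)

  expect_error(classification_metrics(c("a", "b"), "a"),
               class = "mt_param_error")
})

test_that("ROC/AUC implements the pair statistic with ties at one half", {
  # perfectly separating scores
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1.0)

  # actives {0.9, 0.4}, inactives {0.6, 0.1}: 3 of 4 pairs correct
  r2 <- roc_auc(c(0.9, 0.4, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.75)

  # all scores equal: all ties, AUC one half
  r3 <- roc_auc(rep(0.5, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r3$auc, 0.5)

  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), class = "mt_degenerate_error")

  # trapezoidal area under the ROC points equals the pair statistic,
  # and AUC(scores) = 1 - AUC(-scores)
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    s <- round(runif(n), 1)   # coarse scores force ties
    r <- roc_auc(s, y)
    expect_equal(r$auc, bf_auc(s, y), tolerance = 1e-12)
    expect_equal(bf_trapezoid(r$points$fpr, r$points$tpr), r$auc,
                 tolerance = 1e-12)
    expect_equal(roc_auc(-s, y)$auc, 1 - r$auc, tolerance = 1e-12)
  }
})

test_that("regression metrics match their formulas", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$mse, 0)
  expect_equal(m$rmse, 0)
  expect_equal(m$r2, 1)

  # truth (1,2,3) vs (2,2,2): SS_res = SS_tot = 2
  m2 <- regression_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m2$mse, 2 / 3, tolerance = 1e-9)
  expect_equal(m2$rmse, sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(round(m2$rmse, 4), 0.8165)
  expect_equal(m2$r2, 0)

  expect_warning(m3 <- regression_metrics(c(2, 2, 2), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(m3$r2))
  expect_error(regression_metrics(1, c(1, 2)), class = "mt_param_error")
})

test_that("cross-validation runs are reproducible and pool correctly", {
  store <- new_store()
  fx <- generate_classification_fixture(store, fixture_spec(n = 40, seed = 21))
  plan <- make_split_plan(store, fx$dataset, "kfold", k = 5, stratified = TRUE,
                          seed = 3, label_feature = fx$feature$uri)
  rec1 <- run_validation(store, "knn", list(k = 3), plan, fx$feature$uri)
  rec2 <- run_validation(store, "knn", list(k = 3), plan, fx$feature$uri)
  strip_uri <- function(r) unclass(r$aggregate)
  expect_identical(strip_uri(rec1), strip_uri(rec2))

  # rerun from the persisted record reproduces the aggregate
  rec3 <- rerun_validation(store, rec1$uri)
  expect_identical(strip_uri(rec3), strip_uri(rec1))

  # pooled confusion counts equal the sum of per-fold counts
  fm <- Filter(Negate(is.null), rec1$fold_metrics)
  for (nm in c("tp", "fp", "tn", "fn", "n_unpredicted")) {
    expect_equal(sum(vapply(fm, `[[`, numeric(1), nm)), rec1$aggregate[[nm]])
  }

  # memorization: predicting the training set with k=1 is perfect
  m <- build_knn_classifier(store, fx$dataset, fx$feature$uri,
                            params = list(k = 1))
  pr <- predict_with_model(store, m, fx$dataset)
  truth <- vapply(names(fx$dataset$entries), function(cu)
    fx$dataset$entries[[cu]][[fx$feature$uri]], character(1))
  expect_identical(unname(pr$predictions$value), unname(truth))
})

test_that("a single-class training fold is excluded with a warning", {
  tw <- tiny_store_with_csv(c("CCO,active", "CCCO,active", "CC(C)O,active",
                              "CCN,inactive"))
  store <- tw$store
  plan <- make_split_plan(store, tw$ingest$dataset, "loo")
  expect_warning(
    rec <- run_validation(store, "knn", list(k = 1, s_min = 0), plan,
                          tw$ingest$feature$uri),
    "excluded from aggregate")
  inactive_uri <- names(which(vapply(
    names(plan$assignment), function(cu)
      tw$ingest$dataset$entries[[cu]][[tw$ingest$feature$uri]] == "inactive",
    logical(1))))
  expect_equal(rec$failed_folds, unname(plan$assignment[inactive_uri]))
  expect_equal(rec$aggregate$n_test, 3L)
})

test_that("per-fold feature selection sees only its training fold", {
  # Crafted dataset: actives of group A carry the nitro group, actives of
  # group B carry bromine. With a manual 2-fold plan, fold 1 trains on
  # group B only and fold 2 on group A only, so the chi-squared-selected
  # label sets must differ between folds.
  rows <- c("CC[N+](=O)[O-],active", "CCC[N+](=O)[O-],active",
            "CCO,inactive", "CCCO,inactive",
            "CCBr,active", "CCCBr,active",
            "CCOC,inactive", "CCCOC,inactive")
  tw <- tiny_store_with_csv(rows)
  store <- tw$store
  d <- tw$ingest$dataset
  smi_of <- vapply(d$compounds, `[[`, character(1), "canonical_smiles")
  group_a <- grepl("N", smi_of)  | smi_of %in% c("CCO", "CCCO")
  plan <- structure(list(
    dataset = d$uri, method = "kfold", k = 2L, stratified = FALSE,
    seed = 0L, label_feature = tw$ingest$feature$uri, test_fraction = NA_real_,
    assignment = setNames(ifelse(group_a, 2L, 1L), names(d$compounds))
  ), class = "mt_split_plan")
  rec <- run_validation(store, "knn", list(k = 3, s_min = 0, select_top_k = 4),
                        plan, tw$ingest$feature$uri)
  sel1 <- rec$fold_selected[[1]]   # trained on group A (nitro signal)
  sel2 <- rec$fold_selected[[2]]   # trained on group B (bromo signal)
  expect_false(setequal(sel1, sel2))
  expect_true(any(grepl("N\\+", sel1)))
  expect_true(any(grepl("Br", sel2)))
  expect_false(any(grepl("Br", sel1)))
})
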