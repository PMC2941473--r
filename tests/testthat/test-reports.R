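demo_pred_content <- function() {
  list(
    title = "demo",
    inputs = list(query = "CCO"),
    predictions = data.frame(model = "urn:m/1", activity = "active",
                             confidence = 0.8, ad_inside = TRUE,
                             ad_score = 0.9, stringsAsFactors = FALSE),
    provenance = list(models = "urn:m/1"))
}

test_that("report rendering is deterministic and schema-checked", {
  rep <- render_report(demo_pred_content(), "prediction_single", "html")
  expect_match(rep$document, "active")
  expect_match(rep$document, "confidence")
  expect_match(rep$document, "ad_inside")
  # well-formed markup
  expect_silent(xml2::read_xml(rep$document))
  # byte-identical on re-render
  rep2 <- render_report(demo_pred_content(), "prediction_single", "html")
  expect_identical(rep$document, rep2$document)

  # structured form round-trips through JSON
  st <- render_report(demo_pred_content(), "prediction_single", "structured")
  back <- jsonlite::fromJSON(st$document)
  expect_identical(back$report_type, "prediction_single")
  expect_identical(back$predictions$activity, "active")

  # schema mismatches are rejected
  bad <- demo_pred_content()
  bad$predictions$ad_inside <- NULL
  expect_error(render_report(bad, "prediction_single", "html"),
               "applicability domain", class = "mt_schema_error")
  expect_error(render_report(list(title = "x"), "model_comparison", "html"),
               class = "mt_schema_error")
  expect_error(render_report(demo_pred_content(), "not_a_type", "html"),
               class = "mt_schema_error")
})

test_that("validation reports carry every metrics-bundle field", {
  tw <- tiny_store_with_csv(c("CCO,active", "CCCO,active", "CC(C)O,active",
                              "CCN,inactive", "CCCN,inactive",
                              "CC(C)N,inactive"))
  store <- tw$store
  plan <- make_split_plan(store, tw$ingest$dataset, "kfold", k = 2,
                          stratified = TRUE, seed = 2,
                          label_feature = tw$ingest$feature$uri)
  rec <- run_validation(store, "knn", list(k = 1, s_min = 0), plan,
                        tw$ingest$feature$uri)
  rep <- render_report(list(title = "v", metrics = unclass(rec$aggregate),
                            provenance = list(validation = rec$uri)),
                       "model_validation", "html")
  for (nm in c("tp", "fp", "tn", "fn", "n_unpredicted", "percent_unpredicted",
               "precision", "recall", "f2", "auc")) {
    expect_match(rep$document, nm, fixed = TRUE)
  }
  expect_match(rep$document, "ROC points")
})

workflow_store <- function(n = 24, seed = 31) {
  store <- new_store()
  ont <- build_endpoint_ontology(store)
  csv <- tempfile(fileext = ".csv")
  fx <- generate_classification_fixture(store, fixture_spec(n = n, seed = seed),
                                        csv_path = csv)
  res <- toxcreate_run(store, csv,
                       validation = list(method = "kfold", k = 3, seed = 5,
                                         stratified = TRUE),
                       endpoint_ref = ont$leaves[["Mutagenicity"]])
  list(store = store, ont = ont, res = res, csv = csv, fx = fx)
}

test_that("the prediction workflow runs exactly five ordered stages", {
  w <- workflow_store()
  msgs <- character(0)
  rep <- withCallingHandlers(
    toxpredict_run(w$store, "CCC[N+](=O)[O-]"),
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  steps <- grep("^STEP", msgs, value = TRUE)
  expect_length(steps, 5L)
  expect_identical(substr(steps, 1, 5), paste0("STEP", 1:5))
  expect_s3_class(rep, "mt_report")
  expect_true(all(c("activity", "confidence", "ad_inside") %in%
                    names(rep$content$predictions)))
})

test_that("experimental data for a stored compound enters the report", {
  w <- workflow_store()
  # query a compound of the training set: its activity measurement is
  # experimental data in the store
  smi <- w$store$datasets[[w$res$dataset_uri]]$compounds[[1]]$canonical_smiles
  rep <- suppressMessages(toxpredict_run(w$store, smi))
  expect_false(is.null(rep$content$experimental))
  expect_match(rep$content$experimental$note,
               "Experimental data for this structure is available")
  expect_match(rep$document, "Experimental data")
})

test_that("workflow exception paths match the published wording", {
  w <- workflow_store()
  err <- tryCatch(suppressMessages(toxpredict_run(w$store, "C1CC(")),
                  error = function(e) e)
  expect_s3_class(err, "mt_workflow_error")
  expect_match(conditionMessage(err), "Incorrect chemical structure")

  # endpoint filter matching no model
  eco <- w$ont$subclasses[["ecotoxic effects"]]
  err2 <- tryCatch(
    suppressMessages(toxpredict_run(w$store, "CC[N+](=O)[O-]", endpoint = eco)),
    error = function(e) e)
  expect_match(conditionMessage(err2), "Endpoint unavailable")
})

test_that("model creation workflow: build, validate, persist, re-predict", {
  w <- workflow_store()
  expect_match(w$res$model_uri, "model/")
  expect_match(w$res$validation_uri, "validation/")
  expect_s3_class(w$res$report, "mt_report")
  expect_silent(xml2::read_xml(w$res$report$document))

  # a second model on the same data; compare predictions on one structure
  d <- w$store$datasets[[w$res$dataset_uri]]
  lab <- names(Filter(function(ft) ft$value_kind == "nominal", d$features))[1]
  m2 <- build_knn_classifier(w$store, d, lab, params = list(k = 1))
  register_model(w$store, m2)
  rep <- toxcreate_predict(w$store, "CCCC[N+](=O)[O-]")
  expect_equal(nrow(rep$content$predictions), 2L)

  # persistence: a fresh session loads the store and still predicts
  dir <- tempfile("persist")
  store_save(w$store, dir)
  s2 <- store_load(dir)
  rep2 <- toxcreate_predict(s2, "CCCC[N+](=O)[O-]")
  expect_equal(nrow(rep2$content$predictions), 2L)
  expect_identical(sort(rep2$content$predictions$activity),
                   sort(rep$content$predictions$activity))
})

test_that("model comparison ranks by criterion and checks endpoints", {
  w <- workflow_store()
  store <- w$store
  d <- store$datasets[[w$res$dataset_uri]]
  lab <- names(Filter(function(ft) ft$value_kind == "nominal", d$features))[1]
  plan <- make_split_plan(store, d, "kfold", k = 3, stratified = TRUE,
                          seed = 8, label_feature = lab)
  r1 <- run_validation(store, "knn", list(k = 3), plan, lab)
  r2 <- run_validation(store, "knn", list(k = 3, s_min = 0.9), plan, lab)
  rep <- compare_models(store, list(r1, r2), criterion = "auc")
  rk <- rep$content$ranking
  expect_setequal(rk$validation, c(r1$uri, r2$uri))   # a permutation
  expect_true(all(diff(rk$auc) <= 0 | is.na(diff(rk$auc))))

  # an error criterion ranks ascending
  repp <- compare_models(store, list(r1, r2), criterion = "percent_unpredicted")
  expect_true(all(diff(repp$content$ranking$percent_unpredicted) >= 0))

  # records over different endpoints are rejected
  store2 <- new_store()
  fx2 <- generate_classification_fixture(store2, fixture_spec(n = 12, seed = 1))
  plan2 <- make_split_plan(store2, fx2$dataset, "kfold", k = 2,
                           stratified = TRUE, seed = 1,
                           label_feature = fx2$feature$uri)
  r3 <- run_validation(store2, "knn", list(k = 1), plan2, fx2$feature$uri)
  expect_error(compare_models(store, list(r1, r3)), class = "mt_param_error")

  # feature-selection evaluation reports both metric columns
  r_sel <- run_validation(store, "knn", list(k = 3, select_top_k = 10),
                          plan, lab)
  fe <- feature_selection_report(store, r_sel, r1)
  expect_match(fe$document, "With feature selection")
  expect_match(fe$document, "Without feature selection")
})

test_that("the CLI drives the workflows end to end", {
  tmp <- tempfile("cli"); dir.create(tmp)
  csv <- file.path(tmp, "toy.csv")
  sdir <- file.path(tmp, "store")
  expect_equal(suppressMessages(minitox_cli(
    c("fixtures", "make", "--n", "24", "--seed", "13", "--out", csv))), 0L)
  expect_true(file.exists(csv))
  expect_equal(suppressMessages(minitox_cli(
    c("toxcreate", "build", "--csv", csv, "--store", sdir,
      "--folds", "3", "--param", "k=3"))), 0L)
  out <- file.path(tmp, "rep.html")
  expect_equal(suppressMessages(minitox_cli(
    c("toxpredict", "--query", "CC[N+](=O)[O-]", "--store", sdir,
      "--out", out))), 0L)
  expect_true(file.exists(out))
  expect_silent(xml2::read_xml(out))
  # an unparsable query exits non-zero
  expect_gt(suppressMessages(minitox_cli(
    c("toxpredict", "--query", "X((", "--store", sdir))), 0L)
})
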