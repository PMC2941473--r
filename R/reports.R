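REPORT_TYPES <- c("prediction_single", "prediction_multi", "model_validation",
                  "dataset_predictions", "model_comparison", "feature_eval")

#' Render a report
#'
#' Renders report content as well-formed XHTML or as a structured (JSON)
#' document. Rendering is deterministic: the same content produces
#' byte-identical output, and the structured form round-trips through
#' [jsonlite::fromJSON]. Content is schema-checked per report type: a
#' single-compound prediction must carry activity, applicability domain
#' and confidence; a model comparison must carry a ranking and its
#' criterion.
#'
#' @param content named list; always `title` and `provenance` (named
#'   list of URIs/parameters), plus type-specific parts (`predictions`
#'   data.frame, `metrics`, `ranking`, ...).
#' @param report_type one of `prediction_single`, `prediction_multi`,
#'   `model_validation`, `dataset_predictions`, `model_comparison`,
#'   `feature_eval`.
#' @param format `"html"` or `"structured"`.
#' @return an `mt_report`: `report_type`, `format`, `content`,
#'   `document` (character).
#' @export
render_report <- function(content, report_type, format = c("html", "structured")) {
  format <- match.arg(format)
  if (!report_type %in% REPORT_TYPES) {
    mt_abort(sprintf("unknown report type '%s'", report_type), "mt_schema_error")
  }
  check_report_schema(content, report_type)
  doc <- if (format == "html") render_html(content, report_type)
         else render_structured(content, report_type)
  structure(list(report_type = report_type, format = format,
                 content = content, document = doc),
            class = "mt_report")
}

check_report_schema <- function(content, report_type) {
  need <- function(fields) {
    missing <- setdiff(fields, names(content))
    if (length(missing)) {
      mt_abort(sprintf("report content for '%s' lacks field(s): %s",
                       report_type, paste(missing, collapse = ", ")),
               "mt_schema_error")
    }
  }
  need(c("title", "provenance"))
  switch(report_type,
    prediction_single = {
      need("predictions")
      pcols <- c("activity", "confidence", "ad_inside")
      missing <- setdiff(pcols, names(content$predictions))
      if (length(missing)) {
        mt_abort(sprintf(
          "single-prediction report must include activity, applicability domain and confidence (missing: %s)",
          paste(missing, collapse = ", ")), "mt_schema_error")
      }
    },
    prediction_multi = need("predictions"),
    model_validation = need("metrics"),
    dataset_predictions = need("predictions"),
    model_comparison = {
      need(c("ranking", "criterion"))
    },
    feature_eval = need(c("with_selection", "without_selection"))
  )
  invisible(TRUE)
}

render_structured <- function(content, report_type) {
  payload <- c(list(report_type = report_type), content)
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null", na = "null"))
}

html_table <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return("<p>none</p>")
  head_row <- paste0("<tr>", paste0("<th>", xml_escape(names(df)), "</th>",
                                    collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(df[i, , drop = FALSE], function(v) {
      s <- if (is.numeric(v)) num_chr(v) else as.character(v)
      if (is.na(s)) s <- "NA"
      paste0("<td>", xml_escape(s), "</td>")
    }, character(1))
    paste0("<tr>", paste(cells, collapse = ""), "</tr>")
  }, character(1))
  paste0("<table>", head_row, paste(rows, collapse = ""), "</table>")
}

html_kv <- function(lst) {
  if (length(lst) == 0L) return("<p>none</p>")
  rows <- vapply(names(lst), function(nm) {
    v <- lst[[nm]]
    s <- if (is.numeric(v)) paste(num_chr(v), collapse = ", ") else
      paste(as.character(v), collapse = ", ")
    sprintf("<tr><th>%s</th><td>%s</td></tr>", xml_escape(nm), xml_escape(s))
  }, character(1))
  paste0("<table>", paste(rows, collapse = ""), "</table>")
}

metrics_html <- function(mtr) {
  flat <- mtr[!vapply(mtr, is.null, logical(1))]
  roc <- flat$roc
  flat$roc <- NULL
  flat <- lapply(flat, function(v) if (is.data.frame(v)) NULL else v)
  flat <- flat[!vapply(flat, is.null, logical(1))]
  out <- html_kv(flat)
  if (!is.null(roc)) out <- paste0(out, "<h4>ROC points</h4>", html_table(roc))
  out
}

render_html <- function(content, report_type) {
  body <- c(sprintf("<h1>%s</h1>", xml_escape(content$title)),
            sprintf("<p class='type'>Report type: %s</p>", report_type))
  if (!is.null(content$inputs)) {
    body <- c(body, "<h2>Inputs</h2>", html_kv(content$inputs))
  }
  if (!is.null(content$structure_check)) {
    sc <- content$structure_check
    body <- c(body, "<h2>Structure check</h2>",
              sprintf("<p>%d component(s)</p>", sc$components),
              if (length(sc$warnings)) {
                paste0("<ul>", paste0("<li>", xml_escape(sc$warnings), "</li>",
                                      collapse = ""), "</ul>")
              } else "<p>no warnings</p>")
  }
  if (!is.null(content$experimental)) {
    body <- c(body, "<h2>Experimental data</h2>",
              sprintf("<p>%s</p>", xml_escape(content$experimental$note)),
              html_table(content$experimental$measurements))
  }
  if (!is.null(content$predictions)) {
    body <- c(body, "<h2>Predictions</h2>", html_table(content$predictions))
  }
  if (!is.null(content$metrics)) {
    body <- c(body, "<h2>Validation metrics (aggregate)</h2>",
              metrics_html(content$metrics))
  }
  if (!is.null(content$per_fold)) {
    body <- c(body, "<h2>Per-fold summary (mean, sd)</h2>",
              html_kv(lapply(content$per_fold, function(v)
                sprintf("%s (sd %s)", num_chr(v[["mean"]]), num_chr(v[["sd"]])))))
  }
  if (!is.null(content$ranking)) {
    body <- c(body, sprintf("<h2>Ranking by %s</h2>",
                            xml_escape(content$criterion)),
              html_table(content$ranking))
  }
  if (!is.null(content$with_selection)) {
    body <- c(body, "<h2>With feature selection</h2>",
              metrics_html(content$with_selection),
              "<h2>Without feature selection</h2>",
              metrics_html(content$without_selection))
  }
  if (!is.null(content$supporting)) {
    body <- c(body, "<h2>Supporting information</h2>")
    for (nm in names(content$supporting)) {
      v <- content$supporting[[nm]]
      body <- c(body, sprintf("<h3>%s</h3>", xml_escape(nm)),
                if (is.data.frame(v)) html_table(v) else
                  html_kv(as.list(v)))
    }
  }
  body <- c(body, "<h2>Provenance</h2>", html_kv(content$provenance))
  paste0(
    "<html xmlns=\"http://www.w3.org/1999/xhtml\"><head><title>",
    xml_escape(content$title), "</title></head><body>",
    paste(body, collapse = "\n"), "</body></html>")
}

#' @export
print.mt_report <- function(x, ...) {
  cat(sprintf("<mt_report %s (%s), %d bytes>\n", x$report_type, x$format,
              nchar(x$document)))
  invisible(x)
}

# ---- model registry hook --------------------------------------------------

#' Register a model into the ontology hub
#'
#' Adds the model's type, algorithm, title and (when the dependent
#' feature is endpoint-annotated) endpoint triples to the registry, so
#' the prediction workflow can discover it. Called automatically by the
#' model-building workflow.
#'
#' @param store an `mt_store`.
#' @param model an `mt_model` or URI.
#' @export
register_model <- function(store, model) {
  m <- if (is.character(model)) store$models[[model]] else model
  meta <- list(
    list(p = q("ot", "algorithm"), o = m$algorithm, kind = "uri"),
    list(p = q("ot", "trainingDataset"), o = m$training_dataset, kind = "uri"),
    list(p = q("ot", "dependentVariables"), o = m$dependent_feature,
         kind = "uri"),
    list(p = q("dc", "title"), o = paste0(m$kind, " model"), kind = "string")
  )
  dep <- store$features[[m$dependent_feature]]
  if (!is.null(dep) && !is.null(dep$endpoint_ref)) {
    meta[[length(meta) + 1L]] <- list(p = q("ot", "endpoint"),
                                      o = dep$endpoint_ref, kind = "uri")
  }
  register_resource(store, m$uri, "Model", meta)
}

registered_models <- function(store) {
  res <- query_triples(store, list(c("?m", q("rdf", "type"), q("ot", "Model"))))
  if (nrow(res) == 0L) character(0) else res$m
}

model_endpoint <- function(store, muri) {
  res <- query_triples(store, list(c(muri, q("ot", "endpoint"), "?e")))
  if (nrow(res) == 0L) NA_character_ else res$e[1]
}

# ---- ToxPredict-style workflow --------------------------------------------

#' Predict the toxicity of a structure (five-step workflow)
#'
#' Runs the end-user prediction workflow in exactly five logged stages
#' (markers `STEP1`..`STEP5`): (1) resolve the query — free-text search
#' over stored compounds, else parse as SMILES; (2) structure display
#' and graph-level consistency check; (3) model discovery through the
#' ontology registry, with endpoint column and optional endpoint filter;
#' (4) estimation through the task service — feature resolution,
#' prediction and applicability domain per selected model, plus stored
#' experimental data when found; (5) report rendering.
#'
#' @param store an `mt_store` with at least one registered model.
#' @param query chemical name, SMILES or stored InChI.
#' @param endpoint optional endpoint class URI filter.
#' @param models `"all"` or character vector of model URIs.
#' @param ad applicability-domain spec: `"similarity:t=<x>"`, `"range"`,
#'   an `mt_ad_model`/URI, or `NULL` (a default similarity AD on each
#'   model's training set).
#' @param out optional path for the HTML document.
#' @return an `mt_report` (`prediction_single`), whose structured twin
#'   is in `$content`.
#' @export
toxpredict_run <- function(store, query, endpoint = NULL, models = "all",
                           ad = NULL, out = NULL) {
  # STEP 1: enter/select a chemical compound
  message("STEP1 search/resolve structure: ", query)
  hits <- search_compounds(store, query)
  cp <- if (length(hits)) hits[[1]] else {
    parsed <- tryCatch(add_compound(store, query, origin_inventory = "query"),
                       error = function(e) e)
    if (inherits(parsed, "error")) {
      mt_abort(paste("Incorrect chemical structure. Unable to predict",
                     "endpoint. Please consult the structure documentation",
                     "and advice services."), "mt_workflow_error")
    }
    parsed
  }

  # STEP 2: display selected/found structures
  g <- parse_smiles(cp$canonical_smiles)
  sc <- check_structure(g)
  message(sprintf("STEP2 structure check: %s (%d component(s), %d warning(s))",
                  cp$canonical_smiles, sc$components, length(sc$warnings)))

  # STEP 3: select models via the ontology hub
  muris <- registered_models(store)
  if (!identical(models, "all")) muris <- intersect(muris, models)
  model_table <- data.frame(
    model = muris,
    endpoint = vapply(muris, function(mu) model_endpoint(store, mu),
                      character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(endpoint)) {
    keep <- model_table$endpoint %in% endpoint_descendants(store, endpoint)
    model_table <- model_table[keep, , drop = FALSE]
  }
  if (nrow(model_table) == 0L) {
    mt_abort("Endpoint unavailable. Unable to predict endpoint.",
             "mt_workflow_error")
  }
  message(sprintf("STEP3 model selection: %d model(s) from ontology registry",
                  nrow(model_table)))

  # STEP 4: perform the estimation (task service + AD)
  qd <- new_dataset(store, compounds = list(cp),
                    values = setNames(list(list()), cp$uri),
                    title = "query")
  store_dataset(store, qd)
  rows <- list(); supporting <- list()
  for (mu in model_table$model) {
    task <- create_task(store, "predict_with_model",
                        list(model = mu, dataset = qd$uri))
    if (task$status != "Completed") {
      mt_abort(sprintf("Unable to predict endpoint: %s", task$error),
               "mt_workflow_error")
    }
    pr <- task$result
    adres <- apply_ad_spec(store, ad, store$models[[mu]], cp)
    p1 <- pr$predictions[1, ]
    rows[[mu]] <- data.frame(
      model = mu,
      activity = if (p1$unpredicted) "UNPREDICTED" else p1$value,
      confidence = p1$confidence,
      score = p1$score,
      ad_inside = adres$inside,
      ad_score = adres$score,
      stringsAsFactors = FALSE)
    if (length(pr$supporting)) supporting[[mu]] <- pr$supporting[[1]]
  }
  preds <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  exp_hits <- query_datasets(store, compound = cp$uri, endpoint = endpoint)
  exp_hits <- Filter(function(h) nrow(h$measurements) > 0, exp_hits)
  message(sprintf("STEP4 estimation: %d model prediction(s), %d experimental dataset(s)",
                  nrow(preds), length(exp_hits)))

  # STEP 5: display the results
  content <- list(
    title = sprintf("Toxicity prediction for %s", cp$canonical_smiles),
    inputs = list(query = query, compound = cp$uri,
                  smiles = cp$canonical_smiles),
    structure_check = list(components = sc$components, warnings = sc$warnings),
    predictions = preds,
    supporting = supporting,
    provenance = list(
      models = model_table$model,
      endpoints = unique(model_table$endpoint),
      query_dataset = qd$uri)
  )
  if (length(exp_hits)) {
    content$experimental <- list(
      note = paste("Experimental data for this structure is available in the",
                   "database and is summarized here:"),
      measurements = do.call(rbind, lapply(exp_hits, `[[`, "measurements")))
  }
  report <- render_report(content, "prediction_single", "html")
  if (!is.null(out)) writeLines(report$document, out)
  message("STEP5 report rendered",
          if (!is.null(out)) paste0(" to ", out) else "")
  report
}

apply_ad_spec <- function(store, ad, model, cp) {
  if (inherits(ad, "mt_ad_model")) return(apply_ad(store, ad, cp))
  if (is.character(ad) && !is.null(store$ad_models[[ad]])) {
    return(apply_ad(store, ad, cp))
  }
  train <- model$training_dataset
  admod <- if (is.null(ad)) {
    build_ad(store, train, "similarity")
  } else if (identical(ad, "range")) {
    d <- run_descriptor_algorithm(store, train, "descriptors")
    build_ad(store, d, "range")
  } else if (grepl("^similarity", ad)) {
    t <- if (grepl(":t=", ad)) as.numeric(sub("^.*:t=", "", ad)) else 0.3
    build_ad(store, train, "similarity", list(t = t))
  } else {
    mt_abort(sprintf("unknown AD spec '%s'", ad), "mt_param_error")
  }
  apply_ad(store, admod, cp)
}

# ---- ToxCreate-style workflow ---------------------------------------------

#' Create and validate a model from a user CSV (four-step workflow)
#'
#' (1) Upload: the training CSV (`smiles,activity`) is ingested into a
#' dataset; (2) model creation through the task service, with the model
#' permanently registered in the ontology hub; (3) validation
#' (cross-validation by default) through the independent validation
#' service; (4) a model-validation report. The stored model can predict
#' arbitrary structures at any later time (see [toxcreate_predict()]).
#'
#' @param store an `mt_store`.
#' @param csv_path training CSV path.
#' @param algorithm `"knn"` (the lazy-learning representative).
#' @param params algorithm parameters.
#' @param validation list: `method`, `k`, `seed`, `stratified`.
#' @param endpoint_ref optional endpoint class URI for the new activity
#'   feature.
#' @param out optional path for the HTML report.
#' @return list `dataset_uri`, `model_uri`, `validation_uri`, `report`,
#'   `ingest` (rejected-row report).
#' @export
toxcreate_run <- function(store, csv_path, algorithm = "knn", params = list(),
                          validation = list(method = "kfold", k = 10L,
                                            seed = 42L, stratified = TRUE),
                          endpoint_ref = NULL, out = NULL) {
  ing <- ingest_training_csv(store, csv_path, endpoint_ref = endpoint_ref)
  d <- ing$dataset
  task <- create_task(store, "build_knn_classifier",
                      list(dataset = d$uri, dependent_feature = ing$feature$uri,
                           params = params))
  if (task$status != "Completed") {
    mt_abort(sprintf("model building failed: %s", task$error),
             "mt_workflow_error")
  }
  m <- task$result
  register_model(store, m)
  plan <- make_split_plan(store, d, method = validation$method %||% "kfold",
                          k = validation$k %||% 10L,
                          stratified = validation$stratified %||% TRUE,
                          seed = validation$seed %||% 42L,
                          label_feature = ing$feature$uri)
  rec <- run_validation(store, algorithm, params, plan, ing$feature$uri)
  content <- list(
    title = sprintf("Model validation: %s on %s", algorithm, d$title),
    inputs = list(csv = csv_path, n_compounds = length(d$compounds),
                  n_rejected_rows = nrow(ing$rejected)),
    metrics = unclass(rec$aggregate),
    per_fold = rec$per_fold_summary,
    provenance = list(model = m$uri, algorithm = m$algorithm,
                      dataset = d$uri, dataset_hash = d$snapshot_hash,
                      validation = rec$uri,
                      split = sprintf("%s k=%s seed=%d stratified=%s",
                                      plan$method, plan$k, plan$seed,
                                      plan$stratified),
                      parameters = paste(names(m$parameters),
                                         vapply(m$parameters, as.character,
                                                character(1)),
                                         sep = "=", collapse = " "))
  )
  report <- render_report(content, "model_validation", "html")
  if (!is.null(out)) writeLines(report$document, out)
  list(dataset_uri = d$uri, model_uri = m$uri, validation_uri = rec$uri,
       report = report, ingest = ing[c("rejected", "conflicts")])
}

#' Predict one structure with several stored models
#'
#' @param store an `mt_store`.
#' @param smiles structure to predict.
#' @param models `"all"` or model URIs.
#' @return an `mt_report` (`prediction_multi`) with one row per model.
#' @export
toxcreate_predict <- function(store, smiles, models = "all") {
  cp <- add_compound(store, smiles, origin_inventory = "query")
  muris <- registered_models(store)
  if (!identical(models, "all")) muris <- intersect(muris, models)
  if (length(muris) == 0L) {
    mt_abort("no stored models available for prediction", "mt_workflow_error")
  }
  qd <- new_dataset(store, compounds = list(cp),
                    values = setNames(list(list()), cp$uri), title = "query")
  store_dataset(store, qd)
  rows <- lapply(muris, function(mu) {
    pr <- predict_with_model(store, mu, qd)
    p1 <- pr$predictions[1, ]
    data.frame(model = mu,
               activity = if (p1$unpredicted) "UNPREDICTED" else p1$value,
               confidence = p1$confidence, stringsAsFactors = FALSE)
  })
  content <- list(
    title = sprintf("Predictions for %s", cp$canonical_smiles),
    inputs = list(smiles = cp$canonical_smiles),
    predictions = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    provenance = list(models = muris, query_dataset = qd$uri))
  render_report(content, "prediction_multi", "html")
}

# ---- model comparison -----------------------------------------------------

#' Compare validated models by a performance criterion
#'
#' Ranks validation records over the same dataset and endpoint by a
#' metric of the aggregate bundle (AUC by default; error criteria such
#' as RMSE/MSE rank ascending).
#'
#' @param store an `mt_store`.
#' @param records list of `mt_validation_record`s or URIs (>= 2).
#' @param criterion aggregate metric name (`auc`, `precision`, `recall`,
#'   `f2`, `mse`, `rmse`, `r2`, `percent_unpredicted`).
#' @return an `mt_report` (`model_comparison`) whose `content$ranking`
#'   is a permutation of the input records.
#' @export
compare_models <- function(store, records, criterion = "auc") {
  recs <- lapply(records, function(r) {
    if (is.character(r)) store$validations[[r]] else r
  })
  if (length(recs) < 2L) {
    mt_abort("model comparison needs at least two validation records",
             "mt_param_error")
  }
  snaps <- vapply(recs, `[[`, character(1), "dataset_snapshot")
  deps <- vapply(recs, `[[`, character(1), "dependent_feature")
  ep_of <- function(fu) {
    ft <- store$features[[fu]]
    if (is.null(ft) || is.null(ft$endpoint_ref)) fu else ft$endpoint_ref
  }
  if (length(unique(snaps)) > 1L || length(unique(vapply(deps, ep_of,
                                                         character(1)))) > 1L) {
    mt_abort("validation records cover different datasets/endpoints",
             "mt_param_error")
  }
  vals <- vapply(recs, function(r) r$aggregate[[criterion]] %||% NA_real_,
                 numeric(1))
  asc <- criterion %in% c("mse", "rmse", "percent_unpredicted")
  ord <- order(if (asc) vals else -vals)
  ranking <- data.frame(
    rank = seq_along(recs),
    validation = vapply(recs, `[[`, character(1), "uri")[ord],
    algorithm = vapply(recs, `[[`, character(1), "algorithm")[ord],
    value = vals[ord],
    stringsAsFactors = FALSE)
  names(ranking)[names(ranking) == "value"] <- criterion
  content <- list(
    title = sprintf("Model comparison by %s", criterion),
    criterion = criterion,
    ranking = ranking,
    provenance = list(dataset_hash = snaps[1],
                      records = ranking$validation))
  render_report(content, "model_comparison", "html")
}

#' Evaluate a feature-selection algorithm
#'
#' Side-by-side metrics for a validation run with chi-squared feature
#' selection against the same run without it.
#'
#' @param store an `mt_store`.
#' @param with_selection,without_selection `mt_validation_record`s or
#'   URIs.
#' @return an `mt_report` (`feature_eval`).
#' @export
feature_selection_report <- function(store, with_selection, without_selection) {
  w <- if (is.character(with_selection)) store$validations[[with_selection]]
       else with_selection
  wo <- if (is.character(without_selection)) store$validations[[without_selection]]
        else without_selection
  content <- list(
    title = "Feature selection evaluation",
    with_selection = unclass(w$aggregate),
    without_selection = unclass(wo$aggregate),
    provenance = list(with_record = w$uri, without_record = wo$uri,
                      dataset_hash = w$dataset_snapshot))
  render_report(content, "feature_eval", "html")
}
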