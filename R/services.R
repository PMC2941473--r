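# Fixed vocabulary namespaces. The core/algorithm/endpoint terms mirror
# the framework's resource names; the IRIs are this package's own.
NS <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  dc   = "http://purl.org/dc/elements/1.1/",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  ot   = "http://minitox.org/ns/core#",
  ota  = "http://minitox.org/ns/algorithm-types#",
  ote  = "http://minitox.org/ns/endpoints#"
)

q <- function(prefix, local) paste0(NS[[prefix]], local)

TYPE_CLASSES <- c(
  Dataset = "ot", DataEntry = "ot", Compound = "ot", Feature = "ot",
  FeatureValue = "ot", Model = "ot", Algorithm = "ot", Validation = "ot",
  ADModel = "ot", Task = "ot",
  DescriptorCalculation = "ota", Classification = "ota", Regression = "ota",
  FeatureSelection = "ota", DataCleanup = "ota"
)

type_class_uri <- function(name) {
  pfx <- TYPE_CLASSES[name]
  if (is.na(pfx)) {
    mt_abort(sprintf("unknown type class '%s'", name), "mt_schema_error")
  }
  q(pfx, name)
}

mt_triple <- function(s, p, o, kind = "uri") {
  list(s = s, p = p, o = as.character(o), kind = kind)
}

triple_key <- function(tr) paste(tr$s, tr$p, tr$o, tr$kind, sep = "\r")

add_triples <- function(store, triples) {
  keys <- vapply(store$triples, triple_key, character(1))
  for (tr in triples) {
    k <- triple_key(tr)
    if (!(k %in% keys)) {
      store$triples[[length(store$triples) + 1L]] <- tr
      keys <- c(keys, k)
    }
  }
  invisible(NULL)
}

#' Register a resource in the ontology/registry hub
#'
#' Stores `uri rdf:type <class>` plus any metadata triples, with set
#' semantics (idempotent). The registry is the single discovery path:
#' the prediction workflow lists exactly the Model-typed subjects
#' registered here.
#'
#' @param store an `mt_store`.
#' @param uri resource URI.
#' @param type_class vocabulary class name (e.g. `"Model"`,
#'   `"Algorithm"`, `"Feature"`).
#' @param metadata list of triples, each `list(p =, o =, kind =)` (kind
#'   `"uri"`, `"string"` or `"number"`).
#' @export
register_resource <- function(store, uri, type_class, metadata = list()) {
  cls <- type_class_uri(type_class)
  triples <- list(mt_triple(uri, q("rdf", "type"), cls))
  for (mtd in metadata) {
    triples[[length(triples) + 1L]] <-
      mt_triple(uri, mtd$p, mtd$o, mtd$kind %||% "uri")
  }
  add_triples(store, triples)
  mt_log(store, "register_resource", uri)
  invisible(uri)
}

#' Query the registry with basic graph patterns
#'
#' Conjunctive triple patterns; each pattern is `c(s, p, o)` where a
#' term starting with `?` is a variable and shared variables join
#' patterns. Results are all satisfying bindings, deterministically
#' ordered (row-wise C-locale sort).
#'
#' @param store an `mt_store`.
#' @param patterns list of length-3 character vectors.
#' @return data.frame with one column per variable (names without the
#'   `?`); zero rows when unsatisfiable.
#' @export
query_triples <- function(store, patterns) {
  if (length(patterns) == 0L) mt_abort("need at least one pattern", "mt_param_error")
  bindings <- list(character(0))   # one empty binding
  for (pat in patterns) {
    new_bindings <- list()
    for (b in bindings) {
      subst <- vapply(pat, function(term) {
        if (startsWith(term, "?") && term %in% names(b)) b[[term]] else term
      }, character(1))
      for (tr in store$triples) {
        vals <- c(tr$s, tr$p, tr$o)
        ok <- TRUE
        ext <- b
        for (j in 1:3) {
          if (startsWith(subst[j], "?")) {
            v <- subst[j]
            if (v %in% names(ext) && ext[[v]] != vals[j]) { ok <- FALSE; break }
            ext[v] <- vals[j]
          } else if (subst[j] != vals[j]) { ok <- FALSE; break }
        }
        if (ok) new_bindings[[length(new_bindings) + 1L]] <- ext
      }
    }
    bindings <- new_bindings
    if (length(bindings) == 0L) break
  }
  vars <- unique(unlist(lapply(patterns, function(p) p[startsWith(p, "?")])))
  out <- as.data.frame(
    setNames(lapply(vars, function(v) {
      vapply(bindings, function(b) {
        if (v %in% names(b)) b[[v]] else NA_character_
      }, character(1))
    }), sub("^\\?", "", vars)),
    stringsAsFactors = FALSE)
  if (nrow(out) > 1L) {
    key <- do.call(paste, c(out, sep = "\r"))
    out <- out[order_c(key), , drop = FALSE]
    out <- out[!duplicated(key[order_c(key)]), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# ---- endpoint ontology ----------------------------------------------------

ENDPOINT_SUBCLASSES <- c(
  "ecotoxic effects",
  "environmental fate parameters",
  "human health effects",
  "physico-chemical effects",
  "toxicokinetics"
)

# REACH endpoint list (15 entries) attached as leaf classes.
REACH_ENDPOINTS <- list(
  "Skin irritation" = "human health effects",
  "Skin corrosion" = "human health effects",
  "Eye irritation" = "human health effects",
  "Dermal sensitisation" = "human health effects",
  "Mutagenicity" = "human health effects",
  "Acute oral toxicity" = "human health effects",
  "Acute inhalative toxicity" = "human health effects",
  "Acute dermal toxicity" = "human health effects",
  "Repeated dose toxicity (28 days)" = "human health effects",
  "Repeated dose toxicity (90 days)" = "human health effects",
  "Reproductive toxicity screening" = "human health effects",
  "Developmental toxicity" = "human health effects",
  "Two-generation reproductive toxicity study" = "human health effects",
  "Toxicokinetics" = "toxicokinetics",
  "Carcinogenicity study" = "human health effects"
)

endpoint_uri <- function(label) {
  slug <- gsub("(^-+|-+$)", "", gsub("[^A-Za-z0-9]+", "-", label))
  q("ote", slug)
}

#' Build the toxicity endpoint ontology
#'
#' Creates a root endpoint class with exactly five direct subclasses
#' (ecotoxic effects, environmental fate parameters, human health
#' effects, physico-chemical effects, toxicokinetics) and attaches the
#' 15 REACH endpoints as leaf classes via `rdfs:subClassOf`. The
#' subclass closure is queryable via [endpoint_descendants()].
#'
#' @param store an `mt_store`.
#' @return list `root` (root class URI), `subclasses` (named URIs of the
#'   5 direct subclasses), `leaves` (named URIs of the REACH endpoints).
#' @export
build_endpoint_ontology <- function(store) {
  root <- q("ote", "ToxicologicalEndpoint")
  triples <- list(
    mt_triple(root, q("rdf", "type"), q("rdfs", "Class")),
    mt_triple(root, q("rdfs", "label"), "toxicological endpoint", "string")
  )
  subs <- setNames(vapply(ENDPOINT_SUBCLASSES, endpoint_uri, character(1)),
                   ENDPOINT_SUBCLASSES)
  for (lab in ENDPOINT_SUBCLASSES) {
    triples <- c(triples, list(
      mt_triple(subs[[lab]], q("rdf", "type"), q("rdfs", "Class")),
      mt_triple(subs[[lab]], q("rdfs", "subClassOf"), root),
      mt_triple(subs[[lab]], q("rdfs", "label"), lab, "string")))
  }
  leaves <- setNames(vapply(names(REACH_ENDPOINTS), endpoint_uri, character(1)),
                     names(REACH_ENDPOINTS))
  for (lab in names(REACH_ENDPOINTS)) {
    parent <- subs[[REACH_ENDPOINTS[[lab]]]]
    triples <- c(triples, list(
      mt_triple(leaves[[lab]], q("rdf", "type"), q("rdfs", "Class")),
      mt_triple(leaves[[lab]], q("rdfs", "subClassOf"), parent),
      mt_triple(leaves[[lab]], q("rdfs", "label"), lab, "string")))
  }
  add_triples(store, triples)
  list(root = root, subclasses = subs, leaves = leaves)
}

#' Subclass closure of an endpoint class
#'
#' @param store an `mt_store` with the endpoint ontology built.
#' @param uri an endpoint class URI.
#' @return character vector: `uri` itself plus every class reachable by
#'   inverse `rdfs:subClassOf`.
#' @export
endpoint_descendants <- function(store, uri) {
  children_of <- function(u) {
    vapply(Filter(function(tr) {
      tr$p == q("rdfs", "subClassOf") && tr$o == u
    }, store$triples), `[[`, character(1), "s")
  }
  seen <- character(0)
  frontier <- uri
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unlist(lapply(frontier, children_of)), seen)
  }
  sort_c(unique(seen))
}

# ---- tasks ----------------------------------------------------------------

TASK_OPERATIONS <- c("ingest_training_csv", "run_descriptor_algorithm",
                     "build_knn_classifier", "build_ols_regressor",
                     "predict_with_model", "build_ad", "run_validation")

#' Asynchronous task contract
#'
#' Operations run in-process but follow the asynchronous task contract:
#' a task is created `Queued` (HTTP-like code 202), transitions through
#' `Running` (202) to `Completed` (200, result URI set) or `Error`
#' (500, detail preserved); every transition is appended to a monotone
#' log that [poll_task()] exposes.
#'
#' @param store an `mt_store`.
#' @param operation one of the registered operation names
#'   (`ingest_training_csv`, `run_descriptor_algorithm`,
#'   `build_knn_classifier`, `build_ols_regressor`,
#'   `predict_with_model`, `build_ad`, `run_validation`).
#' @param args named list of arguments passed to the operation (the
#'   store is supplied automatically).
#' @return the completed (or failed) `mt_task`: `uri`, `status`,
#'   `http_code`, `percent`, `result` (operation return value),
#'   `result_uri`, `error`, `transitions`.
#' @export
create_task <- function(store, operation, args = list()) {
  if (!operation %in% TASK_OPERATIONS) {
    mt_abort(sprintf("unknown operation '%s'", operation), "mt_notfound_error")
  }
  task <- structure(list(
    uri = mt_uri(store, "task"),
    operation = operation,
    status = "Queued", http_code = 202L, percent = 0,
    result = NULL, result_uri = NULL, error = NULL,
    transitions = list()
  ), class = "mt_task")
  task <- task_transition(task, "Queued", 202L, 0)
  task <- task_transition(task, "Running", 202L, 10)
  store$tasks[[task$uri]] <- task

  out <- tryCatch(
    do.call(get(operation, envir = asNamespace("minitox")),
            c(list(store = store), args)),
    error = function(e) e)

  if (inherits(out, "error")) {
    task$error <- conditionMessage(out)
    task <- task_transition(task, "Error", 500L, 100)
  } else {
    task$result <- out
    task$result_uri <- task_result_uri(out)
    task <- task_transition(task, "Completed", 200L, 100)
  }
  store$tasks[[task$uri]] <- task
  task
}

task_result_uri <- function(out) {
  if (is.character(out) && length(out) == 1L) return(out)
  if (is.list(out) && !is.null(out$uri)) return(out$uri)
  if (is.list(out) && !is.null(out$dataset) && is.list(out$dataset) &&
      !is.null(out$dataset$uri)) return(out$dataset$uri)
  NULL
}

task_transition <- function(task, status, code, percent) {
  task$status <- status
  task$http_code <- code
  task$percent <- percent
  task$transitions[[length(task$transitions) + 1L]] <- list(
    time = Sys.time(), status = status, http_code = code, percent = percent)
  task
}

#' @rdname create_task
#' @param uri task URI.
#' @export
poll_task <- function(store, uri) {
  task <- store$tasks[[uri]]
  if (is.null(task)) mt_abort(sprintf("task <%s> not found", uri),
                              "mt_notfound_error")
  task
}

#' @export
print.mt_task <- function(x, ...) {
  cat(sprintf("<mt_task %s: %s (%d) %g%%>\n", x$uri, x$status, x$http_code,
              x$percent))
  invisible(x)
}

# ---- feature resolution ---------------------------------------------------

#' Resolve a model's independent features on a query dataset
#'
#' For each independent feature missing from the query dataset, the
#' feature's `has_source` is consulted: if it points at a
#' descriptor-calculation algorithm, that algorithm is invoked to compute
#' the values for the query structures; if it points at a dataset (an
#' experimental feature), resolution fails for compounds not in that
#' dataset. An already-prepared dataset passes through unchanged.
#'
#' @param store an `mt_store`.
#' @param model an `mt_model`.
#' @param dataset the query `mt_dataset`.
#' @return the prepared `mt_dataset`.
#' @export
resolve_features <- function(store, model, dataset) {
  for (fu in model$independent_features) {
    missing_for <- vapply(names(dataset$compounds), function(cu) {
      v <- dataset$entries[[cu]][[fu]]
      is.null(v) || (length(v) == 1L && is.na(v))
    }, logical(1))
    if (!any(missing_for)) next
    ft <- store$features[[fu]] %||% dataset$features[[fu]]
    if (is.null(ft)) {
      mt_abort(sprintf("unresolvable feature <%s>: unknown feature", fu),
               "mt_resolve_error")
    }
    src <- ft$has_source
    alg <- store$algorithms[[src]]
    if (!is.null(alg)) {
      dataset$features[[fu]] <- ft   # reuse the model's feature object
      dataset <- run_descriptor_algorithm(store, dataset, alg)
    } else if (!is.null(store$datasets[[src]])) {
      src_d <- store$datasets[[src]]
      for (cu in names(dataset$compounds)[missing_for]) {
        v <- src_d$entries[[cu]][[fu]]
        if (is.null(v)) {
          mt_abort(sprintf(
            "unresolvable feature <%s>: experimental feature has no value for unseen compound <%s>",
            fu, cu), "mt_resolve_error")
        }
        dataset$entries[[cu]][[fu]] <- v
      }
    } else {
      mt_abort(sprintf("unresolvable feature <%s>: source <%s> unknown",
                       fu, src), "mt_resolve_error")
    }
  }
  dataset
}
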