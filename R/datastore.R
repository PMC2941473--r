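#' Create an in-memory resource store
#'
#' The store is the desk-scale stand-in for the framework's distributed
#' services: it holds compounds, features, datasets, models,
#' applicability-domain models, validation records, the ontology/registry
#' triples and the task log, all addressed by stable URIs. URIs are
#' `<base><kind>/<counter>` so the web-addressable design is emulated
#' without a network.
#'
#' @param base_uri URI prefix for minted resources (default
#'   `urn:minitox:`).
#' @return an environment of class `mt_store`.
#' @export
new_store <- function(base_uri = "urn:minitox:") {
  store <- new.env(parent = emptyenv())
  store$base_uri <- base_uri
  store$counters <- new.env(parent = emptyenv())
  store$compounds <- list()        # uri -> mt_compound
  store$smiles_index <- character(0)  # canonical smiles -> compound uri
  store$features <- list()         # uri -> mt_feature
  store$datasets <- list()         # uri -> mt_dataset
  store$models <- list()           # uri -> mt_model
  store$ad_models <- list()        # uri -> mt_ad_model
  store$validations <- list()      # uri -> mt_validation_record
  store$algorithms <- list()       # uri -> mt_algorithm
  store$triples <- list()          # registry triples
  store$tasks <- list()            # uri -> mt_task
  store$log <- list()
  class(store) <- "mt_store"
  register_builtin_algorithms(store)
  store
}

#' @export
print.mt_store <- function(x, ...) {
  cat(sprintf(
    "<mt_store %s: %d compounds, %d datasets, %d models, %d validations, %d triples>\n",
    x$base_uri, length(x$compounds), length(x$datasets), length(x$models),
    length(x$validations), length(x$triples)))
  invisible(x)
}

mt_uri <- function(store, kind) {
  ctr <- (get0(kind, envir = store$counters, ifnotfound = 0L)) + 1L
  assign(kind, ctr, envir = store$counters)
  paste0(store$base_uri, kind, "/", ctr)
}

#' Register a compound in the store
#'
#' Parses and canonicalizes the structure; a compound with the same
#' canonical SMILES is returned rather than duplicated (names and
#' identifiers are merged onto the existing record).
#'
#' @param store an `mt_store`.
#' @param smiles structure as SMILES.
#' @param names character vector of chemical names/synonyms.
#' @param inchi optional InChI string, stored as an opaque identifier
#'   (never computed).
#' @param origin_inventory tag identifying the inventory the compound
#'   originated from.
#' @return the `mt_compound` (fields `uri`, `canonical_smiles`, `names`,
#'   `inchi`, `origin_inventory`).
#' @export
add_compound <- function(store, smiles, names = character(0), inchi = NULL,
                         origin_inventory = "user") {
  can <- cached_canonical(smiles)
  existing <- store$smiles_index[can]
  if (!is.na(existing)) {
    cp <- store$compounds[[existing]]
    cp$names <- sort_c(unique(c(cp$names, names)))
    if (!is.null(inchi) && is.null(cp$inchi)) cp$inchi <- inchi
    store$compounds[[existing]] <- cp
    return(cp)
  }
  cp <- structure(list(
    uri = mt_uri(store, "compound"),
    canonical_smiles = can,
    names = sort_c(unique(names)),
    inchi = inchi,
    origin_inventory = origin_inventory
  ), class = "mt_compound")
  store$compounds[[cp$uri]] <- cp
  store$smiles_index[can] <- cp$uri
  cp
}

#' Define a feature
#'
#' A feature is any property object attachable to a compound — a
#' descriptor, an experimental endpoint value, or a model prediction. The
#' `has_source` provenance link (the algorithm, model or dataset that
#' produced it) is mandatory.
#'
#' @param store an `mt_store`.
#' @param name feature name.
#' @param value_kind one of `numeric`, `nominal`, `string`.
#' @param has_source URI of the producing algorithm/model/dataset.
#' @param nominal_domain allowed values (nominal features).
#' @param endpoint_ref optional endpoint-ontology class URI.
#' @param units optional unit string.
#' @return the `mt_feature`.
#' @export
new_feature <- function(store, name, value_kind, has_source,
                        nominal_domain = NULL, endpoint_ref = NULL,
                        units = NULL) {
  if (!value_kind %in% c("numeric", "nominal", "string")) {
    mt_abort(sprintf("unknown value_kind '%s'", value_kind), "mt_schema_error")
  }
  if (is.null(has_source) || !nzchar(has_source)) {
    mt_abort("feature requires a has_source provenance URI", "mt_schema_error")
  }
  ft <- structure(list(
    uri = mt_uri(store, "feature"),
    name = name,
    value_kind = value_kind,
    nominal_domain = nominal_domain,
    has_source = has_source,
    endpoint_ref = endpoint_ref,
    units = units
  ), class = "mt_feature")
  store$features[[ft$uri]] <- ft
  ft
}

#' Assemble a dataset
#'
#' @param store an `mt_store`.
#' @param compounds list of `mt_compound`s (entry order preserved).
#' @param features list of `mt_feature`s.
#' @param values named list: compound uri -> named list feature uri ->
#'   value. Missing values are simply absent.
#' @param title dataset title.
#' @return the `mt_dataset` (not yet stored; see [store_dataset()]).
#' @export
new_dataset <- function(store, compounds = list(), features = list(),
                        values = list(), title = "dataset") {
  uris <- vapply(compounds, `[[`, character(1), "uri")
  if (anyDuplicated(uris)) {
    mt_abort("duplicate compound uris in dataset", "mt_schema_error")
  }
  d <- structure(list(
    uri = mt_uri(store, "dataset"),
    title = title,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    compounds = setNames(compounds, vapply(compounds, `[[`, character(1), "uri")),
    features = setNames(features, vapply(features, `[[`, character(1), "uri")),
    entries = values
  ), class = "mt_dataset")
  d$snapshot_hash <- dataset_snapshot_hash(d)
  d
}

# SHA-256 over the sorted canonical serialization of the dataset content.
dataset_snapshot_hash <- function(d) {
  lines <- character(0)
  for (cu in names(d$entries)) {
    ev <- d$entries[[cu]]
    for (fu in names(ev)) {
      v <- ev[[fu]]
      vs <- if (is.numeric(v)) num_chr(v) else as.character(v)
      lines <- c(lines, paste(cu, fu, vs, sep = "\t"))
    }
  }
  lines <- c(lines, paste0("compound\t", names(d$compounds)),
             paste0("feature\t", names(d$features)))
  digest::digest(paste(sort_c(lines), collapse = "\n"), algo = "sha256",
                 serialize = FALSE)
}

validate_dataset <- function(store, d) {
  if (anyDuplicated(names(d$compounds))) {
    mt_abort("duplicate compound uris in dataset", "mt_schema_error")
  }
  for (cu in names(d$entries)) {
    ev <- d$entries[[cu]]
    for (fu in names(ev)) {
      ft <- d$features[[fu]] %||% store$features[[fu]]
      if (is.null(ft)) {
        mt_abort(sprintf("entry references unknown feature <%s>", fu),
                 "mt_schema_error")
      }
      v <- ev[[fu]]
      if (is.null(v) || (length(v) == 1L && is.na(v))) next
      if (ft$value_kind == "numeric" && !is.numeric(v)) {
        mt_abort(sprintf("non-numeric value for numeric feature <%s>", fu),
                 "mt_schema_error")
      }
      if (ft$value_kind == "nominal" && !(as.character(v) %in% ft$nominal_domain)) {
        mt_abort(sprintf("value '%s' outside nominal domain of <%s>", v, fu),
                 "mt_schema_error")
      }
    }
  }
  invisible(TRUE)
}

#' Dataset CRUD
#'
#' Store, fetch, update and delete datasets under stable URIs. Updates
#' replace the content and refresh the snapshot hash; every mutation is
#' logged.
#'
#' @param store an `mt_store`.
#' @param d an `mt_dataset`.
#' @param uri dataset URI.
#' @return `store_dataset` the URI; `get_dataset` the dataset;
#'   `update_dataset`/`delete_dataset` invisibly.
#' @export
store_dataset <- function(store, d) {
  validate_dataset(store, d)
  d$snapshot_hash <- dataset_snapshot_hash(d)
  store$datasets[[d$uri]] <- d
  for (ft in d$features) store$features[[ft$uri]] <- ft
  mt_log(store, "store_dataset", d$uri)
  d$uri
}

#' @rdname store_dataset
#' @export
get_dataset <- function(store, uri) {
  d <- store$datasets[[uri]]
  if (is.null(d)) mt_abort(sprintf("dataset <%s> not found", uri), "mt_notfound_error")
  d
}

#' @rdname store_dataset
#' @export
update_dataset <- function(store, uri, d) {
  if (is.null(store$datasets[[uri]])) {
    mt_abort(sprintf("dataset <%s> not found", uri), "mt_notfound_error")
  }
  validate_dataset(store, d)
  d$uri <- uri
  d$snapshot_hash <- dataset_snapshot_hash(d)
  store$datasets[[uri]] <- d
  mt_log(store, "update_dataset", uri)
  invisible(uri)
}

#' @rdname store_dataset
#' @export
delete_dataset <- function(store, uri) {
  if (is.null(store$datasets[[uri]])) {
    mt_abort(sprintf("dataset <%s> not found", uri), "mt_notfound_error")
  }
  store$datasets[[uri]] <- NULL
  mt_log(store, "delete_dataset", uri)
  invisible(NULL)
}

#' Query datasets by compound and endpoint
#'
#' Returns every stored dataset containing the compound; when `endpoint`
#' is given, only datasets holding a feature whose `endpoint_ref` is that
#' ontology class or one of its descendants, together with the matching
#' measurements.
#'
#' @param store an `mt_store`.
#' @param compound optional compound URI.
#' @param endpoint optional endpoint class URI.
#' @return list of `list(dataset, measurements)`; `measurements` is a
#'   data.frame of `compound`, `feature`, `feature_name`, `value`.
#' @export
query_datasets <- function(store, compound = NULL, endpoint = NULL) {
  eps <- if (!is.null(endpoint)) endpoint_descendants(store, endpoint) else NULL
  out <- list()
  for (du in sort_c(names(store$datasets))) {
    d <- store$datasets[[du]]
    if (!is.null(compound) && !(compound %in% names(d$compounds))) next
    feats <- d$features
    if (!is.null(eps)) {
      keep <- vapply(feats, function(ft) {
        !is.null(ft$endpoint_ref) && ft$endpoint_ref %in% eps
      }, logical(1))
      if (!any(keep)) next
      feats <- feats[keep]
    }
    rows <- list()
    cus <- if (!is.null(compound)) compound else names(d$entries)
    for (cu in cus) {
      ev <- d$entries[[cu]]
      for (fu in intersect(names(ev), names(feats))) {
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cu, feature = fu, feature_name = feats[[fu]]$name,
          value = as.character(ev[[fu]]), stringsAsFactors = FALSE)
      }
    }
    out[[du]] <- list(
      dataset = du,
      measurements = if (length(rows)) do.call(rbind, rows) else
        data.frame(compound = character(0), feature = character(0),
                   feature_name = character(0), value = character(0))
    )
  }
  out
}

#' Free-text compound search
#'
#' Union of case-insensitive substring match on names, exact
#' canonical-SMILES match (the query is parsed and canonicalized when it
#' parses), and exact match on the stored InChI identifier. Results are
#' unique and URI-sorted.
#'
#' @param store an `mt_store`.
#' @param query search text.
#' @return list of `mt_compound`s.
#' @export
search_compounds <- function(store, query) {
  hits <- character(0)
  for (cp in store$compounds) {
    if (any(grepl(tolower(query), tolower(cp$names), fixed = TRUE))) {
      hits <- c(hits, cp$uri)
    }
    if (!is.null(cp$inchi) && identical(cp$inchi, query)) hits <- c(hits, cp$uri)
  }
  can <- tryCatch(canonical_smiles(parse_smiles(query)), error = function(e) NULL)
  if (!is.null(can)) {
    u <- store$smiles_index[can]
    if (!is.na(u)) hits <- c(hits, u)
  }
  lapply(sort_c(unique(hits)), function(u) store$compounds[[u]])
}

#' Ingest a training CSV (SMILES + binary activity)
#'
#' Reads the model-training upload format: a header `smiles,activity`
#' (case-insensitive) and one structure per row with a two-level class
#' label. Structures are parsed, canonicalized and deduplicated by
#' canonical form; duplicates with conflicting labels get a missing value
#' and a logged conflict warning. Unparsable rows are reported and
#' skipped, the run continues.
#'
#' @param store an `mt_store`.
#' @param path CSV file path.
#' @param endpoint_ref optional endpoint class URI for the activity
#'   feature.
#' @param title dataset title (defaults to the file name).
#' @return list with `dataset` (stored `mt_dataset`), `feature` (the
#'   nominal activity feature), `rejected` (data.frame `row`, `smiles`,
#'   `reason`) and `conflicts` (character vector of compound URIs whose
#'   labels conflicted).
#' @export
ingest_training_csv <- function(store, path, endpoint_ref = NULL,
                                title = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("smiles", "activity") %in% names(df))) {
    mt_abort("CSV header must contain 'smiles' and 'activity'", "mt_schema_error")
  }
  levels_seen <- sort_c(unique(as.character(df$activity)))
  if (length(levels_seen) > 2L) {
    mt_abort(sprintf("activity has %d levels; a binary domain is required",
                     length(levels_seen)), "mt_schema_error")
  }
  duri <- mt_uri(store, "dataset")
  ft <- new_feature(store, "activity", "nominal", has_source = duri,
                    nominal_domain = levels_seen, endpoint_ref = endpoint_ref)
  compounds <- list()
  values <- list()
  rejected <- data.frame(row = integer(0), smiles = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  conflicts <- character(0)
  for (i in seq_len(nrow(df))) {
    smi <- df$smiles[i]
    cp <- tryCatch(add_compound(store, smi, origin_inventory = title),
                   error = function(e) e)
    if (inherits(cp, "error")) {
      rejected <- rbind(rejected, data.frame(
        row = i, smiles = smi, reason = conditionMessage(cp),
        stringsAsFactors = FALSE))
      mt_log(store, "ingest_rejected_row", sprintf("row %d: %s", i, smi))
      next
    }
    lab <- as.character(df$activity[i])
    if (!is.null(values[[cp$uri]])) {
      old <- values[[cp$uri]][[ft$uri]]
      if (!is.null(old) && !is.na(old) && !identical(old, lab)) {
        values[[cp$uri]][[ft$uri]] <- NA_character_
        conflicts <- c(conflicts, cp$uri)
        mt_log(store, "ingest_label_conflict", cp$uri)
      }
      next
    }
    compounds[[length(compounds) + 1L]] <- cp
    values[[cp$uri]] <- setNames(list(lab), ft$uri)
  }
  d <- structure(list(
    uri = duri, title = title,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    compounds = setNames(compounds, vapply(compounds, `[[`, character(1), "uri")),
    features = setNames(list(ft), ft$uri),
    entries = values
  ), class = "mt_dataset")
  d$snapshot_hash <- dataset_snapshot_hash(d)
  store_dataset(store, d)
  list(dataset = store$datasets[[duri]], feature = ft,
       rejected = rejected, conflicts = unique(conflicts))
}

#' Write a dataset back to the training CSV format
#'
#' Inverse of [ingest_training_csv()] at the canonical-form level: one
#' row per compound with its canonical SMILES and the value of the given
#' nominal feature.
#'
#' @param d an `mt_dataset`.
#' @param feature_uri the activity feature URI.
#' @param path output path.
#' @export
write_training_csv <- function(d, feature_uri, path) {
  rows <- data.frame(smiles = character(0), activity = character(0),
                     stringsAsFactors = FALSE)
  for (cu in names(d$compounds)) {
    v <- d$entries[[cu]][[feature_uri]]
    rows <- rbind(rows, data.frame(
      smiles = d$compounds[[cu]]$canonical_smiles,
      activity = if (is.null(v)) NA_character_ else as.character(v),
      stringsAsFactors = FALSE))
  }
  write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
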