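# Store persistence: resources are written as Turtle documents plus a
# JSON manifest, so a later process session can reload the store and
# keep predicting with previously built models.

uri_filename <- function(uri) {
  gsub("(^_+|_+$)", "", gsub("[^A-Za-z0-9]+", "_", uri))
}

#' Save / load a store to a directory
#'
#' `store_save` writes every dataset, model, applicability-domain model
#' and validation record as a Turtle document, and the compounds,
#' features, registry triples and URI counters as a JSON manifest.
#' `store_load` reconstructs an equivalent store in a fresh session;
#' models are immediately usable for prediction.
#'
#' @param store an `mt_store`.
#' @param dir directory path.
#' @return `store_save` the directory (invisibly); `store_load` the
#'   reconstructed `mt_store`.
#' @export
store_save <- function(store, dir) {
  for (sub in c("datasets", "models", "admodels", "validations")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  manifest <- list(
    base_uri = store$base_uri,
    counters = as.list(store$counters),
    compounds = lapply(unname(store$compounds), function(cp)
      cp[c("uri", "canonical_smiles", "names", "inchi", "origin_inventory")]),
    features = lapply(unname(store$features), function(ft)
      ft[c("uri", "name", "value_kind", "nominal_domain", "has_source",
           "endpoint_ref", "units")]),
    triples = store$triples
  )
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             file.path(dir, "manifest.json"))
  save_set <- list(datasets = store$datasets, models = store$models,
                   admodels = store$ad_models, validations = store$validations)
  for (sub in names(save_set)) {
    for (res in save_set[[sub]]) {
      writeLines(rdf_write(res, "turtle"),
                 file.path(dir, sub, paste0(uri_filename(res$uri), ".ttl")))
    }
  }
  invisible(dir)
}

#' @rdname store_save
#' @export
store_load <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = FALSE)
  store <- new_store(manifest$base_uri)
  for (nm in names(manifest$counters)) {
    assign(nm, as.integer(manifest$counters[[nm]]), envir = store$counters)
  }
  for (cp in manifest$compounds) {
    cp <- structure(list(
      uri = cp$uri, canonical_smiles = cp$canonical_smiles,
      names = as.character(unlist(cp$names)),
      inchi = cp$inchi, origin_inventory = cp$origin_inventory
    ), class = "mt_compound")
    store$compounds[[cp$uri]] <- cp
    store$smiles_index[cp$canonical_smiles] <- cp$uri
  }
  for (ft in manifest$features) {
    ft <- structure(list(
      uri = ft$uri, name = ft$name, value_kind = ft$value_kind,
      nominal_domain = if (length(ft$nominal_domain))
        as.character(unlist(ft$nominal_domain)) else NULL,
      has_source = ft$has_source, endpoint_ref = ft$endpoint_ref,
      units = ft$units
    ), class = "mt_feature")
    store$features[[ft$uri]] <- ft
  }
  store$triples <- lapply(manifest$triples, function(tr)
    mt_triple(tr$s, tr$p, tr$o, tr$kind))
  loaders <- list(datasets = "datasets", models = "models",
                  admodels = "ad_models", validations = "validations")
  for (sub in names(loaders)) {
    files <- list.files(file.path(dir, sub), pattern = "\\.ttl$",
                        full.names = TRUE)
    for (f in sort_c(files)) {
      res <- rdf_read(f)
      store[[loaders[[sub]]]][[res$uri]] <- res
    }
  }
  store
}
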