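#' Build an applicability-domain model
#'
#' Two standard AD families are provided. `similarity`: the training
#' fingerprints are stored and a query is inside the domain when its
#' maximal Tanimoto similarity to the training set reaches the threshold
#' `t`. `range`: the observed `[min, max]` of each numeric descriptor
#' feature is stored and a query is inside when every descriptor falls
#' within its bounds.
#'
#' @param store an `mt_store`.
#' @param dataset training `mt_dataset` (or URI), non-empty.
#' @param method `"similarity"` or `"range"`.
#' @param params `similarity`: `t` in `[0,1]` (default 0.3),
#'   `max_path_atoms`, `L`; `range`: `features` (URIs of numeric
#'   features; defaults to all numeric features in the dataset).
#' @return an `mt_ad_model`, stored in the store.
#' @export
build_ad <- function(store, dataset, method = c("similarity", "range"),
                     params = list()) {
  method <- match.arg(method)
  d <- if (is.character(dataset)) get_dataset(store, dataset) else dataset
  if (length(d$compounds) == 0L) {
    mt_abort("cannot build an applicability domain on an empty dataset",
             "mt_degenerate_error")
  }
  ad <- list(
    uri = mt_uri(store, "admodel"),
    method = method,
    training_dataset = d$uri
  )
  if (method == "similarity") {
    t <- params$t %||% 0.3
    if (!is.numeric(t) || t < 0 || t > 1) {
      mt_abort("similarity threshold t must lie in [0,1]", "mt_param_error")
    }
    pv <- list(max_path_atoms = params$max_path_atoms %||% 7L,
               L = params$L %||% 1024L)
    smis <- vapply(d$compounds, `[[`, character(1), "canonical_smiles")
    smis <- sort_c(unname(smis))
    ad$threshold <- t
    ad$fp_params <- pv
    ad$smiles <- smis
    ad$fingerprints <- lapply(smis, function(s) knn_fingerprint(s, pv))
  } else {
    feats <- params$features
    if (is.null(feats)) {
      feats <- names(d$features)[vapply(d$features, function(ft)
        ft$value_kind == "numeric", logical(1))]
    }
    if (length(feats) == 0L) {
      mt_abort("range AD requires numeric descriptor features",
               "mt_degenerate_error")
    }
    bounds <- lapply(feats, function(fu) {
      vals <- unlist(lapply(d$entries, function(ev) {
        v <- ev[[fu]]
        if (is.null(v) || is.na(v)) NULL else as.numeric(v)
      }))
      if (is.null(vals)) c(NA_real_, NA_real_) else range(vals)
    })
    names(bounds) <- feats
    bounds <- bounds[!vapply(bounds, anyNA, logical(1))]
    if (length(bounds) == 0L) {
      mt_abort("range AD found no feature values", "mt_degenerate_error")
    }
    ad$bounds <- bounds
  }
  ad <- structure(ad, class = "mt_ad_model")
  store$ad_models[[ad$uri]] <- ad
  mt_log(store, "build_ad", ad$uri)
  ad
}

#' Apply an applicability-domain model to a compound
#'
#' @param store an `mt_store`.
#' @param ad an `mt_ad_model` or its URI.
#' @param compound an `mt_compound`, a compound URI, or a SMILES string.
#' @return list `inside` (logical), `score` (similarity method: maximal
#'   Tanimoto to the training set; range method: fraction of descriptors
#'   within bounds).
#' @export
apply_ad <- function(store, ad, compound) {
  if (is.character(ad)) ad <- store$ad_models[[ad]]
  if (is.null(ad)) mt_abort("AD model not found", "mt_notfound_error")
  smi <- if (inherits(compound, "mt_compound")) {
    compound$canonical_smiles
  } else if (is.character(compound) && !is.null(store$compounds[[compound]])) {
    store$compounds[[compound]]$canonical_smiles
  } else {
    compound
  }
  g <- parse_smiles(smi)   # raises mt_parse_error on bad structures
  if (ad$method == "similarity") {
    fp <- knn_fingerprint(canonical_smiles(g), ad$fp_params)
    score <- if (length(ad$fingerprints)) {
      max(vapply(ad$fingerprints, function(nf) tanimoto(fp, nf), numeric(1)))
    } else 0
    list(inside = score >= ad$threshold, score = score)
  } else {
    vals <- molecular_descriptors(g)
    # map bound feature URIs to descriptor names via the stored features
    inside_each <- vapply(names(ad$bounds), function(fu) {
      ft <- store$features[[fu]]
      nm <- if (!is.null(ft) && ft$name %in% DESCRIPTOR_NAMES) ft$name else NULL
      if (is.null(nm)) return(NA)
      b <- ad$bounds[[fu]]
      vals[[nm]] >= b[1] && vals[[nm]] <= b[2]
    }, logical(1))
    inside_each <- inside_each[!is.na(inside_each)]
    if (length(inside_each) == 0L) {
      mt_abort("range AD bounds reference no computable descriptor features",
               "mt_schema_error")
    }
    score <- mean(inside_each)
    list(inside = score == 1, score = score)
  }
}

#' @export
print.mt_ad_model <- function(x, ...) {
  cat(sprintf("<mt_ad_model %s (%s)>\n", x$uri, x$method))
  invisible(x)
}
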