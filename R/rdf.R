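# RDF exchange: datasets, features, models, AD models and validation
# records serialize to a fixed triple vocabulary and back, in Turtle and
# RDF/XML. Triples are emitted in sorted order so output is
# byte-deterministic; write -> read -> write is byte-identical.

pred_prefixed <- function(uri) {
  for (pfx in names(NS)) {
    if (startsWith(uri, NS[[pfx]])) {
      return(paste0(pfx, ":", substring(uri, nchar(NS[[pfx]]) + 1L)))
    }
  }
  NULL
}

# ---- resource -> triples --------------------------------------------------

resource_to_triples <- function(resource) {
  if (inherits(resource, "mt_dataset")) dataset_to_triples(resource)
  else if (inherits(resource, "mt_feature")) feature_to_triples(resource)
  else if (inherits(resource, "mt_model")) model_to_triples(resource)
  else if (inherits(resource, "mt_ad_model")) ad_to_triples(resource)
  else if (inherits(resource, "mt_validation_record")) validation_to_triples(resource)
  else mt_abort("unsupported resource kind for RDF serialization",
                "mt_schema_error")
}

feature_to_triples <- function(ft) {
  tr <- list(
    mt_triple(ft$uri, q("rdf", "type"), q("ot", "Feature")),
    mt_triple(ft$uri, q("dc", "title"), ft$name, "string"),
    mt_triple(ft$uri, q("ot", "valueKind"), ft$value_kind, "string"),
    mt_triple(ft$uri, q("ot", "hasSource"), ft$has_source)
  )
  for (v in ft$nominal_domain) {
    tr[[length(tr) + 1L]] <- mt_triple(ft$uri, q("ot", "acceptValue"), v, "string")
  }
  if (!is.null(ft$endpoint_ref)) {
    tr[[length(tr) + 1L]] <- mt_triple(ft$uri, q("ot", "endpoint"), ft$endpoint_ref)
  }
  if (!is.null(ft$units)) {
    tr[[length(tr) + 1L]] <- mt_triple(ft$uri, q("ot", "units"), ft$units, "string")
  }
  tr
}

compound_to_triples <- function(cp) {
  tr <- list(
    mt_triple(cp$uri, q("rdf", "type"), q("ot", "Compound")),
    mt_triple(cp$uri, q("ot", "smiles"), cp$canonical_smiles, "string"),
    mt_triple(cp$uri, q("ot", "originInventory"), cp$origin_inventory, "string")
  )
  for (nm in cp$names) {
    tr[[length(tr) + 1L]] <- mt_triple(cp$uri, q("rdfs", "label"), nm, "string")
  }
  if (!is.null(cp$inchi)) {
    tr[[length(tr) + 1L]] <- mt_triple(cp$uri, q("ot", "inchi"), cp$inchi, "string")
  }
  tr
}

dataset_to_triples <- function(d) {
  tr <- list(
    mt_triple(d$uri, q("rdf", "type"), q("ot", "Dataset")),
    mt_triple(d$uri, q("dc", "title"), d$title, "string"),
    mt_triple(d$uri, q("dc", "date"), d$created, "string"),
    mt_triple(d$uri, q("ot", "snapshotHash"), d$snapshot_hash, "string")
  )
  for (ft in d$features) tr <- c(tr, feature_to_triples(ft))
  for (cp in d$compounds) tr <- c(tr, compound_to_triples(cp))
  cus <- names(d$compounds)
  for (i in seq_along(cus)) {
    cu <- cus[i]
    e <- sprintf("%s/entry/%d", d$uri, i)
    tr <- c(tr, list(
      mt_triple(d$uri, q("ot", "dataEntry"), e),
      mt_triple(e, q("rdf", "type"), q("ot", "DataEntry")),
      mt_triple(e, q("ot", "entryIndex"), num_chr(i), "number"),
      mt_triple(e, q("ot", "compound"), cu)))
    ev <- d$entries[[cu]]
    fus <- sort_c(names(ev))
    for (j in seq_along(fus)) {
      fu <- fus[j]
      v <- ev[[fu]]
      vn <- sprintf("%s/value/%d", e, j)
      kind <- if (is.numeric(v)) "number" else "string"
      ov <- if (is.na(v)) "NA" else if (kind == "number") num_chr(v) else
        as.character(v)
      tr <- c(tr, list(
        mt_triple(e, q("ot", "values"), vn),
        mt_triple(vn, q("rdf", "type"), q("ot", "FeatureValue")),
        mt_triple(vn, q("ot", "feature"), fu),
        mt_triple(vn, q("ot", "value"), ov, if (is.na(v)) "string" else kind)))
    }
  }
  tr
}

param_triples <- function(uri, params) {
  tr <- list()
  for (nm in sort_c(names(params))) {
    p <- sprintf("%s/param/%s", uri, nm)
    v <- params[[nm]]
    tr <- c(tr, list(
      mt_triple(uri, q("ot", "parameter"), p),
      mt_triple(p, q("ot", "paramName"), nm, "string"),
      mt_triple(p, q("ot", "paramValue"),
                if (is.numeric(v)) num_chr(v) else as.character(v),
                if (is.numeric(v)) "number" else "string")))
  }
  tr
}

model_to_triples <- function(m) {
  tr <- list(
    mt_triple(m$uri, q("rdf", "type"), q("ot", "Model")),
    mt_triple(m$uri, q("ot", "modelKind"), m$kind, "string"),
    mt_triple(m$uri, q("ot", "algorithm"), m$algorithm),
    mt_triple(m$uri, q("ot", "trainingDataset"), m$training_dataset),
    mt_triple(m$uri, q("ot", "dependentVariables"), m$dependent_feature),
    mt_triple(m$uri, q("ot", "predictedVariables"), m$predicted_feature),
    mt_triple(m$uri, q("ot", "confidenceVariable"), m$confidence_feature)
  )
  for (fu in m$independent_features) {
    tr[[length(tr) + 1L]] <- mt_triple(m$uri, q("ot", "independentVariables"), fu)
  }
  if (!is.null(m$positive_class)) {
    tr[[length(tr) + 1L]] <- mt_triple(m$uri, q("ot", "positiveClass"),
                                       m$positive_class, "string")
  }
  for (cl in m$class_levels) {
    tr[[length(tr) + 1L]] <- mt_triple(m$uri, q("ot", "classLevel"), cl, "string")
  }
  tr <- c(tr, param_triples(m$uri, m$parameters))
  if (m$kind == "knn") {
    for (i in seq_along(m$state$smiles)) {
      nb <- sprintf("%s/neighbor/%d", m$uri, i)
      tr <- c(tr, list(
        mt_triple(m$uri, q("ot", "trainingInstance"), nb),
        mt_triple(nb, q("ot", "instanceIndex"), num_chr(i), "number"),
        mt_triple(nb, q("ot", "smiles"), m$state$smiles[i], "string"),
        mt_triple(nb, q("ot", "classValue"), m$state$labels[i], "string")))
    }
    for (lab in m$state$selected_labels) {
      tr[[length(tr) + 1L]] <- mt_triple(m$uri, q("ot", "selectedLabel"),
                                         lab, "string")
    }
  } else if (m$kind == "ols") {
    tr[[length(tr) + 1L]] <- mt_triple(m$uri, q("ot", "intercept"),
                                       num_chr(m$state$beta0), "number")
    for (i in seq_along(m$state$beta)) {
      cf <- sprintf("%s/coef/%d", m$uri, i)
      tr <- c(tr, list(
        mt_triple(m$uri, q("ot", "coefficient"), cf),
        mt_triple(cf, q("ot", "coefFeature"), names(m$state$beta)[i]),
        mt_triple(cf, q("ot", "coefValue"), num_chr(m$state$beta[i]), "number")))
    }
  }
  tr
}

ad_to_triples <- function(ad) {
  tr <- list(
    mt_triple(ad$uri, q("rdf", "type"), q("ot", "ADModel")),
    mt_triple(ad$uri, q("ot", "adMethod"), ad$method, "string"),
    mt_triple(ad$uri, q("ot", "trainingDataset"), ad$training_dataset)
  )
  if (ad$method == "similarity") {
    tr <- c(tr, list(
      mt_triple(ad$uri, q("ot", "threshold"), num_chr(ad$threshold), "number")))
    tr <- c(tr, param_triples(ad$uri, ad$fp_params))
    for (i in seq_along(ad$smiles)) {
      nb <- sprintf("%s/neighbor/%d", ad$uri, i)
      tr <- c(tr, list(
        mt_triple(ad$uri, q("ot", "trainingInstance"), nb),
        mt_triple(nb, q("ot", "instanceIndex"), num_chr(i), "number"),
        mt_triple(nb, q("ot", "smiles"), ad$smiles[i], "string")))
    }
  } else {
    for (i in seq_along(ad$bounds)) {
      bn <- sprintf("%s/bound/%d", ad$uri, i)
      b <- ad$bounds[[i]]
      tr <- c(tr, list(
        mt_triple(ad$uri, q("ot", "bound"), bn),
        mt_triple(bn, q("ot", "feature"), names(ad$bounds)[i]),
        mt_triple(bn, q("ot", "minValue"), num_chr(b[1]), "number"),
        mt_triple(bn, q("ot", "maxValue"), num_chr(b[2]), "number")))
    }
  }
  tr
}

metrics_to_triples <- function(uri, mtr) {
  tr <- list(mt_triple(uri, q("ot", "task"), mtr$task, "string"))
  scalars <- c("tp", "fp", "tn", "fn", "n_unpredicted", "percent_unpredicted",
               "precision", "recall", "f2", "fbeta", "auc", "mse", "rmse",
               "r2", "n_test")
  for (nm in scalars) {
    v <- mtr[[nm]]
    if (is.null(v)) next
    tr[[length(tr) + 1L]] <- mt_triple(uri, q("ot", paste0("metric_", nm)),
                                       num_chr(v), "number")
  }
  if (!is.null(mtr$positive)) {
    tr[[length(tr) + 1L]] <- mt_triple(uri, q("ot", "positiveClass"),
                                       mtr$positive, "string")
  }
  if (!is.null(mtr$roc)) {
    pts <- paste(sprintf("%s:%s:%s", num_chr(mtr$roc$threshold),
                         num_chr(mtr$roc$fpr), num_chr(mtr$roc$tpr)),
                 collapse = ";")
    tr[[length(tr) + 1L]] <- mt_triple(uri, q("ot", "rocPoints"), pts, "string")
  }
  tr
}

validation_to_triples <- function(rec) {
  tr <- list(
    mt_triple(rec$uri, q("rdf", "type"), q("ot", "Validation")),
    mt_triple(rec$uri, q("ot", "algorithmName"), rec$algorithm, "string"),
    mt_triple(rec$uri, q("ot", "algorithm"), rec$algorithm_uri),
    mt_triple(rec$uri, q("ot", "dependentVariables"), rec$dependent_feature),
    mt_triple(rec$uri, q("ot", "datasetHash"), rec$dataset_snapshot, "string"),
    mt_triple(rec$uri, q("ot", "fbeta"), num_chr(rec$fbeta), "number")
  )
  if (!is.null(rec$positive_class)) {
    tr[[length(tr) + 1L]] <- mt_triple(rec$uri, q("ot", "positiveClass"),
                                       rec$positive_class, "string")
  }
  for (fu in rec$independent_features) {
    tr[[length(tr) + 1L]] <- mt_triple(rec$uri, q("ot", "independentVariables"), fu)
  }
  for (mu in rec$models) {
    tr[[length(tr) + 1L]] <- mt_triple(rec$uri, q("ot", "model"), mu)
  }
  for (fi in rec$failed_folds) {
    tr[[length(tr) + 1L]] <- mt_triple(rec$uri, q("ot", "failedFold"),
                                       num_chr(fi), "number")
  }
  tr <- c(tr, param_triples(rec$uri, rec$params))

  plan <- rec$plan
  pn <- paste0(rec$uri, "/plan")
  tr <- c(tr, list(
    mt_triple(rec$uri, q("ot", "splitPlan"), pn),
    mt_triple(pn, q("ot", "dataset"), plan$dataset),
    mt_triple(pn, q("ot", "splitMethod"), plan$method, "string"),
    mt_triple(pn, q("ot", "stratified"),
              if (plan$stratified) "true" else "false", "string"),
    mt_triple(pn, q("ot", "randomSeed"), num_chr(plan$seed), "number")))
  if (!is.na(plan$k)) {
    tr[[length(tr) + 1L]] <- mt_triple(pn, q("ot", "foldCount"),
                                       num_chr(plan$k), "number")
  }
  if (!is.na(plan$test_fraction)) {
    tr[[length(tr) + 1L]] <- mt_triple(pn, q("ot", "testFraction"),
                                       num_chr(plan$test_fraction), "number")
  }
  if (!is.null(plan$label_feature)) {
    tr[[length(tr) + 1L]] <- mt_triple(pn, q("ot", "labelFeature"),
                                       plan$label_feature)
  }
  for (i in seq_along(plan$assignment)) {
    an <- sprintf("%s/assign/%d", pn, i)
    tr <- c(tr, list(
      mt_triple(pn, q("ot", "assignment"), an),
      mt_triple(an, q("ot", "assignIndex"), num_chr(i), "number"),
      mt_triple(an, q("ot", "compound"), names(plan$assignment)[i]),
      mt_triple(an, q("ot", "fold"), as.character(plan$assignment[i]), "string")))
  }
  for (fi in seq_along(rec$fold_metrics)) {
    mtr <- rec$fold_metrics[[fi]]
    if (is.null(mtr)) next
    fn <- sprintf("%s/fold/%d", rec$uri, fi)
    tr <- c(tr, list(
      mt_triple(rec$uri, q("ot", "foldResult"), fn),
      mt_triple(fn, q("ot", "foldIndex"), num_chr(fi), "number"),
      mt_triple(fn, q("ot", "trainHash"), rec$fold_hashes[[fi]][["train"]], "string"),
      mt_triple(fn, q("ot", "testHash"), rec$fold_hashes[[fi]][["test"]], "string")))
    tr <- c(tr, metrics_to_triples(fn, mtr))
    if (fi <= length(rec$fold_selected) && !is.null(rec$fold_selected[[fi]])) {
      for (lab in rec$fold_selected[[fi]]) {
        tr[[length(tr) + 1L]] <- mt_triple(fn, q("ot", "selectedLabel"),
                                           lab, "string")
      }
    }
  }
  agg <- paste0(rec$uri, "/aggregate")
  tr <- c(tr, list(mt_triple(rec$uri, q("ot", "aggregateResult"), agg)))
  tr <- c(tr, metrics_to_triples(agg, rec$aggregate))
  tr
}

# ---- serialization --------------------------------------------------------

sort_triples <- function(triples) {
  keys <- vapply(triples, function(tr) paste(tr$s, tr$p, tr$o, tr$kind,
                                             sep = "\r"), character(1))
  ord <- order_c(keys)
  triples[ord][!duplicated(keys[ord])]
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

ttl_unescape <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub('\\"', '"', x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

write_turtle <- function(triples) {
  triples <- sort_triples(triples)
  header <- sprintf("@prefix %s: <%s> .", names(NS), unname(NS))
  body <- vapply(triples, function(tr) {
    p <- pred_prefixed(tr$p) %||% sprintf("<%s>", tr$p)
    o <- if (tr$kind == "uri") {
      sprintf("<%s>", tr$o)
    } else if (tr$kind == "number") {
      sprintf('"%s"^^xsd:double', tr$o)
    } else {
      sprintf('"%s"', ttl_escape(tr$o))
    }
    sprintf("<%s> %s %s .", tr$s, p, o)
  }, character(1))
  paste(c(header, "", body, ""), collapse = "\n")
}

parse_turtle <- function(doc) {
  lines <- strsplit(doc, "\n", fixed = TRUE)[[1]]
  prefixes <- character(0)
  triples <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "@prefix")) {
      m <- regmatches(ln, regexec("^@prefix ([A-Za-z0-9]+): <([^>]*)> \\.$", ln))[[1]]
      if (length(m)) prefixes[m[2]] <- m[3]
      next
    }
    m <- regmatches(ln, regexec(
      "^<([^>]*)> ([A-Za-z0-9]+:[A-Za-z0-9_]+|<[^>]*>) (.*) \\.$", ln))[[1]]
    if (length(m) == 0L) {
      mt_abort(sprintf("cannot parse Turtle line: %s", ln), "mt_rdf_error")
    }
    s <- m[2]
    p <- if (startsWith(m[3], "<")) {
      substr(m[3], 2, nchar(m[3]) - 1L)
    } else {
      parts <- strsplit(m[3], ":", fixed = TRUE)[[1]]
      base <- prefixes[parts[1]]
      if (is.na(base)) mt_abort(sprintf("unknown prefix '%s'", parts[1]),
                                "mt_rdf_error")
      paste0(base, paste(parts[-1], collapse = ":"))
    }
    ostr <- m[4]
    if (startsWith(ostr, "<")) {
      triples[[length(triples) + 1L]] <-
        mt_triple(s, p, substr(ostr, 2, nchar(ostr) - 1L), "uri")
    } else if (grepl("^[A-Za-z0-9]+:[A-Za-z0-9_-]+$", ostr)) {
      parts <- strsplit(ostr, ":", fixed = TRUE)[[1]]
      base <- prefixes[parts[1]]
      if (is.na(base)) mt_abort(sprintf("unknown prefix '%s'", parts[1]),
                                "mt_rdf_error")
      triples[[length(triples) + 1L]] <-
        mt_triple(s, p, paste0(base, parts[2]), "uri")
    } else {
      lm <- regmatches(ostr, regexec(
        '^"((?:[^"\\\\]|\\\\.)*)"(\\^\\^xsd:double)?$', ostr))[[1]]
      if (length(lm) == 0L) {
        mt_abort(sprintf("cannot parse Turtle object: %s", ostr), "mt_rdf_error")
      }
      kind <- if (nzchar(lm[3])) "number" else "string"
      triples[[length(triples) + 1L]] <-
        mt_triple(s, p, ttl_unescape(lm[2]), kind)
    }
  }
  triples
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

write_rdfxml <- function(triples) {
  triples <- sort_triples(triples)
  subjects <- unique(vapply(triples, `[[`, character(1), "s"))
  ns_attrs <- paste(sprintf('xmlns:%s="%s"', names(NS), unname(NS)),
                    collapse = "\n         ")
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           sprintf("<rdf:RDF %s>", ns_attrs))
  for (s in subjects) {
    out <- c(out, sprintf('  <rdf:Description rdf:about="%s">', xml_escape(s)))
    for (tr in triples) {
      if (tr$s != s) next
      p <- pred_prefixed(tr$p)
      if (is.null(p)) {
        mt_abort(sprintf("predicate <%s> outside fixed vocabulary", tr$p),
                 "mt_rdf_error")
      }
      out <- c(out, if (tr$kind == "uri") {
        sprintf('    <%s rdf:resource="%s"/>', p, xml_escape(tr$o))
      } else if (tr$kind == "number") {
        sprintf('    <%s rdf:datatype="%sdouble">%s</%s>',
                p, NS[["xsd"]], xml_escape(tr$o), p)
      } else {
        sprintf("    <%s>%s</%s>", p, xml_escape(tr$o), p)
      })
    }
    out <- c(out, "  </rdf:Description>")
  }
  paste(c(out, "</rdf:RDF>", ""), collapse = "\n")
}

parse_rdfxml <- function(doc) {
  x <- xml2::read_xml(doc)
  nsmap <- xml2::xml_ns(x)
  triples <- list()
  for (desc in xml2::xml_children(x)) {
    s <- xml2::xml_attr(desc, "about")
    for (el in xml2::xml_children(desc)) {
      name <- xml2::xml_name(el, ns = nsmap)   # "pfx:local" wrt document map
      parts <- strsplit(name, ":", fixed = TRUE)[[1]]
      base <- unname(nsmap[parts[1]])
      p <- paste0(base, parts[2])
      res <- xml2::xml_attr(el, "resource")
      if (!is.na(res)) {
        triples[[length(triples) + 1L]] <- mt_triple(s, p, res, "uri")
      } else {
        dt <- xml2::xml_attr(el, "datatype")
        kind <- if (!is.na(dt) && grepl("double$", dt)) "number" else "string"
        triples[[length(triples) + 1L]] <-
          mt_triple(s, p, xml2::xml_text(el), kind)
      }
    }
  }
  triples
}

#' Write a resource as RDF
#'
#' Serializes a dataset, feature, model, applicability-domain model or
#' validation record to the package's fixed RDF vocabulary. Triples are
#' emitted in sorted order, so the same resource always produces
#' byte-identical output.
#'
#' @param resource the resource object.
#' @param format `"turtle"` or `"rdfxml"`.
#' @return a single character string (the document).
#' @export
rdf_write <- function(resource, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  triples <- resource_to_triples(resource)
  if (format == "turtle") write_turtle(triples) else write_rdfxml(triples)
}

#' Read a resource from RDF
#'
#' Parses a Turtle or RDF/XML document in the package vocabulary
#' (auto-detected) and reconstructs the resource. A feature without its
#' mandatory `hasSource` raises a schema error naming the subject URI.
#'
#' @param document document string (or path to a file containing it).
#' @return the reconstructed resource object.
#' @export
rdf_read <- function(document) {
  if (length(document) == 1L && !grepl("\n", document) && file.exists(document)) {
    document <- paste(readLines(document, warn = FALSE), collapse = "\n")
  }
  triples <- if (grepl("^\\s*<\\?xml", document)) parse_rdfxml(document)
             else parse_turtle(document)
  resource_from_triples(triples)
}

# ---- triples -> resource --------------------------------------------------

triple_index <- function(triples) {
  s <- vapply(triples, `[[`, character(1), "s")
  p <- vapply(triples, `[[`, character(1), "p")
  o <- vapply(triples, `[[`, character(1), "o")
  k <- vapply(triples, `[[`, character(1), "kind")
  data.frame(s = s, p = p, o = o, kind = k, stringsAsFactors = FALSE)
}

tidx_objs <- function(idx, s, p) idx$o[idx$s == s & idx$p == p]
tidx_obj <- function(idx, s, p) {
  v <- tidx_objs(idx, s, p)
  if (length(v) == 0L) NULL else v[1]
}
tidx_num <- function(idx, s, p) {
  v <- tidx_obj(idx, s, p)
  if (is.null(v)) NULL
  else if (v == "NA") NA_real_
  else as.numeric(v)
}

resource_from_triples <- function(triples) {
  idx <- triple_index(triples)
  types <- idx[idx$p == q("rdf", "type"), ]
  root_of <- function(cls) types$s[types$o == q("ot", cls)]
  if (length(root_of("Dataset"))) return(dataset_from_triples(idx, root_of("Dataset")[1]))
  if (length(root_of("Validation"))) return(validation_from_triples(idx, root_of("Validation")[1]))
  if (length(root_of("ADModel"))) return(ad_from_triples(idx, root_of("ADModel")[1]))
  if (length(root_of("Model"))) return(model_from_triples(idx, root_of("Model")[1]))
  if (length(root_of("Feature"))) return(feature_from_triples(idx, root_of("Feature")[1]))
  mt_abort("document contains no recognised resource", "mt_rdf_error")
}

feature_from_triples <- function(idx, uri) {
  src <- tidx_obj(idx, uri, q("ot", "hasSource"))
  if (is.null(src)) {
    mt_abort(sprintf("schema error: feature <%s> lacks mandatory hasSource", uri),
             "mt_rdf_schema_error")
  }
  dom <- sort_c(tidx_objs(idx, uri, q("ot", "acceptValue")))
  structure(list(
    uri = uri,
    name = tidx_obj(idx, uri, q("dc", "title")),
    value_kind = tidx_obj(idx, uri, q("ot", "valueKind")),
    nominal_domain = if (length(dom)) dom else NULL,
    has_source = src,
    endpoint_ref = tidx_obj(idx, uri, q("ot", "endpoint")),
    units = tidx_obj(idx, uri, q("ot", "units"))
  ), class = "mt_feature")
}

compound_from_triples <- function(idx, uri) {
  structure(list(
    uri = uri,
    canonical_smiles = tidx_obj(idx, uri, q("ot", "smiles")),
    names = sort_c(tidx_objs(idx, uri, q("rdfs", "label"))),
    inchi = tidx_obj(idx, uri, q("ot", "inchi")),
    origin_inventory = tidx_obj(idx, uri, q("ot", "originInventory"))
  ), class = "mt_compound")
}

dataset_from_triples <- function(idx, uri) {
  types <- idx[idx$p == q("rdf", "type"), ]
  fus <- sort_c(types$s[types$o == q("ot", "Feature")])
  features <- setNames(lapply(fus, function(fu) feature_from_triples(idx, fu)), fus)
  entries_uris <- tidx_objs(idx, uri, q("ot", "dataEntry"))
  eidx <- vapply(entries_uris, function(e) tidx_num(idx, e, q("ot", "entryIndex")),
                 numeric(1))
  entries_uris <- entries_uris[order(eidx)]
  cus <- vapply(entries_uris, function(e) tidx_obj(idx, e, q("ot", "compound")),
                character(1))
  compounds <- setNames(lapply(cus, function(cu) compound_from_triples(idx, cu)),
                        cus)
  entries <- list()
  for (ei in seq_along(entries_uris)) {
    e <- entries_uris[ei]
    vals <- list()
    for (vn in tidx_objs(idx, e, q("ot", "values"))) {
      fu <- tidx_obj(idx, vn, q("ot", "feature"))
      raw <- idx[idx$s == vn & idx$p == q("ot", "value"), ]
      v <- if (raw$kind[1] == "number") as.numeric(raw$o[1]) else {
        if (raw$o[1] == "NA") NA_character_ else raw$o[1]
      }
      vals[[fu]] <- v
    }
    entries[[cus[ei]]] <- vals[sort_c(names(vals))]
  }
  d <- structure(list(
    uri = uri,
    title = tidx_obj(idx, uri, q("dc", "title")),
    created = tidx_obj(idx, uri, q("dc", "date")),
    compounds = compounds,
    features = features,
    entries = entries
  ), class = "mt_dataset")
  d$snapshot_hash <- dataset_snapshot_hash(d)
  stored <- tidx_obj(idx, uri, q("ot", "snapshotHash"))
  if (!is.null(stored) && !identical(stored, d$snapshot_hash)) {
    mt_abort(sprintf("snapshot hash mismatch for <%s>", uri), "mt_rdf_error")
  }
  d
}

params_from_triples <- function(idx, uri) {
  out <- list()
  for (p in tidx_objs(idx, uri, q("ot", "parameter"))) {
    nm <- tidx_obj(idx, p, q("ot", "paramName"))
    raw <- idx[idx$s == p & idx$p == q("ot", "paramValue"), ]
    out[[nm]] <- if (raw$kind[1] == "number") as.numeric(raw$o[1]) else raw$o[1]
  }
  out[sort_c(names(out))]
}

model_from_triples <- function(idx, uri) {
  kind <- tidx_obj(idx, uri, q("ot", "modelKind"))
  params <- params_from_triples(idx, uri)
  cls <- sort_c(tidx_objs(idx, uri, q("ot", "classLevel")))
  m <- structure(list(
    uri = uri,
    kind = kind,
    algorithm = tidx_obj(idx, uri, q("ot", "algorithm")),
    parameters = params,
    training_dataset = tidx_obj(idx, uri, q("ot", "trainingDataset")),
    independent_features = sort_c(tidx_objs(idx, uri, q("ot", "independentVariables"))),
    dependent_feature = tidx_obj(idx, uri, q("ot", "dependentVariables")),
    predicted_feature = tidx_obj(idx, uri, q("ot", "predictedVariables")),
    confidence_feature = tidx_obj(idx, uri, q("ot", "confidenceVariable")),
    positive_class = tidx_obj(idx, uri, q("ot", "positiveClass")),
    class_levels = if (length(cls)) cls else NULL
  ), class = "mt_model")
  if (identical(kind, "knn")) {
    nbs <- tidx_objs(idx, uri, q("ot", "trainingInstance"))
    ni <- vapply(nbs, function(nb) tidx_num(idx, nb, q("ot", "instanceIndex")),
                 numeric(1))
    nbs <- nbs[order(ni)]
    smis <- vapply(nbs, function(nb) tidx_obj(idx, nb, q("ot", "smiles")),
                   character(1))
    labs <- vapply(nbs, function(nb) tidx_obj(idx, nb, q("ot", "classValue")),
                   character(1))
    sel <- sort_c(tidx_objs(idx, uri, q("ot", "selectedLabel")))
    if (length(sel) == 0L) sel <- NULL
    pv <- m$parameters
    m$state <- list(
      smiles = unname(smis), labels = unname(labs),
      fingerprints = lapply(unname(smis), function(s) knn_fingerprint(s, pv, sel)),
      selected_labels = sel)
  } else if (identical(kind, "ols")) {
    cfs <- tidx_objs(idx, uri, q("ot", "coefficient"))
    feats <- vapply(cfs, function(cf) tidx_obj(idx, cf, q("ot", "coefFeature")),
                    character(1))
    vals <- vapply(cfs, function(cf) tidx_num(idx, cf, q("ot", "coefValue")),
                   numeric(1))
    ord <- order_c(feats)
    m$independent_features <- unname(feats[ord])
    m$state <- list(beta0 = tidx_num(idx, uri, q("ot", "intercept")),
                    beta = setNames(unname(vals[ord]), unname(feats[ord])))
  }
  m
}

ad_from_triples <- function(idx, uri) {
  method <- tidx_obj(idx, uri, q("ot", "adMethod"))
  ad <- list(uri = uri, method = method,
             training_dataset = tidx_obj(idx, uri, q("ot", "trainingDataset")))
  if (method == "similarity") {
    ad$threshold <- tidx_num(idx, uri, q("ot", "threshold"))
    ad$fp_params <- params_from_triples(idx, uri)
    nbs <- tidx_objs(idx, uri, q("ot", "trainingInstance"))
    ni <- vapply(nbs, function(nb) tidx_num(idx, nb, q("ot", "instanceIndex")),
                 numeric(1))
    nbs <- nbs[order(ni)]
    ad$smiles <- unname(vapply(nbs, function(nb)
      tidx_obj(idx, nb, q("ot", "smiles")), character(1)))
    ad$fingerprints <- lapply(ad$smiles, function(s)
      knn_fingerprint(s, ad$fp_params))
  } else {
    bns <- sort_c(tidx_objs(idx, uri, q("ot", "bound")))
    bounds <- lapply(bns, function(bn) {
      c(tidx_num(idx, bn, q("ot", "minValue")),
        tidx_num(idx, bn, q("ot", "maxValue")))
    })
    names(bounds) <- vapply(bns, function(bn)
      tidx_obj(idx, bn, q("ot", "feature")), character(1))
    ad$bounds <- bounds[sort_c(names(bounds))]
  }
  structure(ad, class = "mt_ad_model")
}

metrics_from_triples <- function(idx, uri) {
  task <- tidx_obj(idx, uri, q("ot", "task"))
  out <- list(task = task, positive = tidx_obj(idx, uri, q("ot", "positiveClass")))
  scalars <- c("tp", "fp", "tn", "fn", "n_unpredicted", "percent_unpredicted",
               "precision", "recall", "f2", "fbeta", "auc", "mse", "rmse",
               "r2", "n_test")
  ints <- c("tp", "fp", "tn", "fn", "n_unpredicted", "n_test")
  for (nm in scalars) {
    v <- tidx_num(idx, uri, q("ot", paste0("metric_", nm)))
    if (!is.null(v)) out[[nm]] <- if (nm %in% ints) as.integer(v) else v
  }
  roc <- tidx_obj(idx, uri, q("ot", "rocPoints"))
  if (!is.null(roc)) {
    parts <- strsplit(strsplit(roc, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    out$roc <- data.frame(
      threshold = as.numeric(vapply(parts, `[`, character(1), 1)),
      fpr = as.numeric(vapply(parts, `[`, character(1), 2)),
      tpr = as.numeric(vapply(parts, `[`, character(1), 3)))
  }
  structure(out, class = "mt_metrics")
}

validation_from_triples <- function(idx, uri) {
  pn <- tidx_obj(idx, uri, q("ot", "splitPlan"))
  ans <- tidx_objs(idx, pn, q("ot", "assignment"))
  ai <- vapply(ans, function(an) tidx_num(idx, an, q("ot", "assignIndex")),
               numeric(1))
  ans <- ans[order(ai)]
  folds_raw <- vapply(ans, function(an) tidx_obj(idx, an, q("ot", "fold")),
                      character(1))
  cus <- vapply(ans, function(an) tidx_obj(idx, an, q("ot", "compound")),
                character(1))
  method <- tidx_obj(idx, pn, q("ot", "splitMethod"))
  assignment <- if (method == "train_test") {
    setNames(folds_raw, cus)
  } else {
    setNames(as.integer(folds_raw), cus)
  }
  plan <- structure(list(
    dataset = tidx_obj(idx, pn, q("ot", "dataset")),
    method = method,
    k = { v <- tidx_num(idx, pn, q("ot", "foldCount"))
          if (is.null(v)) NA_integer_ else as.integer(v) },
    stratified = identical(tidx_obj(idx, pn, q("ot", "stratified")), "true"),
    seed = as.integer(tidx_num(idx, pn, q("ot", "randomSeed"))),
    label_feature = tidx_obj(idx, pn, q("ot", "labelFeature")),
    test_fraction = { v <- tidx_num(idx, pn, q("ot", "testFraction"))
                      if (is.null(v)) NA_real_ else v },
    assignment = assignment
  ), class = "mt_split_plan")

  fns <- tidx_objs(idx, uri, q("ot", "foldResult"))
  fis <- vapply(fns, function(fn) tidx_num(idx, fn, q("ot", "foldIndex")),
                numeric(1))
  fns <- fns[order(fis)]; fis <- sort(fis)
  fold_metrics <- list(); fold_hashes <- list(); fold_selected <- list()
  for (j in seq_along(fns)) {
    fi <- as.integer(fis[j])
    fold_metrics[[fi]] <- metrics_from_triples(idx, fns[j])
    fold_hashes[[fi]] <- c(train = tidx_obj(idx, fns[j], q("ot", "trainHash")),
                           test = tidx_obj(idx, fns[j], q("ot", "testHash")))
    sel <- sort_c(tidx_objs(idx, fns[j], q("ot", "selectedLabel")))
    if (length(sel)) fold_selected[[fi]] <- sel
  }
  indep <- sort_c(tidx_objs(idx, uri, q("ot", "independentVariables")))
  structure(list(
    uri = uri,
    algorithm = tidx_obj(idx, uri, q("ot", "algorithmName")),
    algorithm_uri = tidx_obj(idx, uri, q("ot", "algorithm")),
    params = params_from_triples(idx, uri),
    plan = plan,
    dependent_feature = tidx_obj(idx, uri, q("ot", "dependentVariables")),
    independent_features = if (length(indep)) indep else NULL,
    positive_class = tidx_obj(idx, uri, q("ot", "positiveClass")),
    fbeta = tidx_num(idx, uri, q("ot", "fbeta")),
    dataset_snapshot = tidx_obj(idx, uri, q("ot", "datasetHash")),
    fold_hashes = fold_hashes,
    fold_metrics = fold_metrics,
    fold_selected = fold_selected,
    failed_folds = as.integer(sort(as.numeric(
      tidx_objs(idx, uri, q("ot", "failedFold"))))),
    models = sort_c(tidx_objs(idx, uri, q("ot", "model"))),
    aggregate = metrics_from_triples(idx, paste0(uri, "/aggregate")),
    per_fold_summary = summarize_folds(fold_metrics)
  ), class = "mt_validation_record")
}
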