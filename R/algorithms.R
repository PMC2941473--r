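OTA_CATEGORIES <- c("DescriptorCalculation", "Classification", "Regression",
                    "FeatureSelection", "DataCleanup")

new_algorithm <- function(store, name, category, parameters = list(),
                          metadata = list()) {
  if (!category %in% OTA_CATEGORIES) {
    mt_abort(sprintf("unknown algorithm category '%s'", category),
             "mt_schema_error")
  }
  for (p in parameters) {
    if (is.null(p$default)) {
      mt_abort(sprintf("parameter '%s' of algorithm '%s' has no default",
                       p$name, name), "mt_schema_error")
    }
  }
  alg <- structure(list(
    uri = paste0(store$base_uri, "algorithm/", name),
    name = name, category = category,
    parameters = parameters, metadata = metadata
  ), class = "mt_algorithm")
  store$algorithms[[alg$uri]] <- alg
  alg
}

# Template metadata follows the uniform algorithm description table:
# semantic input/output, formats, user parameters, reporting info,
# background and performance notes.
register_builtin_algorithms <- function(store) {
  for (dn in DESCRIPTOR_NAMES) {
    new_algorithm(store, paste0("descriptor-", dn), "DescriptorCalculation",
      metadata = list(
        input = "chemical structure", output = paste("descriptor", dn),
        input_format = "dataset", output_format = "dataset (augmented)",
        descriptor_type = "physico-chemical",
        reporting = "numeric descriptor column",
        background = "fixed 2D graph descriptor",
        performance = "linear in atoms"))
  }
  new_algorithm(store, "descriptors", "DescriptorCalculation",
    metadata = list(
      input = "chemical structure", output = "all six physico-chemical descriptors",
      input_format = "dataset", output_format = "dataset (augmented)",
      descriptor_type = "physico-chemical",
      reporting = "numeric descriptor columns",
      background = "MW, heavy atoms, cyclomatic rings, aromatic atoms, HBD, HBA",
      performance = "linear in atoms"))
  new_algorithm(store, "fingerprint", "DescriptorCalculation",
    parameters = list(
      list(name = "max_path_atoms", type = "integer", default = 7L,
           range = c(1L, 12L)),
      list(name = "L", type = "integer", default = 1024L, range = c(64L, 65536L))),
    metadata = list(
      input = "chemical structure", output = "binary substructure (path) features",
      input_format = "dataset", output_format = "dataset (augmented)",
      descriptor_type = "sub-structural",
      reporting = "one binary column per path label present",
      background = "linear-path enumeration, FNV-1a hashed bits",
      performance = "exponential in max_path_atoms, fast for small molecules"))
  new_algorithm(store, "chi2", "FeatureSelection",
    parameters = list(list(name = "top_k", type = "integer", default = 10L,
                           range = c(1L, NA))),
    metadata = list(
      input = "binary features + binary class", output = "ranked feature list",
      input_format = "dataset", output_format = "ranking table",
      selection_type = "class-sensitive filter",
      reporting = "chi-squared score per feature",
      background = "2x2 contingency chi-squared, no continuity correction",
      performance = "linear in features"))
  new_algorithm(store, "knn", "Classification",
    parameters = list(
      list(name = "k", type = "integer", default = 5L, range = c(1L, NA)),
      list(name = "s_min", type = "numeric", default = 0.3, range = c(0, 1)),
      list(name = "max_path_atoms", type = "integer", default = 7L,
           range = c(1L, 12L)),
      list(name = "L", type = "integer", default = 1024L, range = c(64L, 65536L)),
      list(name = "select_top_k", type = "integer", default = 0L,
           range = c(0L, NA))),
    metadata = list(
      input = "training structures, training activities",
      output = "prediction model",
      input_format = "dataset", output_format = "model",
      learning_type = "lazy",
      applicability = "similarity cutoff s_min gates predictions",
      confidence = "winning class weight share",
      interpretability = "nearest neighbours with similarities",
      background = "similarity-weighted k-nearest-neighbour vote on path fingerprints",
      performance = "prediction linear in training-set size"))
  new_algorithm(store, "ols", "Regression",
    metadata = list(
      input = "training descriptors, numeric target", output = "prediction model",
      input_format = "dataset", output_format = "model",
      learning_type = "eager",
      confidence = "not estimated",
      interpretability = "linear coefficients",
      background = "least-squares fit with intercept; minimal-norm solution on rank-deficient designs",
      performance = "cubic in features"))
  invisible(NULL)
}

algorithm_by_name <- function(store, name) {
  alg <- store$algorithms[[paste0(store$base_uri, "algorithm/", name)]]
  if (is.null(alg)) mt_abort(sprintf("unknown algorithm '%s'", name),
                             "mt_notfound_error")
  alg
}

algorithm_defaults <- function(alg) {
  vals <- lapply(alg$parameters, `[[`, "default")
  setNames(vals, vapply(alg$parameters, `[[`, character(1), "name"))
}

merge_params <- function(alg, params) {
  out <- algorithm_defaults(alg)
  for (nm in names(params)) out[[nm]] <- params[[nm]]
  out
}

#' Run a descriptor-calculation algorithm over a dataset
#'
#' Adds new features, one per computed descriptor (or per path label for
#' the fingerprint algorithm), with `has_source` set to the algorithm
#' URI. Existing entries are untouched and re-running the same algorithm
#' is idempotent: a feature with the same name and source is reused, not
#' duplicated. Compounds whose structure fails to parse get missing
#' values and a logged note.
#'
#' @param store an `mt_store`.
#' @param dataset an `mt_dataset` or its URI.
#' @param algorithm algorithm name (`descriptors`, `descriptor-MW`, ...,
#'   `fingerprint`) or `mt_algorithm`.
#' @param params named list overriding parameter defaults.
#' @return the augmented `mt_dataset` (also stored back under its URI).
#' @export
run_descriptor_algorithm <- function(store, dataset, algorithm, params = list()) {
  d <- if (is.character(dataset)) get_dataset(store, dataset) else dataset
  alg <- if (is.character(algorithm)) algorithm_by_name(store, algorithm) else algorithm
  if (alg$category != "DescriptorCalculation") {
    mt_abort(sprintf("'%s' is not a descriptor-calculation algorithm", alg$name),
             "mt_schema_error")
  }
  pv <- merge_params(alg, params)

  existing_by_key <- setNames(
    names(d$features),
    vapply(d$features, function(ft) paste(ft$name, ft$has_source), character(1)))
  get_feature <- function(name, kind) {
    key <- paste(name, alg$uri)
    fu <- existing_by_key[key]
    if (!is.na(fu)) return(d$features[[fu]])
    ft <- new_feature(store, name, kind, has_source = alg$uri,
                      nominal_domain = if (kind == "nominal") c("0", "1"))
    d$features[[ft$uri]] <<- ft
    existing_by_key[key] <<- ft$uri
    ft
  }

  for (cu in names(d$compounds)) {
    cp <- d$compounds[[cu]]
    g <- tryCatch(parse_smiles(cp$canonical_smiles), error = function(e) NULL)
    if (is.null(g)) {
      mt_log(store, "descriptor_skip_unparseable", cu)
      next
    }
    if (alg$name == "fingerprint") {
      fp <- path_fingerprint(g, pv$max_path_atoms, pv$L)
      for (lab in names(fp$labels)) {
        ft <- get_feature(paste0("fp:", lab), "numeric")
        d$entries[[cu]][[ft$uri]] <- 1
      }
    } else {
      vals <- molecular_descriptors(g)
      wanted <- if (alg$name == "descriptors") DESCRIPTOR_NAMES else
        sub("^descriptor-", "", alg$name)
      for (dn in wanted) {
        ft <- get_feature(dn, "numeric")
        d$entries[[cu]][[ft$uri]] <- unname(vals[[dn]])
      }
    }
  }
  d$snapshot_hash <- dataset_snapshot_hash(d)
  store$datasets[[d$uri]] <- d
  mt_log(store, "run_descriptor_algorithm", paste(alg$uri, d$uri))
  d
}

#' Rank binary features by chi-squared association with a binary class
#'
#' For each feature, the 2x2 contingency table of feature presence
#' against class is scored by the chi-squared statistic (no continuity
#' correction). Features with a zero margin (present in all compounds or
#' in none) score 0 by convention. Ranking is by descending score, ties
#' broken by feature URI.
#'
#' @param dataset an `mt_dataset`.
#' @param binary_features character vector of feature URIs (presence =
#'   value present and non-zero).
#' @param target_feature URI of the two-level nominal target.
#' @param top_k number of features to return.
#' @return data.frame `feature`, `score`, best first.
#' @export
chi2_rank_features <- function(dataset, binary_features, target_feature,
                               top_k = length(binary_features)) {
  cls <- vapply(names(dataset$entries), function(cu) {
    v <- dataset$entries[[cu]][[target_feature]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  keep <- !is.na(cls)
  cls <- cls[keep]
  levs <- sort_c(unique(cls))
  if (length(levs) < 2L) {
    mt_abort("chi-squared ranking requires both classes present",
             "mt_degenerate_error")
  }
  y <- cls == levs[2]
  n <- length(y)
  scores <- vapply(binary_features, function(fu) {
    x <- vapply(names(dataset$entries)[keep], function(cu) {
      v <- dataset$entries[[cu]][[fu]]
      !is.null(v) && !is.na(v) && as.numeric(v) != 0
    }, logical(1))
    chi2_2x2(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
  }, numeric(1))
  ord <- order_c(-scores, binary_features)
  out <- data.frame(feature = binary_features[ord], score = scores[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  head(out, top_k)
}

# chi-squared of a 2x2 table, Sum (O-E)^2/E, no continuity correction;
# any zero margin yields 0.
chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(0)
  o <- c(a, b, c, d)
  e <- c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  sum((o - e)^2 / e)
}

# ---- k-NN classifier ------------------------------------------------------

#' Build a similarity-weighted k-nearest-neighbour classifier
#'
#' A lazy learner over path fingerprints: training stores each compound's
#' fingerprint and class label. At prediction time neighbours with
#' Tanimoto similarity `>= s_min` vote, weighted by similarity (see
#' [predict_with_model()]). With `select_top_k > 0`, path-label features
#' are first ranked by chi-squared on the training data and fingerprints
#' are restricted to the selected labels.
#'
#' @param store an `mt_store`.
#' @param dataset training `mt_dataset` (or URI).
#' @param dependent_feature URI of the two-level nominal activity
#'   feature.
#' @param params named list: `k` (default 5), `s_min` (default 0.3),
#'   `max_path_atoms`, `L`, `select_top_k`.
#' @param positive_class label treated as the positive class for ROC
#'   scores; defaults to the first nominal-domain level in C-locale
#'   order.
#' @return an `mt_model`, stored in the store.
#' @export
build_knn_classifier <- function(store, dataset, dependent_feature,
                                 params = list(), positive_class = NULL) {
  d <- if (is.character(dataset)) get_dataset(store, dataset) else dataset
  alg <- algorithm_by_name(store, "knn")
  pv <- merge_params(alg, params)

  labs <- character(0); smis <- character(0)
  for (cu in names(d$compounds)) {
    v <- d$entries[[cu]][[dependent_feature]]
    if (is.null(v) || is.na(v)) next
    labs <- c(labs, as.character(v))
    smis <- c(smis, d$compounds[[cu]]$canonical_smiles)
  }
  if (length(labs) < 2L || length(unique(labs)) < 2L) {
    mt_abort("k-NN training requires at least two compounds and both classes",
             "mt_degenerate_error")
  }
  if (pv$k > length(labs)) {
    mt_log(store, "knn_k_truncated",
           sprintf("k=%d > n=%d, truncated", pv$k, length(labs)))
    pv$k <- length(labs)
  }
  # deterministic neighbour order: canonical SMILES
  ord <- order_c(smis)
  smis <- smis[ord]; labs <- labs[ord]

  selected <- NULL
  if (pv$select_top_k > 0L) {
    selected <- knn_select_labels(smis, labs, pv)
  }
  fps <- lapply(smis, function(s) knn_fingerprint(s, pv, selected))

  if (is.null(positive_class)) positive_class <- sort_c(unique(labs))[1]
  m <- structure(list(
    uri = mt_uri(store, "model"),
    kind = "knn",
    algorithm = alg$uri,
    parameters = pv,
    training_dataset = d$uri,
    independent_features = character(0),  # computed from structure
    dependent_feature = dependent_feature,
    positive_class = positive_class,
    class_levels = sort_c(unique(labs)),
    state = list(smiles = smis, labels = labs, fingerprints = fps,
                 selected_labels = selected)
  ), class = "mt_model")
  m <- attach_prediction_features(store, m)
  store$models[[m$uri]] <- m
  mt_log(store, "build_knn_classifier", m$uri)
  m
}

knn_select_labels <- function(smis, labs, pv) {
  counts <- lapply(smis, function(s) cached_path_labels(s, pv$max_path_atoms))
  all_labels <- sort_c(unique(unlist(lapply(counts, names))))
  pres <- vapply(counts, function(ct) all_labels %in% names(ct),
                 logical(length(all_labels)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = length(all_labels))
  levs <- sort_c(unique(labs))
  y <- labs == levs[2]
  scores <- apply(pres, 1, function(x) {
    chi2_2x2(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
  })
  ord <- order_c(-scores, all_labels)
  all_labels[ord][seq_len(min(pv$select_top_k, length(all_labels)))]
}

# Path-label enumeration is a pure function of (canonical SMILES,
# max_path_atoms); memoised because cross-validation recomputes the same
# training fingerprints fold after fold.
.mt_fp_cache <- new.env(parent = emptyenv())

cached_path_labels <- function(smiles, max_path_atoms) {
  key <- paste0(max_path_atoms, "\r", smiles)
  labels <- get0(key, envir = .mt_fp_cache, ifnotfound = NULL)
  if (is.null(labels)) {
    labels <- enumerate_path_labels(parse_smiles(smiles), max_path_atoms)
    assign(key, labels, envir = .mt_fp_cache)
  }
  labels
}

knn_fingerprint <- function(smiles, pv, selected = NULL) {
  labels <- cached_path_labels(smiles, pv$max_path_atoms)
  if (!is.null(selected)) labels <- labels[names(labels) %in% selected]
  fingerprint_from_labels(labels, pv$L)
}

attach_prediction_features <- function(store, m) {
  kind <- if (m$kind == "knn") "nominal" else "numeric"
  pf <- new_feature(store, paste0("predicted-", m$uri), kind,
                    has_source = m$uri,
                    nominal_domain = if (kind == "nominal") m$class_levels)
  cf <- new_feature(store, paste0("confidence-", m$uri), "numeric",
                    has_source = m$uri)
  m$predicted_feature <- pf$uri
  m$confidence_feature <- cf$uri
  m
}

# ---- OLS regressor --------------------------------------------------------

#' Build an ordinary-least-squares regression model
#'
#' Least-squares fit with intercept of a numeric target on numeric
#' features. Rows with any missing value are dropped (and counted).
#' Rank-deficient designs get the minimal-norm least-squares solution
#' (SVD pseudoinverse), logged.
#'
#' @param store an `mt_store`.
#' @param dataset training `mt_dataset` (or URI).
#' @param independent_features URIs of numeric predictor features (must
#'   be present in the training dataset).
#' @param dependent_feature URI of the numeric target feature.
#' @return an `mt_model` with state `beta0` (intercept) and `beta`
#'   (named coefficient vector).
#' @export
build_ols_regressor <- function(store, dataset, independent_features,
                                dependent_feature) {
  d <- if (is.character(dataset)) get_dataset(store, dataset) else dataset
  alg <- algorithm_by_name(store, "ols")
  missing_f <- setdiff(independent_features, names(d$features))
  if (length(missing_f)) {
    mt_abort(sprintf("independent feature(s) not in training dataset: %s",
                     paste(missing_f, collapse = ", ")), "mt_schema_error")
  }
  rows <- list(); y <- numeric(0)
  dropped <- 0L
  for (cu in names(d$compounds)) {
    ev <- d$entries[[cu]]
    x <- vapply(independent_features, function(fu) {
      v <- ev[[fu]]
      if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    yv <- ev[[dependent_feature]]
    yv <- if (is.null(yv) || is.na(yv)) NA_real_ else as.numeric(yv)
    if (anyNA(x) || is.na(yv)) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- x
    y <- c(y, yv)
  }
  if (length(rows) == 0L) {
    mt_abort("no complete rows for OLS fit", "mt_degenerate_error")
  }
  X <- cbind(1, do.call(rbind, rows))
  fit <- ols_minimal_norm(X, y)
  if (fit$rank < ncol(X)) {
    mt_log(store, "ols_rank_deficient",
           sprintf("rank %d < %d columns; minimal-norm solution used",
                   fit$rank, ncol(X)))
  }
  beta <- fit$coef
  m <- structure(list(
    uri = mt_uri(store, "model"),
    kind = "ols",
    algorithm = alg$uri,
    parameters = list(),
    training_dataset = d$uri,
    independent_features = independent_features,
    dependent_feature = dependent_feature,
    positive_class = NULL,
    class_levels = NULL,
    state = list(beta0 = beta[1],
                 beta = setNames(beta[-1], independent_features),
                 n_used = length(y), n_dropped = dropped)
  ), class = "mt_model")
  m$kind <- "ols"
  m <- attach_prediction_features(store, m)
  store$models[[m$uri]] <- m
  mt_log(store, "build_ols_regressor", m$uri)
  m
}

# Minimal-norm least squares via SVD pseudoinverse.
ols_minimal_norm <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > tol * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  coef <- sv$v %*% (dinv * (t(sv$u) %*% y))
  list(coef = as.numeric(coef), rank = sum(keep))
}

# ---- prediction -----------------------------------------------------------

#' Similarity-weighted k-NN vote
#'
#' The voting core of the lazy classifier, exposed for testing and
#' interpretability: neighbours with similarity `>= s_min` are ranked by
#' similarity (stable order on ties), the top `k` vote with weight equal
#' to their similarity, and the class with the larger summed weight
#' wins. Confidence is the winning weight share; the ROC score is the
#' positive class's weight share. A weight tie goes to the class with
#' the larger prior, then to the C-locale smaller label.
#'
#' @param sims similarities of the query to each training instance.
#' @param labels training class labels, aligned with `sims`.
#' @param k number of voting neighbours.
#' @param s_min similarity gate; with no neighbour at or above it the
#'   query is unpredicted.
#' @param positive positive class label for the ROC score.
#' @param priors optional named training-class counts for tie breaking.
#' @return list `unpredicted`, `value`, `confidence`, `score`,
#'   `neighbours` (indices of the voting neighbours).
#' @export
knn_weighted_vote <- function(sims, labels, k, s_min, positive,
                              priors = table(labels)) {
  elig <- which(sims >= s_min)
  if (length(elig) == 0L) {
    return(list(unpredicted = TRUE, value = NA_character_,
                confidence = NA_real_, score = NA_real_,
                neighbours = integer(0)))
  }
  elig <- elig[order(-sims[elig])]   # stable: ties keep input order
  nn <- elig[seq_len(min(k, length(elig)))]
  w <- tapply(sims[nn], labels[nn], sum)
  w <- w[!is.na(w)]
  best <- names(w)[w == max(w)]
  if (length(best) > 1L) {
    pr <- priors[best]
    best <- best[pr == max(pr)]
    best <- sort_c(best)[1]
  }
  total <- sum(w)
  pos_w <- if (positive %in% names(w)) w[[positive]] else 0
  list(unpredicted = FALSE, value = best,
       confidence = unname(w[[best]] / total),
       score = pos_w / total, neighbours = nn)
}

#' Predict a dataset with a trained model
#'
#' k-NN: neighbours with Tanimoto similarity `>= s_min` are ranked by
#' similarity (ties by canonical SMILES) and the top `k` vote with weight
#' equal to their similarity. The prediction is the class with the larger
#' summed weight; confidence is the winning weight divided by the total
#' weight; the numeric ROC score is the positive class's weight share. A
#' weighted-vote tie goes to the class with the larger training prior,
#' then to the C-locale smaller label. A compound with no neighbour at or
#' above `s_min` is UNPREDICTED: its value is missing and it is listed in
#' the result's `unpredicted` set. OLS: the linear predictor, with an
#' empty confidence column.
#'
#' @param store an `mt_store`.
#' @param model an `mt_model` or its URI.
#' @param dataset an `mt_dataset` (or URI) of query compounds; missing
#'   independent features are resolved via their `has_source` algorithm
#'   (see [resolve_features()]).
#' @return a list: `dataset` (augmented with the model's predicted and
#'   confidence features), `predictions` (data.frame `compound`, `value`,
#'   `confidence`, `score`, `unpredicted`), `supporting` (per-compound
#'   nearest-neighbour tables for k-NN, coefficients for OLS).
#' @export
predict_with_model <- function(store, model, dataset) {
  m <- if (is.character(model)) store$models[[model]] else model
  if (is.null(m)) mt_abort("model not found", "mt_notfound_error")
  d <- if (is.character(dataset)) get_dataset(store, dataset) else dataset
  d <- resolve_features(store, m, d)
  for (fu in c(m$predicted_feature, m$confidence_feature)) {
    if (is.null(d$features[[fu]])) d$features[[fu]] <- store$features[[fu]]
  }

  preds <- data.frame(compound = names(d$compounds), value = NA_character_,
                      confidence = NA_real_, score = NA_real_,
                      unpredicted = FALSE, stringsAsFactors = FALSE)
  supporting <- list()

  if (m$kind == "knn") {
    pv <- m$parameters
    priors <- table(m$state$labels)
    for (i in seq_len(nrow(preds))) {
      cu <- preds$compound[i]
      fp <- knn_fingerprint(d$compounds[[cu]]$canonical_smiles, pv,
                            m$state$selected_labels)
      sims <- vapply(m$state$fingerprints, function(nf) tanimoto(fp, nf),
                     numeric(1))
      vote <- knn_weighted_vote(sims, m$state$labels, pv$k, pv$s_min,
                                m$positive_class, priors)
      if (vote$unpredicted) {
        preds$unpredicted[i] <- TRUE
        next
      }
      preds$value[i] <- vote$value
      preds$confidence[i] <- vote$confidence
      preds$score[i] <- vote$score
      supporting[[cu]] <- data.frame(
        neighbour = m$state$smiles[vote$neighbours],
        label = m$state$labels[vote$neighbours],
        similarity = sims[vote$neighbours], stringsAsFactors = FALSE)
      d$entries[[cu]][[m$predicted_feature]] <- vote$value
      d$entries[[cu]][[m$confidence_feature]] <- vote$confidence
    }
  } else if (m$kind == "ols") {
    for (i in seq_len(nrow(preds))) {
      cu <- preds$compound[i]
      ev <- d$entries[[cu]]
      x <- vapply(m$independent_features, function(fu) {
        v <- ev[[fu]]
        if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
      }, numeric(1))
      if (anyNA(x)) {
        preds$unpredicted[i] <- TRUE
        next
      }
      yhat <- m$state$beta0 + sum(m$state$beta * x)
      preds$value[i] <- num_chr(yhat)
      preds$score[i] <- yhat
      d$entries[[cu]][[m$predicted_feature]] <- yhat
    }
    supporting$coefficients <- c(`(Intercept)` = m$state$beta0, m$state$beta)
  } else {
    mt_abort(sprintf("unknown model kind '%s'", m$kind), "mt_schema_error")
  }
  d$snapshot_hash <- dataset_snapshot_hash(d)
  list(dataset = d, predictions = preds, supporting = supporting, model = m$uri)
}

#' @export
print.mt_model <- function(x, ...) {
  cat(sprintf("<mt_model %s (%s), trained on %s>\n", x$uri, x$kind,
              x$training_dataset))
  invisible(x)
}
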