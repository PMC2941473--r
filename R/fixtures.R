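# Synthetic toy-QSAR data with a planted structure-activity signal.
# Molecules are assembled from a small fragment grammar (alkyl chains,
# branches, pendant benzene rings); positives additionally carry the
# toxicophore fragment -- by default the charged nitro group, grafted
# through a methylene carbon so bracket/charge parsing is exercised.
# The grammar guarantees valence-clean molecules of at most ~20 heavy
# atoms (sub-second fingerprints).

#' Specification for a synthetic fixture
#'
#' @param n number of compounds (>= 4).
#' @param toxicophore SMILES fragment appended to positives (default the
#'   charged nitro group attached via a carbon).
#' @param prevalence fraction of molecules carrying the toxicophore.
#' @param noise label-flip probability epsilon in `[0, 0.5]`
#'   (classification).
#' @param seed random seed.
#' @param beta regression coefficients `c(beta0, beta_count, beta_mw)`
#'   for `y = beta0 + beta_count * toxicophore_count + beta_mw * (MW/100)
#'   + N(0, sigma)`.
#' @param sigma regression noise standard deviation.
#' @return a list of class `mt_fixture_spec`.
#' @export
fixture_spec <- function(n = 200L, toxicophore = "C[N+](=O)[O-]",
                         prevalence = 0.5, noise = 0, seed = 1L,
                         beta = c(0.5, 2, 1), sigma = 0.2) {
  if (n < 4L) mt_abort("fixture needs n >= 4", "mt_param_error")
  if (prevalence < 0 || prevalence > 1) {
    mt_abort("prevalence must lie in [0,1]", "mt_param_error")
  }
  if (noise < 0 || noise > 0.5) {
    mt_abort("label noise must lie in [0, 0.5]", "mt_param_error")
  }
  structure(list(n = as.integer(n), toxicophore = toxicophore,
                 prevalence = prevalence, noise = noise,
                 seed = as.integer(seed), beta = beta, sigma = sigma),
            class = "mt_fixture_spec")
}

# Random valence-clean skeleton: an alkyl chain with optional methyl
# branches and at most one pendant phenyl, <= 14 skeleton heavy atoms
# (plus <= 4 toxicophore atoms stays under 20).
random_skeleton <- function() {
  len <- sample(2:8, 1)
  units <- character(len)
  phenyl_used <- FALSE
  for (i in seq_len(len)) {
    r <- runif(1)
    mid <- i > 1L && i < len   # ether O never terminal: keeps the
                               # attachment point a carbon
    if (r < 0.20 && i > 1L) {
      units[i] <- "C(C)"
    } else if (r < 0.30 && !phenyl_used && i > 1L) {
      units[i] <- "C(c1ccccc1)"
      phenyl_used <- TRUE
    } else if (r < 0.42 && mid) {
      units[i] <- "O"
    } else {
      units[i] <- "C"
    }
  }
  paste(units, collapse = "")
}

#' Generate a classification fixture
#'
#' Draws `n` molecules from the fragment grammar; a `prevalence`
#' fraction carries the toxicophore. The label is
#' "carries-toxicophore", independently flipped with probability
#' `noise`; with `noise = 0` the labels match substructure presence
#' exactly, so the planted signal is fully detectable. Deterministic
#' given the seed.
#'
#' @param store an `mt_store`.
#' @param spec an `mt_fixture_spec`.
#' @param csv_path optional path; when given, the dataset is also
#'   written as a training CSV (`smiles,activity`).
#' @param endpoint_ref optional endpoint class URI for the activity
#'   feature.
#' @return list `dataset` (stored `mt_dataset`), `feature` (activity
#'   feature), `truth` (data.frame `smiles`, `has_toxicophore`,
#'   `label`), `csv_path`.
#' @export
generate_classification_fixture <- function(store, spec = fixture_spec(),
                                            csv_path = NULL,
                                            endpoint_ref = NULL) {
  rows <- with_seed(spec$seed, {
    n_pos <- round(spec$n * spec$prevalence)
    has_tox <- sample(c(rep(TRUE, n_pos), rep(FALSE, spec$n - n_pos)))
    smiles <- character(spec$n)
    for (i in seq_len(spec$n)) {
      smiles[i] <- if (has_tox[i]) {
        paste0(random_skeleton(), spec$toxicophore)
      } else {
        random_skeleton()
      }
    }
    flip <- runif(spec$n) < spec$noise
    label <- ifelse(xor(has_tox, flip), "active", "inactive")
    data.frame(smiles = smiles, has_toxicophore = has_tox, label = label,
               stringsAsFactors = FALSE)
  })

  duri <- mt_uri(store, "dataset")
  ft <- new_feature(store, "activity", "nominal", has_source = duri,
                    nominal_domain = c("active", "inactive"),
                    endpoint_ref = endpoint_ref)
  compounds <- list(); values <- list()
  for (i in seq_len(nrow(rows))) {
    cp <- add_compound(store, rows$smiles[i], origin_inventory = "fixture")
    if (!is.null(values[[cp$uri]])) next   # rare duplicate structure
    compounds[[length(compounds) + 1L]] <- cp
    values[[cp$uri]] <- setNames(list(rows$label[i]), ft$uri)
  }
  d <- structure(list(
    uri = duri, title = sprintf("synthetic classification fixture n=%d", spec$n),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    compounds = setNames(compounds, vapply(compounds, `[[`, character(1), "uri")),
    features = setNames(list(ft), ft$uri),
    entries = values
  ), class = "mt_dataset")
  d$snapshot_hash <- dataset_snapshot_hash(d)
  store_dataset(store, d)
  if (!is.null(csv_path)) {
    write.csv(rows[, c("smiles", "label")] |>
                setNames(c("smiles", "activity")),
              csv_path, row.names = FALSE, quote = TRUE)
  }
  list(dataset = store$datasets[[duri]], feature = ft, truth = rows,
       csv_path = csv_path)
}

#' Generate a regression fixture
#'
#' Same molecule grammar; the numeric target is
#' `y = beta0 + beta_count * (toxicophore count) + beta_mw * (MW / 100)
#' + N(0, sigma)`. With `sigma = 0` an OLS fit on (count, MW/100)
#' recovers the planted coefficients exactly.
#'
#' @param store an `mt_store`.
#' @param spec an `mt_fixture_spec`.
#' @return list `dataset` (stored, with numeric features
#'   `toxicophore_count`, `mw100` and target `y`), `features` (named
#'   URIs), `truth` (data.frame with generator internals).
#' @export
generate_regression_fixture <- function(store, spec = fixture_spec()) {
  rows <- with_seed(spec$seed, {
    n_pos <- round(spec$n * spec$prevalence)
    count <- sample(c(rep(1L, n_pos), rep(0L, spec$n - n_pos)))
    smiles <- character(spec$n)
    for (i in seq_len(spec$n)) {
      smiles[i] <- if (count[i] > 0L) {
        paste0(random_skeleton(), spec$toxicophore)
      } else {
        random_skeleton()
      }
    }
    eps <- rnorm(spec$n, 0, spec$sigma)
    data.frame(smiles = smiles, count = count, eps = eps,
               stringsAsFactors = FALSE)
  })
  duri <- mt_uri(store, "dataset")
  f_count <- new_feature(store, "toxicophore_count", "numeric", has_source = duri)
  f_mw <- new_feature(store, "mw100", "numeric", has_source = duri)
  f_y <- new_feature(store, "y", "numeric", has_source = duri)
  compounds <- list(); values <- list()
  for (i in seq_len(nrow(rows))) {
    cp <- add_compound(store, rows$smiles[i], origin_inventory = "fixture")
    if (!is.null(values[[cp$uri]])) next
    mw <- molecular_descriptors(parse_smiles(cp$canonical_smiles))[["MW"]]
    y <- spec$beta[1] + spec$beta[2] * rows$count[i] +
      spec$beta[3] * (mw / 100) + rows$eps[i]
    compounds[[length(compounds) + 1L]] <- cp
    values[[cp$uri]] <- setNames(list(rows$count[i], mw / 100, y),
                                 c(f_count$uri, f_mw$uri, f_y$uri))
  }
  d <- structure(list(
    uri = duri, title = sprintf("synthetic regression fixture n=%d", spec$n),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    compounds = setNames(compounds, vapply(compounds, `[[`, character(1), "uri")),
    features = setNames(list(f_count, f_mw, f_y),
                        c(f_count$uri, f_mw$uri, f_y$uri)),
    entries = values
  ), class = "mt_dataset")
  d$snapshot_hash <- dataset_snapshot_hash(d)
  store_dataset(store, d)
  list(dataset = store$datasets[[duri]],
       features = c(count = f_count$uri, mw100 = f_mw$uri, y = f_y$uri),
       truth = rows)
}
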