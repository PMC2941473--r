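make_demo_dataset <- function(store, smiles = c("CCO", "CCN", "CCC"),
                              vals = c(1.2, 3.4, 5.6)) {
  cps <- lapply(smiles, function(s) add_compound(store, s))
  duri_placeholder <- paste0(store$base_uri, "algorithm/descriptor-MW")
  ft <- new_feature(store, "LogP", "numeric", has_source = duri_placeholder)
  values <- setNames(lapply(vals, function(v) setNames(list(v), ft$uri)),
                     vapply(cps, `[[`, character(1), "uri"))
  new_dataset(store, cps, list(ft), values, title = "demo")
}

test_that("dataset CRUD: store/fetch identity, update, delete", {
  store <- new_store()
  d <- make_demo_dataset(store)
  uri <- store_dataset(store, d)
  got <- get_dataset(store, uri)
  expect_identical(got$snapshot_hash, d$snapshot_hash)
  expect_identical(names(got$compounds), names(d$compounds))

  # update replaces content and refreshes the hash iff content changes
  d2 <- got
  d2$entries[[1]][[1]] <- 9.9
  update_dataset(store, uri, d2)
  expect_false(identical(get_dataset(store, uri)$snapshot_hash,
                         d$snapshot_hash))
  update_dataset(store, uri, d2)   # no content change
  expect_identical(get_dataset(store, uri)$snapshot_hash,
                   dataset_snapshot_hash(d2))

  delete_dataset(store, uri)
  expect_error(get_dataset(store, uri), class = "mt_notfound_error")
  expect_error(update_dataset(store, uri, d2), class = "mt_notfound_error")
})

test_that("nominal-domain violations are rejected", {
  store <- new_store()
  cp <- add_compound(store, "CCO")
  ft <- new_feature(store, "activity", "nominal", has_source = "urn:x",
                    nominal_domain = c("active", "inactive"))
  d <- new_dataset(store, list(cp), list(ft),
                   setNames(list(setNames(list("active"), ft$uri)), cp$uri))
  uri <- store_dataset(store, d)
  bad <- d
  bad$entries[[cp$uri]][[ft$uri]] <- "maybe"
  expect_error(update_dataset(store, uri, bad), "nominal domain",
               class = "mt_schema_error")
})

test_that("training CSV ingestion parses, canonicalizes and deduplicates", {
  tw <- tiny_store_with_csv(c("CCO,active", "CCN,inactive",
                              "CCC,active", "CCCC,inactive"))
  expect_equal(length(tw$ingest$dataset$compounds), 4L)
  expect_equal(length(tw$ingest$dataset$features), 1L)
  expect_equal(tw$ingest$feature$value_kind, "nominal")
  expect_identical(tw$ingest$feature$has_source, tw$ingest$dataset$uri)
  expect_equal(nrow(tw$ingest$rejected), 0L)

  # a bad SMILES row is reported, the run continues
  tw2 <- tiny_store_with_csv(c("CCO,active", "C1CC,active",
                               "CCN,inactive", "CCC,inactive"))
  expect_equal(length(tw2$ingest$dataset$compounds), 3L)
  expect_equal(nrow(tw2$ingest$rejected), 1L)
  expect_equal(tw2$ingest$rejected$row, 2L)

  # duplicate structures merge; conflicting labels become missing
  tw3 <- tiny_store_with_csv(c("CCO,active", "OCC,inactive", "CC,inactive"))
  expect_equal(length(tw3$ingest$dataset$compounds), 2L)
  expect_equal(length(tw3$ingest$conflicts), 1L)
  cu <- tw3$ingest$conflicts[1]
  expect_true(is.na(tw3$ingest$dataset$entries[[cu]][[tw3$ingest$feature$uri]]))

  # duplicates with agreeing labels do not conflict
  tw4 <- tiny_store_with_csv(c("CCO,active", "OCC,active", "CC,inactive"))
  expect_equal(length(tw4$ingest$conflicts), 0L)

  # more than two activity levels is an error
  expect_error(
    tiny_store_with_csv(c("CCO,a", "CCN,b", "CCC,c")),
    "binary", class = "mt_schema_error")
})

test_that("ingest(write_csv(d)) reproduces the dataset at canonical level", {
  tw <- tiny_store_with_csv(c("OCC,active", "CCN,inactive", "C(C)C,active"))
  d <- tw$ingest$dataset
  out <- tempfile(fileext = ".csv")
  write_training_csv(d, tw$ingest$feature$uri, out)
  store2 <- new_store()
  ing2 <- ingest_training_csv(store2, out)
  smi1 <- sort(vapply(d$compounds, `[[`, character(1), "canonical_smiles"))
  smi2 <- sort(vapply(ing2$dataset$compounds, `[[`, character(1),
                      "canonical_smiles"))
  expect_identical(unname(smi1), unname(smi2))
  lab1 <- sort(unlist(lapply(d$entries, function(e) unlist(e))))
  lab2 <- sort(unlist(lapply(ing2$dataset$entries, function(e) unlist(e))))
  expect_identical(unname(lab1), unname(lab2))
})

test_that("dataset query filters by compound and endpoint closure", {
  store <- new_store()
  ont <- build_endpoint_ontology(store)
  hh <- ont$subclasses[["human health effects"]]
  muta <- ont$leaves[["Mutagenicity"]]
  carc <- ont$leaves[["Carcinogenicity study"]]

  cp <- add_compound(store, "CCO")
  other <- add_compound(store, "CCN")
  mk <- function(ep, cps) {
    ft <- new_feature(store, "act", "nominal", has_source = "urn:x",
                      nominal_domain = c("p", "n"), endpoint_ref = ep)
    d <- new_dataset(store, cps, list(ft),
                     setNames(lapply(cps, function(z)
                       setNames(list("p"), ft$uri)),
                       vapply(cps, `[[`, character(1), "uri")))
    store_dataset(store, d)
  }
  d1 <- mk(muta, list(cp))
  d2 <- mk(carc, list(cp))
  d3 <- mk(muta, list(other))

  hits <- query_datasets(store, compound = cp$uri)
  expect_setequal(names(hits), c(d1, d2))

  # endpoint = parent class matches features tagged with child classes
  hits_hh <- query_datasets(store, compound = cp$uri, endpoint = hh)
  expect_setequal(names(hits_hh), c(d1, d2))
  hits_muta <- query_datasets(store, compound = cp$uri, endpoint = muta)
  expect_setequal(names(hits_muta), d1)
  # filtered results are a subset of unfiltered ones
  expect_true(all(names(hits_muta) %in% names(hits)))
  # excluding filter yields empty result, not an error
  eco <- ont$subclasses[["ecotoxic effects"]]
  expect_length(query_datasets(store, compound = cp$uri, endpoint = eco), 0L)
})

test_that("free-text compound search unions names, SMILES and InChI", {
  store <- new_store()
  add_compound(store, "CCO", names = c("ethanol", "ethyl alcohol"),
               inchi = "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3")
  add_compound(store, "CCN", names = "ethylamine")

  expect_equal(length(search_compounds(store, "Ethan")), 1L)
  hits <- search_compounds(store, "OCC")   # canonical equality
  expect_equal(length(hits), 1L)
  expect_identical(hits[[1]]$canonical_smiles, "CCO")
  expect_equal(length(search_compounds(store,
    "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3")), 1L)
  # matching by both name and structure returns the compound once
  add_compound(store, "CCC", names = "CCO-like solvent")
  expect_equal(length(search_compounds(store, "CCO")), 2L)  # union, no dup
})

test_that("minimal SDF V2000 reading", {
  sdf <- c(
    "ethanol", "  synthetic", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0",
    "M  END",
    "> <LogP>", "-0.31", "",
    "$$$$")
  f <- tempfile(fileext = ".sdf")
  writeLines(sdf, f)
  store <- new_store()
  d <- read_sdf_v2000_minimal(store, f)
  expect_equal(length(d$compounds), 1L)
  expect_identical(d$compounds[[1]]$canonical_smiles, "CCO")
  expect_equal(length(d$features), 1L)
  ft <- d$features[[1]]
  expect_identical(ft$name, "LogP")
  expect_identical(ft$value_kind, "numeric")
  expect_identical(ft$has_source, d$uri)
  expect_equal(d$entries[[1]][[ft$uri]], -0.31)

  # counts line declaring more bonds than present
  bad <- sdf
  bad[4] <- "  3  3  0  0  0  0  0  0  0  0999 V2000"
  writeLines(bad, f)
  expect_error(read_sdf_v2000_minimal(new_store(), f), class = "mt_sdf_error")

  # bond referencing a missing atom
  bad2 <- sdf
  bad2[9] <- "  2  7  1  0"
  writeLines(bad2, f)
  expect_error(read_sdf_v2000_minimal(new_store(), f), "missing atom",
               class = "mt_sdf_error")

  # two records sharing a structure are deduplicated by canonical form
  rec2 <- sdf
  rec2[1] <- "ethanol again"
  rec2[5:7] <- c(
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0")
  writeLines(c(sdf, rec2), f)
  store3 <- new_store()
  d3 <- read_sdf_v2000_minimal(store3, f)
  expect_equal(length(d3$compounds), 1L)
})
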