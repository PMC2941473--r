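test_that("descriptor algorithms augment datasets with provenance", {
  tw <- tiny_store_with_csv(c("CCO,active", "CCN,inactive", "CCC,active",
                              "CC,inactive"))
  store <- tw$store
  d <- run_descriptor_algorithm(store, tw$ingest$dataset, "descriptor-MW")
  mw_alg <- paste0(store$base_uri, "algorithm/descriptor-MW")
  new_f <- Filter(function(ft) identical(ft$has_source, mw_alg), d$features)
  expect_length(new_f, 1L)
  fu <- new_f[[1]]$uri
  vals <- vapply(d$entries, function(e) e[[fu]], numeric(1))
  expect_length(vals, 4L)
  expect_equal(unname(vals[1]), 46.069, tolerance = 1e-6)
  # original activity entries untouched
  expect_true(all(vapply(d$entries, function(e)
    tw$ingest$feature$uri %in% names(e), logical(1))))

  # idempotent re-run: no duplicate features
  d2 <- run_descriptor_algorithm(store, d, "descriptor-MW")
  expect_length(Filter(function(ft) identical(ft$has_source, mw_alg),
                       d2$features), 1L)
  expect_identical(d2$snapshot_hash, d$snapshot_hash)

  # fingerprint algorithm over benzene: one feature per distinct path label
  tw2 <- tiny_store_with_csv(c("c1ccccc1,active", "CC,inactive"))
  d3 <- run_descriptor_algorithm(tw2$store, tw2$ingest$dataset, "fingerprint")
  benz_labels <- names(path_fingerprint(parse_smiles("c1ccccc1"))$labels)
  fp_alg <- paste0(tw2$store$base_uri, "algorithm/fingerprint")
  fp_feats <- Filter(function(ft) identical(ft$has_source, fp_alg), d3$features)
  got <- sub("^fp:", "", vapply(fp_feats, `[[`, character(1), "name"))
  expect_true(all(benz_labels %in% got))
  # benzene simple paths: one distinct label per length 1..6
  expect_length(benz_labels, 6L)
})

test_that("chi-squared ranking matches the direct-formula oracle", {
  # planted feature present in 10/10 actives, 0/10 inactives: chi2 = 20
  store <- new_store()
  cps <- lapply(sprintf("%sC", strrep("C", 1:20)), function(s)
    add_compound(store, s))
  target <- new_feature(store, "act", "nominal", has_source = "urn:x",
                        nominal_domain = c("a", "i"))
  f_planted <- new_feature(store, "planted", "numeric", has_source = "urn:x")
  f_indep <- new_feature(store, "indep", "numeric", has_source = "urn:x")
  f_all <- new_feature(store, "allon", "numeric", has_source = "urn:x")
  values <- list()
  for (i in seq_along(cps)) {
    active <- i <= 10
    v <- setNames(list(if (active) "a" else "i"), target$uri)
    if (active) v[[f_planted$uri]] <- 1
    if (i %% 2 == 0) v[[f_indep$uri]] <- 1   # same prevalence in both classes
    v[[f_all$uri]] <- 1
    values[[cps[[i]]$uri]] <- v
  }
  d <- new_dataset(store, cps, list(target, f_planted, f_indep, f_all), values)
  rk <- chi2_rank_features(d, c(f_planted$uri, f_indep$uri, f_all$uri),
                           target$uri, top_k = 3)
  expect_identical(rk$feature[1], f_planted$uri)
  expect_equal(rk$score[1], 20)
  expect_equal(rk$score[rk$feature == f_indep$uri], 0)
  expect_equal(rk$score[rk$feature == f_all$uri], 0)   # zero margin
  expect_true(all(rk$score >= 0))

  # oracle agreement on random binary tables
  set.seed(42)
  for (rep in 1:20) {
    x <- runif(20) < 0.5
    y <- c(rep(TRUE, 10), rep(FALSE, 10))
    expect_equal(minitox:::chi2_2x2(sum(x & y), sum(x & !y),
                                    sum(!x & y), sum(!x & !y)),
                 bf_chi2(x, y), tolerance = 1e-12)
  }

  # degenerate single-class target
  bad <- d
  for (cu in names(bad$entries)) bad$entries[[cu]][[target$uri]] <- "a"
  expect_error(chi2_rank_features(bad, f_planted$uri, target$uri),
               class = "mt_degenerate_error")
})

test_that("label permutation collapses the planted chi-squared score", {
  store <- new_store()
  fx <- generate_classification_fixture(store, fixture_spec(n = 200, seed = 3))
  d <- run_descriptor_algorithm(store, fx$dataset, "fingerprint")
  fp_alg <- paste0(store$base_uri, "algorithm/fingerprint")
  feats <- names(Filter(function(ft) identical(ft$has_source, fp_alg),
                        d$features))
  rk <- chi2_rank_features(d, feats, fx$feature$uri, top_k = 1)
  planted_score <- rk$score[1]
  # permute class labels: the planted signal should collapse
  perm <- d
  labs <- vapply(names(d$entries), function(cu)
    d$entries[[cu]][[fx$feature$uri]], character(1))
  set.seed(99)
  labs_p <- sample(labs)
  for (i in seq_along(labs_p)) {
    perm$entries[[names(d$entries)[i]]][[fx$feature$uri]] <- labs_p[i]
  }
  rk_p <- chi2_rank_features(perm, feats, fx$feature$uri, top_k = 1)
  expect_gt(planted_score, 50)
  expect_lt(rk_p$score[1], planted_score / 5)
})

test_that("k-NN building validates input and stores neighbours", {
  tw <- tiny_store_with_csv(c("CCO,active", "CCCO,active", "CC(C)O,active",
                              "CCCCO,active", "CC(C)CO,active",
                              "CCN,inactive", "CCCN,inactive",
                              "CC(C)N,inactive", "CCCCN,inactive",
                              "CC(C)CN,inactive"))
  store <- tw$store
  m <- build_knn_classifier(store, tw$ingest$dataset, tw$ingest$feature$uri)
  expect_length(m$state$smiles, 10L)
  expect_equal(m$parameters$k, 5L)
  expect_equal(m$parameters$s_min, 0.3)

  # k > n is truncated and logged
  m2 <- build_knn_classifier(store, tw$ingest$dataset, tw$ingest$feature$uri,
                             params = list(k = 50))
  expect_equal(m2$parameters$k, 10L)
  expect_true(any(vapply(store$log, function(l)
    l$event == "knn_k_truncated", logical(1))))

  # single-class training set is rejected
  tws <- tiny_store_with_csv(c("CCO,active", "CCC,active"))
  expect_error(
    build_knn_classifier(tws$store, tws$ingest$dataset, tws$ingest$feature$uri),
    class = "mt_degenerate_error")
})

test_that("weighted vote matches the hand-computed oracle", {
  # (0.9 active), (0.8 inactive), (0.7 inactive), k=3:
  # inactive weight 1.5 vs active 0.9 -> inactive, confidence 1.5/2.4
  v <- knn_weighted_vote(c(0.9, 0.8, 0.7), c("active", "inactive", "inactive"),
                         k = 3, s_min = 0.3, positive = "active")
  expect_false(v$unpredicted)
  expect_identical(v$value, "inactive")
  expect_equal(v$confidence, 1.5 / 2.4)
  expect_equal(v$score, 0.9 / 2.4)

  # all below the gate: unpredicted
  v2 <- knn_weighted_vote(c(0.1, 0.2), c("active", "inactive"),
                          k = 3, s_min = 0.3, positive = "active")
  expect_true(v2$unpredicted)

  # unanimous neighbours give confidence exactly 1
  v3 <- knn_weighted_vote(c(0.9, 0.5), c("active", "active"),
                          k = 2, s_min = 0.3, positive = "active")
  expect_equal(v3$confidence, 1)

  # weight tie: larger training prior wins, then smaller label
  v4 <- knn_weighted_vote(c(0.5, 0.5), c("active", "inactive"), k = 2,
                          s_min = 0, positive = "active",
                          priors = c(active = 3, inactive = 7))
  expect_identical(v4$value, "inactive")
  v5 <- knn_weighted_vote(c(0.5, 0.5), c("active", "inactive"), k = 2,
                          s_min = 0, positive = "active",
                          priors = c(active = 5, inactive = 5))
  expect_identical(v5$value, "active")
})

test_that("k-NN prediction contracts: memorization, gating, invariance", {
  tw <- tiny_store_with_csv(c("CCO,active", "CCCO,active", "CCN,inactive",
                              "CCCN,inactive"))
  store <- tw$store
  m <- build_knn_classifier(store, tw$ingest$dataset, tw$ingest$feature$uri,
                            params = list(k = 1))
  # query identical to a training active
  cp <- add_compound(store, "CCO")
  qd <- new_dataset(store, list(cp), values = setNames(list(list()), cp$uri))
  pr <- predict_with_model(store, m, qd)
  expect_identical(pr$predictions$value, "active")
  expect_equal(pr$predictions$confidence, 1.0)

  # far-away query is unpredicted under the gate
  far <- add_compound(store, "I")
  qd2 <- new_dataset(store, list(far), values = setNames(list(list()), far$uri))
  pr2 <- predict_with_model(store, m, qd2)
  expect_true(pr2$predictions$unpredicted)
  expect_true(is.na(pr2$predictions$value))

  # row-order invariance: shuffled training entries give the same model
  d_rev <- tw$ingest$dataset
  ord <- rev(seq_along(d_rev$compounds))
  d_rev$compounds <- d_rev$compounds[ord]
  d_rev$entries <- d_rev$entries[ord]
  m_rev <- build_knn_classifier(store, d_rev, tw$ingest$feature$uri,
                                params = list(k = 1))
  expect_identical(m_rev$state$smiles, m$state$smiles)
  pr_rev <- predict_with_model(store, m_rev, qd)
  expect_identical(pr_rev$predictions$value, pr$predictions$value)

  # confidence lies in (0,1] for predicted compounds
  m3 <- build_knn_classifier(store, tw$ingest$dataset, tw$ingest$feature$uri,
                             params = list(k = 4, s_min = 0))
  prs <- predict_with_model(store, m3, tw$ingest$dataset)
  conf <- prs$predictions$confidence
  expect_true(all(conf > 0 & conf <= 1))
})

test_that("OLS fits, handles degeneracy and recovers planted coefficients", {
  store <- new_store()
  cps <- lapply(c("C", "CC", "CCC"), function(s) add_compound(store, s))
  fx <- new_feature(store, "x", "numeric", has_source = "urn:x")
  fy <- new_feature(store, "y", "numeric", has_source = "urn:x")
  mk <- function(xs, ys) {
    new_dataset(store, cps, list(fx, fy), setNames(lapply(seq_along(cps),
      function(i) setNames(list(xs[i], ys[i]), c(fx$uri, fy$uri))),
      vapply(cps, `[[`, character(1), "uri")))
  }
  d <- mk(c(1, 2, 3), c(2, 4, 6))
  m <- build_ols_regressor(store, d, fx$uri, fy$uri)
  expect_equal(m$state$beta0, 0, tolerance = 1e-10)
  expect_equal(unname(m$state$beta), 2, tolerance = 1e-10)

  # constant target: slope 0, intercept = mean
  d2 <- mk(c(1, 2, 3), c(5, 5, 5))
  m2 <- build_ols_regressor(store, d2, fx$uri, fy$uri)
  expect_equal(m2$state$beta0, 5, tolerance = 1e-10)
  expect_equal(unname(m2$state$beta), 0, tolerance = 1e-10)

  # sigma = 0 fixture recovers the planted coefficients to 1e-6
  rf <- generate_regression_fixture(store, fixture_spec(n = 40, seed = 6,
                                                        sigma = 0))
  m3 <- build_ols_regressor(store, rf$dataset,
                            rf$features[c("count", "mw100")],
                            rf$features[["y"]])
  expect_equal(m3$state$beta0, 0.5, tolerance = 1e-6)
  expect_equal(unname(m3$state$beta[rf$features[["count"]]]), 2,
               tolerance = 1e-6)
  expect_equal(unname(m3$state$beta[rf$features[["mw100"]]]), 1,
               tolerance = 1e-6)

  # residuals orthogonal to design columns
  rf2 <- generate_regression_fixture(store, fixture_spec(n = 40, seed = 8,
                                                         sigma = 0.5))
  m4 <- build_ols_regressor(store, rf2$dataset,
                            rf2$features[c("count", "mw100")],
                            rf2$features[["y"]])
  pr <- predict_with_model(store, m4, rf2$dataset)
  X <- t(vapply(names(rf2$dataset$entries), function(cu) {
    c(1, rf2$dataset$entries[[cu]][[rf2$features[["count"]]]],
      rf2$dataset$entries[[cu]][[rf2$features[["mw100"]]]])
  }, numeric(3)))
  y <- vapply(names(rf2$dataset$entries), function(cu)
    rf2$dataset$entries[[cu]][[rf2$features[["y"]]]], numeric(1))
  resid <- y - pr$predictions$score
  expect_lt(max(abs(t(X) %*% resid)), 1e-8)

  # rank deficiency: duplicated predictor gives the minimal-norm solution
  fdup <- new_feature(store, "xdup", "numeric", has_source = "urn:x")
  d3 <- mk(c(1, 2, 3), c(2, 4, 6))
  for (cu in names(d3$entries)) {
    d3$entries[[cu]][[fdup$uri]] <- d3$entries[[cu]][[fx$uri]]
  }
  d3$features[[fdup$uri]] <- fdup
  m5 <- build_ols_regressor(store, d3, c(fx$uri, fdup$uri), fy$uri)
  expect_equal(unname(m5$state$beta[1]), unname(m5$state$beta[2]),
               tolerance = 1e-6)   # minimal norm spreads weight evenly
  expect_equal(unname(sum(m5$state$beta)), 2, tolerance = 1e-6)

  # zero complete rows
  d4 <- mk(c(NA, NA, NA), c(1, 2, 3))
  expect_error(build_ols_regressor(store, d4, fx$uri, fy$uri),
               class = "mt_degenerate_error")
})
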