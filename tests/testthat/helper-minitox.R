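# Independent brute-force oracles and small generators shared across
# the suite. Oracles deliberately avoid the code paths they check.

# AUC by exhaustive pair counting, ties counted one half.
bf_auc <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Trapezoidal area under an ROC polygon.
bf_trapezoid <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# Confusion-based measures by direct formula.
bf_class_metrics <- function(truth, pred, positive, beta = 2) {
  ok <- !is.na(pred)
  tp <- sum(ok & truth == positive & pred == positive)
  fp <- sum(ok & truth != positive & pred == positive)
  fn <- sum(ok & truth == positive & pred != positive)
  tn <- sum(ok & truth != positive & pred != positive)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  f <- (1 + beta^2) * p * r / (beta^2 * p + r)
  list(tp = tp, fp = fp, tn = tn, fn = fn, precision = p, recall = r, f = f,
       n_unpredicted = sum(!ok))
}

bf_regression <- function(t, p) {
  mse <- sum((t - p)^2) / length(t)
  list(mse = mse, rmse = sqrt(mse),
       r2 = 1 - sum((t - p)^2) / sum((t - mean(t))^2))
}

# Chi-squared of a 2x2 table straight from observed/expected cells.
bf_chi2 <- function(x, y) {
  o <- c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
  n <- length(x)
  e <- c(sum(x) * sum(y), sum(x) * sum(!y), sum(!x) * sum(y),
         sum(!x) * sum(!y)) / n
  if (any(e == 0)) return(0)
  sum((o - e)^2 / e)
}

# Graph isomorphism by brute-force permutation search (n <= 8 atoms).
bf_isomorphic <- function(g1, g2) {
  n <- nrow(g1$atoms)
  if (n != nrow(g2$atoms) || nrow(g1$bonds) != nrow(g2$bonds)) return(FALSE)
  akey <- function(g) sprintf("%s|%d|%d|%d", g$atoms$element, g$atoms$charge,
                              as.integer(g$atoms$aromatic), g$atoms$implicit_h)
  bmat <- function(g) {
    m <- matrix(0, n, n)
    for (k in seq_len(nrow(g$bonds))) {
      m[g$bonds$a[k], g$bonds$b[k]] <- g$bonds$order[k]
      m[g$bonds$b[k], g$bonds$a[k]] <- g$bonds$order[k]
    }
    m
  }
  k1 <- akey(g1); k2 <- akey(g2)
  m1 <- bmat(g1); m2 <- bmat(g2)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  for (p in perms(seq_len(n))) {
    if (all(k1 == k2[p]) && all(m1 == m2[p, p])) return(TRUE)
  }
  FALSE
}

# Random SMILES drawn from the fixture grammar (with and without the
# charged toxicophore), used for canonicalization/fingerprint/RDF
# property tests.
random_fixture_smiles <- function(n, seed = 1L) {
  store <- new_store()
  fx <- generate_classification_fixture(
    store, fixture_spec(n = n, seed = seed, prevalence = 0.5))
  fx$truth$smiles
}

# A tiny stored two-class dataset for datastore/validation tests.
tiny_store_with_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("smiles,activity", rows), path)
  store <- new_store()
  ing <- ingest_training_csv(store, path)
  list(store = store, ingest = ing, path = path)
}

random_perm_graph <- function(g, seed) {
  set.seed(seed)
  permute_atoms(g, sample(nrow(g$atoms)))
}
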