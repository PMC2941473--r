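# minitox

A desk-scale, self-contained R implementation of an interoperable
predictive-toxicology (QSAR) framework. It is aimed at two audiences:
non-specialists who want a toxicity estimate for a single chemical
structure, and QSAR practitioners who want to build, validate and
compare models on their own `smiles,activity` training tables — without
any external database, web service or toolkit.

Everything lives behind one in-memory resource store that emulates the
service architecture of distributed predictive-toxicology platforms:
compounds, features, datasets, algorithms, models, applicability
domains, validation records, an ontology/registry hub with
basic-graph-pattern queries, and an asynchronous task contract.
Resources exchange RDF (Turtle and RDF/XML) deterministically, so every
artifact can be persisted, inspected and reloaded as plain text.

## What is inside

* **Chemistry core** — a SMILES-subset parser (organic subset, aromatic
  lowercase, bracket charges/H-counts, rings, branches), a
  Morgan-style canonicalizer, graph-level structure checking, six
  physico-chemical descriptors (MW, heavy atoms, cyclomatic rings,
  aromatic atoms, HBD, HBA), linear-path substructure fingerprints
  (FNV-1a hashed, default 1024 bits) and Tanimoto similarity
  `|A∩B| / |A∪B|`.
* **Algorithms** — a typed registry (descriptor calculation,
  classification, regression, feature selection, data cleanup) with
  template metadata, plus representative payloads: descriptor
  calculation, χ² feature ranking on 2×2 contingency tables,
  similarity-weighted k-nearest-neighbour classification
  (defaults k = 5, s_min = 0.3), and OLS regression with a
  minimal-norm fallback for rank-deficient designs.
* **Applicability domain** — distance-to-training (max Tanimoto ≥ t)
  and descriptor-range methods, applied per prediction.
* **Validation** — an independent service with explicit, seeded split
  plans (train/test, k-fold, leave-one-out, stratified), the standard
  metric bundle (confusion matrix, unpredicted counts,
  precision/recall/F2, ROC/AUC as the Mann–Whitney pair statistic with
  ties at ½, MSE/RMSE/R²) and bit-reproducible re-runs from persisted
  records.
* **Workflows** — `toxpredict_run()` (five logged stages: resolve
  structure → check → discover models via the ontology → estimate with
  tasks, feature resolution and AD → report) and `toxcreate_run()`
  (ingest CSV → build model → cross-validate → report), plus HTML/JSON
  reports, model comparison and a `minitox` CLI.
* **Fixtures** — a synthetic toy-QSAR generator that plants a
  toxicophore (a charged nitro group by default) into grammar-generated
  molecules, so the whole stack is testable offline.

## Worked example

```r
library(minitox)

store <- new_store()
ont <- build_endpoint_ontology(store)

# 1. make a 60-compound training table with a planted nitro toxicophore
fx <- generate_classification_fixture(store,
        fixture_spec(n = 60, noise = 0, seed = 7),
        csv_path = "toy.csv")

# 2. ingest, build a k-NN model, 5-fold cross-validate
res <- toxcreate_run(store, "toy.csv", params = list(k = 3),
                     validation = list(method = "kfold", k = 5,
                                       seed = 42, stratified = TRUE))
store$validations[[res$validation_uri]]$aggregate
#> Classification metrics (n=50): TP 25 FP 0 TN 25 FN 0 | unpredicted 0 (0.0%)
#>   precision 1.0000  recall 1.0000  F2 1.0000  AUC 1.0000

# 3. predict a new structure through the five-step workflow
rep <- toxpredict_run(store, "CCC[N+](=O)[O-]")
#> STEP1 search/resolve structure: CCC[N+](=O)[O-]
#> STEP2 structure check: CCC[N+](=O)[O-] (1 component(s), 0 warning(s))
#> STEP3 model selection: 1 model(s) from ontology registry
#> STEP4 estimation: 1 model prediction(s), 0 experimental dataset(s)
#> STEP5 report rendered
rep$content$predictions
#>                 model activity confidence score ad_inside ad_score
#> 1 urn:minitox:model/1   active          1     1      TRUE        1
```

On this noise-free fixture the planted substructure determines the
label, so the cross-validated metrics are perfect and the nitro query
is predicted active with confidence 1 inside the applicability domain;
with label noise (`noise > 0`) the metrics degrade accordingly.

The same flows are available from the shell:

```sh
inst/scripts/minitox fixtures make --n 200 --noise 0.1 --seed 42 --out toy.csv
inst/scripts/minitox toxcreate build --csv toy.csv --store ./st --folds 10
inst/scripts/minitox toxpredict --query "CC[N+](=O)[O-]" --store ./st --out report.html
```

## Scope

No 3D geometry, aromaticity perception, InChI computation, external
database connectors, PDF/QMRF reporting or networked deployment; the
vignette in `vignettes/` documents the model, the defaults and the
design decisions in detail.
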