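---
title: "minitox: methods, defaults and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{minitox: methods, defaults and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the architecture

Predictive toxicology asks a deceptively simple question: given a
chemical structure, how likely is it to produce a toxic effect for a
defined endpoint (mutagenicity, skin irritation, carcinogenicity, ...)?
Production platforms answer it with a constellation of interoperable
services — compound and dataset stores, descriptor and learning
algorithms, models, applicability-domain estimators, an independent
validation service, an ontology registry, asynchronous tasks, report
generators — exchanging resources as RDF. `minitox` reproduces that
architecture at desk scale, entirely in memory and entirely
deterministic, so that every piece of the pipeline can be exercised,
validated and inspected offline.

The package intentionally separates three concerns the way the large
platforms do:

* the **store** (`new_store()`) owns resources and URIs;
* **algorithms** are registered, typed (descriptor calculation,
  classification, regression, feature selection, data cleanup) and
  described by template metadata, and models carry full provenance
  (algorithm, parameters, training dataset, feature URIs);
* **validation** is an independent module that only consumes the public
  predict contract — it never reaches into model internals.

# The chemistry core

## SMILES subset

The parser accepts the organic subset B, C, N, O, P, S, F, Cl, Br, I,
aromatic lowercase `b c n o p s`, bracket atoms with an explicit
hydrogen count and a formal charge in −2..+2, branches, single-digit
ring closures (reusable after closing) and the bond symbols `- = # :`.
Stereochemistry, isotopes and wildcards are rejected: they are not
needed by any consumer in the package, and a partial implementation
would be worse than a clear error.

Implicit hydrogens follow the standard default-valence rule: B 3, C 4,
N 3, O 2, P 3 or 5, S 2, 4 or 6, halogens 1, choosing the smallest
default valence that is at least the bond-order sum (aromatic bonds
count 1.5; the sum is rounded up). Bracket atoms carry exactly their
written H count. A consequence worth knowing: **there is no aromaticity
perception**. Lowercase input is trusted, and Kekulé-written benzene
(`C1=CC=CC=C1`) is a *different graph* from aromatic-written benzene
(`c1ccccc1`). Similarity users who mix the two notations will see lower
similarities than a perceiving toolkit would report; the test suite
pins this behaviour down explicitly.

## Canonicalization

Canonical SMILES are produced by iterative neighbourhood refinement
(Morgan-style) seeded by (element, aromatic flag, charge, degree,
H count), with remaining ties broken by individualizing each atom of
the lowest tied class in turn and keeping the lexicographically
smallest emitted string. This branch-and-minimize step makes the
output provably order-invariant even on symmetric graphs where plain
refinement stalls, at a worst-case exponential cost that is irrelevant
at fixture scale (≤ 20 heavy atoms; the 500-molecule invariance suite
runs in well under a minute). The output is *implementation-canonical*:
stable across atom orderings and across sessions, but not intended to
match any external toolkit's canonical form. String comparisons and
tie-breaks always use C-locale (radix) ordering so results do not
depend on the session locale.

## Fingerprints, descriptors, similarity

Path fingerprints enumerate every simple path of 1..7 atoms (default),
label it with atom/bond symbols read in the lexicographically smaller
direction, and hash each label with FNV-1a 64-bit modulo L = 1024.
FNV-1a was chosen because it is trivially portable and fully specified;
the 64-bit multiply lives in a ten-line C++ routine because R lacks
native unsigned 64-bit arithmetic. The label multiset is retained so
that feature selection and reports can name actual substructures
rather than bit positions. Tanimoto similarity is `|A∩B| / |A∪B|` on
bit sets, defined as 1.0 when both sets are empty (identity of
indiscernibles; only empty graphs produce empty fingerprints).

The six descriptors are deliberately boring and exactly specified:
molecular weight from a fixed table of standard atomic weights rounded
to three decimals (shipped in the package so results cannot drift with
an external mass table), heavy-atom count, cyclomatic ring count
(bonds − atoms + components), aromatic-atom count, and Lipinski-style
donors (N/O bearing ≥ 1 H) and acceptors (N and O count).

# Representative algorithms

The k-nearest-neighbour classifier is the lazy-learning representative:
training stores fingerprints and labels; prediction ranks neighbours
with Tanimoto ≥ s_min (default 0.3), lets the top k (default 5) vote
with weight equal to similarity, and reports the winning weight share
as confidence and the positive class's weight share as the ROC score.
A query with no neighbour at or above s_min is **unpredicted** — the
similarity gate doubles as an implicit applicability filter, and the
unpredicted count is reported separately from the confusion matrix.
Vote ties go to the class with the larger training prior, then to the
C-locale smaller label; neighbour ties in similarity are broken by
canonical SMILES. All three rules exist purely for determinism.

χ² feature ranking scores the 2×2 contingency of feature presence
against class with no continuity correction; a zero-margin feature
(present everywhere or nowhere) scores 0 by convention rather than
producing 0/0. OLS regression fits with an intercept and falls back to
the minimal-norm (SVD pseudoinverse) solution on rank-deficient
designs, which keeps collinear toy descriptor sets from crashing a
workflow; the event is logged.

Aggregation of several models' predictions into a consensus is
deliberately **not** implemented: no combination rule is defined for
it in the framework this package mirrors, and inventing one silently
would misrepresent the comparison reports. The comparison report ranks
models instead.

# Applicability domain

Two standard AD families are implemented, because the framework
promises AD facilities without fixing an algorithm: a
distance-to-training method (inside iff max Tanimoto to the training
set ≥ t, default t = 0.3, matching s_min) and a descriptor-range
method (inside iff every descriptor falls within the training
min/max). The AD verdict is attached to prediction reports as a
separate column and never suppresses a prediction — the model's own
s_min gate is the only mechanism that declines to predict. Both call
patterns are supported: an AD can be built as part of the prediction
workflow or separately and passed in by URI.

# Validation

Split plans are materialized once: the seed *and* the explicit
compound-to-fold assignment are stored, so re-running a validation
needs no PRNG parity with anything — reproducibility rests on the
assignment table. Stratified k-fold deals each class round-robin after
a seeded shuffle, so per-class fold counts differ by at most one; a
class smaller than k triggers a warning and best-effort balance.

Metrics follow the standard definitions: precision TP/(TP+FP), recall
TP/(TP+FN), and the F2 measure F_β with β = 2 — the β = 2 reading is
taken literally from the framework's metric table, and a `fbeta`
argument exposes β = 1 for users who want the balanced F-measure. AUC
is computed as the Mann–Whitney pair statistic with ties counted ½,
and the ROC points at unique thresholds are emitted alongside; the
trapezoidal area under those points equals the pair statistic, which
the tests verify against exhaustive pair counting. Unpredicted
compounds never enter the confusion matrix or the ROC;
percent-unpredicted is denominated by the full test size. R² is
1 − SS_res/SS_tot about the truth mean of the evaluated set and is
reported missing (with a warning) when the truth has zero variance.

Across folds, the headline aggregate **pools** predictions (pooled
confusion counts, AUC on pooled scores) and the per-fold mean ± sd is
reported alongside; pooling was chosen because the alternative
(averaging fold AUCs) is undefined for folds that end up single-class
and hides the unpredicted accounting. A fold whose training portion is
single-class is marked failed, excluded from the aggregate and
recorded. Per-fold feature computation (χ² selection) runs on the
training fold only; an acceptance test constructs a dataset whose
per-fold selections must differ to prove no test-fold information
leaks into training.

# Synthetic fixtures: what they emulate and what they do not

The generator assembles molecules from a small valence-clean grammar —
alkyl chains of 2–8 units with methyl branches, at most one pendant
phenyl, occasional ether oxygens — and grafts a toxicophore (default:
the charged nitro group, written `C[N+](=O)[O-]` so bracket and charge
parsing are exercised) into a `prevalence` fraction (default 0.5). The
label is "carries the toxicophore", flipped independently with
probability ε (default 0). The regression target is
y = β₀ + β₁·count + β₂·(MW/100) + N(0, σ) with defaults
β = (0.5, 2, 1), σ = 0.2 — magnitudes chosen so the structural term
and the size term contribute comparably at the grammar's MW range
(~40–230 g/mol), a realistic regime for a toy QSAR.

With ε = 0 the structure–activity rule is exact, so a green
cross-validation test establishes that the pipeline *can recover a
clean planted signal* (AUC ≥ 0.95, χ² rank 1 on a nitro-derived path
label) — and nothing more. Real toxicity data has class imbalance,
activity cliffs, measurement noise, congeneric series and chemistry
far outside this grammar; no green fixture test speaks to those. The
grammar also keeps molecules ≤ 20 heavy atoms so fingerprints stay
sub-second, which means the fixtures never probe ring-closure digits
beyond one simultaneous ring, nor sulfur/phosphorus chemistry (the
parser supports both; the fixtures do not generate them).

# Numerical and serialization choices

* Numbers are serialized with 17 significant digits (and integers as
  `x.0`), which round-trips IEEE doubles exactly; negative zero is
  normalized to `0.0` first.
* RDF output sorts triples bytewise, so the same resource always
  serializes byte-identically, and write → read → write is
  byte-identical in both Turtle and RDF/XML. Dataset snapshot hashes
  are SHA-256 over the sorted canonical serialization, making them
  insensitive to entry order.
* The OLS pseudoinverse truncates singular values below 1e-10 of the
  maximum; residual-orthogonality is tested at 1e-8.
* Fingerprint and canonicalization results are memoised (they are pure
  functions of the input string), which makes repeated
  cross-validation runs cheap without affecting any result.
* The RDF vocabulary mirrors the framework's resource names
  (`Dataset`, `DataEntry`, `Compound`, `Feature`, `FeatureValue`,
  `Model`, `Algorithm`, `hasSource`, algorithm-type and endpoint
  namespaces) under this package's own IRIs; the original platform's
  exact OWL IRIs are not reproduced, and only `hasSource` semantics
  are load-bearing (feature resolution follows it to recompute
  descriptors for unseen structures, and fails loudly when a feature's
  source is experimental data the query compound does not have).

# Known limitations

* No aromaticity/tautomer normalization: notation changes structure
  identity (documented above), which is the main caveat for similarity
  and deduplication users.
* The Turtle reader covers the package's own regular output plus
  simple prefixed-name documents, not the full Turtle grammar.
* The task contract is synchronous in-process: status snapshots are
  recorded at stage boundaries (Queued → Running → Completed/Error
  with 202/200/500 codes), which preserves the polling semantics but
  not true concurrency.
* χ² scores are reported without multiple-testing correction; they
  rank features, they do not test hypotheses.
* The fingerprint is a linear-path design; branched or ring-context
  substructures map onto sets of path labels rather than single
  features.
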