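---
title: "Methods: GO frequency features and ensembles of classifier chains for multi-label protein localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GO frequency features and ensembles of classifier chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccloc)
```

## The model

`eccloc` predicts the set of subcellular locations of a bacterial protein.
The prediction problem is multi-label: a protein may legitimately reside in
several compartments at once, and the correlations between compartments are
informative.

### GO frequency features

A query protein is characterized through its homologs rather than through
its own (possibly unannotated) accession. From a homology-search hit table,
the hits with pairwise similarity of at least 60 % form the *typical
homologous set*; exact self-hits are excluded and multiple HSPs against the
same subject are collapsed to one homolog, because the representation counts
*proteins*, not alignments. With `N_h` the size of that set, the coordinate
of the query on GO term `j` is

$$f_j = \frac{1}{N_h} \sum_{k=1}^{N_h} g(j,k), \qquad
g(j,k) = \begin{cases} 1 & \text{homolog } k \text{ is annotated with term } j\\
0 & \text{otherwise,}\end{cases}$$

a frequency in $(0, 1]$ rather than a bare 0/1 indicator, so better-supported
terms weigh more. Homologs with no annotation record still count in `N_h`:
the denominator is the homolog-set size, so unannotated homologs dilute all
frequencies rather than silently shrinking the set (a switchable judgment
call — the data do not dictate it, and the opposite convention is one filter
away in user code).

The feature space is the set of distinct GO terms in the annotation table,
ordered lexicographically; the ordering is arbitrary in principle, and fixing
it lexicographically makes feature matrices reproducible across runs and
machines. No ontology-graph propagation is performed: a term counts only if
it is directly annotated, which keeps the representation an exact function of
the annotation table. Matrices are sparse (`Matrix::dgCMatrix`) and exported
as MatrixMarket files with sidecar row/column id lists.

### The dipeptide backup encoder

Proteins without a usable GO representation — an empty typical homologous
set, or homologs matching nothing in the annotation table — are encoded from
sequence alone: 20 amino acid composition frequencies followed by 400
adjacent-dipeptide frequencies, 420 dimensions in total. Residues and pairs
are enumerated in alphabetical one-letter order (row-major for pairs), and a
column legend is written alongside every exported matrix. Nonstandard
letters (B, J, O, U, X, Z), gaps and stop symbols are deleted before
counting, and adjacency is evaluated on the cleaned string; deletion (rather
than mapping to a 21st symbol) keeps both blocks proper frequency
distributions. The two blocks are normalized separately — each sums to 1 —
as their definitions imply; a joint normalization would make the blocks'
scales depend on sequence length.

### Binary relevance, classifier chains, and the ensemble

Each location is a one-vs-rest binary problem. *Binary relevance* (BR)
trains the `N` binary scorers independently. A *classifier chain* (CC)
fixes a label order and trains the `j`-th scorer on the base features plus
the 0/1 values of the `j − 1` earlier labels, so downstream scorers can
exploit label correlations. At training time the augmentation uses the
**true** labels (teacher forcing), which is the original chain formulation;
at prediction time it uses the chain's own hard decisions (score > 0),
evaluated sequentially. The *ensemble of classifier chains* (ECC) trains
`m` chains with label orders drawn uniformly at random from a seeded RNG —
with replacement, since for small `N` distinct orders run out quickly — and
averages the `m` signed score vectors. Decision rule, shared by all three:
every label with a strictly positive score is predicted; if none is
positive, the single top-scoring label is predicted (ties break to the
lowest label index), so the predicted set is never empty. A zero score is a
non-member.

The base learner is an L2-regularized linear SVM (`e1071`, linear kernel,
`C = 1`, no feature scaling — all features already live in `[0, 1]`). The
fitted hyperplane is extracted as an explicit weight vector and intercept,
verified exactly against the library's own decision values, so every chain
scorer is a plain linear function: fast to evaluate, deterministic, and
serializable to a JSON archive (doubles stored as hexadecimal float
literals, making the save/load round trip bit-exact). Binary subproblems
that lose one class entirely — routine during leave-one-out on a rare
location — are replaced by a constant scorer (−1 with no positives, +1 with
no negatives, matching the typical decision-value scale) so evaluation runs
never abort.

## Evaluation protocol and measures

The jackknife (leave-one-out) driver retrains on the `N_dif − 1` remaining
proteins for every held-out protein. GO-representable proteins are scored
by an ECC over GO vectors fitted on the representable training proteins;
the others by an ECC over dipeptide vectors — a parallel ensemble of the
same form, the minimal consistent choice for the backup path. Feature
vectors depend only on external knowledge (hits, annotations, sequences),
never on the other proteins' labels, so they are computed once; the
leave-one-out structure applies to classifier training. Chain orders are
drawn once per run (per feature mode, derived deterministically from the
run seed), not per fold, so folds are comparable and the whole run is
reproducible from one seed.

With `Y_i` and `Z_i` the true and predicted label sets:

* **overall locative accuracy** $= \frac{1}{N_{loc}} \sum_i |Y_i \cap Z_i|$,
  with $N_{loc} = \sum_i |Y_i|$ the number of (protein, location) pairs;
* **overall absolute accuracy** $= \frac{1}{N_{dif}} \sum_i 1(Y_i \equiv Z_i)$,
  stricter since superset predictions score zero;
* **per-location success rate** = the fraction of a location's carrier
  proteins whose predicted set contains it (its locative recall). This
  definition is the one that decomposes the locative accuracy: weighting
  each location's rate by its carrier count and dividing by $N_{loc}$
  reproduces the overall locative accuracy exactly, an identity the test
  suite checks to $10^{-12}$ on random predictions.

## The synthetic-data generator

Real inputs for this problem require a homology search and a GOA snapshot.
`simulate_world()` generates structurally faithful stand-ins: each location
owns a few dedicated *signature* GO terms; each protein receives 3–6
homologs whose annotations carry the signature terms of the protein's
locations with probability `signature_strength` (scalar, or per-label),
plus uniform noise terms; each protein also receives sub-threshold decoy
hits (which the 60 % filter must remove) and a random sequence, so the
backup path is always exercisable. A configurable fraction of proteins
carries a fixed co-occurring location pair, giving chains a correlation to
exploit; with `pair_exclusive = TRUE` the pair's locations never occur
alone, making the second member deterministically dependent on the first.

Generator defaults mirror a small version of the gram-positive benchmark
composition: 60 proteins over 4 locations with 4 dual-location proteins
(hence 64 locative proteins), full-strength noiseless signatures. What the
generator does *not* emulate: realistic GO term co-annotation structure,
the heavy-tailed homolog-set sizes and annotation depths of real GOA data,
sequence composition biases, and class imbalance at benchmark scale. Tests
passing on these worlds therefore validate the *machinery* — feature
construction, chaining, averaging, decision rule, metrics — not
benchmark-level accuracy on biological data, which additionally depends on
the annotation snapshot and homology-search quality.

## Numerical and design choices

* **Similarity threshold**: 60 % by default, applied to the percent-identity
  column of the tabular hit format — the only similarity field universally
  present; the threshold is a plain parameter everywhere it occurs.
* **Problem sizes**: tests and the acceptance script use worlds of 12–80
  proteins and ensembles of 2–10 chains; these sizes already exercise every
  code path (both feature modes, degenerate folds, multi-label decisions)
  while keeping a full leave-one-out run to seconds. Ensemble defaults in
  the API remain `m = 25` (and 40 is the documented choice for the larger
  8-location setting).
* **Seeds**: one user-visible seed per run; component seeds (per feature
  mode) are derived from it by a fixed integer map. Identical seed and
  configuration give bit-identical reports.
* **Degenerate inputs**: empty homolog sets raise a typed condition that
  callers route to the backup encoder; sequences shorter than 2 residues
  after cleaning are rejected with an explanatory error; an annotation term
  missing from a supplied index is an error rather than a silent drop.
* **Teacher forcing**: training chains on true previous labels (rather than
  on the chain's own predictions) is the package's default and only mode;
  it is the standard chain formulation and keeps training order-independent
  of prediction quality.

## Known limitations

* When a location pair is perfectly deterministic (B occurs exactly when A
  does), BR's two binary subproblems coincide, so BR is already
  label-consistent and chaining adds no information; with very noisy
  features the hard 0/1 augmentation can even inject extra noise into
  downstream scorers. ECC's advantage is therefore largest for *imperfect*
  label correlations, and on strongly separable worlds ECC and BR tie.
* Scores are raw signed margins, not calibrated probabilities; averaging
  across chains assumes comparable margin scales, which the shared base
  learner and feature scale provide here.
* The per-location success rate is a recall; a location never predicted for
  non-carriers is invisible to it. The absolute accuracy is the measure
  that penalizes over-prediction.
* Leave-one-out retrains one model per protein per mode; at thousands of
  proteins a user should expect runtimes in minutes and may prefer reducing
  `m` before anything else, since members are independent and accuracy
  saturates quickly on separable data.
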