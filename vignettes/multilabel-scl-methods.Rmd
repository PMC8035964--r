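---
title: "Methods: multi-label subcellular localization by view consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-label subcellular localization by view consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclconsensus)
```

## The model

A bacterial protein is annotated with a *set* of subcellular locations drawn
from a fixed universe of `Q` compartments (six for Gram-negative organisms:
cytoplasm, inner membrane, outer membrane, periplasm, extracellular space,
gas vesicle; five for Gram-positive, which lack the outer membrane and
periplasm but add the cell wall). The target is a binary vector
`y ∈ {0,1}^Q` with at least one bit set; dual-location proteins set two.

The package learns `h : x → 2^y` by the **Label Powerset** transformation:
each distinct label subset observed in training becomes one class of an
ordinary multi-class problem. This captures label co-occurrence without any
independence assumption — the cost is that a subset never seen in training
can never be predicted, which matters precisely for the rare dual-location
classes. The remedy implemented here is decision-level fusion: member models
trained on different feature views each predict one subset, and the
**OR consensus** returns the union of those subsets. Two consequences are
used as exact test invariants:

* the consensus set is a superset of each member's set, so per-instance
  recall can only rise;
* the predicted-set size is monotone non-decreasing in the number of
  members.

Per-label marginal scores are obtained by summing the base classifier's
class posteriors over all classes containing the label; consensus scores
take the element-wise maximum of member scores. The marginals feed only the
ranking metrics (rank loss, ROC/AUC) — hard decisions always come from the
argmax class, with ties broken by higher training class frequency and then
lexicographic class key, so predictions are deterministic.

## Feature views

**PseAAC** (`pseaac()`): Chou's Type-I encoding. The first 20 components are
residue frequencies; component `20 + k` is `w·θ_k` where
`θ_k` averages, over positions `i`, the mean squared difference of
standardized hydrophobicity, hydrophilicity and side-chain mass between
residues `i` and `i + k`; the whole vector is normalized to sum 1.
Defaults: `λ = 30` capped at `min(L) − 1` over the batch so the feature
space stays rectangular, `w = 0.05`, population-variance standardization of
the property scales. With `λ = 0` the encoding is exactly the amino-acid
composition (an asserted identity).

**PSSM → ACC** (`read_pssm()`, `acc_transform()`): profiles are consumed,
not produced — the parser reads PSI-BLAST ASCII output and takes the
log-odds block by default (`block = "percent"` selects the weighted-observed
percentages instead; the choice is exposed because published pipelines are
often silent about which block fed their features, and the log-odds block is
the conventional notion of a "profile"). The auto-cross covariance transform
yields `400·lg` features; the canonical ordering is the AC block by
(amino acid, lag) followed by the CC block by ordered pair `(i, j)`, `i ≠ j`,
by (i, j, lag). Only the total length is forced by the definition; this
particular order is simply fixed and documented so persisted feature tables
are stable. The lagged index in the cross term is `k + lag` — the lag must
appear in the lagged factor for the quantity to be a lagged covariance at
all. Default `lg = 1` keeps the view at 400 features, encoding
nearest-neighbour order only.

**GO terms** (`build_go_vocabulary()`, `go_features()`): the vocabulary is
the sorted union of distinct GO ids over the three sub-ontologies on
*training* proteins. Inside cross-validation it is rebuilt per fold; building
it once from all data is the other defensible reading of common practice, but
fold-local construction is the default here because a global vocabulary leaks
which terms exist in the held-out fold into the feature definition. Encoding
is 0/1 presence or the annotation predictor's PPV confidence; unseen ids are
ignored and unannotated proteins get a zero vector — annotation absence is an
expected state, not an error.

## Base classifier

Default: probability random forest (`ranger`), 500 trees, fixed seed,
single-threaded for bit-reproducibility. An RBF-kernel SVM with probability
estimates (`e1071`) is available via `base = "svm"`. No hyperparameter search
is performed; 500 trees is a conventional forest size at which out-of-bag
estimates stabilize for feature spaces of a few hundred columns. A powerset
class with a single training example is legal but flagged with a warning,
since a 5-fold split will then necessarily produce folds missing that class.

## Evaluation layer

Example-based metrics (Jaccard accuracy, precision, recall, F1, subset
accuracy, Hamming loss) are averaged per instance; label-based metrics are
aggregated macro (mean of per-label ratios) and micro (pooled counts). Two
conventions deserve note:

* **Empty predictions.** Label Powerset can never emit an empty set, but the
  metric layer accepts arbitrary matrices, so the conventions are fixed:
  an empty predicted set contributes 0 to the precision average, and Jaccard
  uses the true union. A label with a zero macro denominator contributes 0
  and triggers a warning.
* **Macro F1.** Two definitions circulate: the harmonic mean of macro
  precision and macro recall (`macro_f1`), and the unweighted mean of
  per-label F1 scores (`macro_f1_per_label`). They differ by ~0.004 on
  realistic confusion tables, which exceeds a 3-decimal report's precision,
  so the report carries both.

Rank loss is the standard pairwise formulation — over all (relevant,
irrelevant) label pairs of an instance, an inversion counts 1 and a tie ½,
averaged over instances having at least one label of each kind (degenerate
instances are excluded and counted). ROC/AUC is micro-averaged over the
flattened (instance, label) pairs and integrated by the trapezoid rule,
which equals the tie-corrected Mann–Whitney U statistic (cross-checked
against an independent ROC implementation in the tests).

The per-location confusion table tallies TP/FP/FN/TN per compartment with
`Correct = TP + TN` and `Wrong = FP + FN`; `TP + FP + FN + TN = N` per row is
asserted, and the identity `hamming_loss = (ΣFP + ΣFN)/(N·Q)` links the
example-based and pooled-count views exactly
(`label_metrics_from_counts()` exposes the count-level entry point so a
published confusion table can be checked for internal consistency without
the underlying matrices).

Cross-validation (`scl_cv()`) uses a seeded shuffle with round-robin
assignment (fold sizes differ by ≤ 1), fits every requested view per fold,
pools held-out predictions (each protein predicted exactly once) and
evaluates up to eight variants: three single views (PseAAC, PSSM, GO in 0/1
and PPV flavours), two feature fusions (column concatenation), and two OR
consensus models (PSSM+GO, and PseAAC+PSSM+GO). All consensus members share
the same fold split.

## The synthetic-data generator

`simulate_scl_dataset()` exists so the complete pipeline is testable without
external services; its defaults are the study conditions used throughout the
tests.

* **Labels** follow the empirical class balance of the curated Gram-negative
  benchmark (6,578 proteins: 4,152 cytoplasmic down to 10 gas-vesicle, 39
  dual-location proteins concentrated on eight compartment pairs) or its
  Gram-positive counterpart, expressed as a label-set distribution. Dual-site
  mass is therefore <1%, as in the real data.
* **Sequences** are i.i.d. residues with a mild per-location tilt
  (`seq_signal = 0.5` multiplies two favoured residues' sampling weight), so
  the PseAAC view is weakly informative — mirroring its last-place ranking on
  real benchmarks.
* **PSSMs** are integers in the PSI-BLAST log-odds range [−10, 12]
  (Gaussian, sd 2, rounded and clipped). Each location shifts three
  designated columns by `pssm_signal = 2`, applied over motif-like segments
  (a persistent two-state occupancy process with flip probability 0.1)
  rather than uniformly: the ACC features are covariances and hence
  invariant to any constant column shift, so a uniform shift would be
  invisible to the model by construction. Segment-wise shifts create the
  lagged covariance ACC is designed to measure.
* **GO annotations**: each location owns five disjoint indicative terms
  (2 MF + 2 BP + 1 CC) emitted with probability `go_emission = 0.9` and
  PPV ~ Beta(5, 2) clipped to (0, 1] — right-skewed, like a confident
  annotation predictor; noise terms arrive at Poisson rate
  `noise_rate = 0.5` with weak Beta(2, 5) PPVs. Default vocabulary sizes are
  40 MF / 50 BP / 20 CC.
* **Scale.** The recovery benchmark runs at N = 500 with 5-fold CV and the
  end-to-end smoke at N = 300 — large enough for the binomial 3σ bands used
  in the distributional checks to be meaningful, small enough to keep a full
  eight-variant run in tens of seconds.

What passing these tests shows — and what it does not: the generator plants
clean, compartment-disjoint signal with no homology structure, no
phylogenetic correlation between proteins, no biased annotation coverage and
no correlation between views beyond the shared labels. Recovery therefore
validates the machinery (encoders, LP learning, fusion, metrics), not the
attainable accuracy on real proteomes; on real data the GO view's advantage
depends entirely on annotation transfer quality.

## Numerical choices and degenerate inputs

* Seeds: every stochastic step (fold split, forest, generator) takes an
  explicit integer seed; fold-level fits use `seed + fold`. The global RNG
  state is saved and restored around seeded sections.
* `lg ≥ L` or `λ ≥ L` raise errors naming the offending input; constant
  PSSM columns give zero covariances; a single observed powerset class
  yields a constant classifier without fitting a forest.
* Ties: argmax ties are broken by class frequency then lexicographic key;
  score ties in rank loss and AUC earn ½ credit.
* Report writers round to 3 decimals for display; full precision is kept in
  the returned objects.

## Known limitations

Label Powerset cannot predict unseen label subsets (the consensus mitigates
but does not remove this); the LP+forest pipeline offers no calibrated
probability of multi-location membership, only marginal scores; imbalance is
handled by evaluation (macro metrics, per-location tables) rather than by
resampling; and PSSM generation and GO annotation prediction are consumed as
inputs — the package deliberately does not run profile searches or
annotation servers.
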