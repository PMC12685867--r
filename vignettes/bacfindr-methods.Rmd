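---
title: "bacfindr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bacfindr: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacfindr)
```

`bacfindr` predicts whether a protein sequence is a bacteriocin — a
ribosomally synthesized antimicrobial peptide — from sequence alone. This
vignette is the package's own account of the science inside it: the
descriptor model, the two feature selectors, the classifier and its
evaluation, the synthetic benchmark, and every numerically consequential
convention the implementation commits to.

## The descriptor model

Every sequence is mapped to a fixed, ordered 1,103-feature vector. The
alphabet order `A R N D C Q E G H I L K M F P S T W Y V` anchors all
feature numbering (`aac_5` = cysteine fraction; `alphabetOrder()` exposes
it), and `featureSchemaTable()` is the single source of truth for the
vocabulary.

- **AAC / DC** — residue and adjacent-pair frequencies, unit-sum by
  construction.
- **PseAAC (type 1)** — composition plus λ = 10 correlation factors
  τⱼ, each the average over positions j apart of the mean squared
  difference of three standardized scales (hydrophobicity,
  hydrophilicity, side-chain mass). First 20 components are
  f_r / (1 + w Στ), the tail w τⱼ / (1 + w Στ) with w = 0.05, so the 30
  components always sum to 1. λ is forced by the printed dimensionality
  (30 = 20 + λ); the weight is the conventional default.
- **APseAAC (type 2)** — 2λ factors alternating hydrophobicity- and
  hydrophilicity-based terms at each lag. The classic type-2 definition
  multiplies scale values, which can produce negative components and a
  non-unit sum. This package instead uses per-scale *squared differences*,
  the same Θ form as type 1. That choice is deliberate: it keeps every
  component non-negative, makes the vector a probability-like unit-sum
  object, and makes the correlation tail vanish exactly for homopolymers —
  three invariants the test suite asserts.
- **CTD** — seven physicochemical properties (hydrophobicity, normalized
  van der Waals volume, polarity, polarizability, charge, secondary
  structure, solvent accessibility, in that order) each partition the
  alphabet into three groups (the classic Dubchak convention, reproduced
  in `CTD_GROUPS` inside the package). Composition is the group fraction;
  transition is the rate of adjacent inter-group pairs over L − 1, for
  pairs (1,2), (1,3), (2,3); distribution records, per group, the
  positions (as % of L) of the first, 25%, 50%, 75% and 100% occurrences,
  the q-quantile occurrence being the ⌈q·k⌉-th of k occurrences. An
  absent group contributes zeros. The property order is what makes
  `dist_93` the 50%-quantile of buried residues (solvent accessibility,
  group 1) — an anchor the tests pin down.
- **SS** — fractions and longest runs of H/E/C states. External
  predictions (`.ss2` files) take precedence; otherwise a
  Chou–Fasman-style propensity argmax, smoothed with a centered window of
  5 and with ties resolved H > E > C, supplies the states. The window of
  5 is the smallest that suppresses single-residue state flicker.
- **SOCN / QSO** — lag-d coupling numbers τ_d = Σᵢ d(Rᵢ, Rᵢ₊d)² for
  d = 1..20 and their unit-sum combination with composition at
  w = 0.1. The 20 × 20 distance matrix is **constructed by the package**:
  the Euclidean distance over the three standardized PseAAC scales,
  scaled by 1/√3 so each squared entry is a mean squared scale
  difference. It is a synthetic stand-in built from published scales, not
  a reprint of a published distance table; all package-level guarantees
  (homopolymer → zero coupling, unit-sum QSO, w → 0 collapse onto AAC)
  are independent of the specific entries.
- **PSSM transitions** — log-odds scores squashed with the logistic
  function; feature (a, b) is the mean over adjacent positions of
  σ(Sᵢ,ₐ)·σ(Sᵢ₊₁,ᵦ). The *product* of squashed scores (rather than a
  sum) is the committed form: it makes the 400-vector itself unit-sum
  when rows are one-hot and reduces to the constant 1/4 on a zero
  profile, both of which the tests exploit. When no profile is supplied,
  a pseudo-profile S[i, a] = BLOSUM62(residueᵢ, a) keeps the full schema
  computable offline; `featurize()` records which sequences used the
  fallback in its metadata.

Sequences of 20 residues or fewer are rejected with a named error: the
lag-20 families are undefined there, and silently padding or truncating
would change the meaning of the panel.

## Correlation pruning

`pearsonPrune()` scans features in schema order and drops feature j as
soon as some already-kept i < j satisfies |r(i, j)| ≥ 0.9 (inclusive).
Keep-first greedy order makes the result reproducible without an
importance heuristic. Zero-variance features, for which r is undefined,
are dropped and reported separately rather than propagating NaN. The
number of survivors is data-dependent and is not a contract of the
operation.

## CVFS: cross-validated consensus selection

Each of e runs splits the training data into c disjoint *stratified*
parts (stratification matters: at c = 2 on a few dozen samples an
unstratified split can produce a single-class part), fits an XGBoost
model per part, and takes the features with positive gain — a
parameter-free reading of "top-ranked" that avoids inventing a k. The
per-run intersection across parts, repeated e times with run-derived
seeds, yields e feature sets; the consensus keeps features present in at
least ⌈p·e⌉ of them. The ceiling is computed with a 1e−9 guard because
0.8 × 5 exceeds 4 in double arithmetic. Defaults c = 2, e = 5, p = 0.4.

One deliberately resolved ambiguity: hyperparameters are *not*
re-grid-searched inside every partition. The per-part models use one
fixed configuration (callers may pass a tuned one); re-searching per part
would multiply cost ~36-fold while leaving the consensus mechanics — the
part of the procedure that does the selecting — unchanged.

## HFE: hypergraph feature evaluation

Samples are vertices. Each feature's values are discretized into uniform
bins over the training range (left-closed/right-open, last bin closed, a
value on an interior boundary joins the upper bin; constant features form
a single bin; out-of-range values clamp to edge bins). Every non-empty
(feature, bin) set of samples is a hyperedge; two more hyperedges hold
the classes, so each vertex lies in exactly m + 1 edges.

The ratings come from a lazy random walk (stay with probability α,
otherwise pick an incident hyperedge ∝ its weight, then a vertex inside
∝ its weight). With uniform weights, a step that traverses edge e lands
in each class with probability proportional to the class's membership in
e — α cancels from the conditional landing distribution, so it affects
only the mixing of the simulation oracle, never the scores. That gives
the closed forms R1 = n_min/n (minority retention), R2 = n_maj/n,
R0 = |n₊ − n₋|/n (separation), with minority designated from the overall
training class sizes (ties → positive class). The test suite validates
the closed forms against an actual seeded walk simulation, within three
standard errors at 10⁵ steps.

Per-feature scores aggregate separation across bins,
S(f) = Σ_b (n_b/N)·R0(e_{f,b}) ∈ [0, 1]: 1 for a feature whose bins are
class-pure, 0 for a constant feature on balanced data, invariant to
duplicating the sample set. Features are ranked by descending S with ties
broken by ascending schema index, and the top z = round(β·m) are kept —
rounding half away from zero (base R's `round()` is banker's rounding and
would give 90.3 → 90 but 180.5 → 180), implemented as `floor(x + 0.5)`.
With m = 602 this budget yields 90, 181 and 301 features at β = 15%, 30%
and 50%. Bin counts of 5 or 10 balance resolution against hyperedge
sparsity; both are exercised.

## Classifier, metrics, attribution

`trainModel()` grid-searches XGBoost over max_depth {3, 5, 7} ×
eta {0.05, 0.1, 0.3} × nrounds {100, 300} × subsample {0.8, 1.0} by
stratified 5-fold CV accuracy on the training split only, breaking ties
toward the smaller model (fewer rounds, then shallower trees, then grid
order), then refits on the full training data. Training is single-threaded
with a fixed booster seed, so identical calls produce byte-identical
serialized bundles — asserted in the tests. The train/test split assigns
floor(0.2·n_class) samples per class to the test side, a committed
deterministic rounding rule.

Evaluation thresholds probabilities at 0.5 and derives accuracy,
precision, recall, F1 and MCC from the confusion counts; any metric with
a zero denominator is reported as 0 and flagged rather than NaN. AUC uses
the rank (Mann–Whitney) formulation with mean ranks on ties. SHAP values
are exact tree-SHAP contributions on the margin scale; per-feature mean
|SHAP| importances are summed into the nine descriptor families, and the
family sums conserve the grand total exactly. The local-accuracy identity
(base value + row sum = margin) holds to float32 representation error,
since boosters evaluate in single precision.

## The synthetic benchmark, and what it does not show

`generateSequences()` draws i.i.d. residues per class: uniform 1/20
baseline, with the positive class's cysteine frequency multiplied by 0.3
and L/I/V/F by 1.5 (renormalized); lengths uniform on 30–120; 283
sequences per class by default, with `balanceDownsample()` providing the
majority-class down-sampling utility for unbalanced inputs. The planted
direction — cysteine-depleted, hydrophobic-enriched positives — mirrors
the compositional signal that distinguishes real bacteriocins, and an
i.i.d. emission model is the right null for descriptor families that are
themselves compositional. A null configuration (identical emissions)
makes all feature scores exchangeable, which the tests verify by
permutation.

What passing on this benchmark shows: the descriptor → prune → select →
train → explain chain recovers a known compositional signal (the cysteine
composition `aac_5` reliably tops the HFE ranking) and classifies well
above chance. What it does not show: performance on real bacteriocins.
Real sequences have motif structure, length–composition dependence,
phylogenetic redundancy and database curation artifacts that i.i.d.
emissions do not emulate. The planted effect sizes also bound achievable
accuracy: with overlapping class emission distributions, even the
Bayes-optimal rule on residue counts misclassifies a nontrivial fraction
of sequences, so held-out accuracies in the high 0.8s on this benchmark
reflect the configured signal strength, not a pipeline deficiency —
stronger multipliers would push accuracy toward 1 at the cost of a less
realistic recovery problem.

Problem sizes used in the package's own simulation studies: the recovery
and end-to-end checks run on the default 283 + 283 sequences with 10 and
5 replicate seeds respectively, and the end-to-end runs use a 2-point
hyperparameter grid (max_depth {3, 5}, eta 0.3, 100 rounds) — the full
36-point grid is exercised separately on a small fixture, since grid
extent changes fit quality only marginally on data this size.

## Degenerate inputs and other committed conventions

- FASTA records with non-standard residues (B, Z, X, U, O, `*`, gaps):
  rejected by default with the offending residue and position named;
  `invalid = "drop"` discards them with a warning.
- PSSM files: only the first 20 (log-odds) columns are read, re-ordered
  into the canonical alphabet by the file's own header.
- Feature tables: TSV, header = schema names, first column `sample_id`,
  optional last column `label`, floats at 10 significant digits — enough
  for a bit-stable read/write round trip at textual precision.
- Empty hyperedges are never stored; empty selected sets are an error at
  training time; single-class partitions are an error in CVFS.
- All tie-breaks (feature ranking, grid search, SS states) are
  deterministic and documented at the point of use.

## Known limitations

- The physicochemical distance matrix behind SOCN/QSO is
  package-constructed (see above), so absolute SOCN/QSO values are not
  comparable with implementations using a published distance table, even
  though all structural properties match.
- The SS and PSSM fallbacks are intentionally simple; ingesting real
  predictions/profiles is always preferable and takes precedence.
- Binary classification only; multi-class labels and learned hyperedge
  weights are out of scope.
- CVFS selected-set sizes are seed- and data-dependent by nature; only
  the consensus mechanics, not specific counts, are guaranteed.
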