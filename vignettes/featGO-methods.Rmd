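---
title: "Feature-based GO term prediction: models, choices and limits"
author: "featGO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based GO term prediction: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

featGO assigns Gene Ontology (GO) terms to protein sequences without
using homology. The premise is that proteins sharing a function tend to
share biophysical attributes — secondary-structure content,
transmembrane helices, intrinsically disordered regions, signal
peptides, sequence motifs — even when their sequences have diverged
beyond recognition. Prediction is cast as one binary classification
problem per GO term: a support vector machine with an RBF kernel scores
a sequence's feature vector, and a Platt sigmoid converts the raw
decision value into a posterior-style confidence in [0, 1], reported to
three decimals.

The surrounding machinery follows standard practice in protein function
prediction: annotation sets are closed upwards over the "is a" relation
of the ontology before any comparison; evaluation is protein-centric
precision/recall with Fmax; and the specificity of a correct prediction
is weighted by its information content, estimated from annotation counts
as

$$IC(t) = -\log_2 \frac{N(\{t\} \cup P(t))}{N(P(t))},$$

where $P(t)$ is the set of direct "is a" parents of $t$ and $N(\cdot)$
counts the proteins annotated with every term of its argument. This
conditional (parent-relative) form has two consequences worth knowing:
a term carried by every protein that carries its parents is worth 0
bits, and along a chain the ICs telescope so that the summed IC of a
perfectly predicted root-to-leaf path equals the leaf's annotation
surprisal. Both are asserted by the test suite. The base (2, bits) is a
configurable choice; nothing downstream depends on it beyond scaling.

Only "is a" edges participate in propagation; "part of" and other
relations are ignored throughout. Domain roots are removed from
propagated sets used for comparison (they carry no information), but the
annotation table itself keeps root counts because the naive baseline and
$N(\cdot)$ need them.

## The feature registry

Each sequence is encoded through 14 named feature groups totalling 258
scalars: amino-acid composition (20), reduced-alphabet dipeptide
composition (49, seven physicochemical classes), global sequence
properties (12), physicochemical class fractions (10), secondary
structure (15, Chou–Fasman propensities smoothed over a 7-residue
window), transmembrane helices (8, Kyte–Doolittle means over 19-residue
windows, cutoff 1.6), intrinsic disorder (10, TOP-IDP propensity
smoothed over 15 residues, disordered where positive), signal peptide
heuristics (5), low-complexity summaries (5, Shannon entropy in
12-residue windows, cutoff 2.2 bits), N-glycosylation motifs (4),
phosphorylation motifs (8), coiled-coil heptad scores (4, 28-residue
windows), hydrophobic moments (8, Eisenberg scale, 11-residue windows at
100° and 160°), and property autocorrelations (100: five residue scales
× lags 1–20).

These extractors are fast, deterministic approximations built from
published residue propensity scales, not reimplementations of dedicated
predictors (PSIPRED/DISOPRED/TMHMM-class tools). Where higher fidelity
is needed, `registerExternalGroup()` swaps any group for a lookup table
of externally computed values while preserving the registry layout, so
trained models and downstream code are unaffected. Window lengths and
cutoffs above are the documented defaults; they were chosen from the
literature ranges (TM windows of 19–21 residues, disorder windows of
~15) and are not tuned per dataset.

The two composition groups sum to one by construction; the test suite
asserts this and the locality of external replacement (non-replaced
groups are bitwise unchanged).

## Per-term training protocol

For a candidate term, positives are the proteins carrying the term after
propagation; negatives are proteins annotated in the same GO domain but
with neither the term nor any of its descendants. This descendant
exclusion keeps label noise out of the negative set: a protein annotated
only below the candidate is a positive by subsumption, never a negative.
Candidates need at least `minPos = 50` positives — with fewer, the
stratified folds below cannot be filled meaningfully.

Training then proceeds as:

1. stratified 70/30 train/validation split;
2. the fold count k is the largest of {5, 4, 3} giving at least 10
   positives per stratified fold (candidates failing all three are
   rejected);
3. grid search over RBF cost and width by mean cross-validated MCC on
   the full group set. The default grid is log-spaced, cost ∈ {0.5, 2,
   8} and γ ∈ {0.25, 1, 4}/d with d the current feature count, so the
   width adapts as groups are eliminated;
4. greedy backward elimination of feature groups: each candidate removal
   gets a fresh grid search; the best removal is committed while its CV
   MCC is at least the incumbent's, iterating to convergence or a single
   group. Ties favour removal — parsimony at equal accuracy;
5. refit on the full training split, validation MCC on the held-out
   30%; the term is retained iff validation MCC ≥ 0.05;
6. retained terms are refit on train+validation, and the Platt sigmoid
   is fitted to cross-validated decision values of that final
   configuration — never to training-set decision values, which are
   optimistically biased and produce overconfident posteriors.

Class imbalance is handled by per-class error weights proportional to
inverse class frequency. Features are scaled columnwise into [−1, 1]
using the statistics of whatever subset the SVM at hand is fitted on;
columns constant in training map to 0. All randomness — split, folds,
the single fold-resampling retry on a degenerate fold — derives from one
integer seed, making training bit-reproducible.

Trained models are stored as self-describing JSON (selected groups,
hyperparameters, scaling statistics, support vectors, dual
coefficients, Platt parameters, validation MCC) plus a library
manifest, so scoring does not depend on any fitting backend's binary
serialisation format.

## Baselines

The naive model scores every term by its propagated annotation count
divided by the domain root count (three decimals), restricted to
experimentally supported evidence codes (EXP, IDA, IPI, IMP, IGI, IEP,
IC, TAS) and excluding "protein binding" (GO:0005515), and assigns that
same table to every query. Scores are anti-monotone along "is a" paths
by construction.

The similarity-transfer baseline moves a subject's annotations to the
query with confidence = alignment percent identity / 100, keeping the
maximum per (query, term). Its E-value filter keeps hits with E-value
*greater than* 1e-03: the deliberately counter-intuitive remote-homology
regime, in which transfers can only come from distant relatives. Because
the conventional direction is also useful, the filter is exposed as a
window `[evalueMin, evalueMax]`; set `evalueMin = 0, evalueMax = 1e-3`
to keep strong hits instead.

Two evidence-code lists exist deliberately: the baseline list above
includes IPI; the benchmark list used for reference annotations excludes
it (physical-interaction inferences are considered too indirect to serve
as evaluation truth).

## Evaluation

For threshold $v$, a protein's predicted set is the propagated, root-free
closure of its predictions scoring ≥ v. Precision is averaged over the
$n$ proteins with at least one prediction at $v$; recall over all $m$
benchmark proteins; $F(v)$ is their harmonic mean and Fmax its maximum
over the grid (the distinct scores united with a 0.01 lattice — scores
are 3-decimal, so the lattice loses nothing material).

The top-l evaluation ranks each protein's predictions, trims to length
l ∈ {1,...,5, n} (n = the protein's reference-set size), and resolves
score ties by uniformly sampling orderings without replacement — 1000
replicates by default, averaged within protein before averaging across
proteins. Trimmed lists are compared as emitted, without further
propagation: the object under study is the ranked list a user would
read. When the trim boundary is tie-free the deterministic trim is used
(the replicate average is exact). Rows are reported only when at least
25 proteins qualify (have ≥ l predictions and ≥ l reference terms), the
same reporting floor used for the accuracy-versus-depth summaries.
The summed information content of the true positives accompanies each
row when an IC table is supplied, so shallow-but-safe predictions can
be told apart from informative ones.

## Splice-isoform analysis

Isoform catalogues are filtered by five rules — unknown sequence,
length < 15, length > 1500, non-standard residues, isoforms recorded in
a separate database entry — with a cascade: losing a main isoform
removes its alternatives. The final dataset is invariant to the order
of rule application (the tests shuffle and compare).

Predictions become calls only when the score reaches `callThreshold`
(default 0.5 — the natural cut for a calibrated posterior; the
literature states no convention for turning posteriors into calls) *and*
the term lies in the propagated curated annotation set of the parent
entry, screening out spurious assignments.

Three statistics summarise a term g across the dataset:

* **conservation** — entries where g is called on *all* isoforms over
  entries where it is called on at least one, reported only when at
  least 20 entries are covered;
* **primarity** $\delta_G = m_G/n - a_G/(m-n)$, with $m_G$/$a_G$ the
  main/alternative isoforms carrying g, n the entry count and m the
  total isoform count. This is the difference of the two prevalences:
  +1 when g is on every main and no alternative, 0 when equally
  associated, −1 in the opposite extreme, and invariant under
  duplicating every entry. Among the functional forms consistent with
  the stated sign behaviour it is the simplest, and it needs no
  normalising constants beyond n and m;
* **feature enrichment** $E_{g,f} = (\hat p - 50)/50$, where $\hat p$
  is the mid-rank percentile of the variant-set median of feature f
  within the training positives' empirical distribution. The mid-rank
  convention makes $E = 0$ exactly when the medians coincide, ±1 at the
  distribution extremes, and handles ties gracefully; a constant
  training distribution degenerates to {−1, 0, +1} by median
  comparison.

Feature–score association uses Pearson correlation, with groups
summarised by the median over their scalars; undefined cells (fewer
than 3 pairs, zero variance) propagate as NA — the "grey cell" case.
A per-domain median cut on validation MCC (`topClassifiers`) reproduces
the top-half reporting filter used for such summaries.

## The synthetic-data generators

The generators exist so every stage is testable offline, with known
ground truth. `makeToyOntology` builds a three-domain random "is a" DAG;
`makeProteome` plants feature-to-function rules: a disorder rule draws
each protein's residues from a mixture of disorder- and order-promoting
pools with a uniform per-protein mixing weight, so disorder content
varies continuously and the planted threshold on the realised
disordered fraction is the true label boundary; a transmembrane rule
inserts a 25-residue hydrophobic stretch. Labels are the predicate
evaluated on the extracted features, flipped at the rule's noise rate
(0.1 in the reference experiment — enough to be non-trivial, well below
the 0.5 identifiability limit). Each protein also receives one
background annotation per domain, drawn uniformly outside the planted
subgraph: real proteins carry annotations beyond any single studied
term, and without them a benchmark degenerates until a constant
predictor is unbeatable. Sequence lengths are uniform on [50, 600],
inside the isoform retention window.

The reference experiment (`plantedBenchmarkWorld`) uses a 60-term
ontology, 200 training and 100 held-out proteins, plants the rule on
the deepest biological_process term, and trains the full candidate
library (every BP term with ≥ 50 positives). Problem sizes were chosen
so the planted signal is comfortably detectable (two-sample t-statistics
well above 3) while a full library train stays in the minutes range on
one core. Note what these fixtures do *not* emulate: realistic sequence
evolution, correlated annotations, database noise, or the breadth of a
real proteome — passing tests demonstrate correctness of the machinery
and recoverability of planted structure, not expected accuracy on real
data.

## Numerical and degenerate-input choices

* Scores are rounded half-up to exactly three decimals at every output
  surface.
* MCC with any zero denominator factor is 0 by convention.
* A protein with no prediction above threshold contributes to recall
  (as 0) but is excluded from the precision average, exactly as the
  n-denominator averaging prescribes.
* Platt fitting uses the stabilised Newton iteration with backtracking;
  targets are the standard smoothed frequencies.
* Fold assignment is fixed before the grid search, so every candidate
  configuration sees identical folds; a fold left single-class is
  resampled once with an incremented seed, then the candidate is
  rejected.
* OBO parsing refuses cyclic graphs and dangling `is_a` references
  (naming the stanza), maps `alt_id`s silently, and keeps obsolete
  terms out of the DAG.

## Known limitations

* The 0.05 retention floor is meaningful only when the validation set
  is large. At a few hundred proteins (say 60 validation instances),
  chance validation MCC has standard deviation near $1/\sqrt{60}
  \approx 0.13$, so a classifier trained on uninformative labels clears
  0.05 roughly a third of the time. Concentration of chance MCC below
  the floor requires validation sets in the thousands; small-study
  users should treat retention at this floor as a weak filter, not a
  significance test. The random-label control in the test suite
  documents this behaviour.
* The built-in feature extractors approximate, and cannot substitute
  for, dedicated structure predictors; the external-group hook is the
  fidelity path.
* The naive/library comparison on synthetic data is sensitive to how
  much of a small vocabulary the reference sets cover: with very few
  terms per domain, predicting everything is artificially precise. The
  reference experiment sizes the vocabulary to avoid that regime.
* Isoform conservation and primarity are descriptive statistics;
  no significance testing is attached, and none is claimed.
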