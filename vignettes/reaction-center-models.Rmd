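---
title: "Reaction-center-aware models of enzyme-reaction pairs: methods"
author: "rcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-center-aware models of enzyme-reaction pairs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Most enzymes carry secondary, less efficient activities beyond their
canonical reaction — the underground metabolism. Screening candidate
enzyme-reaction pairs experimentally is slow, so a model that scores the
hypothesis "this amino-acid sequence significantly catalyzes this reaction"
is a practical pre-screen for metabolic engineering and for reasoning about
evolvability. `rcnet` implements such a model as a two-tower scorer: a
reaction encoder and a protein tower map both inputs into one vector space,
and the score is the sigmoid of their dot product,

$$ \hat p = \sigma\big(\langle z_\text{rxn},\, W_p\, e_\text{prot}\rangle\big), $$

where $e_\text{prot}$ is a precomputed fixed-length protein embedding
(1280-dimensional by default, the output dimension of a protein language
model; the language model itself is consumed as input, never run here) and
$W_p$ is learned.

## Reactions, reaction centers, standardization

Reactions enter as atom-mapped reaction SMILES
(`reactants>agents>products`; agents are parsed and discarded with a
warning). The package carries its own restricted SMILES reader/writer for
heavy-atom graphs, because the central objects — atom maps, reaction
centers, editable molecular graphs — must survive parsing intact.
Canonicalization uses iterative invariant refinement with full
individualization branching, so isomorphic graphs always serialize
identically; this canonical form is the equality predicate used everywhere
(operator validation, RC grouping, spectator matching).

Standardization removes stereochemistry, neutralizes condition-dependent
charges through an explicit rule table (protonate O⁻/S⁻ anions, deprotonate
N⁺H; permanently charged quaternary nitrogen is left alone) and
re-canonicalizes. It is idempotent, and every fired transform is reported.
The rule table is configuration because published pipelines rarely enumerate
their normalization lists; the default covers the charge states that depend
on assay conditions (carboxylates, phosphates, thiolates, ammonium).

The **reaction center (RC)** is the atom set whose bonding environment
changes: atoms incident to a formed, broken or order-changed bond, plus
atoms whose hydrogen count changes. Including hydrogen-count changes is a
deliberate choice — without it, hydrogenations and redox steps with implicit
hydrogens would have empty RCs; hydrogens themselves are implicit and never
RC atoms. Two derivation routes exist and must agree: an exact diff over a
total atom map, and application of minimal reaction operators (mapped core
patterns; every pattern match is tried with all others protected, the
operator's bond changes and hydrogen deltas are applied, and a match counts
only if the generated products equal the actual products canonically).
Identity reactions (empty RC) are flagged and rejected at dataset load.

## Similarity metrics

**RCMCS** (reaction-center maximum common subgraph) scores two reactions as
the atom count of the largest common subgraph containing both RCs, divided
by the atom count of the larger reaction. "Common subgraph" is pinned as
follows, since the term alone underdetermines the metric: the correspondence
is injective and side-respecting (reactant atoms to reactant atoms, product
to product), atoms must agree on element (always) plus aromaticity and bond
order under the default criteria (charge is ignored — charges were
neutralized upstream), the correspondence is edge-consistent in the induced
sense (matched atom pairs are bonded in one reaction iff bonded in the
other), it contains a full RC-to-RC isomorphism, and every connected
component of the common subgraph touches the RC — except components that
cover an entire molecule in both reactions (fully matched spectator
molecules, needed so self-similarity is exactly 1 for multi-molecule
reactions). Without the RC-anchoring rule, atom-count MCS degenerates into
element-multiset matching; with it, the metric grows outward from the
mechanistic core, which is what the green-highlighted overlap of two similar
reactions should look like. Pairs whose RCs admit no compatible
correspondence score 0: the constrained MCS is empty, and a total,
conservative metric is preferable to an error.

The production search is a branch-and-bound over RC isomorphisms plus
anchored growth with an exclusion branch (complete, with an element-count
upper bound for pruning). An independent exhaustive oracle implements the
same definition without pruning and is compared against the production
path over full pairwise sweeps in the tests. Because search time is
worst-case exponential, each pair carries a **deterministic node budget**
(default 2e5 search nodes, a few seconds of work) rather than a wall-clock
timeout: budget-exhausted pairs fall back to the best correspondence found
so far and are flagged in the matrix's `flags` slot, so benchmark matrices
are auditable and bit-reproducible across machines of different speeds.

**GSI** (global sequence identity) aligns two sequences locally
(Smith-Waterman, BLOSUM62, gap open 11 / extend 1 — the field's default
parameters, via `Biostrings::pairwiseAlignment`) and divides the number of
identical aligned positions by the length of the **longer** sequence. The
denominator is a choice: an alignment-length denominator would make the
score local rather than global; dividing by the longer sequence makes two
sequences of very different length dissimilar even when the shorter aligns
perfectly, which is the intended "global" reading.

## Stratified similarity split

Generalization claims hinge on test items being controllably dissimilar
from training items. The split works on one entity type at a time (reactions
under RCMCS, proteins under GSI; pairs inherit the fold of their split
entity and the counterpart is left uncontrolled). For ascending similarity
bounds (default 0.4, 0.6, 0.8, 1.0) the not-yet-assigned pool is clustered
by single linkage at the bound — connected components of the "similarity at
least the bound" graph — and whole clusters are sampled (uniformly, weighted
by size) into the test fold until the stratum quota is met, then the bound
is relaxed. Whole-cluster sampling gives a hard guarantee: a test entity's
maximum similarity to anything outside its cluster set is strictly below the
sampling bound. The lower edge of a stratum is *not* guaranteed, so realized
maximum-train similarity is measured afterwards and entities are re-labelled
by measurement, with up to two repair iterations before the residual
imbalance is reported in the assignment. If the pool collapses into a single
cluster too large to sample at some bound, the split aborts with a collapse
error naming the bound — the behavior one hits on real protein data when
pushing the similarity floor too low. Inner cross-validation folds (default
3) re-run the same procedure on the train/validation pool.

Negatives are sampled **globally**: uniformly without replacement from the
fold's entities crossed with all counterpart entities, minus the global
positive set — 1:1 with positives in test and validation folds, 3:1 in
training folds. No auxiliary similarity metric biases the sampling; the only
assumption is sparsity of the true adjacency. The analytic bound on mislabel
probability is `observed density / assumed coverage`: at the observed
density of 0.03% and an assumed 10% coverage of true promiscuity, a sampled
negative is a true positive with probability at most 0.3%.

## Encoders

All graph encoders run **directed-edge message passing**: hidden states live
on directed bonds; the initial state is a rectified linear transform of the
source atom's features concatenated with the bond features; each update
aggregates states flowing into the edge's source excluding the edge's own
reverse (no immediate backtracking), re-adding the initial state before the
nonlinearity; node embeddings combine atom features with the sum of incoming
edge states. With $M$ total message passings the receptive field is $M-1$
bonds. Node-centric passing is not offered — it would blur exactly the
receptive-field semantics the RC-aggregated encoder depends on.

Atom features: one-hot element (C N O S P F Cl Br I B + other), degree 0-5,
formal charge -2..+2, hydrogen count 0-4, hybridization (sp/sp2/sp3/other),
aromaticity bit, atomic mass / 100, and a two-bit reactant/product side tag
(without it, mean aggregation would be blind to reaction direction). Bond
features: one-hot order, conjugation, ring membership, and a dedicated
virtual-edge bit.

* `bag_of_molecules` — plain disjoint union of all molecules; reaction
  vector = mean over atom embeddings.
* `rc_aggregated` — one initially stateless, all-zero-featured virtual node
  wired by virtual edges to every RC atom **on both sides** (the RC is
  defined on both, so wiring one side only would break the side symmetry of
  the construction); the reaction vector is the virtual node's embedding.
  With $M = 4$ the embedding depends on features within 3 bonds of the RC
  and on nothing else — a property the tests assert bit-exactly.
* `rc_connected` — virtual node present, but the reaction vector is the
  mean over **real atom** embeddings (the virtual node is not an atom and is
  excluded from the mean).
* `cgr` — condensed graph of reaction: one node per mapped atom pair
  carrying concatenated reactant/product features; edges carry
  before/after bond-state pairs with an explicit absent state for formed and
  broken bonds. Requires a total atom map.
* `morgan` — circular substructure count fingerprints (radius 2, 2048 bins)
  summed per side; the reaction fingerprint is the elementwise absolute
  difference of the side sums, then a learned linear projection. Message
  passing without learnable weights — the benchmark the GNNs are measured
  against.

Defaults follow the reference configuration: embedding dimension 300,
$M = 4$ for `rc_aggregated` and 6 for the other graph encoders, loss weights
$m = p = 3$, 25 training epochs, per-track decision threshold. Hidden
dimension defaults to the embedding dimension; the nonlinearity is fixed to
the rectifier; weight initialization is seeded Glorot.

## Training

The loss is the weighted binary cross-entropy
$l(x,y) = -[\,m p\, y \log \sigma(x) + (1-y)\log(1-\sigma(x))\,]$ with
$m$ the negative multiple and $p$ the positive multiplier (the weight
$mp = 9$ on the positive term compensates the 3:1 negative oversampling in
training folds; with $mp = 1$ it is plain BCE). It is evaluated through
softplus for numerical stability, and its analytic gradient is checked
against finite differences in the tests. One reading note: the weight sits
on the positive term exactly as written, i.e. positives carry weight
$m \cdot p$; the alternative reading (weighting negatives by $m$) is not
implemented.

Gradients flow through the package's own backward pass (cached forward
states per reaction; reverse-mode through readout, message passing and both
projections), optimized with adaptive moment estimation. Batches are
shuffled pairs with no per-batch class balancing — the loss weight already
compensates. Learning rate and batch size are not part of the reference
configuration and are package choices: `lr = 1e-3`, full batch by default;
the desk-scale experiments below use `lr = 2e-3`, batch 64, which reaches a
stable optimum on the synthetic task within the 25-epoch budget. Training is
single-threaded and bit-deterministic given the seeds: identical seeds give
identical weight checksums. The decision threshold is selected on validation
scores by maximizing F1 over midpoints of adjacent distinct scores (ties to
the smallest; a degenerate all-equal score vector falls back to midpoints
with the 0/1 bounds and is flagged).

Hyperparameters are selected by grid search with three-fold
cross-validation; negatives are resampled per rotation so the held-out fold
always carries the validation ratio. Ties resolve to the earliest grid cell.

## Evaluation

Standard confusion-matrix metrics at the selected threshold; ROC by
threshold sweep over distinct scores with trapezoid area (cross-checked
against an independent implementation in the tests); one-class inputs
produce explicit undefined markers rather than NaN. Binned evaluation
assigns each test pair to the bin of its split entity's **realized**
maximum-train similarity — entity-level binning, because the split entity is
the controlled variable — with default edges 0, 0.2, ..., 1.0 and a
low-confidence flag for bins under 10 pairs.

The RC-proximity analysis asks whether an encoder has learned
mechanism-relevant structure: reactions are grouped by their shared RC (the
RC extracted as a reaction of its own is a valid, balanced reaction and can
be embedded like any other), and the sigmoid-dot-product similarity between
the group's mean embedding and the RC's own embedding is recorded —
computed exactly the way enzyme-reaction scores are, which is meaningful
because all inputs live in one vector space. Reported per group, with the
fraction of groups at similarity at least 0.8 as the summary and a per-RC
win/loss comparison between two encoders.

## The synthetic data generator

Everything above is exercisable offline on generated data with the
statistical shape the method assumes:

* **Reactions**: six hand-written, chemically valid mapped cores (ester
  hydrolysis, ketone reduction, decarboxylation, amide hydrolysis, alcohol
  oxidation, esterification) decorated with random substituent trees at
  designated attachment points, identically on both sides, preserving the
  map. The derived RC always equals the template core, so reaction families
  share an RC by construction. Heavy-element counts balance across sides in
  every template; the two hydrogen-transfer cores (ketone reduction, alcohol
  oxidation) exchange implicit hydrogens with a redox cofactor pool that is
  not part of the represented system, exactly the implicit-hydrogen redox
  case that motivates counting hydrogen-count changes toward the RC.
* **Proteins**: clustered embeddings (centroid plus Gaussian noise) and
  mutated-centroid sequences, so GSI orders within-cluster above
  between-cluster pairs.
* **Positives**: protein cluster $c$ catalyzes reaction family
  $((c-1) \bmod F)+1$ with a within-block probability tuned to hit the
  target density (default 0.01 — sparse but learnable at this scale; the
  0.03% density of the real corpus would leave ~12 positives on a 200x200
  grid, far too few to train on, and is used for the analytic
  misassignment bound instead); a promiscuity fraction (default 5%) of
  positives is planted across families. By default only 20% of clusters are
  catalytically active toward the sampled families (`activeFraction`): with
  every cluster active, unobserved within-block pairs make up ~1/F of all
  negatives and are label-indistinguishable from positives, capping the
  achievable ranking quality regardless of model; concentrating activity
  keeps overall density sparse while the planted blocks stay dense enough
  to learn. The planted signal is RC-local by construction — labels depend
  only on the template family, never on substituents — which is the basis
  for the RC-aggregated encoder's advantage being testable at all.

Default scale is 200 reactions x 200 proteins with 1280-dimensional
embeddings, trainable in about a minute per model on one CPU; the test suite
uses smaller instances of the same generator. The learnability experiment
trains on a random reaction-level split of this dataset and reports held-out
ranking quality over three generator seeds; its chance-level control is a
permutation test — the held-out scores evaluated against seeded permutations
of the held-out labels — because with a handful of planted blocks the
retrain-on-shuffled-labels estimator is block-correlated and too noisy to
certify chance at this scale. What the generator does *not*
emulate: real reaction-chemistry diversity (six cores, not thousands),
tautomerism, real protein-family structure, or label noise. Passing tests
on synthetic data therefore demonstrate correctness of the machinery and
learnability of a planted RC-local signal — not real-corpus accuracy, which
requires the full curated database and pretrained language-model
embeddings.

## Numerical and degenerate-input choices

* Atom indices are 0-based in all external files, 1-based in memory (the R
  convention); atom-map numbers are 1-based as in reaction SMILES.
* MCS per-pair search budget 2e5 nodes, deterministic (see above); oracle
  size guard 16 atoms per side.
* Seeds fan out from the single pipeline seed by a fixed integer hash per
  stage, all below 2^31; every stochastic stage is independently
  reproducible.
* Manifests carry config and input hashes, package version and seed — no
  timestamps — so identical runs are byte-identical.
* Ties: threshold selection takes the smallest maximizing midpoint;
  cross-validation takes the earliest grid cell; operator-match assignments
  are ordered by matched atom indices.
* Collapse, empty-RC, one-class-label and insufficient-negative conditions
  are errors or flagged warnings, never silent.

## Known limitations

The SMILES subset covers the organic subset plus bracket atoms, aromatic
rings as written, and no stereochemistry (removed by design) — unusual
inorganic species may not round-trip. Aromaticity is taken as written rather
than perceived, so inputs should use a consistent aromatic form.
Operator patterns are concrete mapped cores (element-exact with free
substitution), a deliberate subset of full SMARTS. The MCS node budget
makes very large similarity problems approximate (flagged, never silent).
Training is CPU-bound and intended for desk-scale experiments; the
architecture matches the reference configuration, but reproducing published
real-corpus accuracies is out of scope here.
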