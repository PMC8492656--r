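---
title: "Closed-loop design of chimeric enzyme libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop design of chimeric enzyme libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraML)
```

`chimeraML` engineers chimeric enzymes by recombining a small set of
homologous parents at structurally chosen breakpoints and searching the
resulting combinatorial library with an active-learning loop. This
vignette explains the models, the tunable parameters, the synthetic
landscape used for validation, and the numerical and design choices made
where the method leaves room.

## The chimera space

A `parent_set` holds aligned parent sequences (single alignment, gaps
allowed) split into a fixed N-terminal domain and a recombined C-terminal
region, which a `block_partition` cuts into contiguous blocks. A chimera
is written `"A-ATBBAAAB"`: the label before the dash donates the fixed
domain, the rest donate the blocks. Within R all alignment coordinates are
1-based (the natural R convention); all serialized artifacts — partition
JSON, contact-map TSV, interface JSON — use 0-based, half-open
coordinates, which is the convention the files are documented with.

Parents that donate an identical block sequence are indistinguishable at
that block, so `enumerate_space()` collapses them and returns one
canonical representative per distinct protein (alphabetically smallest
label). With three parents, eight blocks, and one block conserved between
two parents this yields the 2·3⁷ = 4374 distinct sequences of the default
synthetic system. Deduplication matters everywhere downstream: landscape
effects, encodings and block distances are all keyed on label *groups* so
that protein-identical chimeras behave identically.

## Disruption scoring and breakpoint placement

The structural cost of recombination is scored against an
ensemble-weighted contact map: residues i and j are in contact when any of
their heavy atoms lie within `cutoff` (default 4.5 Å, all-atom; hydrogens
and alternate conformers beyond the first are ignored), weighted by the
fraction of ensemble models containing the contact. Sequence-adjacent
pairs (|i−j| < 2) are excluded — they are intact in every chimera and
carry no signal; the margin is configurable via `min_seq_sep`.

A chimera's disruption E sums the weights of contacts whose residue pair
co-occurs in no single parent (the standard recombination rule), and its
mutation level m is the aligned Hamming distance to the closest parent.
`raspp()` searches breakpoint placements by dynamic programming: for the
DP objective the broken fraction of each contact is computed under
uniform, independent block labels, which makes library-average disruption
separable into per-block "saved" weight; candidates from a sweep over
(minimum, maximum) block-length constraints are then re-scored *exactly*
by full enumeration, binned on integer ⟨m⟩, reduced to per-bin minima and
returned as a nondominated frontier. Ties break on lexicographic
breakpoint order for determinism. Golden-Gate-style assembly constraints
enter as the caller-supplied `allowed_columns` set; the package does not
model overhang chemistry.

## Seed design

The first batch should be maximally informative rather than maximally
active. Informativeness of a set S drawn from the library is its Gaussian
entropy H(S) = ½ log det(2πe K_SS) under the model prior; because entropy
is submodular, greedy selection enjoys the usual (1 − 1/e) guarantee.
The marginal gain of a candidate is ½ log of its posterior variance given
the current set, so each greedy sweep scores all candidates with one
Cholesky factorization. Numerical choices: a jitter of 1e-8 × mean
diagonal is added before factorization (duplicate encodings otherwise make
K singular); ties break on the alphabetically smallest block string; the
selection starts from the parental chimeras; σ² defaults to 1 (the argmax
at fixed set size does not depend on it). Whether "20 seeds" counts the
starting parents is ambiguous in this kind of protocol, so both readings
are supported (`count_includes_initial`).

## Sequence-function models

**Encodings.** The default `hamming` scheme one-hot encodes each distinct
parental residue option at each alignment column; `structure` encodes
residue-pair combinations at contacting column pairs; `block` is a coarse
per-block label one-hot. Columns conserved across all parents contribute
only a constant to a linear kernel and are dropped by default
(`drop_conserved = FALSE` restores them for exact-dimension work). A
useful property of the full one-hot basis is that each column's options
sum to one, so constants lie in the feature span and the homogeneous
kernel loses nothing by lacking an explicit bias term.

**Classifier.** Activity is binarized at `activity_threshold` (default
1 mg/L — the assay's practical detection scale; the choice is exposed
because any threshold between blank-level noise and the weakest parent
gives the same labels on realistic data). The Gaussian naive Bayes
classifier floors per-feature variances at 1e-9 × the largest feature
variance to survive constant features, and degrades gracefully to a
constant predictor (with a warning) on single-class data.

**Regressor.** The GP uses k(x, x′) = σ² x·x′ with observation noise
σ_n². Targets are mean-centered (mean restored at prediction); the
campaign additionally scales titers by their standard deviation, so the
default σ_n² = 1 means "about one sample-sd of noise", a deliberately
conservative setting that the σ² scan compensates for. Posterior mean and
variance use the Cholesky factorize-and-solve route; when σ_n² = 0 a
jitter of 1e-8 × mean diagonal keeps the factorization well posed, and
predictive variances are clipped at zero.

**Hyperparameter scan.** σ² is scanned over 23 log-spaced values
(half-decade steps, 10⁻⁶ … 10⁵ inclusive). Leave-one-out predictions come
either from n explicit refits or from a closed-form path using the
standard LOO identity, extended to handle the leave-one-out training mean
exactly; the two agree to numerical precision and the fast path is used
in the loop. Maximizing LOO correlation and minimizing LOO MSE can
disagree; the deterministic "balance" rule picks the grid value with the
smallest sum of ranks of (−r, MSE). Constant targets make r undefined, in
which case selection falls back to MSE with a warning.

## Acquisition and the campaign loop

UCB scores are μ + β·sd with β = 1. Batches are assembled by
hallucination: the current argmax is added to the training set as a
pseudo-observation at its own posterior mean — with the same σ_n² as real
data, keeping the refit identical in kind — then scores are recomputed.
Hallucinated points never leave the batch-selection routine. Proposal ties
break on canonical block-string order.

`run_campaign()` drives: greedy seed round, then per round — refit the
classifier on all real data (skipped while fewer than 2 actives or no
inactives exist), refit the regressor, rescan σ², filter the pool
(tested sequences out; classifier-predicted inactives out at the 0.5
cutoff; optionally sequences more than `max_block_distance` exchanges from
every parent), propose a batch, measure, append. The default restricts
rounds 1–3 to at most 4 block exchanges — highly shuffled chimeras are
almost always dead early on, and the cap biases the search toward
functional sequence space while the classifier is still data-starved; the
exact cap and duration are design choices, exposed per round.

`gp_training` selects the regressor's training set: `"active"` (default)
fits on the active subset only, leaving the inactive mass to the
classifier — the division of labor the two-model stack is built for —
falling back to all data while fewer than 4 actives exist; `"all"` fits
on everything. On the default synthetic landscape the active-only setting
finds top-1% chimeras and beats the random baseline more reliably, which
is why it is the default; both are tested.

All campaign randomness derives from one master seed via fixed integer
sub-seeding, making runs bit-reproducible.

## The synthetic landscape

The simulator emulates the statistical structure of an in vivo
fatty-alcohol production assay over the default 4374-chimera library:

* base titer 10 mg/L for the reference parent; per-(block, label group)
  additive effects drawn uniformly on ±15 mg/L (reference labels
  contribute 0), redrawn until every parent stays viable — a library is
  only ever built from functional parents;
* 12 sparse pairwise epistatic terms on ±5 mg/L;
* disruption-linked inactivation: a logistic in SCHEMA E (slope 3,
  hard threshold at slope 0) whose midpoint is placed at the E-quantile
  that brings the *total* inactive fraction — rule-inactivated plus
  additively nonviable — to the target of 70%, matching the regime where
  the large majority of a diverse seed sample is dead;
* replicate noise with sd = 1 mg/L + 20% of the true titer, totals
  clipped at zero — about the replicate spread a shake-flask/GC pipeline
  shows;
* a C16-dominated chain-length mixture (70% C16, 25% C14, 5% C12),
  reflecting that long-chain acyl carriers dominate the precursor pool.

What it deliberately does *not* model: strain-to-strain substrate-pool
differences, expression-level variation, batch effects and assay drift,
or any interface-electrostatics contribution to activity (charge-linked
landscapes can be constructed explicitly for tests). Passing closed-loop
tests on this landscape therefore demonstrates that the optimizer works
when activity is mostly block-additive with disruption-gated activity and
honest replicate noise — not that it would achieve any particular titer
on real pathway flux.

## Validation surface and problem sizes

The test suite checks every numerical component against an independent
oracle: GP posteriors against dense-inverse solves, LOO fast path against
n refits, contact maps and interface sets against brute-force all-pairs
distance scans on toy structures, SCHEMA E against a per-contact
reimplementation, enumeration against translate-and-deduplicate, RASPP
against exhaustive partition search on small alignments, greedy seeding
against stepwise entropy maximization, and the quantitation formula
against hand arithmetic. The closed-loop property — finding a top-1%
chimera and matching or beating an equal-budget random search in at least
8 of 10 seeded campaigns at the standard budget (3 parents + 20 seeds +
10 rounds × 10 proposals) — runs on the full 4374-sequence space; block
effect recovery (r > 0.9) uses 96 simulated measurements. These sizes
keep the whole suite in the minutes range on a single CPU while
exercising the library at its real scale.

## Known limitations

* The homogeneous linear kernel cannot express interactions between
  blocks beyond what the structure encoding's pair features capture;
  strongly epistatic landscapes will cap its predictive ceiling.
* RASPP's frontier is generated through the classic block-length-sweep
  heuristic; it recovers the global minimum-disruption partition but is
  not guaranteed to populate every mutation-level bin with that bin's
  exact optimum.
* The GNB classifier assumes feature independence within classes; on
  one-hot encodings this is wrong in detail (options within a column are
  exclusive) yet works well as a screen, which is all it is used for.
* Strains are modeled independently (`combined_ucb()` sums per-strain
  scores); no information is shared across strains.
* The simulator's inactivation draw is Bernoulli per chimera and frozen
  inside the `landscape_spec` object; it does not model assay-level false
  negatives that re-measurement could flip.
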