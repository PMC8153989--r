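---
title: "Methods: multi-graph representations for drug-disease link prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-graph representations for drug-disease link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`graphdr` predicts drug-disease associations by fusing two node
representations of the bipartite association network — an attribute view
propagated by one graph-convolution pass and a topology view learned from
biased random walks — and classifying pair feature vectors with a Random
Forest. This vignette is the package's own account of the model, its
assumptions, the tunable parameters, the numerical choices, and what the
synthetic benchmark does and does not establish.

## The association network and its canonical order

All matrices share one node order: drugs sorted lexicographically occupy
rows `1..n_d`, diseases `n_d+1..n`. The order is a pure function of the
input file's id set, so every artifact (adjacency, attributes,
convolution features, embeddings, fused pair features) is reproducible
from the inputs alone. The association table is an edge list; a drug or
disease that appears in no pair is simply not part of the network.

## Disease semantic similarity

A MeSH-style tree number such as `C04.557.337` encodes its whole ancestry:
each dot-prefix is an ancestor. A disease's DAG is the union of the
prefix chains of its codes. The contribution of the disease's own code(s)
is exactly 1, and every ancestor `t` contributes
`D(t) = max{ mu * D(t') : t' child of t }` — one decay per edge along the
best path down to a self code. The semantic value `DV(a)` sums the
contributions, and the similarity of two diseases is the shared-ancestor
mass `sum(D_a + D_b)` over `DV(a) + DV(b)`.

Choices worth recording:

* **`mu = 0.5`** (dimensionless decay per hierarchy edge). The measure's
  lineage conventionally uses 0.5; the value is exposed in every surface
  that computes similarities. Larger `mu` flattens the hierarchy (remote
  ancestors count almost as much as the disease itself), smaller `mu`
  makes similarity nearly a shared-leaf indicator.
* **Multiple tree numbers.** A descriptor can legitimately occupy several
  hierarchy positions. Each of the disease's own codes receives
  contribution 1, including a code that is simultaneously an ancestor of
  another of its codes; the max-rule then propagates whichever path is
  stronger. This is a deliberate convention — the measure's definition is
  silent on multi-position descriptors.
* **Algorithm.** Contributions are computed by dynamic programming in
  deepest-first order, which is exact because prefix DAGs only have edges
  from depth `d` to `d+1`; the test suite verifies equality with an
  exhaustive path-enumeration oracle at tolerance 1e-12. Ties in the max
  are unambiguous (the max of a set needs no tie-break).

## Drug fingerprints and the unified attribute matrix

Drug structures (SMILES) are hashed into Morgan/ECFP-style circular
fingerprints. Neighbourhood enumeration and hashing are delegated to
OpenBabel's ECFP implementation via ChemmineOB (radius `r` maps to
`ECFP(2r)`); the native 4096-bit vector is folded to `n_bits` by OR-ing
positions modulo `n_bits` — the standard folding operation, which
preserves set bits at the cost of collisions. Defaults `radius = 2`,
`n_bits = 1024` are the ECFP4 convention. Unparseable SMILES raise an
error naming the drug; the implementation never zero-fills silently,
because an all-zero row would masquerade as a structureless molecule.

Graph convolution needs one attribute dimension for all nodes, but drugs
and diseases carry incommensurable signals (hashed substructure bits vs.
similarity profiles). They are merged by zero-padded block concatenation:
drug rows are `[fingerprint | 0]`, disease rows `[0 | similarity row]`,
`k = n_bits + n_z`. Blocks preserve both signals without an arbitrary
projection; the convolution's random projection then mixes them across
edges.

## View 1: one-pass graph convolution with a random projection

The default propagation is `H = sigma(Ã X W)` with `Ã = A + I` and a
rectifier; a normalized mode applies `D̃^{-1/2} Ã D̃^{-1/2}` first and is
kept for ablation (its identity-activation limit is tested against the
explicit triple matrix product). `m = 64` output dimensions.

`W` is drawn once (Glorot-uniform by default) and **never trained**. No
loss or backpropagation is defined for this stage anywhere in the
procedure: it is a fixed random graph filter in the spirit of random
projections, whose value lies in mixing each node's attribute block with
its neighbours' before classification. Describing it as a neural network
being "trained" would overstate it; the seed of the draw is therefore
mandatory configuration and is recorded in the result object and every
persisted report. Dense base matrices are used throughout — the intended
scale (hundreds to a thousand nodes) does not justify a sparse path.

## View 2: biased walks and skip-gram

Second-order walks: after traversing `t -> v`, neighbour `x` of `v` is
drawn with unnormalised weight `alpha(t, x) * w(v, x)` where `alpha` is
`1/p` for returning (`x = t`), 1 for common neighbours of `t` and `v`,
and `1/q` otherwise. The first step of a walk has no predecessor and is
weight-proportional (`alpha = 1`), the original method's convention.
Defaults `p = q = 1`, walk length 80, 10 walks per node, window 10, 64
dimensions, 5 epochs — the walk method's published defaults, since the
procedure this package implements states none; the embedding dimension
mirrors the convolution's `m = 64` so neither view dominates the fused
vector by width alone.

The sampler and the skip-gram trainer (negative sampling, 5 negatives,
linearly decaying learning rate from 0.025, single-threaded SGD) are
compiled code using a xoshiro256++ generator seeded through splitmix64,
so corpora and embeddings are bit-reproducible across platforms for a
given seed — R's own RNG state is never touched by the compiled loops.
Transition sampling is by direct normalisation over the current node's
neighbour list; at the intended scale this is cheaper than precomputing
alias tables per traversed edge. Isolated nodes produce no walks (logged)
and later fall back to zero embeddings during fusion (logged); dead ends
truncate a walk early.

## Pairs, negatives, evaluation

Positives are the known associations. Negatives are drawn uniformly
without replacement from the unobserved cells of the drug x disease grid
at ratio 1:1 — reported sensitivity/specificity panels imply a balanced
design, and the ratio is configuration. The unobserved complement
inevitably contains undiscovered true associations; treating them as
negatives is the field's standard approximation and biases all reported
metrics slightly downward.

Thresholded metrics (accuracy, sensitivity, specificity, precision, MCC)
use operating point 0.5; AUC is the Wilcoxon rank statistic with
midranks for ties; AUPR integrates the precision-recall step curve over
distinct thresholds. MCC is defined as 0 where its denominator vanishes.
All are verified against brute-force recomputation at 1e-10.

Cross-validation is stratified over pairs (not over drugs or diseases):
every labelled pair is tested exactly once, and both classes appear in
every fold. The default classifier is a 500-tree Random Forest with
sqrt-features per split, single-threaded so reruns are byte-identical;
support-vector, logistic, nearest-neighbour and gradient-boosting
alternatives sit behind the same interface.

**Transductive vs. leakage-safe.** By default the walks and the
convolution see the full association graph, including edges later held
out — the single-pass workflow the method describes, and a genuine
leakage channel that inflates AUC. `transductive = FALSE` recomputes both
views inside each fold from training edges only; held-out nodes absent
from the training graph get zero embeddings. Both protocols are labelled
in the report metadata, and the test suite asserts the directional
property (leakage-safe does not outperform transductive).

## The synthetic benchmark

The generator plants a block structure: drugs and diseases are assigned
uniformly to `n_blocks` blocks; an edge appears with probability
`density` within a matched block and `background` across. Fingerprints
are per-block prototypes (balanced random bits) flipped at rate
`attr_noise`; disease ontologies extend a per-block "spine" of tree-number
components, so within-block semantic similarity exceeds between-block
similarity (exactly 0 across blocks, whose roots differ).

The canonical fixture — 60 drugs, 100 diseases, 4 blocks, density 0.30,
background 0.02, 256 bits, noise 0.05, ontology depth 4, seed 7 — keeps
the expected positive count near 540 (binomial; the suite asserts the
observed count within its 3-sigma band) at overall density ~9%, desk-scale
in seconds. Sizes were chosen so the full acceptance run, including five
evaluation seeds and three feature modes, completes in minutes on one
core.

What passing on this benchmark shows: the pipeline's stages compose
correctly and recover a planted joint signal (topology + attributes)
well above chance, with ablations behaving sensibly. What it does not
show: performance on real pharmacological data. Real fingerprints are
sparse and hierarchical rather than balanced-prototype-plus-noise; real
association networks have heavy-tailed degrees, not block-uniform ones;
real MeSH trees share ancestry across branches. The benchmark is a
correctness instrument, not a claim about clinical utility.

## Degenerate inputs and numerical corner cases

* Empty association files, single-class label vectors, classifiers asked
  to rank a drug associated with every disease, and embedding requests on
  edgeless graphs all raise early, named errors rather than propagating
  NaNs.
* Candidate rankings break score ties lexicographically by disease id so
  output order is deterministic.
* Embedding text files round-trip to at least 8 significant digits
  (`%.10g`); report JSON is written at full precision.
* The pipeline driver validates its whole configuration (unknown keys,
  mode-dependent required inputs) before any computation starts, and
  persists a resolved-configuration snapshot next to its outputs.

## Known limitations

* The attribute view's random projection is untrained by design; a
  learned projection could plausibly do better but would need a training
  objective this method does not define.
* Identifier cross-mapping (e.g. between association-database chemical
  ids and structure-database ids) is out of scope: inputs arrive
  pre-mapped.
* Negative sampling treats unobserved pairs as negatives (see above).
* Dense matrices bound practical problem size to a few thousand nodes.
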