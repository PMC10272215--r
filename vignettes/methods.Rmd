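---
title: "Methods: semantic-teleport walks, typed embeddings and treatment prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic-teleport walks, typed embeddings and treatment prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Molecular knowledge graphs connect drugs, genes/proteins, diseases and
pathways through experimentally supported relations. Guilt-by-association
on such a graph — inferring what a drug does from the neighbourhood it
occupies — sees only the molecular layer. Drugs and diseases, however, also
carry curated *semantic* structure: classification hierarchies (ATC for
drugs; MeSH, Disease Ontology or ICD for diseases) that group entities by
indication and mechanism. `semwalk` extends random-walk graph embedding
with a **teleport operation** that moves the walker between semantically
similar drugs (or diseases), so that the learned space mixes molecular and
semantic evidence, and then predicts drug–disease treatment links from the
embeddings.

The pipeline has five stages.

**1. Semantic similarity.** Each hierarchy is a DAG of terms. The
information content of a term $c$ is
$$IC(c) = 1 - \frac{\log(N(c) + 1)}{\log(N(\mathrm{root}) + 1)},$$
where $N(c)$ counts the terms subsumed by $c$ (transitive descendants).
$IC$ is 0 at the root, 1 at leaves, and non-decreasing along any
root-to-leaf path. Two terms are compared through their most informative
common ancestor (MICA):
$$dist(c_1, c_2) = IC(c_1) + IC(c_2) - 2\,IC(\mathrm{MICA}(c_1, c_2)),
\qquad sim = 1 - dist/2 .$$
Entity-level similarity is the maximum over the entities' term pairs, and
pairs at or below a cutoff (default **0.4**) are masked, yielding a sparse
similarity matrix $S$ per node type. The cutoff suppresses weak relations
(any two drugs are weakly related through the root) and keeps teleport
targets meaningful.

Two conventions deserve a note. First, the denominator uses
$\log(N(\mathrm{root})+1)$: this is the only form under which the bounds
$IC(\mathrm{root})=0$ and $IC \in [0,1]$ hold exactly, and those bounds are
what the rest of the method relies on (maximal distance 2, similarity in
$[0,1]$ with $sim(c,c)=1$). Second, $N$ counts *all* descendants rather
than direct children; the direct-children variant is not monotone along
paths and is provided only as a sensitivity option
(`compute_ic(..., method = "children")`). Multi-rooted hierarchies get a
virtual super-root so every term pair is comparable; entities mapped to
several terms are combined by the maximum (most specific shared role),
with a mean option.

**2. Edge-type transition matrix.** Heterogeneous graphs mix edge
semantics (protein–protein, drug–target, disease–gene, ...). A matrix
$M \in \mathbb{R}^{m \times m}$ over the $m$ edge types reweights steps:
after arriving through type $i$, an edge of type $j$ is scaled by
$M_{ij}$. $M$ is learned by expectation–maximization: starting from all
ones, each iteration samples a walk set under the current $M$ (without
teleport — the matrix models edge-type co-occurrence on the graph itself),
counts each type's occurrences per walk, and sets
$M_{ij} = \mathrm{sigmoid}(\rho(v_i, v_j))$ with $\rho$ the Pearson
correlation of the per-walk count vectors. Zero-variance counts get
$\rho = 0$ (a neutral $M_{ij} = 0.5$) rather than NaN. We run at most 5
iterations with early stopping when no entry moves by more than $10^{-3}$;
the estimate is a sampled quantity, so tighter convergence would chase
Monte-Carlo noise.

**3. Teleport-guided walk.** At a drug or disease node $v$ with a
non-empty similarity row, the walker teleports with probability $\tau$
(default **0.3**), landing on node $n$ with probability
$\tau \, S_{vn} / \sum_k S_{vk}$; otherwise (and always at other node
types) it traverses an edge with unnormalized weight
$$w_{vn} \cdot M_{T(u,v),T(v,n)} \cdot \alpha_{pq}(n, u),$$
where $\alpha_{pq}$ is the node2vec bias: $1/p$ to return to the previous
node $u$, 1 to a neighbour of $u$, $1/q$ otherwise (defaults $p=q=1$,
i.e. neutral). A teleport has no edge type and no meaningful previous
node, so the following step is treated as a fresh start ($M$ factor and
$\alpha$ drop out); similarly a teleport never lands on the current node,
since the similarity matrix stores no self-entries. Drug/disease nodes
whose similarity row is empty traverse with probability 1, and a node with
graph neighbours removed entirely (e.g. a drug only connected through
treatment edges) teleports with probability 1 — that is how such entities
still receive embeddings. From every node we sample 100 walks of 4 nodes
(3 steps); `walk_length` counts nodes. Each walk consumes an RNG
substream derived from (seed, start node, walk index), making corpora
reproducible and independent of scheduling.

**4. Typed skip-gram.** The corpus is embedded with skip-gram and negative
sampling (dimension default **128**, window **4**, 5 negatives, 5 epochs,
initial learning rate 0.025 with linear decay — standard word2vec
conventions where the method itself is silent). The heterogeneous twist
is that negatives for a (center, context) pair are drawn from the unigram
distribution (power 3/4) restricted to nodes of the *context* node's type,
so embeddings stay aware of the node-type structure. We key the pool to
the context (rather than the center) following the metapath2vec++
convention. Teleport steps do not break the window: the walk is used as a
sentence. Training is single-threaded with its own PRNG, so a seed fixes
the embedding exactly.

**5. Prediction and ranking.** A (drug, disease) pair is featurized as the
element-wise difference of its two embedding vectors and classified with
gradient-boosted trees (500 rounds, maximum depth 5 — "below six"). Known
treatments are the positives; negatives are sampled uniformly from the
unlabeled drug-by-disease grid, one *disjoint* set per repeat or ensemble
member, equal in size to the positive set (no reliable true negatives
exist for treatment relations, so unlabeled pairs serve as negatives).
Evaluation is ten-times ten-fold cross-validation (accuracy, AUROC, AUPR;
mean and 95% t-interval over the ten repeat means), or a *disease split*
that holds out whole disease categories in an approximate 8:1:1
train/validation/test ratio so that test-category diseases are never seen
in training. For repurposing, every unlabeled drug is scored by each
ensemble classifier and ranked by mean probability (ties broken
lexicographically by drug id, for deterministic output). Validation
partitions are produced but not used for tuning: hyperparameters are
fixed, and early stopping is off by default.

## Interpretation utilities

The *window neighbours* of an entity are the gene nodes appearing within
$l$ positions of its occurrences across the corpus ($l = 2$ for
neighbourhood inspection, $l = 4$ matching the training window for
enrichment). These gene sets are tested for over-representation against
user-supplied gene sets (GMT-style files) with a one-sided Fisher's exact
test — one-sided because over-representation is the directional question —
and Benjamini–Hochberg correction.

Distances within one embedding space are Euclidean; across spaces they are
compared after z-score normalization against the mean and standard
deviation of *all* pairwise distances of each space (a within-type option
exists but is not the default, since the reference population the
normalization emulates is the whole space). Space comparisons use
two-sided paired t-tests; p-values below the double-precision floor
(~1e-308) are reported as `"< 1e-308"`.

## The synthetic study system

`generate_fixture()` builds the study conditions: a drug–gene–disease–
pathway graph with planted structure at desk scale, defaulting to 40
drugs, 200 genes, 30 diseases, 8 pathways and 4 gene modules. Genes
dominate the node set (72%), mirroring the protein-interaction layer's
dominance in real knowledge graphs. Protein–protein edges are dense
within a module (0.25) and sparse between (0.02); each drug targets 3
genes of a single module and each disease is annotated with 4 — sparse
enough that two same-module entities usually share no genes, which is
precisely the regime where molecular guilt-by-association alone is weak
and the semantic layer should help. A drug treats a disease exactly when
their modules match; 20% of these true pairs are withheld from the labels
(and from the graph) for recovery experiments. Drug and disease
hierarchies are depth-3 balanced trees whose leaf clusters coincide with
the modules, so semantic similarity correlates with shared indication by
construction: same-module entities score between ~0.42 and 1 (above the
0.4 cutoff), cross-module pairs score 0. A 10% noise layer of random
gene–gene, drug–gene and disease–gene edges (carrying their own edge type,
so construction invariants stay checkable) blurs the molecular signal.

What the generator does *not* emulate: realistic degree distributions
(scale-free interactomes), overlapping or nested disease categories,
weighted evidence scores, incomplete ontology annotation, or
million-edge scale. Passing tests on the fixture therefore demonstrate
that the machinery recovers planted multi-layer structure under noise —
not performance on any real knowledge graph.

## Numerical and design choices

- Natural logarithms throughout; the IC ratio is base-invariant.
- Stored similarity entries are strictly above the cutoff; raising the
  cutoff can only remove entries (tested as a nesting property).
- `step_distribution()` is the pure-R reference law; the compiled sampler
  is validated against it empirically (3-standard-error bands) and, for
  $\tau = 0$, against brute-force node2vec enumeration exactly.
- Zero-variance guards: Pearson on constant count vectors is defined as 0;
  z-normalization refuses spaces whose pairwise distances have (relatively)
  zero variance; identical spaces compare as "no difference" (p = 1).
- Walk starts cover every node regardless of type; start nodes with no
  valid first step are skipped and reported as unreachable.
- Multi-edges (same endpoints, different edge types) are supported; rows
  duplicated as unordered endpoint pairs per type are collapsed on input.
- The similarity range is stated as $[0,1]$: $sim(c,c)=1$ follows from
  the formulas even though masking means stored cross-entity values are
  typically below 1.
- Whether real studies combine multiple codes per drug by max or mean is
  unknowable from outside; max is the default, mean is a flag, and the
  choice is recorded in the similarity artifact header.

## Problem sizes in the test suite

The suite exercises the full default study conditions where the claim
demands it: planted-treatment recovery runs the complete pipeline
(similarity cutoff 0.4, $\tau = 0.3$, 100 walks of length 4, dimension
128) under semantic, absent and random teleport on ten seed replicates,
comparing held-out AUROC and same-indication z-distances by one-sided
paired t-tests; the teleport-rate law is checked on over 50,000 step
decisions. Unit tests of mechanics (I/O, folds, ensembles) use smaller
planted graphs (12 drugs, 60 genes, 8 diseases) and fewer boosting rounds,
since they test contracts rather than the scientific effect. The
classifier ensemble in the recovery experiment uses 3 members: with a
4-module planted grid, 20% of the drug-by-disease grid is positive, and
at most 4 *disjoint* negative sets of that size exist — the 10-member
default remains appropriate for sparse real-world label sets.

## Known limitations

- The EM transition matrix is estimated from sampled walks, so its entries
  carry Monte-Carlo noise of order $1/\sqrt{\text{walks}}$; the early-stop
  tolerance is matched to that noise floor.
- Teleport requires an ontology mapping; unmapped drugs/diseases behave as
  plain graph nodes (or are reported unreachable if also isolated).
- Negative sampling treats unlabeled pairs as negatives; estimated
  probabilities are rankings, not calibrated treatment likelihoods.
- The skip-gram trainer is deliberately single-threaded for exact
  reproducibility; multi-threaded word2vec implementations would be faster
  but non-deterministic.
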