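---
title: "Pathway-structured sparse networks: model, construction, and interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-structured sparse networks: model, construction, and interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`pathnn` classifies cancer patients into long-term survival (LTS; alive or
dead, but observed past 60 months) versus short-term survival (non-LTS; died
within 60 months) from binary genomic alteration features. The network is a
stack of masked affine layers

$$ y = f\big((W \circ M)\,x + b\big), \qquad f = \tanh, $$

where the binary mask $M$ is fixed by a curated pathway hierarchy and only
unmasked weights are trainable. Reading upward from the input:

* **Input layer** — for each gene, three binary features: mutation (any
  somatic mutation), amplification (CNV call $+2$), deletion (CNV call
  $-2$). Intermediate CNV calls $\pm 1$ carry no signal by construction.
* **Gene layer (diagonal)** — one node per gene, connected only to its own
  three feature columns. No cross-gene mixing happens here; this layer
  learns, per gene, how to weigh its alteration types.
* **Pathway layers 1–k** (default $k = 4$) — one node per pathway. Layer 1
  nodes receive the genes annotated to them (the membership adjacency $A$,
  $a_{ij} = 1$ iff gene $j$ belongs to pathway $i$); higher layers receive
  their child pathways (parent–child masks). tanh keeps every hidden node in
  $[-1, 1]$.
* **Heads** — every hidden layer carries a single-unit sigmoid head. The
  model's probability of the positive class (non-LTS, poor prognosis) is a
  convex combination of the heads, uniform by default.

Assumptions worth stating: alterations are treated as exchangeable binary
events (no variant effect sizes, no allele dosage); the pathway hierarchy is
taken as ground truth and never learned; the outcome is a binary horizon
label, not a survival time — censoring before the horizon is handled by
exclusion, not by likelihood weighting.

# From hierarchy files to a network blueprint

The three Reactome-dialect inputs are a gene-set GMT, a two-column
parent–child relation TSV, and a three-column name TSV. Relations are
filtered to the species of interest by an id keyword (default `"HSA"`),
assembled into a DAG (cycles are rejected with the offending edge named),
and layerized:

* **Depth rule.** Roots (in-degree 0) form layer 1; every node is placed at
  one plus its *longest* path from any root. The source material never
  states how a node reachable at several depths is placed; longest-path is
  our decision. It guarantees that for every edge the child is strictly
  below the parent, so every printed edge can be realized in a
  layer-adjacent network. (Shortest-path placement would strand edges whose
  parent sits above the child's shallowest position.)
* **Copy chains.** An edge that skips levels (child more than one layer
  below its parent) is realized by pass-through copies *of the child* at the
  intermediate layers: `P -> C::copy3 -> C` for a parent at layer 2 and a
  child at layer 4. Copies resolve to their original for gene-set lookup.
  Copying the child (rather than the parent) means the pass-through carries
  the child's output upward, which is the semantics the reversed network
  needs.
* **Selection and reversal.** DAG layers $1..k$ are retained and reversed:
  the deepest retained DAG layer becomes pathway layer 1 (nearest the
  genes), the root layer becomes pathway layer $k$ — child outputs feed
  parent inputs.
* **Pruning.** A pathway-layer-1 node with no annotated genes is untrainable
  (its mask row would be all zero) and is pruned with a warning; pruning
  then proceeds bottom-up so every retained node keeps at least one input.
  Nodes whose *outputs* go nowhere are retained — only all-zero mask *rows*
  are forbidden.
* **Determinism.** Nodes are ordered lexicographically within a layer and
  genes lexicographically in the gene list, so identical inputs produce
  byte-identical mask serializations (round-tripped through a
  `layers.json` + sparse-triplet directory).

# Cohort preparation

* Mutation input (MAF-lite records or a count matrix) is binarized by the
  at-least-one rule. Symbols absent from the hierarchy gene list are dropped
  with a logged count; omics matrices missing a sample are imputed all-zero
  with a logged message (mirroring cohorts where mutation and CNV profiling
  disagree by a few samples).
* CNV must already be on the five-level scale $\{-2,-1,0,1,2\}$; anything
  else is a validation error naming the gene and sample.
* Labeling: months $> 60$ is LTS regardless of vital status; died before 60
  months is non-LTS; alive with less than 60 months of follow-up fits
  neither definition and is excluded. Exactly 60 months is assigned LTS (the
  two printed definitions — "more than" and "less than" — leave the
  boundary open; we close it on the LTS side and expose the horizon as a
  parameter).
* The positive class is non-LTS (label 1). The sigmoid output is described
  as 1 = poor prognosis, and with an ~80% non-LTS cohort only the majority
  class as positive is consistent with precision/recall of the reported
  shape (recall 1 at precision ≈ 0.84).
* Splitting is 80/10/10 with validation and test sizes
  $\lfloor f N \rfloor$ and the remainder to training; within that, class
  counts follow largest-remainder proportional allocation, so the split is
  stratified within one sample per class. Stratification is our addition —
  with a 22-sample test set an unstratified draw can lose the minority class
  entirely.

# Training

The loss is binary cross-entropy applied to *every* head and combined with
per-head weights (uniform by default). Deep supervision is our choice: the
five printed heads would otherwise be dead parameters, and supervising
shallow layers regularizes the long tanh chains. Single-head training is one
configuration away (`head_loss_weights = c(0,0,0,0,1)`).

Optimization is Adam (published defaults $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$) at base learning rate 0.001, reduced every 100 epochs;
the decay factor is unstated in the source, and we default to 0.5 as a
conventional reading of "reduce actively". Training is full-batch by
default — cohorts of a few hundred samples do not need minibatching — with
a seeded minibatch mode available. Weights are initialized from a symmetric
uniform scaled by each node's *unmasked* fan-in ($\pm\sqrt{6/\text{fan-in}}$),
seeded; masked entries start at zero, receive zero gradient (the gradient is
multiplied by $M$), and are re-masked after every Adam step so they stay
*exactly* zero — verified after full training, not just one step. Dropout
(inverted, applied to a layer's output before it feeds the next layer;
heads read the undropped activation) defaults to 0.5 after the gene layer
and 0.1 after pathway layers, all configurable. A non-finite loss aborts
with the offending epoch. The best-validation-loss checkpoint is returned
alongside the final model.

# Attribution

Node importance uses difference-from-reference propagation (DeepLIFT with
the rescale rule). The reference input is the all-zero profile — no
mutation, no CNV call — which is the natural "unaltered patient" baseline
and gives reference activation 0 at every node when biases are zero. For a
target output $t$ with reference $t^0$ and $\Delta t = t - t^0$, multipliers
are propagated backward: the linear rule across masked affine maps, and for
each tanh/sigmoid node the exact finite-difference ratio
$\Delta\text{out}/\Delta\text{in}$, with the removable singularity at
$\Delta\text{in} \approx 0$ replaced by the derivative at the reference.
Because every multiplier is an exact difference ratio, contributions at any
layer that separates the target from the input sum *exactly* to $\Delta t$
— the suite asserts this at $10^{-5}$ and observes machine precision.

**Choice of target.** The default target is the final (deepest) head. With
that target the network is a chain, every hidden layer is a separating cut,
and summation-to-delta holds at every layer. We deliberately do not default
to the combined-head output: heads tap intermediate layers, so for the
combined target a hidden layer beyond the gene layer does not separate the
target from the input (earlier heads bypass it) and no correct attribution
can make per-layer contributions sum to the combined $\Delta t$. Combined
and single-head targets remain available; for the combined target the
identity is guaranteed only at the input and gene layers, and the report
carries the per-sample $\Delta t$ so users can check any cut themselves.

Node scores aggregate as the signed sum of per-sample contributions over the
evaluation cohort; layers are ranked by absolute aggregate with
lexicographic tie-breaks, which makes rankings deterministic and invariant
to sample order. The input layer additionally aggregates by feature type
(mutation vs amplification vs deletion). The Sankey export keeps the top-k
nodes per layer with per-layer normalized color weights and the retained
$|W \circ M|$ edges among them.

# Metrics and baselines

ROC AUC uses the midrank (Mann–Whitney) convention — constant scores give
0.5. AUPR is average precision by step interpolation (the sum of precision
times recall increment at each distinct threshold); the convention is
declared in the report because interpolated variants differ. Thresholded
metrics default to a 0.5 cutoff, configurable. Both AUC and AUPR are tested
against brute-force pair-counting / loop reimplementations at $10^{-9}$.

The baseline harness fits five classical families on the same binary
feature matrix the network consumes (the representation the baselines see is
our choice; the source implies but never states it): L2 logistic regression
(glmnet ridge at $\lambda = 1/n$, the analogue of a unit-cost default),
linear and RBF-kernel SVMs, a CART-style decision tree, and a random forest
(100 bagged trees, per-split feature subsampling, $\sqrt{p}$ features per
split). No SVM or tree package is assumed to be installed: the SVMs are
in-package primal squared-hinge minimizers (L-BFGS; the RBF bandwidth is the
"scale" heuristic $1/(p \cdot \mathrm{var}(X))$) and the trees are an
in-package Gini CART for binary features. These are honest members of the
named families, not wrappers, and their defaults are documented here rather
than inherited from an external library.

# The synthetic world

The fixture generator stands in for the real inputs end to end: a two-root,
depth-5, binary-branching pathway tree (62 pathways) written in the three
Reactome dialects, with three level-skipping cross edges (so the copy-chain
machinery is always exercised) and two non-human decoy relations (so the
species filter is always exercised); leaf pathways draw 5 genes from a
100-gene pool and internal pathways inherit the union of their descendants.
The cohort plants three driver genes altered at elevated rates (mutation
0.30, CNV 0.15 — the recurrence scale of TP53-class drivers) against
background rates of 0.05 / 0.02 / 0.02 (order-of-magnitude realistic for
exome-scale binary calls), and draws the outcome from a logistic model with
log-odds $+3$ per driver mutation and $+2$ per driver CNV call; the
intercept is solved by bisection so the expected positive rate is 0.80,
matching a heavily imbalanced survival cohort. Survival months are drawn
uniformly within the label-consistent interval (labels, not times, are what
the pipeline consumes), and a 10% censored block (alive, under 60 months)
is appended to exercise exclusion. Signal genes are drawn from the genes the
hierarchy actually covers — a driver invisible to the network would test
nothing. Everything is a pure function of the manifest seed; same seed,
byte-identical files.

What the fixtures do *not* emulate: mutational signatures and gene-length
effects, segment-level CNV correlation, pathway-size biases of real
annotation, survival-time distributions, covariate confounding. A green
recovery test therefore establishes that the pipeline can find a strong,
independently planted per-gene signal through the pathway bottleneck — not
that it would rank real cancer drivers correctly on a real cohort.

# Numerical choices and degenerate inputs

* Probabilities are clamped at $10^{-7}$ inside the cross-entropy.
* The rescale singularity threshold is $10^{-9}$ on $|\Delta(\text{pre-activation})|$.
* Masked-weight freezing is multiplicative ($W \circ M$ at every use and
  after every update), matching the published formulation literally and
  keeping gradients trivial; parameter counting reads $M$, never $W$.
* Serialization writes weights as `%.17g` text, which round-trips IEEE
  doubles exactly; model reload is bit-identical and forward passes on the
  reloaded model are bit-identical.
* Empty relation files parse to an empty DAG; an empty DAG cannot be
  layerized (structural error); `k` outside the hierarchy depth is a
  configuration error; a pathway layer emptied by pruning is a structural
  error.
* Dense-equivalent parameter counts use doubles (the published configuration
  overflows 32-bit integers).

# Known limitations

* Training is plain R matrix arithmetic — fine for cohorts of hundreds of
  samples and fixture-scale hierarchies; the full 11,460-gene architecture
  would train slowly here, though all counting/reporting paths handle its
  dimensions.
* The trainer offers no cross-validation or hyperparameter search; the
  validation split is used only for checkpoint selection.
* Attribution significance is not assessed (no permutation p-values on node
  scores); rankings are descriptive.
* Baselines aim for sane, documented defaults of each family, not for exact
  numeric parity with any specific external library.
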