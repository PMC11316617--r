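---
title: "Methods: learning and benchmarking a sparse backbone of gene activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning and benchmarking a sparse backbone of gene activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Co-expression and ChIP-derived regulatory networks are dense: almost every
pair of strongly expressed genes ends up connected, and the result is hard to
interpret or to feed into graph-based predictors. `latentdag` instead learns
a *sparse Bayesian-network backbone* directly from a conditions-by-genes
expression matrix $X \in \mathbb{R}^{n \times d}$ under a linear structural
equation model,

$$x = W^\top x + e, \qquad X \approx XW,$$

where $w_{ij} \neq 0$ means gene $i$ is a parent of gene $j$. The weights are
estimated by penalized least squares

$$\min_W \; \frac{1}{2n}\lVert X - XW\rVert_F^2 + \lambda \lVert W \rVert_1
\quad \text{s.t.} \quad h(W) = 0,$$

with the smooth acyclicity measure

$$h(W) = -\log\det(sI - W \odot W) + d \log s,$$

which is zero exactly when the support of $W$ is a DAG and positive on any
cyclic support within its domain (spectral radius of $W \odot W$ below $s$).
A trace-of-matrix-exponential form, $\operatorname{tr} e^{W\odot W} - d$, is
available as an alternative backend (`learner_config(constraint = "expm")`);
the two agree on the zero set but the log-determinant form has better-behaved
gradients near dense iterates.

### Optimization

The constrained problem is solved by path following: stage $t$ minimizes
$\mu_t(\text{score} + \lambda\lVert W\rVert_1) + h(W)$ with
$\mu_{t+1} = 0.1\,\mu_t$, warm-starting from the previous stage, so the
acyclicity term progressively dominates. Defaults: `mu_init = 1`,
`mu_decay = 0.1`, `path_stages = 4`.

Each stage is solved with bound-constrained L-BFGS-B on the split variables
$W = W^+ - W^-$, $W^\pm \ge 0$, which turns the L1 penalty into a linear term
and leaves inactive coefficients at exactly zero. Points outside the domain
of $h$ return a large finite barrier with a shrink-back gradient ($W = 0$ is
always feasible), so line searches retreat on their own. A first-order
alternative (`optimizer = "adam"`: adaptive-moment steps, proximal
soft-thresholding for the L1 term, backtracking step halving at the domain
boundary) reaches the same optima more slowly and is kept for comparison.

We verified on simulated linear SEMs (20 genes, 20 edges, coefficient
magnitudes 0.5–2, 1000 samples) that both solvers agree and that the
penalized optimum is support-perfect: a fixed cut at 0.3 recovers the true
graph exactly on every seed we examined.

### Adaptive thresholding

The binary network keeps edges with $|w_{ij}|$ above a threshold that is
lowered step by step from `t_start = 0.3` until the graph would acquire a
directed cycle; the graph at the last acyclic threshold is returned. The
floor of the scan, `t_floor = 0.05`, is deliberately placed at the L1
soft-threshold noise scale of the solver: penalized solutions carry genuine
but spurious entries of roughly $0.02$–$0.1$ whose subgraph can stay acyclic
far below that scale, and a floor near zero would admit them all. At the
default $\lambda = 0.02$ the 0.05 floor keeps the adaptive rule inside the
signal band; if you lower the floor, raise $\lambda$ accordingly. $\lambda$
itself is exposed and logged with every run; 0.02 is a weak default suited to
z-scaled expression matrices with hundreds to thousands of conditions.

Ties at the threshold are excluded (strict inequality), and the scan order is
deterministic, so repeated runs are bit-identical.

### What the expression data must look like

Columns are genes, rows are conditions (for a perturbation screen: one row
per profiled condition of the z-normalized response matrix). The score
exploits the variance structure of an equal-noise linear SEM; standardizing
the columns before fitting destroys that identifiability and empirically
collapses support recovery, so the matrix is used as provided. The learner
is deterministic; the `seed` field of `learner_config()` is recorded in run
manifests for provenance only.

## Structural analysis

All downstream analyses operate on the undirected skeleton of the learned
network: edge directions of a single member of a Markov equivalence class are
not individually meaningful, so directions are consumed only by the CPDAG
conversion. `to_cpdag()` keeps the skeleton, orients the v-structures, and
closes under the Meek orientation rules (R1–R3, which are complete when the
only orientation constraints come from a DAG's v-structures); the directed
part of the result is exactly the set of compelled edges. We verified this
exhaustively against an equivalence-class enumeration oracle for every DAG on
up to four nodes.

*Separator genes* are nodes of the main component whose removal splits it
into at least two components of at least seven genes each (the size floor is
the `min_component_size` argument). The components other than the largest
remainder form *modules*, tagged with their separating gene(s). The
conditional-independence claim behind a separator is checked with partial
correlations: for in-module/outside pairs, the correlation of regression
residuals given the separator set should shrink toward zero relative to the
plain correlation; `module_independence_report()` returns both columns, and
a paired one-sided test on simulated SEMs with a planted separator confirms
the shrinkage at $n = 2000$.

*Bottleneck genes* are ranked by exact shortest-path betweenness (Brandes;
unnormalized by default, so the middle of a three-node path scores 1). A
"high betweenness" set is the top 5% of nonzero-betweenness genes by
default — the cutoff is a convention, exposed as an argument and meant to be
reported with results. `neighbor_shells()` labels each gene as seed, first
shell, second shell, or other, by successive set differences.

The *knockout response* of gene A under knockdown of gene B is the
control-referenced z-score
$Z(A\mid B) = (\mathrm{Expr}(A\mid B) - \mathrm{Mean}(A\mid\mathrm{Ctrl})) /
\mathrm{Std}(A\mid\mathrm{Ctrl})$ — the subtraction binds before the
division, the only reading under which the quantity is a z-score.

The *length-two overlap test* asks whether backbone edges preferentially
connect gene pairs two steps apart in a combined reference network. The
combined network is supplied as a fixed base plus a replaceable component;
each of the 50 null replicates re-samples the replaceable component as an
Erdős–Rényi graph with the same node and edge count, and significance is the
upper normal tail of the z-score of the observed count against the null mean
and standard deviation.

Group-mean comparisons throughout use two-sided Welch t-tests
(`stats::t.test(var.equal = FALSE)`); community detection uses the Leiden
algorithm at modularity resolution 1, seeded for determinism.

## The network benchmark

To compare networks quantitatively, each one is used as the propagation
structure of a small graph-convolutional regressor predicting a per-gene
scalar from the gene's expression profile across conditions. The propagation
operator is $\hat D^{-1/2}(A + I)\hat D^{-1/2}$; genes absent from a network
keep a unit self-entry so their features pass through unchanged — the model
still predicts for them, it just cannot use neighbors. Architectures share
three hidden sizes: two convolution blocks (`gcn2`, the default), deeper
stacks (`gcn3`, `gcn4`), GAT-style learned attention over neighbors,
a simplified $K = 2$ convolution (the squared operator with a single affine
map and no intermediate activation — algebraically identical to a linear
two-layer stack, which the tests verify), a mean-aggregating inductive SAGE
variant trained on the training subgraph, and a graph-free MLP baseline. All
models are trained full batch with an adaptive-moment optimizer on an MSE
loss masked to the training genes; gradients are hand-derived dense matrix
expressions, finite-difference-checked in the test suite.

The protocol mirrors standard practice: genes are split 70/20/10 into
training, validation and test sets, stratified on membership in the backbone
network (largest-remainder rounding keeps each stratum within one gene of
exact proportionality; when a stratum would be smaller than ten genes the
split falls back to a single stratum); a seeded random search (default 20
trials) over hidden sizes {16…256}, log-uniform learning rate
$[10^{-4}, 10^{-1}]$ and epochs {50…500} selects a configuration by
validation MSE; the final model is retrained on training plus validation
genes and scored on the test genes (MSE and Pearson r, computed per run and
averaged — r is reported missing, not zero, for constant predictions). The
whole process repeats over 5 splits × 10 initializations, and per-run test
MSEs are compared between arms with two-sided Welch t-tests.

### The synthetic benchmark task

Real conservation scores and expression matrices are not required: the
generator builds a *neighbor-mean* task in which the target is
$y_i = 0.8 \cdot \overline{f}_{N(i)} + 0.2 \cdot \overline{f}_i +
\varepsilon$, with $\overline f$ the per-gene feature mean,
$\varepsilon \sim N(0, 0.1^2)$, features drawn as gene-specific means
($N(0,1)$) plus unit noise over 50 conditions, and the graph an
Erdős–Rényi skeleton with 300 genes and 600 edges. By construction 80% of
the target is carried by network neighborhoods, which an MLP cannot see and
a GNN on the wrong (random) graph aggregates incorrectly — so the benchmark
should, and does, rank true graph below MLP and below an ER null in mean
test MSE. The acceptance run uses a reduced search space (hidden {8, 16,
32}, epochs 40–120, 10 trials) so the 150-run protocol completes in a few
minutes on one CPU; the ordering is insensitive to the space.

What this generator does *not* emulate: count-level noise (UMI sampling,
dropout), nonlinear regulation, batch and cell-cycle structure, and the
partial observability of real screens. Passing benchmarks on it demonstrates
that the machinery detects graph-borne signal when present — not that any
particular biological network carries such signal.

## Embedding clustering

Node embeddings are the post-activation output of the last convolution layer
of a trained model (the run with the smallest test MSE, ties broken by run
index, when selecting among replicates). The clustering pipeline
standardizes each embedding dimension, builds a 7-nearest-neighbor graph,
embeds it with a diffusion map (eigenvectors of the normalized adjacency
weighted by eigenvalue to the eighth power, so cluster-scale modes dominate;
`embedding_dim = 20`), and applies density-based hierarchical clustering:
single linkage on mutual-reachability distances with core distances at the
10th neighbor, cut at the shallowest level that yields exactly the requested
number of clusters with at least `min_cluster_size = 10` genes each. Genes
in smaller fragments at the cut are labeled `-1` (unclustered), and the
unclustered fraction is reported. The embedding backend is a contract, not
an implementation: any neighborhood-preserving embedding can be substituted,
and `repulsive_fraction` is accepted for compatibility with repulsion-based
backends.

Clusterings are scored by *within-cluster pair scores*: all
$\binom{m}{2}$ pairs inside each cluster receive a score from a symmetric
pair table (expression correlation, or an external confidence table); pairs
missing from the table get a configurable default (0) and are counted.
Pooled distributions from two clusterings are compared with a Welch t-test.
On a five-module SEM fixture (five disjoint 20-gene modules with
module-specific expression signatures), clustering the embeddings of a GNN
trained on the true graph recovers the modules (ARI at or above 0.7) and
scores above a size-matched random partition.

## Numerical and design notes

* **Degenerate inputs.** Zero-variance genes are dropped (with a warning)
  before correlation networks; an all-constant matrix is an error. A
  single-gene fit returns the 1×1 zero matrix. Cyclic input at `t_start`
  is an error advising a larger start.
* **Turning-point selection** for co-expression thresholds maximizes the
  discrete second difference of log(1 + edge count) over the grid; a flat or
  boundary-peaked second difference yields a no-turning-point flag rather
  than a guess.
* **Percentile gene filters** (mean and standard deviation above the 95th
  percentile) can be combined by union (default) or intersection; the
  source convention is ambiguous, so both are exposed.
* **Region scores** average per-base values over 0-based half-open
  intervals, strand-ignored, weighting partially covered score intervals by
  covered width; genes with no covered base are reported missing.
* **Reproducibility.** Every stochastic step takes a seed; a master seed
  drives split, initialization and search seeds in the protocol, and equal
  seeds give bit-identical reports, edge lists and cluster assignments.
* **Problem sizes.** The shipped tests and the acceptance script use
  desk-scale problems — 10–40 genes for oracle equivalences, 20 genes ×
  1000 samples for recovery, 300 genes × 50 conditions for the benchmark,
  100 genes for clustering — chosen so the full suite runs on a single CPU
  in minutes while exercising every code path at sizes where brute-force
  oracles are feasible.

## Known limitations

Edge directions from a single observational fit are not causally
identifiable beyond the compelled set; the package therefore discards them
for analysis. Support recovery guarantees hold for equal-variance linear
Gaussian SEMs and degrade under heteroscedastic or standardized data. The
GNN trainer is full-batch and dense, appropriate up to a few thousand genes
but not beyond. The flat-cut clustering reproduces the spirit, not the exact
tree-condensation rules, of excess-of-mass density clustering; on strongly
separated data the two coincide.
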