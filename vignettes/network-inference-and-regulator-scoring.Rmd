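---
title: "From expression compendia to prioritized regulators: methods and design"
author: "grnscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expression compendia to prioritized regulators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnscore)
```

## The problem

Transcription factors (TFs) sit at the top of stress-response pathways, but
picking which of thousands of TFs to test experimentally is hard: the
regulators that matter often show only subtle differential expression, so
fold-change ranking misses them. `grnscore` implements a network-based
alternative: reconstruct a genome-scale TF-to-target regulatory network from
an expression compendium, summarize each TF by *where* in the network it
acts rather than by how strongly it responds, and train a margin classifier
on literature-curated marker TFs to score every regulator's association with
the phenotype of interest.

The pipeline has five stages, each exposed as ordinary functions and as a
command-line subcommand:

1. **Inference.** Five complementary algorithms score candidate TF-to-gene
   edges from the expression matrix.
2. **Consensus.** Per-algorithm rankings are combined by average-rank
   aggregation into a single consensus network.
3. **Modules.** Target genes with similar predicted regulator sets are
   linked (Jaccard projection) and clustered with the Markov clustering
   algorithm into co-regulated modules.
4. **Features.** Each TF is described by its Jaccard overlap with every
   module: a TF-by-module connectivity matrix `G`.
5. **Scoring.** A linear-kernel support vector machine trained on
   positive/negative marker TFs ranks all TFs; ranks are rescaled to a
   score in [0, 1].

## Stage 1: the inference ensemble

No single inference algorithm dominates: correlation methods are sensitive
but accumulate indirect edges, information-theoretic methods attenuate them
at some cost in recall, and tree ensembles capture non-additive effects.
The package therefore runs five methods over one shared edge universe - the
ordered TF-to-gene pairs of the matrix, with symmetric methods emitting
TF-TF pairs in both orientations so that directed and undirected rankings
align edge-for-edge.

- **PCC / SCC** (`infer_correlation()`): absolute Pearson or Spearman
  correlation. Absolute values are the default because repression is as
  real as activation; signed ranking is available via `absolute = FALSE`.
- **CLR** (`infer_clr()`): mutual information (MI) rescaled against each
  gene's background MI distribution. For edge $(i,j)$,
  $z_i = \max\!\big(0, (\mathrm{MI}_{ij} - \mu_i)/\sigma_i\big)$ and the
  score is $\sqrt{z_i^2 + z_j^2}$. Backgrounds are taken over the TF-gene
  MI matrix: a TF's background is its row over all genes, a target's its
  column over all TFs. Genes with a degenerate (zero-variance) background
  contribute $z = 0$ rather than an error, because flat profiles are a fact
  of life in real compendia.
- **ARACNe** (`infer_aracne()`): the MI network pruned by the data
  processing inequality (DPI). In every connected triplet the weakest edge
  is deemed indirect and removed when
  $\mathrm{MI}_{\min} < \min(\text{other two}) \cdot (1 - \varepsilon)$.
  The tolerance defaults to $\varepsilon = 0$ (strict). DPI triplets range
  over the full symmetric gene-by-gene MI matrix, so an indirect TF-target
  edge can be explained away by either a TF or a target intermediate.
- **GENIE3-style tree ensembles** (`infer_genie3()`): for each gene as the
  regression target, a random forest predicts its (unit-variance) profile
  from all TF profiles; the importance of TF $t$ for target $g$ is the
  impurity reduction credited to $t$, and edges are ranked globally by
  importance. Defaults follow the method's original description: 1,000
  trees, candidate-feature subset of $\lceil\sqrt{\#\mathrm{TFs}}\rceil$
  per split, trees grown to purity. The forests are fit with `ranger`; the
  per-target decomposition, importance extraction and global ranking are
  the package's own.

**MI estimation.** Profiles are discretized into equal-width bins spanning
`[min, max]` (right-closed intervals, so the maximum lands in the last
bin), with the plug-in (maximum-likelihood) entropy estimate in log base 2.
The default bin count is $\lceil\sqrt{n_\mathrm{samples}}\rceil$. The
plug-in estimator is biased for small samples, but only the *ranks* of MI
values survive into the consensus, and the bias is monotone enough at fixed
sample size not to disturb them; the test suite pins the estimator to a
brute-force oracle at $10^{-12}$.

**Top-K filter.** Each method keeps its `top_k` highest-scoring edges
(default 500,000, intended for compendium-scale inputs where that is well
under 1% of the candidate space). Ties are broken by (regulator, target)
lexicographic order everywhere, so ranks are reproducible to the byte.

## Stage 2: average-rank consensus

For the union of edges kept by any method, an edge-rank matrix `E` holds
each method's rank for each edge; an edge absent from method $m$ receives
$m$'s worst rank plus one. "Worst plus one" (rather than best plus one) is
the only reading under which absence is penalized, which is what makes
aggregation reward consistently high-ranked edges; the literal alternative
is available for sensitivity analysis via the rank matrix itself. Edges are
re-ranked by their mean rank across methods (ties lexicographic), and the
top `K` survive as the consensus. The consensus score stored in the edge
list is the negated mean rank, preserving the "larger is better"
convention of every other method tag.

Aggregation is permutation-invariant in the method order, idempotent on
identical inputs, and monotone: improving an edge in one method can never
worsen its consensus rank. Dropping the two correlation-based methods from
the ensemble (`exclude = c("pcc", "scc")`) reproduces the
aggregate-sans-correlation configuration that tends to win on direct
(binding-type) benchmarks, because the remaining three methods are exactly
the ones designed against indirect edges; the package's own evaluation
stage reports per-method and consensus AUPR so the choice can be made per
dataset.

## Stage 3: modules by Jaccard projection and Markov clustering

The consensus is bipartite-like (TFs point at targets). To find
co-*regulated* - not merely co-expressed - gene groups, each target is
represented by its predicted regulator set and pairs of targets are linked
by the Jaccard index (JI) of those sets. Only "high-overlap" pairs become
edges: the package keeps pairs at or above the `coreg_quantile` of the
nonzero JI values (default `q = 0.95`).

This quantile is the single most scale-sensitive parameter of the package.
In a sparse compendium-scale consensus, nonzero overlaps are dominated by
incidental one-regulator coincidences and only the top few percent reflect
shared programs, so a high quantile is right. In the dense synthetic
benchmark (four programs of fifty targets each), *most* nonzero overlaps
are genuine, the 95th percentile falls inside the within-program
distribution, and the graph fragments; the benchmark configuration
(`benchmark_config()`) therefore uses `q = 0.75`, at which the planted
blocks are recovered with adjusted Rand index above 0.9 in the acceptance
suite. When applying the package to new data, inspect the nonzero JI
distribution before trusting the default.

Clustering uses a full in-package Markov clustering (MCL) iteration:
self-loops at each node's maximum incident weight, column-normalization to
a stochastic matrix, then alternating expansion (matrix squaring) and
inflation (entrywise power, default 2, then renormalization), pruning
entries below $10^{-5}$, until the largest entry change drops below
$10^{-8}$ (cap 200 iterations; non-convergence is an error that reports the
last residual). Clusters are read off the attractor rows; a gene claimed by
two attractor systems goes to the one holding more of its mass, ties
resolved lexicographically. Modules are labeled `M0001, M0002, ...` by
decreasing size; singletons are reported as unassigned rather than as
spurious one-gene modules.

Modules can be annotated with `enrich_modules()`: hypergeometric upper-tail
tests of module-by-annotation overlaps, testing only annotation sets with
between 3 and 500 genes (larger categories link minimally related genes;
smaller ones cannot produce stable overlap statistics),
Benjamini-Hochberg correction across all tests jointly, and a q < 0.05
significance flag. `propagate_annotations()` applies the true-path rule
first - each term inherits the genes of all its descendants, the standard
child-to-ancestor union - and rejects cyclic ontologies.

## Stages 4-5: TF features and the margin classifier

The feature matrix `G` has one row per TF with at least one consensus
target and one column per module; entry $(t, m)$ is the JI between $t$'s
predicted target set and $m$'s genes, in [0, 1]. Features are used raw: the
JI is already bounded and unit-free, and an unstandardized linear model
keeps each hyperplane coefficient interpretable as a module importance.

A linear-kernel SVM (via `e1071`, wrapped so the hyperplane `(w, b)` is
explicit and oriented "positive class up") is trained on labeled marker
TFs. The cost parameter is tuned over the grid 0.001 to 10 in steps of 0.1
(100 values) by stratified five-fold cross-validated mean AUC-PR, ties
going to the smallest cost; AUC-PR is the right summary for the heavily
imbalanced marker sets this design targets. Folds are stratified - the
specification of "equal parts" alone risks single-class folds at small
sample sizes - and fold sizes differ by at most one. Class weights are off
by default, with inverse-prevalence weighting behind `class_weights =
"inverse"`.

Cross-validation (`crossvalidate()`) reports per-run, per-fold AUC-PR over
`n_runs` independent stratified splits. Two randomized baselines
(`baseline()`) calibrate the result: `uniform` replaces the positive set
with a uniformly random TF set of equal size, `family_matched` draws random
positives matching the true positive set's family composition (families
with too few members are sampled with replacement and logged). A real
network signal shows as the true-label classifier beating both; a
family-composition artifact shows as the family-matched baseline tracking
the true classifier.

Final scores (`score_all()`) come from one last five-fold split: every
fold-model scores every TF, a labeled TF averages the four models that had
it in training, and an unlabeled TF averages all five (the only symmetric
choice for TFs that are never held out). TFs are ranked by this mean margin
`D` and the rank is rescaled as
$\mathrm{score} = 1 - (\mathrm{rank} - 1)/(N - 1)$, a strictly decreasing
function of rank with maximum 1 and minimum 0. Rank scaling (rather than
min-max scaling of `D` itself) is the canonical output because it is
comparable across retrainings; the raw margin is kept in the table for
anyone who prefers it. Module importances are the fold-averaged absolute
hyperplane coefficients.

**The score-bin diagnostic** (`decile_diagnostic()`) is an independent
sanity check that uses only held-out information: TFs are sorted by
decreasing score into `n_bins` equal bins (remainder on the leading bins),
and each bin's TF expression profiles serve as features for a linear
classifier of the binary sample condition, evaluated by stratified
three-fold cross-validated AUC-ROC. If the scoring is informative, leading
bins classify samples nearly perfectly and trailing bins sit near 0.5; if
the condition effect is absent, every bin sits near 0.5.

## The synthetic benchmark

Every downstream claim is testable without downloads through
`simulate_grn()` / `simulate_expression()`. The generator plants a modular
ground truth: `n_programs` regulatory programs, each with `tfs_per_program`
TFs regulating every target in its block of `targets_per_program` genes
with weights $\mathcal{N}(w, 0.1w)$ of random sign, plus cross-program
background edges at rate `p_bg`. TF profiles are i.i.d. standard normal;
targets are the weighted sums of their regulators plus
$\mathcal{N}(0, \sigma)$ noise; the TFs of designated stress programs form
the positive class and gain a mean shift `delta` in stress samples.

The default study design - four programs of five TFs and fifty targets,
one stress program, `p_bg = 0.01`, `weight_scale = 1`,
`noise_sd = 0.5`, `delta = 2`, 75 control plus 75 stress samples - is the
condition under which the acceptance suite runs. The linear-additive model
with Gaussian noise is deliberate: it is the common denominator every
method in the ensemble must detect, which makes it a fair shared
acceptance surface. TF families are assigned round-robin across the TF
list, independently of programs, mirroring the biological fact that TF
families span regulatory programs; this is what makes the family-matched
baseline a genuine null rather than a re-draw of the true positives. By
default there is no TF-to-TF regulation (the consensus model assumes no
combinatorial regulation or feedback); `tf_tf_edges = TRUE` enables it for
stress-testing direction handling.

What the generator does *not* emulate: probe/batch effects, nonlinear
kinetics, heteroscedastic noise, unequal module sizes, and correlated TF
programs. Passing the benchmark therefore demonstrates that the machinery
is correct and that the pipeline recovers planted linear-additive
structure; it does not certify performance on any particular organism's
compendium.

**Benchmark scaling.** `benchmark_config()` adapts the budget-like
parameters to the benchmark's 4,380-edge universe: `top_k` is 1.5 times
the planted edge count (1,500), tree ensembles use 200 trees, the score
diagnostic uses 10 bins of the 20 TFs, and the co-regulation quantile is
0.75 as discussed above. The acceptance suite sweeps 10 seeds for the
classifier and diagnostic checks, 5 seeds for consensus-vs-single-method
AUPR and module recovery, and 3 seeds for the `delta = 0` null; these
sizes keep the complete suite and the acceptance script each within a few
minutes on a single core while leaving the statistical conclusions stable
across seeds (the reported quantities move by less than a few percent
between seed sweeps).

## Numerical and degenerate-input choices

- Ties anywhere in ranking are broken by (regulator, target) lexicographic
  order; module ids by decreasing size then smallest member id. Repeated
  runs are byte-identical under a fixed seed (`run_pipeline()` asserts
  this in the test suite).
- All randomness flows from one integer seed through derived per-stage
  seeds; no function touches the caller's RNG state.
- Zero-variance profiles: correlations are defined as 0 (logged), CLR
  z-components with zero-variance backgrounds are 0, tree-ensemble targets
  with zero variance are skipped (logged). Flat probes are data, not
  errors.
- Writers emit doubles with `%.17g`, so every numeric round-trips exactly
  through the text formats.
- The empty Jaccard case `J(∅, ∅)` is defined as 0; a consensus in which
  no two genes share a regulator is a hard error ("degenerate consensus")
  rather than an empty module set.
- `fit_linear_svm` re-orients the hyperplane so larger decision values
  always mean "more positive", independent of factor-level ordering.

## Known limitations

- The MI loop is quadratic in gene count and written in plain R; at
  compendium scale (tens of thousands of genes) CLR/ARACNe need hours, and
  a compiled MI kernel would be the first optimization to make.
- ARACNe's DPI over dense block designs aggressively prunes true edges of
  highly co-regulated target groups (visible in the benchmark's per-method
  AUPR table); this is a property of the algorithm, not a defect of the
  implementation, and is the reason the consensus exists.
- The decile diagnostic trains one classifier per bin; with very many bins
  and few samples it becomes noisy, which is why the benchmark uses 10
  bins rather than the compendium-scale default of 100.
- `score_all` follows the convention that a labeled TF is scored by the
  models that *trained* on it; these margins are in-sample and should be
  read as relative ranks, not calibrated probabilities.
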