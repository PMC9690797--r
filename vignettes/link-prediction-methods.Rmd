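---
title: "Predicting lncRNA-disease associations by similarity fusion and an unbalanced bi-random walk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lncRNA-disease associations by similarity fusion and an unbalanced bi-random walk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubrw)
```

## The problem

Curated catalogues of long non-coding RNA (lncRNA)–disease associations
are sparse: a matrix of roughly a hundred lncRNAs against a couple of
hundred diseases typically has only a few hundred confirmed 1-cells.
Experimental confirmation is slow, so ranking the unobserved pairs by
plausibility is useful for prioritizing candidates. The guiding
assumption throughout this package is *guilt by association*:
functionally similar lncRNAs tend to be involved in phenotypically
similar diseases, and vice versa. Everything the pipeline does is a way
of making that assumption operational on a sparse binary matrix
`Y` (lncRNAs on rows, diseases on columns).

## The model, stage by stage

**Disease semantic similarity.** Each disease is a term in a MeSH-style
hierarchy; its DAG is the ancestor closure of the focal term along
child → parent edges. A term `d` contributes
`delta^h` to the disease's semantics, where `h` is its minimum hop
distance from the focal term — formally the focal term contributes 1 and
any other term contributes `delta` times the largest contribution among
its children inside the DAG. The semantic value of a disease is the sum
of its term contributions, and the similarity of two diseases is the
summed contribution of their shared terms (counted from both sides)
divided by the sum of their semantic values. This lies in [0, 1], is
symmetric, and is 1 exactly for identical DAGs. `delta = 0.5` is the
value this measure is conventionally used with; it is configurable.

**lncRNA functional similarity.** Two lncRNAs are compared through their
associated disease sets: each disease of either set is matched with its
most similar disease in the other set, and the matches are averaged over
both set sizes. An lncRNA with no remaining association (which happens
routinely during cross-validation masking) has an undefined disease set;
we define its self-similarity as 1 and its similarity to everything else
as 0. The alternative — propagating a 0/0 — would poison downstream
matrices, while this convention simply makes the entity inert in the
functional channel; the kernel channel below still gives it structure.

**GIP kernels and the logistic rescaling.** The Gaussian interaction
profile (GIP) kernel compares binary profiles directly:
`exp(-gamma * ||y_i - y_j||^2)` over columns (diseases) or rows
(lncRNAs). We set the bandwidth to `n / sum of squared profile norms`,
the convention that makes the kernel scale-free in the number of
entities; a `bandwidth_convention = "reciprocal"` switch selects the
plain mean squared norm for users who want the literal reciprocal
reading. Because sparse profiles make most kernel values pile up near
small values, the kernel is passed through the logistic map
`1 / (1 + exp(c * K + x))` with `x = log(9999)`, which pins the image of
`K = 0` at exactly 1e-4, and a negative slope `c` (default −21) that
spreads the informative upper range over (0, 1). The exponent is clipped
at ±709 so the transform never overflows and never returns exactly 0
or 1.

**Fusion.** The two channels are combined linearly:
`FD = f1 * Sdis + f2 * LD` for diseases and `FL = f1 * Sl + f2 * LL`
for lncRNAs, with raw (non-normalized) weights, default `f1 = 2`,
`f2 = 10`. No renormalization is applied at this stage; every consumer
of the fused matrices is either scale-invariant (WKNKN, neighbor
ranking) or normalizes on its own terms (column normalization before
the walk).

**WKNKN preprocessing.** Zeros in `Y` are ambiguous — unknown is not
the same as absent. Weighted K-nearest-known-neighbor preprocessing
replaces each zero cell with the average of two estimates: one from the
K most similar diseases (their profiles weighted by similarity and an
`eta^(r-1)` rank decay, normalized by the plain sum of the K
similarities) and one from the K most similar lncRNAs. Known 1-cells
are never modified. As printed, the rank decay appears in the numerator
only; with the default `eta = 1` the fill is an exact
similarity-weighted mean, and a `normalize_with_decay` switch carries
the decay into the denominator for users who prefer a weighted mean at
`eta < 1`. Neighbor ties are broken by ascending entity index, and the
entity itself is never its own neighbor. The fused similarities are
divided by their maximum before use here; since the fill ratio is
scale-invariant this is a formality, but it keeps every quantity that
is interpreted as a probability visibly inside [0, 1].

**Linear neighborhood similarity (LNS).** The similarity networks that
the walk runs on are *reconstruction-weight* networks: each entity is
approximated as a convex combination of its k nearest neighbors by
minimizing `||x_i - sum_j w_ij x_ij||^2 + lam * ||w||^2` subject to
`sum(w) = 1`, `w >= 0`. Writing the objective with the Gram matrix
`G[j, k] = (x_i - x_ij) . (x_i - x_ik)` turns it into the
simplex-constrained quadratic program `min w'(G + lam I)w`. The ridge
`lam = 1` makes the program strictly convex, so the optimum is unique.
Two design points were genuinely open:

* *What is the feature vector `x_i`?* We use the WKNKN-preprocessed
  association profile (row of the filled matrix for lncRNAs, column for
  diseases), matching the stage ordering of the algorithm — WKNKN runs
  before LNS precisely so that LNS sees filled profiles. Rows of the
  fused similarity matrix are available as an alternative
  (`lns_features = "fused"`).
* *How are neighbors chosen?* By fused similarity (default), keeping
  the neighborhood definition consistent with the rest of the pipeline;
  Euclidean feature distance is available
  (`lns_neighbor_metric = "euclidean"`).

The weight matrix is used row-wise and asymmetric, as in label
propagation practice; `lns_symmetrize = TRUE` averages it with its
transpose for users who want a symmetric network.

**The QP solver.** The program is solved exactly by a finite active-set
iteration: solve the equality-constrained system on the current free
set (`(G + lam I)^{-1} 1`, normalized), clamp the most negative weight
to zero, and re-admit a clamped variable when its KKT reduced cost
`2 (A w)_i - mu` is negative. Strict convexity guarantees termination.
The test suite checks it three ways: against a brute-force grid search
over the simplex, against the closed-form KKT solution whenever that is
interior, and against an independent interior-point solver.

**Unbalanced bi-random walk.** The final scores come from simultaneous
restart walks on the two LNS networks after column normalization
(isolated entities give all-zero columns, which are left zero). The
disease-side update is `(1 - alpha) * P %*% MD + alpha * P0` and the
lncRNA side `(1 - alpha) * ML %*% P + alpha * P0`; while both walks are
active their updates are averaged. The two networks get *different*
step caps (`s1` on the disease side, `s2` on the lncRNA side, defaults
3 and 1) because the two topologies differ in density and diameter —
this is the "unbalanced" part. The walk runs exactly `max(s1, s2)`
iterations; the caps are step counts, not a convergence tolerance.
`P(0)` is the WKNKN-filled matrix divided by its total sum, and by
default the restart matrix is this same normalized `P(0)`. That choice
makes the walk scale-coherent: `alpha = 1` is then a true fixed point,
and identity networks leave `P(0)` unchanged. A `restart_unnormalized`
switch restores restarting to the raw filled matrix. The probability
matrix is oriented lncRNAs × diseases throughout; this is the only
orientation under which the two update products type-check against the
association matrix.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.5 | per-hop decay of term contributions (dimensionless) |
| `c` | −21 | logistic slope on the GIP kernel |
| `x` | log(9999) | logistic offset; pins kernel 0 at 1e-4 |
| `f1`, `f2` | 2, 10 | fusion weights, semantic/functional vs kernel channel |
| `K` | 7 | WKNKN neighbor count |
| `eta` | 1 | WKNKN rank decay in (0, 1] |
| `kl`, `kd` | 40, 60 | LNS neighbor counts (lncRNA / disease) |
| `lam` | 1 | LNS ridge regularizer |
| `alpha` | 0.9 | restart weight in (0, 1] |
| `s1`, `s2` | 3, 1 | walk step caps (disease / lncRNA network) |

The defaults are the leave-one-out-tuned operating point for this
method family on the curated LncRNADisease catalogue (115 lncRNAs ×
178 diseases). At desk scale the neighbor counts exceed the entity
counts, so the pipeline caps `K` at `min(nl, nd) - 1` and `kl`, `kd` at
`n - 1`; the cap is silent because cross-validation re-runs the
pipeline hundreds of times and a per-run warning would drown the
console.

## The synthetic generator

Real association catalogues require an external download, so the
package ships a generator that builds the *structure the method
assumes*, at desk scale:

* a complete rooted term hierarchy (default depth 3, branching 3, i.e.
  27 leaves) whose first-level subtrees define disease groups — two
  diseases in the same subtree share a recent ancestor and hence a high
  semantic similarity, two diseases in different subtrees meet only at
  the root;
* a planted-block bipartite matrix: lncRNAs and diseases are
  partitioned into `n_blocks` groups (default 3) aligned with the
  subtrees, and a cell is 1 with probability `density_in = 0.35` inside
  a matched block and `density_out = 0.02` elsewhere. The defaults
  (30 lncRNAs × 24 diseases) give an overall density near 13% — denser
  than a real catalogue, because at 30 × 24 a realistic 2–3% density
  would leave too few positives to cross-validate at all.

What the generator deliberately does **not** emulate: the heavy-tailed
degree distribution of real catalogues (a few hub lncRNAs with dozens
of associations), literature ascertainment bias, and correlated
annotation errors. Passing tests on synthetic data therefore show that
the implementation is faithful and that the method recovers planted
structure of the kind it assumes — they do not certify the AUC one
would obtain on a real catalogue.

## Evaluation

Cross-validation masks known associations: each fold's 1-cells are set
to 0 in the training matrix and the *entire* pipeline — functional
similarity, kernels, fusion, WKNKN, LNS, walk — is recomputed from the
masked matrix. Only the disease semantic similarity is reused across
folds, because it depends on the term DAGs alone. Scores of the
held-out cells are the positives; all cells that are 0 in the full
matrix are the negatives. Within a repeat, pair comparisons are pooled
across folds into a single Mann–Whitney AUC (each positive is compared
against its own fold's negative scores); the mean and standard
deviation across repeats are reported. Fold assignment is a seeded
shuffle of the 1-cells, so results are exactly reproducible.

At the package's desk scale (30 × 24, three blocks, seed 1) the full
pipeline's LOOCV AUC is about 0.76 against roughly 0.63 for a
degenerate baseline that walks on the raw GIP kernels with no logistic
rescaling, fusion, WKNKN or LNS — the margin is what the enrichment
stages buy. These sizes are the package's chosen experimental scale;
the acceptance checks in `tests/` re-run them from scratch.

```{r cv-example, eval = FALSE}
sim <- synthetic_dataset(synthetic_spec(seed = 1))
cv  <- run_cv(sim$Y, sim$Sdis, ubrw_config(), cv_scheme("loocv"))
print(cv)
```

## Numerical conventions and degenerate inputs

* Ties in any neighbor ranking or top-k report break by ascending
  entity index — deterministic and platform-independent.
* All-zero rows/columns of `Y` are accepted; isolated entities get
  self-similarity 1 (functional channel), contribute zero profiles
  (WKNKN), and produce zero columns that normalization leaves zero.
* An all-zero `Y` is an error everywhere a bandwidth or a walk start
  would be undefined.
* The QP clips negative weights below 1e-12 and renormalizes the row;
  row sums are tested to 1e-8.
* Matrix TSV round trips are exact to 1e-12 (17 significant digits on
  write); labels containing separators are rejected rather than quoted.
* Empty matrices are rejected on write; duplicate labels are rejected
  everywhere.

## Known limitations

* The semantic similarity is the hop-decay measure only; information
  content or graph-embedding variants are out of scope.
* The walk has no convergence criterion by design; if you want a
  steady-state diffusion, this is not it.
* LOOCV re-fits the pipeline once per known association. That is cheap
  at desk scale (well under a minute) but quadratic-ish in catalogue
  size; repeated k-fold CV is the practical choice for larger matrices.
* The negatives in evaluation are *all* unknown pairs, so reported
  AUCs inherit the usual caveat of positive-unlabeled evaluation:
  some "negatives" may be undiscovered positives.
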