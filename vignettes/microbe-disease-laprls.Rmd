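---
title: "Laplacian regularized least squares for microbe-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laplacian regularized least squares for microbe-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrlshmda)
```

## The setting

Curated microbe-disease catalogues record experimentally supported links
between microbial genera and human diseases. A typical genus-level
catalogue holds a few hundred verified pairs over roughly 300 microbes and
40 diseases. Two features shape the statistical problem. First, the data
are *positive-unlabeled*: an absent pair may be untested rather than
absent, so there are no verified negatives and ordinary supervised
classification does not apply. Second, the only covariates are the
network itself: no sequence, semantic or phenotypic similarity is assumed.
The model here is therefore semi-supervised and purely topological; it
scores every microbe-disease pair from the 0/1 adjacency matrix alone.

## Model

### Interaction profiles and GIP kernels

Let $Y \in \{0,1\}^{nm \times nd}$ be the adjacency matrix. The
interaction profile of microbe $m_i$ is row $i$ of $Y$; of disease $d_j$,
column $j$. The Gaussian interaction profile (GIP) kernel sets

$$KM(m_i, m_j) = \exp\left(-\gamma_m \lVert IP(m_i) - IP(m_j)\rVert^2\right),
\qquad
\gamma_m = \gamma'_m \Big/ \frac{1}{nm}\sum_{i=1}^{nm} \lVert IP(m_i)\rVert^2 ,$$

and symmetrically $KD$ with $\gamma_d$ for diseases. For 0/1 profiles the
squared norm is the entity's degree, so the bandwidth is one over the mean
number of associations per entity: a network twice as dense halves
$\gamma$, keeping similarities on a comparable scale across datasets. The
raw bandwidths $\gamma'_m = \gamma'_d = 1$ are the conventional default
for GIP kernels in association-prediction work and are exposed as
arguments. The premise the kernel encodes is that microbes implicated in
many common diseases tend to share function, and diseases sharing
microbiome shifts tend to share etiology.

Properties the package asserts in its tests: the kernel is symmetric
positive semidefinite with unit diagonal and entries in $(0,1]$;
off-diagonal entries are non-increasing in $\gamma$; at equal degree, more
shared associations means higher similarity; and the whole construction is
equivariant under entity relabeling.

### Laplacian smoothing and the closed form

Each kernel $S$ is normalized to the symmetric graph Laplacian
$L = D^{-1/2}(D - S)D^{-1/2}$ with $D = \mathrm{diag}(S\mathbf{1})$
(well-defined because the diagonal of $S$ is 1, so row sums are strictly
positive; spectrum in $[0,2]$; $\sqrt{\mathrm{diag}(D)}$ annihilated). The
classifier in each space minimizes the regularized least-squares cost

$$J(F) = \lVert A - F\rVert_F^2 + \eta\, \mathrm{tr}(F^\top L F),$$

whose unique minimizer (for $L \succeq 0$) is
$F^{*} = S\,(S + \eta L S)^{-1} A$, equal to $(I + \eta L)^{-1} A$
whenever $S$ is invertible. The data-fit term anchors scores to the known
labels; the trace term penalizes score differences between similar
entities, the usual bias-variance trade-off controlled by $\eta$
(default 1). $\eta = 0$ returns the labels unchanged; $\eta \to \infty$
flattens scores toward the Laplacian null space. The package verifies the
closed form against a generic numeric minimizer of $J$ and against the
algebraic identity on random instances.

**Orientation.** The label matrix consumed by the two spaces is the
disease-by-microbe matrix $A = Y^\top$: microbe space solves with $A^\top$
(giving an $nm \times nd$ classifier $FM^{*}$), disease space with $A$
(giving $nd \times nm$ $FD^{*}$), and the fusion

$$F^{*} = lw \cdot FM^{*\top} + (1 - lw)\cdot FD^{*}$$

is transposed once at the end so the published score matrix is always
$nm \times nd$, aligned with $Y$. This is the only orientation in which
every product is defined, and it is fixed as the package's convention.
The fusion weight defaults to $lw = 0.5$ — the plain mean of the two
classifiers, which is how the fusion is usually described — and is
exposed for sensitivity analysis.

### Numerical choices

The closed form is computed by a linear solve of
$(S + \eta L S)X = A$, never an explicit inverse. A subtlety matters in
practice: whenever two entities have *identical* profiles — ubiquitous in
sparse catalogues, where many degree-1 microbes attach to the same
popular disease — $S$ has duplicated rows and is exactly singular. The
solver checks the reciprocal condition number (threshold $10^{-12}$) and
falls back to an SVD pseudo-inverse (relative singular-value cutoff
$10^{-10}$), raising a classed warning that the cross-validation drivers
tally into their results rather than spam. For label matrices consistent
with the duplication — always the case here, because identical profiles
imply identical label rows — the pseudo-inverse solution coincides with
the always-well-posed form $(I + \eta L)^{-1}A$ to machine precision,
which the tests assert.

Ties in ranked outputs are broken by entity index order and flagged, so
candidate lists are deterministic and the flag warns when rank order is
not meaningful.

## Evaluation protocols

All three protocols mask known associations and **recompute both GIP
kernels on the masked matrix** before refitting — skipping the
recomputation leaks the held-out edge through the kernels.

* **Global LOOCV.** Each known pair is removed in turn and its score
  recorded from its own masked refit. The pooled held-out scores are
  ranked against the scores of all unknown pairs across all diseases.
  Where the negative scores come from is a genuine design fork: the
  default takes them from the single full-data fit (one fixed reference
  set, one pooled ROC); `negatives = "per_run"` instead compares each
  held-out positive against the unknown-pair scores of its own masked
  run and averages the per-pair concordances. Both are exposed; on
  structured networks they differ by well under the reporting precision.
* **Local LOOCV.** Identical masking loop, but each held-out pair is
  ranked only against the unknown microbes of its own disease column
  (masked-run scores), i.e. the clinically relevant "which microbe next
  for *this* disease" question. Per-pair tie-corrected rank percentiles
  are pooled by averaging into one AUC. Local AUC is typically below
  global AUC: within a column the model cannot lean on between-disease
  popularity differences.
* **Repeated 5-fold CV.** All known pairs are split uniformly at random
  into five near-equal groups (over *pairs*, not entities, and without
  stratification); each group is masked simultaneously and its positives
  are ranked against the unknown-pair scores of the same masked fit.
  Here the per-run negative set is the principled choice, not an option:
  a fold removes a fifth of all edges, which shifts every score in the
  refit, so comparing masked-fit positives against full-fit negatives
  systematically penalizes the positives. The repeat's AUC is the mean
  over its five folds; the summary reports mean and sd over repeats
  (default 100) and, separately, the sd over all fold-level AUCs, since
  the two dispersions answer different questions.

AUC is computed in-package as the trapezoidal area under the tie-grouped
ROC curve, which equals the Mann-Whitney statistic with ties counted 1/2;
the tests check it against brute-force concordance counting and against
`pROC` on random instances. Determinism: the LOOCV protocols involve no
randomness; the k-fold driver derives one sub-seed per repeat from its
master seed and records them, so results are bit-reproducible.

## Synthetic networks

Two generators make every part of the package testable without any
external data.

`random_bipartite()` draws i.i.d. Bernoulli edges; its defaults
(292 × 39, density $483/(292\cdot39) \approx 0.042$) copy the size and
sparsity of a real genus-level catalogue. `planted_block_network()`
partitions microbes and diseases into co-clusters with edge probability
`p_in` inside and `p_out` across — the minimal generative story under
which the GIP premise (co-associated entities are functionally similar)
is true by construction. Its defaults (8 blocks, `p_in = 0.35`,
`p_out = 0.004`) keep catalogue-like sparsity while giving an expected
within-block degree near 2; below that, entities almost never share two
associations, profile similarity carries no information, and no
topological method can beat chance. Both generators repair empty
rows/columns by adding one uniform edge per empty line (capped at 100
rounds) so that every entity has at least one association, as in a real
catalogue where an entity only enters the index by being observed.

What the fixtures do *not* emulate: the heavy-tailed degree
distributions of literature-curated data (a handful of intensively
studied diseases account for much of a real catalogue), curation biases,
and name-level noise. Passing tests on these fixtures therefore
demonstrate correctness of the machinery and sensible ordering of
regimes (planted structure beats the Erdős–Rényi null; stronger contrast
never lowers the AUC), not the absolute AUC level attainable on real
catalogues — popularity structure in real data typically pushes global
AUCs substantially higher than the block fixtures reach at the same
sparsity.

## Problem sizes used

Unit and property tests run on networks between 2 × 2 and 40 × 20.
`scripts/acceptance.R` exercises the full protocols at catalogue scale
(292 × 39, ~580 edges: ~1,160 LOOCV refits plus 500 fold refits), about
a minute of compute; each masked refit is dominated by one 292 × 292 and
one 39 × 39 linear solve.

## Limitations

* Entities with no remaining associations (possible under masking, or for
  genuinely new microbes) have zero profiles; their kernel row is still
  defined, but the model has no information about them — the cold-start
  problem is out of scope.
* Scores are ranking scores, not calibrated probabilities, despite living
  mostly in $[0,1]$.
* Name matching is exact after whitespace normalization; taxonomic
  synonym resolution is deliberately not attempted, since silent merging
  would change the network dimensions.
* The GIP kernel is the only similarity source; plugging in semantic or
  sequence similarities is future work and would replace `gip_similarity`
  outputs, not the LapRLS core.
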