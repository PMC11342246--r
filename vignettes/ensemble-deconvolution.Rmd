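---
title: "Ensemble deconvolution from multi-subject single-cell references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble deconvolution from multi-subject single-cell references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recide)
```

## The problem and the model

Bulk RNA profiling measures a tissue's average expression over a mixture of
cell types. Deconvolution inverts that average: given a bulk profile
$b \in \mathbb{R}^G_{\ge 0}$ and a signature matrix
$S \in \mathbb{R}^{G \times K}_{\ge 0}$ of reference expression for $K$ cell
types over $G$ marker genes, the linear mixing model

$$ b \approx S\,p, \qquad p \ge 0, \qquad \textstyle\sum_k p_k = 1 $$

is solved for the cell-type proportions $p$. Classical single-reference
methods build one $S$ from one single-cell dataset and ignore that gene
expression varies substantially between donors: a reference subject whose
expression idiosyncrasies differ from the bulk sample's donor yields a
systematically biased $\hat p$.

`recide` treats every subject of a multi-subject single-cell reference as an
independent witness. Each subject contributes its own signature matrix and
its own single-reference estimate $\hat p^{(i)}$; the $n$ estimates are then
reduced by PCA, clustered with a Gaussian mixture model, and only the
largest cluster is averaged into the final estimate. The working assumption
is that a large, tight cluster of estimates marks the reference subjects
whose expression is compatible with the bulk donor, while discordant
subjects land in smaller clusters and are discounted.

## Stage 1 — subject-specific signatures

**Partitioning and normalization.** The reference atlas (raw counts, with
per-cell subject and cell-type labels) is split by subject. Within a subject
every cell is library-size normalized to a fixed total (default $10^4$,
"counts per ten thousand"), which makes downstream means comparable across
cells and the pipeline invariant to sequencing depth. Cell types with fewer
than 3 cells in a subject are dropped for that subject — a mean over one or
two cells is too noisy to serve as a basis column — and a subject left with
fewer than two usable cell types is excluded.

**Marker scoring.** For gene $g$ and cell type $t$, let $\lambda_{gt}$ be
the cosine similarity between the gene's expression vector across the
subject's cells and the 0/1 indicator of membership in $t$. The marker score

$$ s_{gt} = \frac{\lambda_{gt}^2}{\lambda_{gt}^2 + \mu \sum_{t' \neq t} \lambda_{gt'}^2} $$

rewards genes that look like a clean indicator of their type and penalizes
expression elsewhere; the penalty weight $\mu$ defaults to 1, the cited
scoring tool's default, since no other value is suggested by the method's
description. The top 100 genes per type (by score, ties broken by gene ID
for reproducibility) enter the candidate marker list.

**Second fold change.** Each candidate is then filtered on its *SecondFC*:
the ratio of its mean normalized expression in the highest-expressing cell
type to the second-highest. Markers are retained only when SecondFC
strictly exceeds 1.5. Two conventions close the degenerate cases: a zero
second-highest mean yields $+\infty$ (the gene passes any threshold), and a
tie at the top yields exactly 1 — such a gene discriminates nothing between
the tied types, so any threshold above 1 removes it. Marker selection
operates on normalized linear-scale expression; the method description does
not fix the scale, and the linear scale keeps scoring, fold changes and the
signature entries consistent with the linear mixing model.

**Stability-driven signature size.** For each candidate per-type marker
count $G$ in a scan range (default 50–100, echoing the 50–150 convention of
signature-matrix builders in this field), the candidate signature is the
union of each type's top-$G$ markers with entries equal to per-type mean
normalized expression, and its 2-norm condition number $\kappa$ is computed.
The $G$ minimizing $\kappa$ wins, ties to the smaller $G$. A low $\kappa$
means the least-squares problem is well posed and estimates are stable
under noise.

**Bulk-similarity refinement.** Reference and bulk data usually come from
different platforms; markers whose reference expression disagrees wildly
with the bulk profile inject pure bias. For each cell type the similarity
score is defined as $n \cdot \cos(S_{\cdot t}|_M,\, b|_M)$ — the marker
count times the cosine between the signature column and the bulk vector
restricted to the marker set $M$. Markers are visited once in ascending
SecondFC order (the least specific first, ties by gene ID); a marker is
removed iff removal strictly increases the score and at least `marker_floor`
(default 3) markers remain. The multiplier $n$ stops the greedy pass from
trivially shrinking $M$ to its single best-matching gene: a removal must
buy enough cosine to pay for the lost count. Three interpretation choices
are deliberate and documented here because the procedure's description
leaves them open: (i) a single ordered sweep, not iteration to a fixed
point (a convergence loop rarely changed results in development and the
procedure reads as one pass); (ii) each candidate is scored against the
already-pruned set (sequential semantics); (iii) genes absent from the bulk
panel contribute zeros to both slices rather than being excluded, so the
count multiplier stays honest. Refinement runs against each bulk sample
separately by default (`refine_per_sample = FALSE` refines once against the
mean bulk profile, a cheaper approximation).

## Stage 2 — single-reference kernels

**Constrained least squares (`nnls`).** $\min \|Sp - b\|^2$ s.t. $p \ge 0$
via Lawson–Hanson, then normalization to the simplex. Non-negativity is
enforced inside the solver while the sum-to-one is a final rescaling — the
two-step behavior keeps the quadratic program always feasible and makes the
estimates invariant to the overall scale of $b$.

**Dampened weighted least squares (`dwls`, recommended).** Ordinary least
squares lets the brightest genes dominate the objective, which is why rare
cell types — visible only through dim markers — are routinely missed.
The dampened scheme iterates

$$ w_j = \min\!\big( 1/\max((Sp)_j^2, \varepsilon),\; 2^d \min_j w_j \big), \qquad
   p \leftarrow \arg\min_{p\ge0} \|W^{1/2}(Sp-b)\|^2 $$

until the normalized solution moves less than `tol` (default $10^{-7}$,
cap 1000 iterations; non-convergence returns the last iterate with a
warning). Uncapped inverse-squared-fitted-value weights overshoot in the
other direction, so the dampening exponent $d$ caps them; $d$ is chosen by
cross-validation — for each candidate the capped-weight problem is solved on
`cv_reps` (100) random gene subsets of fraction 0.5 and the $d$ whose
solutions vary least wins. Exponents beyond
$\lceil \log_2(\max_j w_j / \min_j w_j) \rceil$ leave the cap non-binding
and are collapsed into one candidate. $\varepsilon = 10^{-10}$ floors the
fitted values so all-zero predictions cannot divide by zero. All
cross-validation randomness derives from a per-(subject, sample) seed, so
ensembles are reproducible and order-independent.

## Stage 3 — integration

The $n$ per-subject estimates for one bulk sample form an
$n \times K$ matrix on the simplex. It is centered, projected onto the
fewest principal components explaining 90% of variance (capped at
$\min(n-1, K)$), and clustered with Gaussian mixtures for 1 to 9 components
(capped at $n - 1$), with the component count and covariance model selected
by BIC — the defaults of the model-based clustering tool this stage is built
on. The largest cluster is kept; size ties go to the cluster with the
smallest mean member–centroid distance (a data-driven, deterministic
tie-break), then to the lowest label. The final estimate is the arithmetic
mean of the retained rows, renormalized to sum to one (a no-op up to
floating point, since a mean of simplex points is on the simplex).

Two degenerate regimes are handled explicitly: identical rows form a single
cluster with no model fit, and ensembles with fewer than 5 subjects skip
clustering entirely — a mixture model on a handful of points fits noise —
and fall back to the plain mean. Clustering is per bulk sample: each
deconvolution task is its own evidence about which reference subjects are
compatible with that sample's donor.

## The synthetic study

The generator emulates the features the integration stage exists to
exploit. All subjects share a cell-type universe and a base expression
vector (log-normal, heavy-tailed). Each cell type overexpresses its block of
designated marker genes by `marker_fold` (default 5). Each subject draws one
log-normal multiplier per gene (sd `subject_sd` on the log scale, default
0.3, mean 1), shared across that subject's cell types — subject effects
shift genes coherently while type contrasts persist, the simplest mechanism
that makes single-reference estimates disagree across subjects. Cells then
draw Poisson (optionally negative-binomial) counts around the type profile
scaled to `depth_per_cell` expected counts.

The default abundance profile spans the three size classes used in the
evaluation — four major types (32%, 25%, 15%, 12%), two minor (8%, 6.5%)
and two rare (1%, 0.5%) — over 10 subjects, 1200 genes (40 markers per
type) and 1500 cells per subject. Pseudo-bulk samples sum the raw counts of
`n_cells` cells drawn from one held-out subject, with per-type cell counts
fixed by largest-remainder rounding so ground truth is exact; the truth
table records the *realized* post-rounding proportions, the only defensible
reference point. Summing (rather than averaging) matches the linear mixing
model, and the kernels' scale invariance makes the distinction immaterial
to the estimates.

What the simulation does **not** model: cross-platform chemistry (scRNA-seq
reference vs microarray bulk), gene-length or GC biases, ambient RNA,
doublets, or annotation noise between subjects. Passing the synthetic
benchmarks therefore demonstrates the machinery — identifiability, the
benefit of largest-cluster integration under subject heterogeneity, rare
cell-type calibration — not performance on any particular real cohort.

## Evaluation suite

Per sample, RMSE and Pearson correlation are computed across cell types on
the union of the estimated and true type sets (absent types count as zero);
summaries average per-sample values, matching the per-test-subject
aggregation the framework's benchmarks use. Calibration is assessed by
pooling (sample, cell type) pairs, classing each pair by its *true*
proportion — rare below 2%, major above 10%, minor between, boundaries to
minor — and fitting one OLS line of estimated on true per class; a slope
near 1 is well calibrated, below 1 means shrinkage toward zero, the
signature failure mode for rare types.

The leave-one-out benchmark (`run_benchmark()`) holds out each subject in
turn, builds its pseudo-bulk at its own empirical proportions, and
deconvolves with the remaining subjects — reporting the ensemble estimate,
every single-reference estimate, and their plain mean, so the value added
by clustering is directly measurable.

For triple-negative breast cancer applications the package includes the
prognostic score
$\big(p_{\text{Tfh}} / (p_{\text{PVL-d3}} + \epsilon)\big) \cdot
 \big(p_{\text{PVL-s1}} / (p_{\text{PVL}} + \epsilon)\big)$,
where $p_{\text{PVL}}$ sums all perivascular-like subtypes and scores above
0.0125 classify as favorable prognosis. $\epsilon = 10^{-6}$ guards zero
PVL denominators, a case the score's definition leaves open.

## Numerical and design notes

- Condition numbers and rank checks use singular values with the usual
  `eps`-scaled tolerance; rank-deficient signatures abort with the
  near-collinear cell types named.
- All tie-breaks (marker ranking, refinement order, largest-remainder
  apportionment, cluster-size ties) are deterministic and documented at the
  function level; two runs with one seed produce byte-identical outputs.
- Per-subject kernel seeds are derived as
  `(seed + 7919 * sample + 104729 * subject) mod (2^31 - 1)`, so results do
  not depend on evaluation order and parallel execution over subjects or
  samples would reproduce the serial results exactly.
- Problem sizes in the shipped tests and the acceptance script — 10-subject
  atlases, 1500 cells per subject, 1000-cell pseudo-bulks, 200-replicate
  clustering simulations — were chosen as the smallest sizes at which the
  subject-heterogeneity effects the method targets are clearly expressed.

## Known limitations

- Cell-type labels are taken as given; no cross-subject label
  harmonization is attempted.
- Only the two kernels are implemented; the ensemble wrapper is agnostic,
  and other single-reference solvers can be slotted in by mimicking the
  kernel signature.
- Bulk input must be linear scale; log-transformed input is the caller's
  error to undo and is deliberately not auto-detected.
- Absolute abundances are out of scope: everything lives on the simplex.
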