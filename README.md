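# recide

Ensemble cell-type deconvolution of bulk expression profiles from
multi-subject single-cell references.

## The problem

Estimating cell-type proportions from a bulk RNA profile means solving the
linear mixing model *b ≈ S p* (p ≥ 0, Σp = 1), where *S* is a marker-genes ×
cell-types signature matrix built from a single-cell reference. Classical
methods build one *S* from one pooled reference and inherit whatever
donor-specific expression quirks it carries; when the reference donors'
expression differs from the bulk sample's donor, the estimate is biased —
worst of all for rare cell types (< 2% of cells), which are often the
clinically interesting ones.

`recide` instead runs a full single-reference deconvolution **per reference
subject** and integrates the resulting ensemble:

1. **Subject-specific signatures** — per subject: cosine-similarity marker
   scoring (top 100 per cell type), a second-fold-change specificity filter
   (SecondFC > 1.5), signature assembly at the per-type marker count that
   minimizes the matrix condition number, and a greedy refinement that
   prunes markers whose removal strictly increases
   `n_markers × cosine(signature column, bulk)`.
2. **Per-subject deconvolution** — dampened weighted least squares
   (iteratively reweighted non-negative least squares with gene weights
   `1/max((Sp)², ε)` capped at `min(w)·2^d`, the dampening exponent `d`
   chosen by cross-validation), or a plain constrained-least-squares
   baseline.
3. **Integration** — PCA on the subjects × cell-types estimate matrix, a
   Gaussian-mixture fit with BIC model selection, and the mean of the
   largest cluster, renormalized to the simplex. Subjects whose estimates
   disagree with the consensus land in minor clusters and are discounted.

The package also ships a synthetic multi-subject reference / pseudo-bulk
generator with exact ground truth, the evaluation suite (RMSE, Pearson
correlation, abundance-class calibration slopes, leave-one-out
benchmarking), and a prognostic score for triple-negative breast cancer
based on follicular-helper-T and perivascular-like cell fractions.

## Worked example

Simulate a 10-subject reference (8 cell types, two of them rare at 1% and
0.5%), build a 1000-cell pseudo-bulk from subject `s01`, and deconvolve it
with the other nine subjects as reference:

```r
library(recide)

atlas <- generate_reference(simulation_spec(seed = 7))
pb    <- generate_pseudobulk(atlas, "s01", n_cells = 1000, seed = 7)
ref   <- subset_subjects(atlas, sprintf("s%02d", 2:10))

res <- run_recide(ref, pb$bulk, recide_config(seed = 1))
res$proportions[[1]]
#> integrated_proportions (pb_s01): 8 cell types, n_used = 2
#>    ct1    ct2    ct3    ct4    ct5    ct6    ct7    ct8
#> 0.3061 0.2362 0.1540 0.0777 0.1142 0.0768 0.0139 0.0211

round(pb$truth$proportions, 4)
#>   ct1   ct2   ct3   ct4   ct5   ct6   ct7   ct8
#> 0.320 0.250 0.150 0.120 0.080 0.065 0.010 0.005

prop_rmse(res$proportions[[1]], pb$truth)   #> 0.0217
prop_pcc(res$proportions[[1]], pb$truth)    #> 0.9802
```

`n_used` is the size of the retained estimate cluster: here 2 of the 9
reference subjects formed the tightest consensus, and their average lands
within 0.022 RMSE of the realized mixing proportions, with the two rare
types estimated at 1.4% and 2.1% against true 1% and 0.5%.
`write_proportions()` / `write_diagnostics()` export the results;
`run_benchmark()` runs the full leave-one-out comparison against
single-reference deconvolution. A thin command-line wrapper with
`simulate` / `deconvolve` / `benchmark` / `evaluate` subcommands is
installed at `inst/cli/recide.R`.

## Vignette

`vignettes/ensemble-deconvolution.Rmd` documents the model, every tunable
parameter with its default and rationale, the synthetic study's scope and
blind spots, and the numerical conventions (tie-breaks, tolerances,
degenerate-input policies).
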