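#' Run configuration
#'
#' Collects every tunable parameter of the pipeline in one validated list.
#' Defaults follow the published workflow where it states a value (100 initial
#' markers per cell type, second-fold-change threshold 1.5) and otherwise use
#' the conventions documented in the methods vignette.
#'
#' @param n_markers_init Number of marker genes initially selected per cell
#'   type by cosine scoring (default 100).
#' @param secondfc_threshold Specificity filter: a marker is retained only if
#'   the ratio of its highest to second-highest per-type mean expression
#'   strictly exceeds this value (default 1.5).
#' @param marker_floor Minimum number of markers a cell type may be pruned
#'   down to during bulk-similarity refinement (default 3).
#' @param kernel Deconvolution kernel, `"dwls"` (dampened weighted least
#'   squares, recommended) or `"nnls"` (constrained least squares baseline).
#' @param damping_grid Candidate dampening exponents d; gene weights are
#'   capped at `min(w) * 2^d` (default `0:30`).
#' @param pca_variance Fraction of ensemble variance the retained principal
#'   components must explain before clustering (default 0.9).
#' @param gmm_max_components Largest Gaussian-mixture component count tried
#'   (default 9, capped at one less than the number of subjects).
#' @param min_subjects_for_clustering Below this many usable subjects the
#'   integration step averages all estimates instead of clustering (default 5).
#' @param seed Integer seed from which all pipeline randomness derives.
#' @param refine_per_sample Refine each subject's signature against every bulk
#'   column separately (default `TRUE`); `FALSE` refines once against the mean
#'   bulk profile.
#' @param min_cells_per_type A cell type represented by fewer cells than this
#'   within one subject is dropped for that subject (default 3).
#' @param g_min,g_max Candidate per-type marker counts scanned when minimizing
#'   the signature condition number (defaults 50 and 100).
#' @param normalize_total Per-cell library-size target after normalization
#'   (default 1e4, counts per ten thousand). `NA` disables normalization.
#' @param cosg_mu Penalty weight on a gene's cosine similarity to other cell
#'   types in the marker score (default 1).
#' @param dwls Kernel settings from [dwls_settings()].
#' @param min_shared_genes A subject whose signature shares fewer marker genes
#'   than this with the bulk panel is skipped (default 10).
#'
#' @return A list of class `"recide_config"`.
#' @export
recide_config <- function(n_markers_init = 100L,
                          secondfc_threshold = 1.5,
                          marker_floor = 3L,
                          kernel = c("dwls", "nnls"),
                          damping_grid = 0:30,
                          pca_variance = 0.9,
                          gmm_max_components = 9L,
                          min_subjects_for_clustering = 5L,
                          seed = 1L,
                          refine_per_sample = TRUE,
                          min_cells_per_type = 3L,
                          g_min = 50L,
                          g_max = 100L,
                          normalize_total = 1e4,
                          cosg_mu = 1,
                          dwls = dwls_settings(),
                          min_shared_genes = 10L) {
  kernel <- match.arg(kernel)
  cfg <- list(
    n_markers_init = as.integer(n_markers_init),
    secondfc_threshold = secondfc_threshold,
    marker_floor = as.integer(marker_floor),
    kernel = kernel,
    damping_grid = as.integer(damping_grid),
    pca_variance = pca_variance,
    gmm_max_components = as.integer(gmm_max_components),
    min_subjects_for_clustering = as.integer(min_subjects_for_clustering),
    seed = as.integer(seed),
    refine_per_sample = isTRUE(refine_per_sample),
    min_cells_per_type = as.integer(min_cells_per_type),
    g_min = as.integer(g_min),
    g_max = as.integer(g_max),
    normalize_total = normalize_total,
    cosg_mu = cosg_mu,
    dwls = dwls,
    min_shared_genes = as.integer(min_shared_genes)
  )
  if (cfg$n_markers_init < cfg$marker_floor || cfg$marker_floor < 1L)
    stop("need n_markers_init >= marker_floor >= 1")
  if (cfg$secondfc_threshold < 1)
    stop("secondfc_threshold must be >= 1")
  if (cfg$gmm_max_components < 1L)
    stop("gmm_max_components must be >= 1")
  if (!(cfg$pca_variance > 0 && cfg$pca_variance <= 1))
    stop("pca_variance must lie in (0, 1]")
  if (any(cfg$damping_grid < 0L))
    stop("damping_grid exponents must be non-negative")
  structure(cfg, class = "recide_config")
}

#' Settings for the dampened weighted least squares kernel
#'
#' @param max_iter Maximum reweighting iterations (default 1000).
#' @param tol Convergence tolerance on the max absolute change of the
#'   normalized solution between iterations (default 1e-7).
#' @param cv_subsample_fraction Fraction of genes drawn in each
#'   cross-validation subsample used to pick the dampening exponent
#'   (default 0.5).
#' @param cv_reps Number of cross-validation subsamples per candidate
#'   exponent (default 100).
#'
#' @return A list of class `"dwls_settings"`.
#' @export
dwls_settings <- function(max_iter = 1000L, tol = 1e-7,
                          cv_subsample_fraction = 0.5, cv_reps = 100L) {
  if (tol <= 0) stop("tol must be positive")
  if (cv_reps < 2L) stop("cv_reps must be >= 2")
  if (!(cv_subsample_fraction > 0 && cv_subsample_fraction <= 1))
    stop("cv_subsample_fraction must lie in (0, 1]")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 cv_subsample_fraction = cv_subsample_fraction,
                 cv_reps = as.integer(cv_reps)),
            class = "dwls_settings")
}

#' @export
print.recide_config <- function(x, ...) {
  cat("recide run configuration\n")
  cat("  kernel:", x$kernel,
      "| markers/type:", x$n_markers_init,
      "| SecondFC >", x$secondfc_threshold, "\n")
  cat("  signature gene scan:", x$g_min, "-", x$g_max,
      "| refinement floor:", x$marker_floor,
      if (x$refine_per_sample) "(per sample)" else "(mean bulk)", "\n")
  cat("  integration: PCA", x$pca_variance, "variance, GMM 1..",
      x$gmm_max_components, ", clustering needs >=",
      x$min_subjects_for_clustering, "subjects\n", sep = "")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
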