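#' Reduce a deconvolution ensemble and cluster the subjects
#'
#' Centers the subjects x cell-types estimate matrix, projects it onto the
#' smallest number of principal components explaining at least
#' `config$pca_variance` of the variance (capped at `min(n - 1, #types)`),
#' and fits Gaussian mixture models with 1 to `config$gmm_max_components`
#' components (capped at `n - 1`), selecting the component count and
#' covariance model by BIC. Each subject is assigned its maximum-posterior
#' component. An ensemble whose rows are all identical is a single cluster
#' by definition and no model is fitted.
#'
#' @param ensemble A `"deconvolution_ensemble"`.
#' @param config A [recide_config()].
#' @return Integer cluster label per subject (named).
#' @importFrom mclust Mclust mclustBIC
#' @export
reduce_and_cluster <- function(ensemble, config = recide_config()) {
  est <- ensemble$estimates
  if (is.null(rownames(est)))
    rownames(est) <- sprintf("row%03d", seq_len(nrow(est)))
  rn_orig <- rownames(est)
  # canonical row order so the fit never depends on how subjects were listed
  est <- est[order(rn_orig), , drop = FALSE]
  n <- nrow(est)
  if (n < config$min_subjects_for_clustering)
    stop(sprintf("clustering needs >= %d subjects (have %d); use integrate_small_n",
                 config$min_subjects_for_clustering, n))
  labels <- stats::setNames(rep(1L, n), rownames(est))
  if (all(apply(est, 2, function(col) max(col) - min(col) == 0)))
    return(labels[rn_orig])

  pc <- stats::prcomp(est, center = TRUE, scale. = FALSE)
  pos <- pc$sdev^2 > .Machine$double.eps * max(pc$sdev^2)
  cum <- cumsum(pc$sdev[pos]^2) / sum(pc$sdev[pos]^2)
  k <- min(which(cum >= config$pca_variance))
  k <- min(k, n - 1L, ncol(est))
  scores <- pc$x[, seq_len(k), drop = FALSE]

  g_max <- min(config$gmm_max_components, n - 1L)
  fit <- with_local_seed(config$seed, suppressWarnings(
    mclust::Mclust(scores, G = seq_len(g_max), verbose = FALSE)))
  if (is.null(fit)) return(labels[rn_orig])       # every model failed: one cluster
  labels <- stats::setNames(as.integer(fit$classification), rownames(est))
  labels[rn_orig]
}

#' Members of the largest cluster
#'
#' Ties on cluster size are broken in favor of the tighter cluster (smallest
#' mean Euclidean distance of members to their centroid, computed on the
#' estimate rows), then by the lowest label.
#'
#' @param labels Integer cluster label per subject.
#' @param estimates Optional subjects x cell-types matrix used for the
#'   dispersion tie-break; without it ties fall back to the lowest label.
#' @return Integer indices of the winning cluster's members.
#' @export
select_largest_cluster <- function(labels, estimates = NULL) {
  stopifnot(length(labels) >= 1)
  sizes <- table(labels)
  top <- names(sizes)[sizes == max(sizes)]
  if (length(top) > 1 && !is.null(estimates)) {
    disp <- vapply(top, function(lab) {
      m <- estimates[labels == as.integer(lab), , drop = FALSE]
      ctr <- colMeans(m)
      mean(sqrt(rowSums(sweep(m, 2, ctr)^2)))
    }, numeric(1))
    top <- top[order(disp, as.integer(top))][1]
  } else {
    top <- top[order(as.integer(top))][1]
  }
  which(labels == as.integer(top))
}

#' Average the retained cluster into the final proportion estimate
#'
#' Arithmetic mean of the member rows per cell type, renormalized to sum to
#' one (a no-op up to floating point when every row is on the simplex).
#'
#' @param ensemble A `"deconvolution_ensemble"`.
#' @param members Integer indices of the retained subjects.
#' @param cluster_labels Optional labels stored for diagnostics.
#' @return An `"integrated_proportions"` object:
#'   `list(sample_id, proportions, n_used, cluster_labels)`.
#' @export
integrate_cluster <- function(ensemble, members, cluster_labels = NULL) {
  stopifnot(length(members) >= 1)
  m <- ensemble$estimates[members, , drop = FALSE]
  p <- colMeans(m)
  p <- p / sum(p)
  structure(list(sample_id = ensemble$sample_id, proportions = p,
                 n_used = length(members), cluster_labels = cluster_labels),
            class = "integrated_proportions")
}

#' Plain-average fallback for small ensembles
#'
#' Model-based clustering on a handful of points is noise; below
#' `config$min_subjects_for_clustering` subjects the integration is simply
#' the renormalized mean of all rows.
#'
#' @param ensemble A `"deconvolution_ensemble"`.
#' @param config A [recide_config()].
#' @return An `"integrated_proportions"` object with `n_used` equal to the
#'   number of subjects.
#' @export
integrate_small_n <- function(ensemble, config = recide_config()) {
  n <- nrow(ensemble$estimates)
  if (n == 0) stop("empty ensemble")
  message(sprintf("sample %s: %d subjects < %d, clustering skipped",
                  ensemble$sample_id, n, config$min_subjects_for_clustering))
  integrate_cluster(ensemble, seq_len(n),
                    cluster_labels = stats::setNames(rep(1L, n),
                                                     rownames(ensemble$estimates)))
}

#' Integrate a deconvolution ensemble into one proportion vector
#'
#' Dispatches between the clustering route ([reduce_and_cluster()] +
#' [select_largest_cluster()] + [integrate_cluster()]) and the small-n plain
#' mean, per the configured threshold.
#'
#' @param ensemble A `"deconvolution_ensemble"`.
#' @param config A [recide_config()].
#' @return An `"integrated_proportions"` object.
#' @export
integrate_ensemble <- function(ensemble, config = recide_config()) {
  n <- nrow(ensemble$estimates)
  if (n < config$min_subjects_for_clustering)
    return(integrate_small_n(ensemble, config))
  labels <- reduce_and_cluster(ensemble, config)
  members <- select_largest_cluster(labels, ensemble$estimates)
  integrate_cluster(ensemble, members, cluster_labels = labels)
}

#' @export
print.integrated_proportions <- function(x, ...) {
  cat(sprintf("integrated_proportions (%s): %d cell types, n_used = %d\n",
              x$sample_id, length(x$proportions), x$n_used))
  print(round(x$proportions, 4))
  invisible(x)
}
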