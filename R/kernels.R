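# Run `code` with a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_full_rank <- function(S) {
  sv <- svd(S)
  tol <- max(sv$d) * .Machine$double.eps * max(dim(S))
  if (min(sv$d) <= tol) {
    bad <- colnames(S)[abs(sv$v[, which.min(sv$d)]) > 1e-8]
    stop("signature matrix is rank-deficient; near-collinear cell types: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

as_signature_values <- function(S) {
  if (inherits(S, "signature_matrix")) S <- S$values
  S <- as.matrix(S)
  if (is.null(colnames(S))) colnames(S) <- paste0("ct", seq_len(ncol(S)))
  S
}

# Non-negative least squares via Lawson-Hanson, then simplex normalization.
nnls_simplex <- function(S, b) {
  fit <- pracma::lsqnonneg(S, b)
  p <- fit$x
  if (sum(p) <= 0) stop("degenerate fit: all proportions zero")
  stats::setNames(p / sum(p), colnames(S))
}

#' Constrained least squares deconvolution
#'
#' Solves `argmin ||S p - b||^2` subject to `p >= 0` (Lawson-Hanson active
#' set) and rescales the solution to sum to one. The baseline kernel, and the
#' inner solver of the dampened weighted variant.
#'
#' @param S Signature matrix (genes x cell types) or a `"signature_matrix"`.
#' @param b Bulk expression vector aligned to the rows of `S`.
#' @return Named proportion vector on the simplex.
#' @export
solve_nnls <- function(S, b) {
  S <- as_signature_values(S)
  b <- as.numeric(b)
  stopifnot(length(b) == nrow(S))
  if (all(b == 0)) stop("bulk vector is all zero")
  check_full_rank(S)
  nnls_simplex(S, b)
}

weighted_nnls <- function(S, b, w) {
  sw <- sqrt(w)
  nnls_simplex(S * sw, b * sw)
}

dampened_weights <- function(S, p, d, eps = 1e-10) {
  w <- 1 / pmax(as.numeric(S %*% p)^2, eps)
  pmin(w, min(w) * 2^d)
}

# Pick the dampening exponent: for each candidate d, solve the capped-weight
# problem on cv_reps random gene subsamples and keep the d whose solutions
# vary least. Exponents beyond the point where the cap stops binding give
# identical weights, so the grid is truncated there.
choose_dampening <- function(S, b, p0, grid, settings, eps = 1e-10) {
  w <- 1 / pmax(as.numeric(S %*% p0)^2, eps)
  top <- log2(max(w) / min(w))
  grid <- unique(pmin(grid, ceiling(top)))
  if (length(grid) == 1) return(grid)
  n <- nrow(S)
  k <- max(2L, ceiling(settings$cv_subsample_fraction * n))
  subsets <- replicate(settings$cv_reps, sample.int(n, k), simplify = FALSE)
  crit <- vapply(grid, function(d) {
    wc <- pmin(w, min(w) * 2^d)
    sols <- vapply(subsets, function(ix) {
      tryCatch(weighted_nnls(S[ix, , drop = FALSE], b[ix], wc[ix]),
               error = function(e) rep(NA_real_, ncol(S)))
    }, numeric(ncol(S)))
    mean(apply(sols, 1, stats::var, na.rm = TRUE))
  }, numeric(1))
  grid[which.min(crit)]
}

#' Dampened weighted least squares deconvolution
#'
#' Iteratively reweighted constrained least squares: given the current
#' proportions, each gene is weighted by the inverse squared fitted value
#' `1 / max((S p)_j^2, eps)`, the weights are capped at `min(w) * 2^d`, and
#' the weighted non-negative least squares problem is re-solved until the
#' normalized solution changes by less than `tol`. The dampening exponent
#' `d` is selected by cross-validation: the candidate whose capped-weight
#' solutions vary least across random gene subsamples wins. The weighting
#' prevents a handful of highly expressed genes from dominating the fit,
#' which is what makes rare cell types recoverable.
#'
#' @inheritParams solve_nnls
#' @param settings A [dwls_settings()].
#' @param damping_grid Candidate dampening exponents (default `0:30`).
#' @param seed Seed for the cross-validation subsamples.
#' @param eps Floor on squared fitted values in the weight computation.
#' @return Named proportion vector on the simplex, with attributes
#'   `converged` (logical), `dampening` (chosen d) and `iterations`.
#' @export
solve_dampened_wls <- function(S, b, settings = dwls_settings(),
                               damping_grid = 0:30, seed = 1L, eps = 1e-10) {
  S <- as_signature_values(S)
  b <- as.numeric(b)
  stopifnot(length(b) == nrow(S))
  if (all(b == 0)) stop("bulk vector is all zero")
  check_full_rank(S)

  p0 <- nnls_simplex(S, b)
  d <- with_local_seed(seed, choose_dampening(S, b, p0, damping_grid, settings, eps))

  p <- p0
  converged <- FALSE
  iter <- 0L
  while (iter < settings$max_iter) {
    iter <- iter + 1L
    wc <- dampened_weights(S, p, d, eps)
    p_new <- weighted_nnls(S, b, wc)
    if (max(abs(p_new - p)) < settings$tol) { p <- p_new; converged <- TRUE; break }
    p <- p_new
  }
  if (!converged)
    warning(sprintf("dampened WLS did not converge within %d iterations (d = %d)",
                    settings$max_iter, d))
  structure(p, converged = converged, dampening = d, iterations = iter)
}

#' Deconvolve every bulk sample against every subject's signature
#'
#' Runs the configured kernel once per (subject, sample) pair on the genes
#' shared between the subject's signature and the bulk panel, and collects
#' the estimates into one subjects x cell-types matrix per sample (the union
#' of cell-type sets, with types a subject lacks filled with 0; every row
#' still sums to 1). Subjects sharing fewer than `config$min_shared_genes`
#' genes with the bulk panel are skipped with a warning.
#'
#' @param signatures List of `"signature_matrix"` objects (one per subject).
#' @param bulk A [bulk_matrix()].
#' @param config A [recide_config()].
#' @return Named list over samples of `"deconvolution_ensemble"` objects:
#'   `list(sample_id, subjects, cell_types, estimates)`.
#' @export
deconvolve_ensemble <- function(signatures, bulk, config = recide_config()) {
  stopifnot(length(signatures) >= 1, inherits(bulk, "bulk_matrix"))
  out <- lapply(seq_along(bulk$sample_ids), function(j)
    deconvolve_one_sample(signatures, bulk$values[, j], bulk$sample_ids[j],
                          config, sample_index = j))
  names(out) <- bulk$sample_ids
  out
}

deconvolve_one_sample <- function(signatures, bulk_column, sample_id, config,
                                  sample_index = 1L) {
  rows <- list()
  for (i in seq_along(signatures)) {
    sig <- signatures[[i]]
    shared <- intersect(rownames(sig$values), names(bulk_column))
    if (length(shared) < config$min_shared_genes) {
      warning(sprintf("subject %s skipped for sample %s: only %d shared marker genes",
                      sig$subject_id, sample_id, length(shared)))
      next
    }
    S <- sig$values[shared, , drop = FALSE]
    b <- bulk_column[shared]
    p <- tryCatch({
      if (config$kernel == "dwls")
        solve_dampened_wls(S, b, settings = config$dwls,
                           damping_grid = config$damping_grid,
                           seed = kernel_seed(config$seed, i, sample_index))
      else solve_nnls(S, b)
    }, error = function(e) {
      warning(sprintf("subject %s skipped for sample %s: %s",
                      sig$subject_id, sample_id, conditionMessage(e)))
      NULL
    })
    if (!is.null(p)) rows[[sig$subject_id]] <- p
  }
  if (!length(rows))
    stop("all subjects skipped for sample ", sample_id)
  types <- sort(unique(unlist(lapply(rows, names))))
  est <- t(vapply(rows, function(p) {
    v <- stats::setNames(numeric(length(types)), types)
    v[names(p)] <- p
    v
  }, numeric(length(types))))
  structure(list(sample_id = sample_id, subjects = names(rows),
                 cell_types = types, estimates = est),
            class = "deconvolution_ensemble")
}

# Deterministic per-(subject, sample) kernel seed, kept inside 32-bit range.
kernel_seed <- function(base_seed, subject_index, sample_index) {
  (base_seed + 7919L * sample_index + 104729L * subject_index) %% 2147483647L
}

#' @export
print.deconvolution_ensemble <- function(x, ...) {
  cat(sprintf("deconvolution_ensemble (%s): %d subjects x %d cell types\n",
              x$sample_id, length(x$subjects), length(x$cell_types)))
  invisible(x)
}
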