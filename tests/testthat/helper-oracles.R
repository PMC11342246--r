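# Independent oracles and fixture builders used across the suite.

# Brute-force non-negative (weighted) least squares by active-set
# enumeration: for every support set F, solve the unconstrained weighted LS
# on F and keep the best solution satisfying primal feasibility (x_F >= 0)
# and dual feasibility (KKT gradient >= 0 off the support). Exponential in
# the number of columns, so only for small fixtures; independent of the
# package's Lawson-Hanson route.
qp_nnls_oracle <- function(S, b, w = NULL, normalize = TRUE, tol = 1e-9) {
  k <- ncol(S)
  W <- if (is.null(w)) diag(nrow(S)) else diag(w)
  best <- NULL
  for (mask in 0:(2^k - 1)) {
    F_ <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    x <- numeric(k)
    if (length(F_)) {
      SF <- S[, F_, drop = FALSE]
      A <- t(SF) %*% W %*% SF
      if (rcond(A) < 1e-12) next
      xf <- solve(A, t(SF) %*% W %*% b)
      if (any(xf < -tol)) next
      x[F_] <- pmax(xf, 0)
    }
    grad <- t(S) %*% W %*% (S %*% x - b)
    if (any(grad[setdiff(seq_len(k), F_)] < -max(1e-6, tol * max(abs(grad)))))
      next
    obj <- sum(W %*% (S %*% x - b)^2)
    if (is.null(best) || obj < best$obj - 1e-12) best <- list(x = x, obj = obj)
  }
  p <- best$x
  if (normalize) p <- p / sum(p)
  stats::setNames(p, colnames(S))
}

# Naive dense re-implementation of the cosine marker score: explicit loops
# over genes and cell types, no shared code with cosg_scores().
cosg_oracle <- function(X, cell_types, mu = 1) {
  X <- as.matrix(X)
  types <- sort(unique(cell_types))
  lam <- matrix(0, nrow(X), length(types), dimnames = list(rownames(X), types))
  for (g in seq_len(nrow(X))) {
    xg <- X[g, ]
    for (ti in seq_along(types)) {
      ind <- as.numeric(cell_types == types[ti])
      den <- sqrt(sum(xg^2)) * sqrt(sum(ind^2))
      lam[g, ti] <- if (den > 0) sum(xg * ind) / den else 0
    }
  }
  score <- lam
  for (g in seq_len(nrow(X))) {
    tot <- sum(lam[g, ]^2)
    for (ti in seq_along(types)) {
      l2 <- lam[g, ti]^2
      den <- l2 + mu * (tot - l2)
      score[g, ti] <- if (den > 0) l2 / den * sign(lam[g, ti]) else 0
    }
  }
  score
}

# Random full-column-rank signature matrix with heavy-tailed entries.
random_signature <- function(n_genes, n_types, seed) {
  set.seed(seed)
  repeat {
    S <- matrix(rexp(n_genes * n_types, rate = 0.2), n_genes, n_types,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("ct%d", seq_len(n_types))))
    # plant a marker block per type so columns are well separated
    blk <- max(1L, n_genes %/% (2L * n_types))
    for (t in seq_len(n_types)) {
      rows <- ((t - 1) * blk + 1):(t * blk)
      S[rows, t] <- S[rows, t] + 30
    }
    sv <- svd(S, nu = 0, nv = 0)$d
    if (min(sv) > 1e-8 * max(sv)) return(S)
  }
}

# Random point in the interior of the probability simplex.
random_simplex <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- rgamma(k, shape = 2)
  p / sum(p)
}

# Wrap a plain estimates matrix as a deconvolution ensemble.
as_ensemble <- function(est, sample_id = "s") {
  if (is.null(rownames(est))) rownames(est) <- sprintf("sub%02d", seq_len(nrow(est)))
  if (is.null(colnames(est))) colnames(est) <- sprintf("ct%d", seq_len(ncol(est)))
  structure(list(sample_id = sample_id, subjects = rownames(est),
                 cell_types = colnames(est), estimates = est),
            class = "deconvolution_ensemble")
}

# Small hand-buildable subject reference from a dense matrix (no
# normalization rescaling: total = NA keeps the raw values).
toy_subject <- function(mat, cell_types, subject_id = "toy", total = NA) {
  m <- Matrix::Matrix(mat, sparse = TRUE)
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  recide:::new_subject_reference(subject_id, m, cell_types, total = total)
}

# Tiny atlas with two subjects used by IO and partition tests.
tiny_atlas <- function() {
  counts <- matrix(c(5, 0, 1,  4, 1, 0,  0, 6, 2,  1, 5, 1,
                     6, 0, 0,  5, 1, 1,  0, 7, 1,  0, 5, 2,
                     1, 4, 6,  0, 5, 5), nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"),
                                   sprintf("cell%02d", 1:10)))
  meta <- data.frame(
    cell_id = colnames(counts),
    subject_id = rep(c("s1", "s2"), each = 5),
    cell_type = c("T", "T", "B", "B", "T", "T", "B", "B", "NK", "NK"),
    stringsAsFactors = FALSE)
  reference_atlas(counts, meta)
}
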