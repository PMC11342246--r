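#' Partition an atlas into per-subject references
#'
#' Splits the reference by subject label and normalizes each cell's counts to
#' a fixed library size (counts per `normalize_total`, default 1e4). Within a
#' subject, cell types represented by fewer than `min_cells_per_type` cells
#' are dropped (their per-type means would be too noisy to serve as a basis
#' column); a subject left with fewer than two cell types is excluded.
#'
#' @param atlas A [reference_atlas()].
#' @param config A [recide_config()].
#' @return A named list of `"subject_reference"` objects, each holding
#'   `subject_id`, `gene_ids`, `counts` (sparse genes x cells),
#'   `cell_types` (per cell) and `normalized` (genes x cells, per-cell
#'   library-size scaled).
#' @export
partition_by_subject <- function(atlas, config = recide_config()) {
  stopifnot(inherits(atlas, "reference_atlas"))
  subjects <- unique(atlas$cell_meta$subject_id)
  out <- list()
  for (s in subjects) {
    keep <- atlas$cell_meta$subject_id == s
    cts <- atlas$cell_meta$cell_type[keep]
    tab <- table(cts)
    small <- names(tab)[tab < config$min_cells_per_type]
    if (length(small)) {
      warning(sprintf("subject %s: dropping cell type(s) with < %d cells: %s",
                      s, config$min_cells_per_type, paste(small, collapse = ", ")))
      keep[keep] <- !(cts %in% small)
      cts <- cts[!(cts %in% small)]
    }
    if (length(unique(cts)) < 2) {
      warning(sprintf("subject %s excluded: fewer than 2 usable cell types", s))
      next
    }
    counts <- atlas$counts[, keep, drop = FALSE]
    out[[s]] <- new_subject_reference(s, counts, cts, config$normalize_total)
  }
  if (!length(out)) stop("no usable subjects after partition filters")
  out
}

new_subject_reference <- function(subject_id, counts, cell_types, total = 1e4) {
  normalized <- if (is.na(total)) counts else {
    libsize <- Matrix::colSums(counts)
    scl <- ifelse(libsize > 0, total / libsize, 0)   # all-zero cells stay zero
    counts %*% Matrix::Diagonal(x = scl)
  }
  colnames(normalized) <- colnames(counts)
  structure(list(subject_id = subject_id, gene_ids = rownames(counts),
                 counts = counts, cell_types = cell_types,
                 normalized = normalized),
            class = "subject_reference")
}

#' @export
print.subject_reference <- function(x, ...) {
  cat(sprintf("subject_reference %s: %d genes x %d cells, types: %s\n",
              x$subject_id, length(x$gene_ids), ncol(x$counts),
              paste(sort(unique(x$cell_types)), collapse = ", ")))
  invisible(x)
}

# Mean normalized expression per cell type: genes x types.
type_means <- function(ref) {
  types <- sort(unique(ref$cell_types))
  m <- sapply(types, function(t)
    Matrix::rowMeans(ref$normalized[, ref$cell_types == t, drop = FALSE]))
  m <- matrix(m, nrow = length(ref$gene_ids),
              dimnames = list(ref$gene_ids, types))
  m
}

#' Cosine marker scores for every gene and cell type
#'
#' For gene g and cell type t, the raw statistic is the cosine similarity
#' \eqn{\lambda_{gt}} between the gene's normalized expression vector across
#' the subject's cells and the 0/1 indicator vector of membership in t. The
#' marker score penalizes expression in other cell types:
#' \deqn{s_{gt} = \lambda_{gt}^2 / (\lambda_{gt}^2 + \mu \sum_{t' \ne t} \lambda_{gt'}^2)}
#' with penalty weight \eqn{\mu} (default 1). A gene expressed exclusively
#' and uniformly in one cell type attains the maximal score for that type; a
#' gene flat across all cells scores identically (and sub-maximally) for
#' every type. All-zero genes score 0.
#'
#' @param ref A `"subject_reference"`.
#' @param mu Penalty weight on cross-type similarity.
#' @return Genes x cell-types matrix of scores.
#' @export
cosg_scores <- function(ref, mu = 1) {
  types <- sort(unique(ref$cell_types))
  if (length(types) < 2) stop("marker scoring needs >= 2 cell types")
  X <- ref$normalized
  memb <- sapply(types, function(t) as.numeric(ref$cell_types == t))
  n_t <- colSums(memb)
  # lambda = (X . ind) / (|x_g| sqrt(n_t))
  num <- as.matrix(X %*% memb)
  gene_norm <- sqrt(Matrix::rowSums(X^2))
  lam <- sweep(num, 2, sqrt(n_t), "/") / ifelse(gene_norm > 0, gene_norm, Inf)
  lam2 <- lam^2
  tot <- rowSums(lam2)
  denom <- lam2 + mu * (tot - lam2)
  score <- ifelse(denom > 0, lam2 / denom * sign(lam), 0)
  dimnames(score) <- list(ref$gene_ids, types)
  score
}

#' Select the top-scoring marker genes per cell type
#'
#' @param ref A `"subject_reference"` with at least two cell types.
#' @param n_top Markers initially kept per cell type (default 100).
#' @param mu Penalty weight passed to [cosg_scores()].
#' @return A `"marker_catalog"`: per cell type a data.frame
#'   (`gene`, `marker_score`, `second_fc`) ordered by descending score
#'   (ties broken by gene ID); `second_fc` is `NA` until [filter_markers()]
#'   annotates it. A cell type with no expressed gene gets an empty list with
#'   a warning.
#' @export
score_markers <- function(ref, n_top = 100L, mu = 1) {
  sc <- cosg_scores(ref, mu = mu)
  per_type <- lapply(colnames(sc), function(t) {
    s <- sc[, t]
    expressed <- s > 0
    if (!any(expressed)) {
      warning(sprintf("subject %s: cell type %s has no expressed marker candidates",
                      ref$subject_id, t))
      return(data.frame(gene = character(), marker_score = numeric(),
                        second_fc = numeric(), stringsAsFactors = FALSE))
    }
    ord <- order(-s, names(s), method = "radix")
    ord <- ord[expressed[ord]][seq_len(min(n_top, sum(expressed)))]
    data.frame(gene = names(s)[ord], marker_score = unname(s[ord]),
               second_fc = NA_real_, stringsAsFactors = FALSE)
  })
  names(per_type) <- colnames(sc)
  structure(list(subject_id = ref$subject_id, per_type = per_type),
            class = "marker_catalog")
}

#' @export
print.marker_catalog <- function(x, ...) {
  cat(sprintf("marker_catalog (%s): %s\n", x$subject_id,
              paste(sprintf("%s=%d", names(x$per_type),
                            vapply(x$per_type, nrow, 0L)), collapse = ", ")))
  invisible(x)
}

#' Second fold change of a gene across cell types
#'
#' Ratio of the gene's mean normalized expression in its highest-expressing
#' cell type to the second-highest. A zero second-highest mean yields `Inf`
#' (the gene passes any threshold); a tie at the top yields exactly 1 (the
#' gene discriminates nothing between the tied types and is filtered out by
#' any threshold above 1).
#'
#' @param ref A `"subject_reference"` with >= 2 cell types.
#' @param gene Gene ID (vectorized).
#' @param means Optional precomputed genes x types mean matrix.
#' @return Numeric vector of fold changes.
#' @export
second_fc <- function(ref, gene, means = NULL) {
  if (is.null(means)) means <- type_means(ref)
  if (ncol(means) < 2) stop("second_fc needs >= 2 cell types")
  miss <- setdiff(gene, rownames(means))
  if (length(miss)) stop("gene(s) absent: ", paste(miss, collapse = ", "))
  vapply(gene, function(g) {
    v <- sort(means[g, ], decreasing = TRUE)
    if (v[1] == v[2]) return(1)          # top tie: no discrimination
    if (v[2] == 0) return(Inf)
    v[1] / v[2]
  }, numeric(1))
}

#' Filter a marker catalog by second fold change
#'
#' Retains a marker if and only if its second fold change strictly exceeds
#' the threshold (a gene sitting exactly at the threshold is removed).
#' Per-type ordering is preserved and the fold change is annotated on every
#' retained entry.
#'
#' @param catalog A `"marker_catalog"`.
#' @param ref The `"subject_reference"` the catalog was scored on.
#' @param threshold Fold-change threshold, >= 1 (default 1.5).
#' @return The filtered `"marker_catalog"`.
#' @export
filter_markers <- function(catalog, ref, threshold = 1.5) {
  stopifnot(inherits(catalog, "marker_catalog"), threshold >= 1)
  means <- type_means(ref)
  type_names <- names(catalog$per_type)
  catalog$per_type <- lapply(type_names, function(t) {
    df <- catalog$per_type[[t]]
    if (!nrow(df)) return(df)
    df$second_fc <- second_fc(ref, df$gene, means = means)
    keep <- df[df$second_fc > threshold, , drop = FALSE]
    if (!nrow(keep))
      warning(sprintf("subject %s: cell type %s lost all markers at SecondFC > %g",
                      catalog$subject_id, t, threshold))
    rownames(keep) <- NULL
    keep
  })
  names(catalog$per_type) <- type_names
  catalog
}

#' Build a subject's signature matrix with stability-driven gene counts
#'
#' For each candidate per-type marker count G in `[g_min, g_max]`, forms the
#' matrix whose rows are the union of each cell type's top-G filtered markers
#' and whose entries are the mean normalized expression of each gene over the
#' cells of each type, and computes its 2-norm condition number. The G with
#' the smallest condition number wins (ties go to the smallest G) — the most
#' stable basis for the downstream least-squares problem.
#'
#' @param ref A `"subject_reference"`.
#' @param catalog A filtered `"marker_catalog"` for the same subject.
#' @param g_min,g_max Candidate range of per-type marker counts; types with
#'   fewer filtered markers contribute all of them.
#' @return A `"signature_matrix"`: `subject_id`, `values` (marker genes x
#'   cell types), `per_type_markers` (list), `condition_number`, `g_used`.
#' @export
build_signature <- function(ref, catalog, g_min = 50L, g_max = 100L) {
  stopifnot(inherits(ref, "subject_reference"), inherits(catalog, "marker_catalog"))
  lens <- vapply(catalog$per_type, nrow, 0L)
  types <- names(catalog$per_type)[lens > 0]
  if (length(types) < 2)
    stop(sprintf("subject %s: fewer than 2 cell types with markers", ref$subject_id))
  longest <- max(lens)
  g_hi <- min(g_max, longest)
  g_lo <- min(g_min, g_hi)
  means <- type_means(ref)

  best <- NULL
  for (G in seq(g_lo, g_hi)) {
    per_type <- lapply(catalog$per_type[types], function(df)
      df$gene[seq_len(min(G, nrow(df)))])
    genes <- sort(unique(unlist(per_type)))
    S <- means[genes, types, drop = FALSE]
    sv <- svd(S, nu = 0, nv = 0)$d
    kappa <- if (min(sv) <= max(sv) * .Machine$double.eps * max(dim(S))) Inf
             else max(sv) / min(sv)
    if (is.null(best) || kappa < best$kappa)
      best <- list(kappa = kappa, G = G, S = S, per_type = per_type)
  }
  if (!is.finite(best$kappa)) {
    sv <- svd(best$S)
    bad <- colnames(best$S)[abs(sv$v[, ncol(sv$v)]) > 1e-8]
    stop(sprintf("subject %s: signature rank-deficient at every candidate size; near-collinear cell types: %s",
                 ref$subject_id, paste(bad, collapse = ", ")))
  }
  structure(list(subject_id = ref$subject_id, values = best$S,
                 per_type_markers = best$per_type,
                 condition_number = best$kappa, g_used = best$G),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix (%s): %d marker genes x %d cell types, kappa = %.3g (G = %d)\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              x$condition_number, x$g_used))
  invisible(x)
}
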