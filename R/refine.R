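#' Bulk-similarity score of one cell type's marker set
#'
#' The score is `n_markers * cosine` where the cosine is taken between the
#' signature column of the cell type restricted to the marker subset and the
#' bulk expression vector restricted to the same genes. Genes absent from the
#' bulk panel contribute 0 to the bulk slice (so the marker count in the
#' multiplier stays honest). An empty subset or a zero-norm slice has cosine
#' 0 by convention.
#'
#' @param sig A `"signature_matrix"`.
#' @param cell_type Column of the signature to score.
#' @param marker_subset Subset of that type's markers (default: all of them).
#' @param bulk_column Named numeric vector of bulk expression.
#' @return A list `(cell_type, n_markers, cosine, score)`.
#' @export
similarity_score <- function(sig, cell_type, marker_subset = NULL, bulk_column) {
  if (!cell_type %in% colnames(sig$values))
    stop("cell type absent from signature: ", cell_type)
  if (is.null(marker_subset)) marker_subset <- sig$per_type_markers[[cell_type]]
  stopifnot(all(marker_subset %in% sig$per_type_markers[[cell_type]]))
  n <- length(marker_subset)
  a <- sig$values[marker_subset, cell_type]
  b <- numeric(n)
  hit <- marker_subset %in% names(bulk_column)
  b[hit] <- bulk_column[marker_subset[hit]]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  cosine <- if (n == 0 || na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  list(cell_type = cell_type, n_markers = n, cosine = cosine,
       score = n * cosine)
}

#' Greedily prune each cell type's markers to maximize bulk similarity
#'
#' For every cell type independently, markers are visited once in ascending
#' order of their second fold change (ties broken by gene ID). Each visit
#' tentatively removes the marker from the current (already-pruned) set and
#' recomputes the similarity score against the bulk column; the removal is
#' committed only if the score strictly increases and at least `floor`
#' markers would remain. Committed scores therefore increase strictly, and
#' the final per-type score is never below the initial one. This trims
#' markers whose reference expression disagrees with the bulk profile —
#' typically platform or batch casualties.
#'
#' @param sig A `"signature_matrix"`.
#' @param catalog The filtered `"marker_catalog"` the signature was built
#'   from (supplies the second fold changes driving the traversal order).
#' @param bulk_column Named numeric bulk expression vector.
#' @param floor Minimum surviving markers per type (default 3). A type that
#'   starts below the floor is left untouched.
#' @return The refined `"signature_matrix"`: rows are the union of surviving
#'   markers, values unchanged for surviving entries; per-type refinement
#'   traces in `attr(, "refinement")`.
#' @export
refine_signature <- function(sig, catalog, bulk_column, floor = 3L) {
  stopifnot(inherits(sig, "signature_matrix"), floor >= 1)
  trace <- list()
  new_sets <- sig$per_type_markers
  for (ct in names(sig$per_type_markers)) {
    markers <- sig$per_type_markers[[ct]]
    df <- catalog$per_type[[ct]]
    fc <- df$second_fc[match(markers, df$gene)]
    fc[is.na(fc)] <- Inf
    visit <- markers[order(fc, markers, method = "radix")]
    current <- markers
    score <- similarity_score(sig, ct, current, bulk_column)$score
    initial <- score
    committed <- score                 # score path, one entry per commit
    for (g in visit) {
      if (length(current) <= floor) break
      cand <- setdiff(current, g)
      s2 <- similarity_score(sig, ct, cand, bulk_column)$score
      if (s2 > score) { current <- cand; score <- s2; committed <- c(committed, s2) }
    }
    new_sets[[ct]] <- markers[markers %in% current]   # preserve original order
    trace[[ct]] <- list(initial_score = initial, final_score = score,
                        score_path = committed,
                        n_initial = length(markers), n_final = length(current))
  }
  genes <- sort(unique(unlist(new_sets)))
  out <- sig
  out$values <- sig$values[genes, , drop = FALSE]
  out$per_type_markers <- new_sets
  attr(out, "refinement") <- trace
  out
}
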