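#' Construct a multi-subject single-cell reference atlas
#'
#' @param counts Sparse or dense non-negative matrix of raw counts,
#'   genes x cells. Row and column names are taken as gene and cell IDs when
#'   `gene_ids`/`cell_ids` are not given.
#' @param cell_meta `data.frame` with columns `cell_id`, `subject_id`,
#'   `cell_type`; exactly one row per cell in `counts`.
#' @param gene_ids,cell_ids Optional ID vectors overriding dimnames.
#'
#' @return An object of class `"reference_atlas"` with elements `counts`
#'   (a `dgCMatrix`), `gene_ids`, `cell_ids` and `cell_meta` (ordered as the
#'   matrix columns).
#' @export
reference_atlas <- function(counts, cell_meta, gene_ids = rownames(counts),
                            cell_ids = colnames(counts)) {
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene and cell IDs are required (dimnames or explicit arguments)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs in reference; reference genes must be unique")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell IDs in reference")
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids))
    stop(sprintf("count matrix is %d x %d but %d gene and %d cell IDs supplied",
                 nrow(counts), ncol(counts), length(gene_ids), length(cell_ids)))
  if (any(counts@x < 0)) stop("negative entries in count matrix")
  dimnames(counts) <- list(gene_ids, cell_ids)

  need <- c("cell_id", "subject_id", "cell_type")
  if (!all(need %in% names(cell_meta)))
    stop("cell_meta must have columns cell_id, subject_id, cell_type")
  cell_meta <- as.data.frame(cell_meta)[, need]
  cell_meta[] <- lapply(cell_meta, as.character)
  if (anyDuplicated(cell_meta$cell_id))
    stop("duplicate cell_id rows in metadata")
  missing <- setdiff(cell_ids, cell_meta$cell_id)
  if (length(missing))
    stop("cells missing from metadata: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5) else "")
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL

  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "reference_atlas")
}

#' @export
print.reference_atlas <- function(x, ...) {
  cat(sprintf("reference_atlas: %d genes x %d cells, %d subjects, %d cell types\n",
              length(x$gene_ids), length(x$cell_ids),
              length(unique(x$cell_meta$subject_id)),
              length(unique(x$cell_meta$cell_type))))
  invisible(x)
}

#' Read a reference atlas from Matrix Market files
#'
#' Reads the common sparse interchange layout: a coordinate-format `.mtx`
#' count matrix with one-ID-per-line gene and cell sidecar files, plus a
#' tab-separated per-cell metadata table.
#'
#' @param mtx_path Matrix Market file, genes x cells raw counts.
#' @param gene_path,cell_path One ID per line, matching matrix rows/columns.
#' @param meta_path TSV with header `cell_id`, `subject_id`, `cell_type`.
#'
#' @return A [reference_atlas()].
#' @export
read_reference <- function(mtx_path, gene_path, cell_path, meta_path) {
  counts <- Matrix::readMM(mtx_path)
  gene_ids <- readLines(gene_path)
  cell_ids <- readLines(cell_path)
  if (nrow(counts) != length(gene_ids))
    stop(sprintf("matrix has %d rows but %d gene IDs", nrow(counts), length(gene_ids)))
  if (ncol(counts) != length(cell_ids))
    stop(sprintf("matrix has %d columns but %d cell IDs", ncol(counts), length(cell_ids)))
  meta <- utils::read.delim(meta_path, sep = "\t", header = TRUE,
                            colClasses = "character")
  reference_atlas(counts, meta, gene_ids = gene_ids, cell_ids = cell_ids)
}

#' Write a reference atlas in the Matrix Market layout
#'
#' @param atlas A [reference_atlas()].
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`, `cell_meta.tsv`.
#' @return Invisibly, the directory path.
#' @export
write_reference <- function(atlas, dir) {
  stopifnot(inherits(atlas, "reference_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(atlas$counts, file.path(dir, "matrix.mtx"))
  writeLines(atlas$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(atlas$cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(atlas$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a bulk expression matrix
#'
#' Expects a delimited text file with gene IDs in the first column, sample IDs
#' in the header, and a non-negative numeric body on linear scale
#' (log-transformed input must be undone by the caller). Duplicate gene rows
#' are collapsed by summation, the usual convention when several quantification
#' records map to one symbol.
#'
#' @param path TSV or CSV file; the delimiter is inferred from the extension
#'   (`.csv` means comma, anything else tab) unless `sep` is given.
#' @param sep Optional field separator override.
#'
#' @return An object of class `"bulk_matrix"` with elements `values`
#'   (dense genes x samples matrix), `gene_ids`, `sample_ids`.
#' @export
read_bulk <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("bulk file needs a gene column plus >= 1 sample column")
  genes <- as.character(tab[[1]])
  if (!all(vapply(tab[-1], is.numeric, logical(1))))
    stop("non-numeric entries in bulk matrix body")
  body <- as.matrix(tab[, -1, drop = FALSE])
  bulk_matrix(body, gene_ids = genes, sample_ids = colnames(tab)[-1])
}

#' Construct a bulk matrix
#'
#' @param values Dense non-negative numeric matrix, genes x samples, linear
#'   scale. Duplicate gene rows are summed with a warning.
#' @param gene_ids,sample_ids ID vectors; default to dimnames.
#' @return A `"bulk_matrix"` object.
#' @export
bulk_matrix <- function(values, gene_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample IDs are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("ID lengths do not match matrix dimensions")
  if (any(!is.finite(values))) stop("non-finite entries in bulk matrix")
  if (any(values < 0)) stop("negative entries in bulk matrix; input must be linear scale")
  if (anyDuplicated(gene_ids)) {
    warning("duplicate bulk gene rows collapsed by sum")
    values <- rowsum(values, group = gene_ids, reorder = FALSE)
    gene_ids <- rownames(values)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids),
            class = "bulk_matrix")
}

#' @export
print.bulk_matrix <- function(x, ...) {
  cat(sprintf("bulk_matrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Write integrated proportions to CSV
#'
#' Rows are cell types, columns are samples. Refuses to write vectors that do
#' not lie on the probability simplex.
#'
#' @param results A single `"integrated_proportions"` object or a list of them
#'   (one per sample).
#' @param path Output CSV path.
#' @return Invisibly, the cell-types x samples matrix written.
#' @export
write_proportions <- function(results, path) {
  if (inherits(results, "integrated_proportions")) results <- list(results)
  stopifnot(length(results) >= 1)
  mats <- lapply(results, function(r) {
    stopifnot(inherits(r, "integrated_proportions"))
    p <- r$proportions
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("proportions for sample '%s' are not normalized (sum %.10f)",
                   r$sample_id, sum(p)))
    p
  })
  types <- Reduce(union, lapply(mats, names))
  out <- sapply(mats, function(p) { v <- stats::setNames(numeric(length(types)), types)
                                    v[names(p)] <- p; v })
  out <- matrix(out, nrow = length(types),
                dimnames = list(types, vapply(results, `[[`, "", "sample_id")))
  df <- data.frame(cell_type = rownames(out), out, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Write per-sample integration diagnostics as JSON
#'
#' Sidecar next to the proportions CSV: per sample the cluster labels, the
#' size of the retained cluster and the run manifest.
#'
#' @param result A list as returned by [run_recide()].
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_diagnostics <- function(result, path) {
  manifest <- result$manifest
  manifest$config <- unclass(manifest$config)
  manifest$config$dwls <- unclass(manifest$config$dwls)
  diag <- list(
    samples = lapply(result$proportions, function(p)
      list(sample_id = p$sample_id, n_used = p$n_used,
           cluster_labels = as.list(p$cluster_labels))),
    manifest = manifest)
  jsonlite::write_json(diag, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a proportions CSV written by [write_proportions()]
#'
#' @param path CSV path.
#' @return Cell-types x samples numeric matrix.
#' @export
read_proportions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
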