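#' Specification of a synthetic multi-subject reference
#'
#' Describes the simulated study: several subjects sharing a cell-type
#' universe, each cell type carrying a block of designated marker genes that
#' are `marker_fold`-times overexpressed in that type, and subject-level
#' biological variation injected as gene-wise log-normal multipliers with
#' standard deviation `subject_sd` (on the log scale). The default abundance
#' profile spans the three size classes used throughout the evaluation:
#' major (> 10%), minor (2-10%) and rare (< 2%) cell types, including rare
#' types at 1% and 0.5%.
#'
#' @param n_subjects Number of reference subjects (default 10).
#' @param n_cell_types Number of shared cell types (default 8).
#' @param n_genes Total genes; markers are carved from the front (default 1200).
#' @param n_markers_per_type Designated marker genes per cell type (default 40).
#' @param marker_fold Overexpression factor of a type's markers in that type
#'   (default 5, must exceed 1).
#' @param subject_sd Standard deviation of the per-subject, per-gene
#'   log-normal expression multiplier (default 0.3; 0 removes subject effects).
#' @param abundance_profile Named numeric vector of target cell-type
#'   proportions summing to 1; default
#'   `c(0.32, 0.25, 0.15, 0.12, 0.08, 0.065, 0.01, 0.005)` over types
#'   `ct1..ct8` (requires `n_cell_types = 8`).
#' @param cells_per_subject Cells simulated per subject (default 1500).
#' @param depth_per_cell Expected total counts per cell (default 2000).
#' @param noise Count noise family, `"poisson"` (default) or `"nb"`
#'   (negative binomial).
#' @param nb_size Negative-binomial size (inverse dispersion) when
#'   `noise = "nb"` (default 10).
#' @param seed Integer seed; the generator is fully reproducible from it.
#'
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_subjects = 10L,
                            n_cell_types = 8L,
                            n_genes = 1200L,
                            n_markers_per_type = 40L,
                            marker_fold = 5,
                            subject_sd = 0.3,
                            abundance_profile = NULL,
                            cells_per_subject = 1500L,
                            depth_per_cell = 2000L,
                            noise = c("poisson", "nb"),
                            nb_size = 10,
                            seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(abundance_profile)) {
    if (n_cell_types != 8L)
      stop("default abundance_profile covers 8 cell types; supply one for n_cell_types = ",
           n_cell_types)
    abundance_profile <- stats::setNames(
      c(0.32, 0.25, 0.15, 0.12, 0.08, 0.065, 0.01, 0.005),
      paste0("ct", 1:8))
  }
  if (is.null(names(abundance_profile)))
    names(abundance_profile) <- paste0("ct", seq_along(abundance_profile))
  if (length(abundance_profile) != n_cell_types)
    stop("abundance_profile length must equal n_cell_types")
  if (abs(sum(abundance_profile) - 1) > 1e-8)
    stop("abundance_profile must sum to 1")
  if (any(abundance_profile <= 0)) stop("abundance_profile entries must be positive")
  if (n_cell_types >= 5L && !any(abundance_profile < 0.02))
    stop("with >= 5 cell types at least one must be rare (< 2%)")
  if (marker_fold <= 1) stop("marker_fold must exceed 1")
  if (subject_sd < 0) stop("subject_sd must be >= 0")
  stopifnot(n_subjects >= 1, n_genes >= n_cell_types * n_markers_per_type,
            cells_per_subject >= 1, depth_per_cell >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_cell_types = as.integer(n_cell_types),
                 n_genes = as.integer(n_genes),
                 n_markers_per_type = as.integer(n_markers_per_type),
                 marker_fold = marker_fold, subject_sd = subject_sd,
                 abundance_profile = abundance_profile,
                 cells_per_subject = as.integer(cells_per_subject),
                 depth_per_cell = as.integer(depth_per_cell),
                 noise = noise, nb_size = nb_size, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Largest-remainder apportionment of counts
#'
#' Rounds `total * proportions` to integers that sum exactly to `total`:
#' floors first, then hands the remaining units to the largest fractional
#' parts (ties broken by position).
#'
#' @param proportions Non-negative weights summing to 1.
#' @param total Integer total to apportion.
#' @return Integer vector, same names as `proportions`, summing to `total`.
#' @export
largest_remainder <- function(proportions, total) {
  stopifnot(total >= 0, all(proportions >= 0), abs(sum(proportions) - 1) < 1e-8)
  raw <- proportions * total
  base <- floor(raw)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    frac <- raw - base
    give <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(left)]
    base[give] <- base[give] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

# Expected per-cell expression profiles for one subject: genes x cell types,
# each column scaled to sum depth_per_cell. Marker blocks are deterministic
# (gene (t-1)*m+1 .. t*m belongs to type t); base means and subject
# multipliers are drawn from the stream of the current RNG state.
subject_type_means <- function(spec, base_means, marker_sets) {
  # one multiplier per gene per subject, shared by all of that subject's cell
  # types: subject effects shift genes coherently, type contrasts persist
  mult <- if (spec$subject_sd > 0) {
    stats::rlnorm(spec$n_genes, meanlog = -spec$subject_sd^2 / 2,
                  sdlog = spec$subject_sd)
  } else rep(1, spec$n_genes)
  means <- matrix(base_means * mult, spec$n_genes, spec$n_cell_types)
  for (t in seq_len(spec$n_cell_types))
    means[marker_sets[[t]], t] <- means[marker_sets[[t]], t] * spec$marker_fold
  sweep(means, 2, colSums(means), "/") * spec$depth_per_cell
}

#' Generate a synthetic multi-subject reference atlas
#'
#' For each subject, each cell type's expected profile is the shared base
#' mean vector, multiplied by `marker_fold` on that type's designated marker
#' genes and by an independent per-gene log-normal subject multiplier, then
#' scaled so a cell's expected depth is `depth_per_cell`. Cell counts are
#' drawn from a Poisson (or negative binomial) around that profile. Cell-type
#' counts per subject follow the abundance profile via largest-remainder
#' rounding.
#'
#' @param spec A [simulation_spec()].
#' @return A [reference_atlas()] with cells named
#'   `<subject>_cell<k>`. The designated marker sets are attached as
#'   `attr(, "marker_sets")` and the per-subject expected profiles as
#'   `attr(, "expected_means")` for testing.
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n_per_type <- largest_remainder(spec$abundance_profile, spec$cells_per_subject)
  if (any(spec$abundance_profile * spec$cells_per_subject < 1))
    stop("abundance_profile entry x cells_per_subject < 1: cell type unrepresentable; ",
         "increase cells_per_subject or the rare proportion")

  set.seed(spec$seed)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  types <- names(spec$abundance_profile)
  marker_sets <- lapply(seq_len(spec$n_cell_types), function(t)
    ((t - 1) * spec$n_markers_per_type + 1):(t * spec$n_markers_per_type))
  names(marker_sets) <- types
  # shared baseline expression, heavy-tailed as in real transcriptomes
  base_means <- stats::rlnorm(spec$n_genes, meanlog = 0, sdlog = 1)

  subjects <- sprintf("s%02d", seq_len(spec$n_subjects))
  blocks <- vector("list", spec$n_subjects)
  meta <- vector("list", spec$n_subjects)
  expected <- vector("list", spec$n_subjects)
  type_of_cell <- rep(types, times = n_per_type)
  for (i in seq_along(subjects)) {
    means <- subject_type_means(spec, base_means, marker_sets)
    expected[[i]] <- means
    lam <- means[, match(type_of_cell, types), drop = FALSE]
    cnt <- if (spec$noise == "poisson") {
      matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    } else {
      matrix(stats::rnbinom(length(lam), mu = lam, size = spec$nb_size),
             nrow(lam), ncol(lam))
    }
    blocks[[i]] <- Matrix::Matrix(cnt, sparse = TRUE)
    meta[[i]] <- data.frame(
      cell_id = sprintf("%s_cell%04d", subjects[i], seq_len(spec$cells_per_subject)),
      subject_id = subjects[i], cell_type = type_of_cell,
      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, meta)
  rownames(counts) <- genes
  colnames(counts) <- meta$cell_id
  names(expected) <- subjects
  atlas <- reference_atlas(counts, meta)
  attr(atlas, "marker_sets") <- lapply(marker_sets, function(ix) genes[ix])
  attr(atlas, "expected_means") <- lapply(expected, function(m) {
    dimnames(m) <- list(genes, types); m })
  atlas
}

#' Build a pseudo-bulk sample from one subject's cells
#'
#' Samples cells of the given subject at per-type counts fixed by
#' largest-remainder rounding of `proportions * n_cells`, and sums their raw
#' counts gene-wise into a single bulk column. Sampling is without
#' replacement when a type has enough cells, with replacement otherwise. The
#' returned truth table records the realized (post-rounding) proportions —
#' the only defensible ground truth.
#'
#' @param atlas A [reference_atlas()].
#' @param subject_id Subject whose cells are mixed.
#' @param proportions Named vector over (a subset of) that subject's cell
#'   types, summing to 1. Default: the subject's empirical type proportions.
#' @param n_cells Number of cells mixed into the pseudo-bulk (default 1000).
#' @param seed Integer seed for the cell draw.
#' @param sample_id Name of the bulk column.
#'
#' @return `list(bulk = bulk_matrix (genes x 1), truth = truth_table)` where
#'   the truth table is `list(sample_id, proportions)` of class
#'   `"truth_table"`.
#' @export
generate_pseudobulk <- function(atlas, subject_id, proportions = NULL,
                                n_cells = 1000L, seed = 1L,
                                sample_id = paste0("pb_", subject_id)) {
  stopifnot(inherits(atlas, "reference_atlas"))
  in_subj <- atlas$cell_meta$subject_id == subject_id
  if (!any(in_subj)) stop("unknown subject: ", subject_id)
  subj_types <- atlas$cell_meta$cell_type[in_subj]
  if (is.null(proportions)) {
    tab <- table(subj_types)
    proportions <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  absent <- setdiff(names(proportions)[proportions > 0], unique(subj_types))
  if (length(absent))
    stop("cell type(s) absent from subject ", subject_id, ": ",
         paste(absent, collapse = ", "))

  n_take <- largest_remainder(proportions, n_cells)
  set.seed(seed)
  picked <- unlist(lapply(names(n_take)[n_take > 0], function(ct) {
    pool <- which(in_subj & atlas$cell_meta$cell_type == ct)
    k <- n_take[[ct]]
    if (k <= length(pool)) pool[sample.int(length(pool), k)]
    else pool[sample.int(length(pool), k, replace = TRUE)]
  }), use.names = FALSE)
  col <- Matrix::rowSums(atlas$counts[, picked, drop = FALSE])
  bulk <- bulk_matrix(matrix(col, ncol = 1,
                             dimnames = list(atlas$gene_ids, sample_id)))
  truth <- structure(list(sample_id = sample_id,
                          proportions = n_take[n_take > 0] / n_cells),
                     class = "truth_table")
  list(bulk = bulk, truth = truth)
}

#' Leave-one-out splits over the subjects of an atlas
#'
#' @param atlas A [reference_atlas()] with at least two subjects.
#' @return A list with one element per subject:
#'   `list(held_out, reference_subjects)`.
#' @export
leave_one_out_splits <- function(atlas) {
  stopifnot(inherits(atlas, "reference_atlas"))
  subjects <- unique(atlas$cell_meta$subject_id)
  if (length(subjects) < 2)
    stop("leave-one-out needs >= 2 subjects")
  lapply(subjects, function(s)
    list(held_out = s, reference_subjects = setdiff(subjects, s)))
}

#' Restrict an atlas to a subset of subjects
#'
#' @param atlas A [reference_atlas()].
#' @param subjects Character vector of subject IDs to keep.
#' @return A [reference_atlas()] containing only those subjects' cells.
#' @export
subset_subjects <- function(atlas, subjects) {
  keep <- atlas$cell_meta$subject_id %in% subjects
  if (!any(keep)) stop("no cells left after subject subset")
  reference_atlas(atlas$counts[, keep, drop = FALSE],
                  atlas$cell_meta[keep, , drop = FALSE])
}
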