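#' Run the full ensemble deconvolution pipeline
#'
#' Composes the three workflow stages: (1) partition the reference by
#' subject, score markers by cosine similarity, filter by second fold
#' change, and build each subject's signature matrix at the
#' condition-number-minimizing gene count; (2) optionally refine each
#' signature against the bulk profile and deconvolve every bulk sample with
#' every subject's signature; (3) reduce the per-subject estimates by PCA,
#' cluster them with a Gaussian mixture, and average the largest cluster
#' into the final proportions.
#'
#' @param atlas A [reference_atlas()].
#' @param bulk A [bulk_matrix()].
#' @param config A [recide_config()].
#' @return A list with
#'   `proportions` (named list of `"integrated_proportions"`, one per sample),
#'   `ensembles` (the per-sample `"deconvolution_ensemble"`s), and
#'   `manifest` (config snapshot, seed, problem sizes, per-stage timings,
#'   per-sample `n_used`).
#' @export
run_recide <- function(atlas, bulk, config = recide_config()) {
  stopifnot(inherits(atlas, "reference_atlas"), inherits(bulk, "bulk_matrix"))
  overlap <- length(intersect(atlas$gene_ids, bulk$gene_ids))
  if (overlap == 0) stop("reference and bulk share no genes")
  if (overlap < 100)
    stop(sprintf("only %d genes shared between reference and bulk (>= 100 required)",
                 overlap))
  if (overlap < 500)
    warning(sprintf("only %d genes shared between reference and bulk", overlap))

  t0 <- proc.time()[["elapsed"]]
  refs <- partition_by_subject(atlas, config)
  catalogs <- lapply(refs, function(r) {
    cat0 <- score_markers(r, n_top = config$n_markers_init, mu = config$cosg_mu)
    filter_markers(cat0, r, threshold = config$secondfc_threshold)
  })
  signatures <- mapply(function(r, cat) build_signature(r, cat,
                                                        g_min = config$g_min,
                                                        g_max = config$g_max),
                       refs, catalogs, SIMPLIFY = FALSE)
  t1 <- proc.time()[["elapsed"]]

  mean_bulk <- rowMeans(bulk$values)
  ensembles <- lapply(seq_along(bulk$sample_ids), function(j) {
    bcol <- bulk$values[, j]
    sigs_j <- if (config$refine_per_sample) {
      mapply(function(sig, cat) refine_signature(sig, cat, bcol,
                                                 floor = config$marker_floor),
             signatures, catalogs, SIMPLIFY = FALSE)
    } else {
      mapply(function(sig, cat) refine_signature(sig, cat, mean_bulk,
                                                 floor = config$marker_floor),
             signatures, catalogs, SIMPLIFY = FALSE)
    }
    deconvolve_one_sample(sigs_j, bcol, bulk$sample_ids[j], config,
                          sample_index = j)
  })
  names(ensembles) <- bulk$sample_ids
  t2 <- proc.time()[["elapsed"]]

  proportions <- lapply(ensembles, integrate_ensemble, config = config)
  t3 <- proc.time()[["elapsed"]]

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    n_subjects_used = length(signatures),
    n_samples = length(bulk$sample_ids),
    n_shared_genes = overlap,
    n_used = vapply(proportions, `[[`, 0L, "n_used"),
    timings = c(build_refs = t1 - t0, deconvolve = t2 - t1, integrate = t3 - t2),
    version = as.character(utils::packageVersion("recide")))
  list(proportions = proportions, ensembles = ensembles, manifest = manifest)
}

#' Leave-one-out pseudo-bulk benchmark
#'
#' For every subject in turn: builds a pseudo-bulk sample from that subject's
#' cells at its own empirical cell-type proportions, deconvolves it with the
#' remaining subjects as reference — once through the full ensemble pipeline
#' and once per single-subject reference — and scores everything against the
#' realized ground truth.
#'
#' @param atlas A [reference_atlas()] with at least 3 subjects.
#' @param config A [recide_config()].
#' @param n_cells_per_bulk Cells mixed into each pseudo-bulk (default 1000).
#' @return A list with
#'   `metrics`: `data.frame` (`split`, `method`, `rmse`, `pcc`) where method
#'   is `"recide"`, `"single_mean"` (plain average of all single-reference
#'   estimates, no clustering) or `"single:<subject>"`;
#'   `pairs`: pooled `data.frame` (`split`, `method`, `cell_type`, `true`,
#'   `estimated`) for `"recide"` and `"single_mean"`, for slope analysis;
#'   `truths`: the per-split realized truth tables.
#' @export
run_benchmark <- function(atlas, config = recide_config(),
                          n_cells_per_bulk = 1000L) {
  splits <- leave_one_out_splits(atlas)
  if (length(splits) < 3) stop("benchmark needs >= 3 subjects")
  metrics <- list(); pairs <- list(); truths <- list()
  for (sp in splits) {
    ref <- subset_subjects(atlas, sp$reference_subjects)
    pb <- generate_pseudobulk(atlas, sp$held_out, n_cells = n_cells_per_bulk,
                              seed = kernel_seed(config$seed, 1L,
                                                 match(sp$held_out,
                                                       unique(atlas$cell_meta$subject_id))))
    res <- run_recide(ref, pb$bulk, config)
    truth <- pb$truth
    truths[[sp$held_out]] <- truth
    ens <- res$ensembles[[1]]

    est_recide <- res$proportions[[1]]$proportions
    single_rows <- lapply(seq_along(ens$subjects), function(i)
      stats::setNames(ens$estimates[i, ], ens$cell_types))
    names(single_rows) <- ens$subjects
    est_single_mean <- colMeans(ens$estimates)
    est_single_mean <- est_single_mean / sum(est_single_mean)

    rows <- c(list(recide = est_recide, single_mean = est_single_mean),
              stats::setNames(single_rows, paste0("single:", names(single_rows))))
    metrics[[sp$held_out]] <- data.frame(
      split = sp$held_out,
      method = names(rows),
      rmse = vapply(rows, prop_rmse, 0, truth = truth),
      pcc = vapply(rows, prop_pcc, 0, truth = truth),
      row.names = NULL)
    for (m in c("recide", "single_mean")) {
      al <- align_proportions(rows[[m]], truth)
      pairs[[paste(sp$held_out, m)]] <- data.frame(
        split = sp$held_out, method = m, cell_type = al$types,
        true = unname(al$truth), estimated = unname(al$estimate),
        row.names = NULL)
    }
  }
  list(metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
       pairs = do.call(rbind, c(pairs, make.row.names = FALSE)),
       truths = truths)
}
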