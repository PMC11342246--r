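# Align an estimate and a truth vector on the union of their cell types,
# filling absences with 0.
align_proportions <- function(estimate, truth) {
  if (inherits(estimate, "integrated_proportions")) estimate <- estimate$proportions
  if (inherits(truth, "truth_table")) truth <- truth$proportions
  types <- union(names(estimate), names(truth))
  if (!length(types)) stop("empty cell-type universe")
  e <- stats::setNames(numeric(length(types)), types)
  t_ <- e
  e[names(estimate)] <- estimate
  t_[names(truth)] <- truth
  list(estimate = e, truth = t_, types = types)
}

#' Root mean square error between estimated and true proportions
#'
#' Computed across cell types within one sample, on the union of the two
#' cell-type sets (types missing from either side count as 0).
#'
#' @param estimate Named proportion vector or `"integrated_proportions"`.
#' @param truth Named proportion vector or `"truth_table"`.
#' @return Non-negative scalar.
#' @export
prop_rmse <- function(estimate, truth) {
  al <- align_proportions(estimate, truth)
  sqrt(mean((al$estimate - al$truth)^2))
}

#' Pearson correlation between estimated and true proportions
#'
#' Computed across cell types within one sample. Undefined (returned as `NA`
#' with a warning) when either vector has zero variance.
#'
#' @inheritParams prop_rmse
#' @return Scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
prop_pcc <- function(estimate, truth) {
  al <- align_proportions(estimate, truth)
  if (length(al$types) < 3) stop("PCC needs >= 3 cell types")
  if (stats::sd(al$estimate) == 0 || stats::sd(al$truth) == 0) {
    warning("PCC undefined: zero variance in estimate or truth")
    return(NA_real_)
  }
  stats::cor(al$estimate, al$truth)
}

#' Abundance class of a true cell-type proportion
#'
#' Cell types are stratified by their true abundance: rare below 2%, major
#' above 10%, minor in between (both boundaries inclusive to minor).
#'
#' @param true_proportion Numeric vector in `[0, 1]`.
#' @return Factor with levels `major`, `minor`, `rare`.
#' @export
abundance_class <- function(true_proportion) {
  stopifnot(all(true_proportion >= 0 & true_proportion <= 1))
  out <- ifelse(true_proportion < 0.02, "rare",
                ifelse(true_proportion > 0.10, "major", "minor"))
  factor(out, levels = c("major", "minor", "rare"))
}

#' Regression slope of estimated on true proportions
#'
#' Ordinary least-squares slope (intercept included) of the pooled
#' (true, estimated) pairs; a slope near 1 indicates well-calibrated
#' estimates, slopes below 1 systematic shrinkage toward zero.
#'
#' @param true_values,estimated_values Paired numeric vectors.
#' @return OLS slope.
#' @export
regression_slope <- function(true_values, estimated_values) {
  stopifnot(length(true_values) == length(estimated_values),
            length(true_values) >= 2)
  if (stats::sd(true_values) == 0) stop("true values are constant; slope undefined")
  unname(stats::coef(stats::lm(estimated_values ~ true_values))[2])
}

#' Slopes of estimated vs true proportions stratified by abundance class
#'
#' Pools (sample, cell type) pairs, classes each pair by its TRUE proportion,
#' and fits one OLS line per class.
#'
#' @param pairs `data.frame` with columns `true` and `estimated`.
#' @return `data.frame` with columns `class`, `slope`, `n_points`; classes
#'   with fewer than 2 points or constant truth get `NA`.
#' @export
slope_by_class <- function(pairs) {
  stopifnot(all(c("true", "estimated") %in% names(pairs)))
  cls <- abundance_class(pairs$true)
  do.call(rbind, lapply(levels(cls), function(l) {
    sub <- pairs[cls == l, , drop = FALSE]
    slope <- if (nrow(sub) >= 2 && stats::sd(sub$true) > 0)
      regression_slope(sub$true, sub$estimated) else NA_real_
    data.frame(class = l, slope = slope, n_points = nrow(sub))
  }))
}

#' Prognostic score from T-follicular-helper and perivascular-like fractions
#'
#' For triple-negative breast cancer bulk profiles, the score is the product
#' of the CXCL13+ follicular-helper-T to differentiated-PVL ratio and the
#' immature-PVL to total-PVL ratio:
#' `(p_tfh / (p_pvl_d3 + eps)) * (p_pvl_s1 / (p_pvl_total + eps))`,
#' where the total PVL fraction is the sum of all proportions whose cell-type
#' name starts with the PVL prefix. Scores above the decision threshold
#' (default 0.0125) classify the sample as having a favorable prognosis.
#'
#' @param p Named proportion vector or `"integrated_proportions"`.
#' @param tfh,pvl_d3,pvl_s1 Cell-type names of the CXCL13+ Tfh, differentiated
#'   PVL and immature PVL populations.
#' @param pvl_prefix Prefix identifying all PVL subtypes (default `"PVL"`).
#' @param eps Guard against zero denominators (default 1e-6).
#' @param threshold Favorable-prognosis cutoff (default 0.0125).
#' @return Scalar score with attribute `favorable` (logical).
#' @export
prognostic_score <- function(p,
                             tfh = "T_cells_c3_CD4_Tfh_CXCL13",
                             pvl_d3 = "PVL_Differentiated_s3",
                             pvl_s1 = "PVL_immature_s1",
                             pvl_prefix = "PVL",
                             eps = 1e-6, threshold = 0.0125) {
  if (inherits(p, "integrated_proportions")) p <- p$proportions
  stopifnot(eps > 0)
  missing <- setdiff(c(tfh, pvl_d3, pvl_s1), names(p))
  if (length(missing))
    stop("required cell type(s) absent: ", paste(missing, collapse = ", "))
  pvl_total <- sum(p[startsWith(names(p), pvl_prefix)])
  score <- (p[[tfh]] / (p[[pvl_d3]] + eps)) * (p[[pvl_s1]] / (pvl_total + eps))
  structure(unname(score), favorable = score > threshold)
}

#' Evaluate a set of estimates against ground truth
#'
#' @param estimates List of named proportion vectors (or
#'   `"integrated_proportions"`), one per sample.
#' @param truths List of matching truth vectors (or `"truth_table"`s).
#' @return `data.frame` with one row per sample: `sample`, `rmse`, `pcc`.
#' @export
evaluate_proportions <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths))
  ids <- names(estimates)
  if (is.null(ids)) ids <- as.character(seq_along(estimates))
  data.frame(
    sample = ids,
    rmse = mapply(prop_rmse, estimates, truths),
    pcc = mapply(prop_pcc, estimates, truths),
    row.names = NULL)
}
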