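small_spec <- function(...) {
  simulation_spec(n_subjects = 3, n_cell_types = 4, n_genes = 200,
                  n_markers_per_type = 10, cells_per_subject = 200,
                  depth_per_cell = 500,
                  abundance_profile = c(ct1 = 0.5, ct2 = 0.3, ct3 = 0.15,
                                        ct4 = 0.05),
                  seed = 42, ...)
}

test_that("generator is deterministic and respects the abundance profile", {
  a1 <- generate_reference(small_spec())
  a2 <- generate_reference(small_spec())
  expect_identical(as.matrix(a1$counts), as.matrix(a2$counts))
  expect_identical(a1$cell_meta, a2$cell_meta)

  tab <- table(a1$cell_meta$cell_type[a1$cell_meta$subject_id == "s01"])
  expect_equal(as.numeric(tab[paste0("ct", 1:4)]), c(100, 60, 30, 10))
})

test_that("subject_sd = 0 gives all subjects identical expected profiles", {
  a <- generate_reference(small_spec(subject_sd = 0))
  mu <- attr(a, "expected_means")
  expect_equal(mu$s01, mu$s02)
  expect_equal(mu$s02, mu$s03)
})

test_that("designated markers dominate their own cell type's mean expression", {
  spec <- simulation_spec(n_subjects = 1, n_cell_types = 4, n_genes = 200,
                          n_markers_per_type = 10, marker_fold = 8,
                          cells_per_subject = 2000, depth_per_cell = 500,
                          subject_sd = 0,
                          abundance_profile = c(ct1 = 0.4, ct2 = 0.3,
                                                ct3 = 0.2, ct4 = 0.1),
                          seed = 5)
  a <- generate_reference(spec)
  markers <- attr(a, "marker_sets")
  cts <- a$cell_meta$cell_type
  for (t in names(markers)) {
    own <- mean(as.matrix(a$counts[markers[[t]], cts == t]))
    others <- vapply(setdiff(names(markers), t), function(o)
      mean(as.matrix(a$counts[markers[[t]], cts == o])), numeric(1))
    expect_true(all(own > others))
  }
})

test_that("unrepresentable rare types are refused", {
  expect_error(generate_reference(
    simulation_spec(n_subjects = 2, n_cell_types = 4, n_genes = 100,
                    n_markers_per_type = 5, cells_per_subject = 50,
                    abundance_profile = c(ct1 = 0.6, ct2 = 0.3, ct3 = 0.095,
                                          ct4 = 0.005), seed = 1)),
    "unrepresentable")
})

test_that("largest-remainder apportionment is exact and deterministic", {
  expect_equal(unname(largest_remainder(c(0.55, 0.45), 10)), c(6L, 4L))
  expect_equal(unname(largest_remainder(c(1/3, 1/3, 1/3), 10)), c(4L, 3L, 3L))
  for (seed in 1:20) {
    p <- random_simplex(6, seed)
    n <- sample(50:500, 1)
    k <- largest_remainder(p, n)
    expect_equal(sum(k), n)
    expect_true(all(abs(k - p * n) < 1))   # never off by a full unit
  }
})

test_that("pseudo-bulk is the gene-wise sum of the sampled cells", {
  a <- generate_reference(small_spec())
  pb <- generate_pseudobulk(a, "s01", proportions = c(ct1 = 1), n_cells = 50,
                            seed = 9)
  expect_equal(unname(pb$truth$proportions), 1)
  # a pure ct1 mix must be reproducible and integer-valued raw count sums
  expect_true(all(pb$bulk$values == floor(pb$bulk$values)))
  pb2 <- generate_pseudobulk(a, "s01", proportions = c(ct1 = 1), n_cells = 50,
                             seed = 9)
  expect_identical(pb$bulk$values, pb2$bulk$values)

  res <- generate_pseudobulk(a, "s01", proportions = c(ct1 = 0.55, ct2 = 0.45),
                             n_cells = 10, seed = 2)
  expect_equal(res$truth$proportions, c(ct1 = 0.6, ct2 = 0.4))
  expect_error(generate_pseudobulk(a, "s01", proportions = c(bogus = 1),
                                   n_cells = 10), "absent")
  expect_error(generate_pseudobulk(a, "nope"), "unknown subject")
})

test_that("pseudo-bulk converges to the linear mixing model as cells grow", {
  spec <- small_spec(subject_sd = 0)
  a <- generate_reference(spec)
  mu <- attr(a, "expected_means")$s01
  props <- c(ct1 = 0.5, ct2 = 0.3, ct3 = 0.15, ct4 = 0.05)
  expected_per_cell <- as.numeric(mu %*% props)
  rel_err <- vapply(c(100L, 5000L), function(n) {
    pb <- generate_pseudobulk(a, "s01", proportions = props, n_cells = n, seed = 4)
    obs <- as.numeric(pb$bulk$values) / n
    sqrt(mean((obs - expected_per_cell)^2)) / mean(expected_per_cell)
  }, numeric(1))
  expect_lt(rel_err[2], rel_err[1])
  expect_lt(rel_err[2], 0.35)
})

test_that("leave-one-out splits cover all subjects and never leak", {
  a <- generate_reference(small_spec())
  splits <- leave_one_out_splits(a)
  expect_length(splits, 3)
  held <- vapply(splits, `[[`, "", "held_out")
  expect_setequal(held, unique(a$cell_meta$subject_id))
  for (sp in splits) {
    expect_false(sp$held_out %in% sp$reference_subjects)
    expect_length(sp$reference_subjects, 2)
  }
  one <- subset_subjects(a, "s01")
  expect_error(leave_one_out_splits(one), ">= 2 subjects")
})
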