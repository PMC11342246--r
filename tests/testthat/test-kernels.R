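test_that("both kernels recover exact mixtures from noiseless bulk", {
  for (seed in 1:10) {
    set.seed(seed)
    n_types <- sample(3:6, 1)
    S <- random_signature(sample(20:60, 1), n_types, seed = seed + 100)
    p_star <- random_simplex(n_types)
    b <- as.numeric(S %*% p_star)
    expect_equal(unname(solve_nnls(S, b)), p_star, tolerance = 1e-8)
    p_dwls <- solve_dampened_wls(S, b, settings = dwls_settings(cv_reps = 10),
                                 seed = seed)
    expect_equal(unname(as.numeric(p_dwls)), p_star, tolerance = 1e-6)
    expect_true(attr(p_dwls, "converged"))
  }
})

test_that("kernels are invariant to the overall scale of the bulk", {
  S <- random_signature(30, 4, seed = 1)
  set.seed(2)
  b <- as.numeric(S %*% random_simplex(4)) + rexp(30, 2)
  p1 <- solve_nnls(S, b)
  p2 <- solve_nnls(S, 1000 * b)
  expect_equal(p1, p2, tolerance = 1e-10)
  d1 <- solve_dampened_wls(S, b, settings = dwls_settings(cv_reps = 10), seed = 5)
  d2 <- solve_dampened_wls(S, 1000 * b, settings = dwls_settings(cv_reps = 10), seed = 5)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-8)
})

test_that("NNLS matches the active-set enumeration oracle under noise", {
  for (seed in 1:10) {
    set.seed(seed)
    S <- random_signature(20, 3, seed = seed + 50)
    b <- as.numeric(S %*% c(0.2, 0.3, 0.5)) + rnorm(20, sd = 0.5)
    b <- pmax(b, 0)
    expect_equal(unname(solve_nnls(S, b)), unname(qp_nnls_oracle(S, b)),
                 tolerance = 1e-6)
  }
})

test_that("fixed-weight dampened step equals the weighted QP oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    S <- random_signature(15, 3, seed = seed)
    b <- as.numeric(S %*% random_simplex(3)) + abs(rnorm(15, sd = 2))
    w <- runif(15, 0.1, 4)
    ours <- recide:::weighted_nnls(S, b, w)
    oracle <- qp_nnls_oracle(S, b, w = w)
    expect_equal(unname(ours), unname(oracle), tolerance = 1e-6)
  }
})

test_that("solver rejects degenerate inputs with informative errors", {
  S <- random_signature(20, 3, seed = 3)
  expect_error(solve_nnls(S, rep(0, 20)), "all zero")
  S2 <- cbind(S, ct4 = S[, 3])          # duplicated column
  expect_error(solve_nnls(S2, S[, 1]), "collinear")
  expect_match(tryCatch(solve_nnls(S2, S[, 1]), error = conditionMessage), "ct4")
})

test_that("dampening helps when one dominant gene carries the noise", {
  # one gene 100x brighter than the rest and the only noisy one: plain NNLS
  # chases it, inverse-fitted-value weights suppress it
  set.seed(17)
  n_g <- 30
  S <- matrix(rexp(n_g * 3, 1) + 0.2, n_g, 3,
              dimnames = list(sprintf("g%02d", 1:n_g), c("a", "b", "rare")))
  S[1:4, 1] <- S[1:4, 1] + 8; S[5:8, 2] <- S[5:8, 2] + 8; S[9:12, 3] <- S[9:12, 3] + 8
  S[n_g, ] <- c(300, 290, 5)
  p_star <- c(0.6, 0.37, 0.03)
  err <- replicate(60, {
    b <- as.numeric(S %*% p_star)
    b[n_g] <- b[n_g] * exp(rnorm(1, sd = 0.5))
    p_n <- solve_nnls(S, b)
    p_d <- solve_dampened_wls(S, b, settings = dwls_settings(cv_reps = 10),
                              damping_grid = 0:30, seed = sample.int(1e6, 1))
    c(nnls = abs(p_n[["rare"]] - p_star[3]),
      dwls = abs(p_d[["rare"]] - p_star[3]))
  })
  expect_lt(mean(err["dwls", ]), mean(err["nnls", ]))
})

test_that("ensemble deconvolution fills absent cell types and keeps rows on the simplex", {
  S1 <- random_signature(24, 3, seed = 8)       # ct1..ct3
  S2 <- random_signature(24, 2, seed = 9)       # ct1..ct2 (lacks ct3)
  sig <- function(S, id) structure(
    list(subject_id = id, values = S,
         per_type_markers = stats::setNames(
           rep(list(rownames(S)), ncol(S)), colnames(S)),
         condition_number = 1, g_used = 1L),
    class = "signature_matrix")
  set.seed(10)
  b <- as.numeric(S1 %*% c(0.5, 0.3, 0.2))
  bulk <- bulk_matrix(matrix(b, ncol = 1, dimnames = list(rownames(S1), "s1")))
  cfg <- recide_config(kernel = "nnls")
  ens <- deconvolve_ensemble(list(sig(S1, "subA"), sig(S2, "subB")), bulk, cfg)
  est <- ens$s1$estimates
  expect_equal(dim(est), c(2L, 3L))
  expect_equal(unname(rowSums(est)), c(1, 1), tolerance = 1e-8)
  expect_equal(est["subB", "ct3"], 0)

  # identical signatures give identical rows; single subject is the identity
  ens3 <- deconvolve_ensemble(list(sig(S1, "x"), sig(S1, "y"), sig(S1, "z")),
                              bulk, cfg)
  est3 <- ens3$s1$estimates
  expect_equal(est3["x", ], est3["y", ])
  expect_equal(est3["y", ], est3["z", ])
  one <- deconvolve_ensemble(list(sig(S1, "solo")), bulk, cfg)
  expect_equal(unname(one$s1$estimates[1, ]), unname(solve_nnls(S1, b)),
               tolerance = 1e-12)

  # a subject sharing too few genes is skipped, all skipped is an error
  S3 <- S1[1:5, ]; rownames(S3) <- paste0("zz", 1:5)
  expect_warning(ens4 <- deconvolve_ensemble(
    list(sig(S1, "keep"), sig(S3, "drop")), bulk, cfg), "shared marker genes")
  expect_equal(ens4$s1$subjects, "keep")
  expect_error(suppressWarnings(
    deconvolve_ensemble(list(sig(S3, "drop")), bulk, cfg)), "all subjects skipped")
})
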