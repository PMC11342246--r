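test_that("partition is a conserving split with per-cell normalization", {
  a <- generate_reference(simulation_spec(
    n_subjects = 3, n_cell_types = 4, n_genes = 150, n_markers_per_type = 8,
    cells_per_subject = 120, depth_per_cell = 400,
    abundance_profile = c(ct1 = 0.45, ct2 = 0.3, ct3 = 0.2, ct4 = 0.05),
    seed = 2))
  refs <- partition_by_subject(a, recide_config())
  expect_named(refs, c("s01", "s02", "s03"))
  expect_equal(sum(vapply(refs, function(r) ncol(r$counts), 0L)),
               length(a$cell_ids))
  expect_setequal(unlist(lapply(refs, function(r) colnames(r$counts))),
                  a$cell_ids)
  for (r in refs) {
    cs <- Matrix::colSums(r$normalized)
    nz <- Matrix::colSums(r$counts) > 0
    expect_true(all(abs(cs[nz] - 1e4) < 1e-6))
  }
})

test_that("thin cell types are dropped per subject, thin subjects excluded", {
  atlas <- tiny_atlas()   # s2 has a single T cell
  cfg <- recide_config(min_cells_per_type = 2)
  expect_warning(refs <- partition_by_subject(atlas, cfg), "dropping cell type")
  expect_false("T" %in% refs$s2$cell_types)
  expect_true(all(c("B", "NK") %in% refs$s2$cell_types))

  # a subject reduced below two cell types disappears entirely
  set.seed(1)
  counts <- matrix(rpois(30, 4), nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"), sprintf("k%02d", 1:10)))
  meta <- data.frame(cell_id = colnames(counts),
                     subject_id = rep(c("s1", "s2"), times = c(6, 4)),
                     cell_type = c(rep(c("T", "B"), each = 3), "T", "T", "T", "B"))
  atlas2 <- reference_atlas(counts, meta)
  cfg3 <- recide_config(min_cells_per_type = 3)
  ws <- capture_warnings(refs3 <- partition_by_subject(atlas2, cfg3))
  expect_match(ws, "excluded", all = FALSE)
  expect_named(refs3, "s1")
})

test_that("cosine marker scores match a naive dense re-implementation", {
  set.seed(31)
  for (rep in 1:3) {
    n_g <- sample(20:50, 1); n_c <- sample(30:200, 1)
    types <- sample(c("T", "B", "NK"), n_c, replace = TRUE)
    X <- matrix(rpois(n_g * n_c, 3), n_g, n_c,
                dimnames = list(sprintf("g%02d", 1:n_g), sprintf("c%03d", 1:n_c)))
    ref <- toy_subject(X, types)
    for (mu in c(1, 0.5)) {
      expect_equal(cosg_scores(ref, mu = mu), cosg_oracle(X, types, mu = mu),
                   tolerance = 1e-12)
    }
  }
})

test_that("score extremes behave as the scoring model predicts", {
  # g1: exclusive uniform marker of T; g2: flat everywhere; g3: B-marker
  X <- rbind(g1 = c(5, 5, 5, 0, 0, 0),
             g2 = c(2, 2, 2, 2, 2, 2),
             g3 = c(0, 0, 0, 7, 7, 7),
             g4 = c(4, 0, 4, 1, 0, 1),
             g5 = c(0, 1, 0, 3, 3, 2))
  colnames(X) <- sprintf("c%d", 1:6)
  types <- rep(c("T", "B"), each = 3)
  ref <- toy_subject(X, types)
  sc <- cosg_scores(ref)
  expect_equal(max(sc[, "T"]), sc["g1", "T"])    # perfect indicator wins
  expect_equal(sc["g2", "T"], sc["g2", "B"])     # flat gene is symmetric
  expect_lt(sc["g2", "T"], sc["g1", "T"])        # and strictly sub-maximal
  cat <- score_markers(ref, n_top = 3)
  expect_equal(cat$per_type$T$gene[1], "g1")
  expect_equal(cat$per_type$B$gene[1], "g3")
})

test_that("second fold change follows the top-two-means rule", {
  # per-type means: g1 {T 6, B 2, NK 1}; g2 tie; g3 zero second
  X <- cbind(c(6, 4, 5), c(6, 4, 0), c(2, 4, 0), c(2, 4, 0), c(1, 4, 0), c(1, 4, 0))
  rownames(X) <- c("g1", "g2", "g3"); colnames(X) <- sprintf("c%d", 1:6)
  types <- rep(c("T", "B", "NK"), each = 2)
  ref <- toy_subject(X, types)
  expect_equal(unname(second_fc(ref, "g1")), 3)
  expect_equal(unname(second_fc(ref, "g2")), 1)       # top tie discriminates nothing
  expect_equal(unname(second_fc(ref, "g3")), Inf)     # zero second-highest
  expect_error(second_fc(ref, "nope"), "absent")
})

test_that("fold-change filter keeps exactly the strict exceeders", {
  set.seed(7)
  # 10 genes with engineered per-type means; manual SecondFC bookkeeping
  means_T <- c(9, 6, 4.5, 3.0, 2.4, 2.0, 1.6, 1.5, 1.2, 1.0)
  X <- cbind(matrix(rep(means_T, 2), ncol = 2),          # T cells
             matrix(rep(rep(1, 10), 2), ncol = 2),       # B cells at 1
             matrix(rep(rep(1, 10), 2), ncol = 2))       # NK cells at 1
  rownames(X) <- sprintf("g%02d", 1:10); colnames(X) <- sprintf("c%d", 1:6)
  ref <- toy_subject(X, rep(c("T", "B", "NK"), each = 2))
  cat0 <- score_markers(ref, n_top = 10)
  filt <- filter_markers(cat0, ref, threshold = 1.5)
  # SecondFC for gK is means_T[K] / 1; survivors need > 1.5, strictly:
  expect_setequal(filt$per_type$T$gene,
                  sprintf("g%02d", which(means_T > 1.5)))
  expect_false("g08" %in% filt$per_type$T$gene)   # exactly 1.5 is removed
  expect_true(all(filt$per_type$T$second_fc > 1.5))

  # threshold 1: everything above a tie survives, order preserved
  filt1 <- filter_markers(cat0, ref, threshold = 1)
  expect_setequal(filt1$per_type$T$gene, sprintf("g%02d", which(means_T > 1)))
  expect_error(filter_markers(cat0, ref, threshold = 0.5))
})

test_that("signature construction minimizes the condition number over G", {
  # two orthogonal marker blocks with equal values: kappa = 1 at any G
  X <- rbind(g1 = c(3, 3, 0, 0), g2 = c(3, 3, 0, 0),
             g3 = c(0, 0, 3, 3), g4 = c(0, 0, 3, 3))
  colnames(X) <- sprintf("c%d", 1:4)
  ref <- toy_subject(X, rep(c("T", "B"), each = 2))
  cat0 <- filter_markers(score_markers(ref, n_top = 2), ref, 1.5)
  sig <- build_signature(ref, cat0, g_min = 1, g_max = 2)
  expect_equal(sig$condition_number, 1, tolerance = 1e-12)
  expect_equal(sig$g_used, 1L)                 # tie broken toward smallest G
  expect_equal(dim(sig$values), c(2L, 2L))     # 1 marker per type at G = 1

  # randomized case: chosen G is the argmin of independently computed kappas
  set.seed(12)
  n_c <- 60
  types <- sample(c("T", "B", "NK"), n_c, replace = TRUE)
  X <- matrix(rpois(40 * n_c, 2), 40, n_c,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:n_c)))
  for (ti in 1:3) {  # plant markers so the filter keeps enough genes
    rows <- ((ti - 1) * 8 + 1):(ti * 8)
    X[rows, types == c("T", "B", "NK")[ti]] <-
      X[rows, types == c("T", "B", "NK")[ti]] + 12
  }
  ref <- toy_subject(X, types)
  cat0 <- filter_markers(score_markers(ref, n_top = 8), ref, 1.5)
  sig <- build_signature(ref, cat0, g_min = 2, g_max = 4)
  kappas <- vapply(2:4, function(G) {
    per <- lapply(cat0$per_type, function(df) df$gene[seq_len(min(G, nrow(df)))])
    genes <- sort(unique(unlist(per)))
    m <- sapply(sort(unique(types)), function(t)
      rowMeans(X[genes, types == t, drop = FALSE]))
    kappa(m, exact = TRUE)
  }, numeric(1))
  expect_equal(sig$condition_number, min(kappas), tolerance = 1e-8)
  expect_equal(sig$g_used, (2:4)[which.min(kappas)])
  expect_true(all(vapply(seq_along(kappas), function(i)
    sig$condition_number <= kappas[i] + 1e-8, logical(1))))
})
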