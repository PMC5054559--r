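ref_2type <- function(seed = 1, n_cpgs = 200) {
  generate_reference_profiles(2, n_cpgs, seed = seed, n_markers_per_type = 50)
}

test_that("discriminating-CpG selection ranks by between-type contrast", {
  ref <- ref_2type()
  sel <- select_discriminating_cpgs(ref, 50)
  expect_lte(length(sel), 100)
  d <- abs(ref[1, ] - ref[2, ])
  top50 <- names(sort(d, decreasing = TRUE))[1:50]
  expect_true(all(top50 %in% sel))
  # planted markers are recovered (3+ types: each type's own markers dominate
  # its contrast; with 2 types the contrast is symmetric and cannot attribute
  # a marker to a type)
  ref3 <- generate_reference_profiles(3, 300, seed = 7, n_markers_per_type = 40)
  sel3 <- select_discriminating_cpgs(ref3, 40)
  markers3 <- unlist(attr(ref3, "marker_cpgs"))
  expect_true(all(markers3 %in% sel3))
  expect_error(select_discriminating_cpgs(ref, 500), "exceeds")
  flat <- matrix(0.5, 2, 10, dimnames = list(c("a", "b"), paste0("cg", 1:10)))
  expect_error(select_discriminating_cpgs(flat, 5), "identical")
})

test_that("a pure cell type is recovered as a vertex solution", {
  ref <- ref_2type()
  bm <- rbind(ref[1, , drop = FALSE], ref[2, , drop = FALSE])
  rownames(bm) <- c("s1", "s2")
  pr <- estimate_cell_proportions(bm, ref)
  expect_equal(pr$celltype1, c(1, 0), tolerance = 1e-6)
  expect_equal(pr$celltype2, c(0, 1), tolerance = 1e-6)
  expect_lt(max(pr$residual), 1e-8)
})

test_that("an equal noiseless mixture matches the simplex-grid oracle", {
  ref <- ref_2type()
  y <- 0.5 * ref[1, ] + 0.5 * ref[2, ]
  bm <- matrix(y, 1, dimnames = list("mix", colnames(ref)))
  pr <- estimate_cell_proportions(bm, ref)
  expect_equal(c(pr$celltype1, pr$celltype2), c(0.5, 0.5), tolerance = 1e-6)

  cpgs <- select_discriminating_cpgs(ref, 50)
  W <- ref[, cpgs]
  grid <- simplex_grid(2, 0.01)
  rss <- colSums((t(grid %*% W) - y[cpgs])^2)
  best <- grid[which.min(rss), ]
  expect_equal(unname(best), c(0.5, 0.5))
})

test_that("the solver dominates a 0.01-step simplex grid on 3-type problems", {
  set.seed(17)
  K <- 3
  ref <- generate_reference_profiles(K, 60, seed = 9, n_markers_per_type = 15)
  cpgs <- colnames(ref)
  W <- ref
  grid <- simplex_grid(K, 0.01)
  fitted_grid <- grid %*% W
  for (r in 1:5) {
    pi_true <- as.numeric(rdirichlet_test(c(2, 1, 1)))
    y <- drop(pi_true %*% W) + rnorm(ncol(W), 0, 0.03)
    y <- pmin(pmax(y, 0), 1)
    bm <- matrix(y, 1, dimnames = list("s", cpgs))
    est <- estimate_cell_proportions(bm, ref, cpg_ids = cpgs)
    ours <- sum((drop(as.numeric(est[1, 2:4]) %*% W) - y)^2)
    grid_best <- min(rowSums(sweep(fitted_grid, 2, y)^2))
    expect_lte(ours, grid_best + 1e-9)
  }
})

test_that("estimates are invariant to cell-type and CpG order", {
  ref <- generate_reference_profiles(3, 90, seed = 13, n_markers_per_type = 20)
  set.seed(19)
  y <- drop(c(0.5, 0.3, 0.2) %*% ref) + rnorm(90, 0, 0.02)
  bm <- matrix(pmin(pmax(y, 0), 1), 1, dimnames = list("s", colnames(ref)))
  base <- estimate_cell_proportions(bm, ref, cpg_ids = colnames(ref))
  perm_types <- ref[c(3, 1, 2), ]
  out1 <- estimate_cell_proportions(bm, perm_types, cpg_ids = colnames(ref))
  expect_equal(out1$celltype1, base$celltype1, tolerance = 1e-8)
  expect_equal(out1$celltype3, base$celltype3, tolerance = 1e-8)
  perm_cpgs <- sample(colnames(ref))
  out2 <- estimate_cell_proportions(bm[, perm_cpgs, drop = FALSE],
                                    ref[, perm_cpgs], cpg_ids = perm_cpgs)
  expect_equal(out2$celltype2, base$celltype2, tolerance = 1e-8)
})

test_that("duplicating every reference CpG leaves proportions unchanged", {
  ref <- ref_2type(seed = 23, n_cpgs = 120)
  set.seed(29)
  y <- drop(c(0.7, 0.3) %*% ref) + rnorm(120, 0, 0.02)
  y <- pmin(pmax(y, 0), 1)
  bm <- matrix(y, 1, dimnames = list("s", colnames(ref)))
  base <- estimate_cell_proportions(bm, ref, cpg_ids = colnames(ref))
  dup_ids <- c(colnames(ref), paste0(colnames(ref), "_dup"))
  ref_dup <- cbind(ref, ref)
  colnames(ref_dup) <- dup_ids
  bm_dup <- cbind(bm, bm)
  colnames(bm_dup) <- dup_ids
  dup <- estimate_cell_proportions(bm_dup, ref_dup, cpg_ids = dup_ids)
  expect_equal(dup$celltype1, base$celltype1, tolerance = 1e-8)
})

test_that("noisy 6-type mixtures are recovered within 0.05 mean error", {
  ref <- generate_reference_profiles(6, 600, seed = 31)
  set.seed(37)
  n <- 40
  truth <- t(replicate(n, as.numeric(rdirichlet_test(c(6, 3, 2, 2, 1, 1)))))
  bm <- truth %*% ref + matrix(rnorm(n * 600, 0, 0.02), n)
  bm <- pmin(pmax(bm, 0), 1)
  dimnames(bm) <- list(sprintf("s%02d", 1:n), colnames(ref))
  est <- estimate_cell_proportions(bm, ref)
  mae <- mean(abs(as.matrix(est[, 2:7]) - truth))
  expect_lte(mae, 0.05)
  expect_true(all(as.matrix(est[, 2:7]) >= 0))
  expect_true(all(rowSums(as.matrix(est[, 2:7])) <= 1 + 1e-8))
})

test_that("deconvolution validates its inputs", {
  ref <- ref_2type()
  bm <- matrix(0.5, 1, 1, dimnames = list("s", "cg00000001"))
  expect_error(estimate_cell_proportions(bm, ref, cpg_ids = "cg00000001"),
               "fewer usable reference CpGs")
  expect_error(estimate_cell_proportions(bm, ref[1, , drop = FALSE]),
               "at least 2")
})
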