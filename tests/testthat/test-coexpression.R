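# expression with two clean planted blocks plus background genes
block_expr <- function(seed = 1, n = 60, sizes = c(12, 10), n_noise = 8, rho = 0.9) {
  set.seed(seed)
  mats <- lapply(seq_along(sizes), function(m) {
    f <- rnorm(n)
    t(sapply(seq_len(sizes[m]), function(i) sqrt(rho) * f + sqrt(1 - rho) * rnorm(n)))
  })
  out <- rbind(do.call(rbind, mats), matrix(rnorm(n_noise * n), n_noise, n))
  rownames(out) <- paste0("g", seq_len(nrow(out)))
  out
}

test_that("adjacency implements the soft-threshold formulas", {
  x <- c(1, -1, 1, -1)
  y <- x + sqrt(3) * c(1, 1, -1, -1)       # cor(x, y) = 0.5 exactly
  expr <- rbind(a = x, b = y, c = -x)      # cor(a, c) = -1
  A2 <- adjacency(expr, network_params(beta = 2))
  expect_equal(A2["a", "b"], 0.25, tolerance = 1e-12)   # 0.5^2
  expect_equal(A2["a", "c"], 1, tolerance = 1e-12)      # |-1|^2
  As <- adjacency(expr, network_params(beta = 2, signed = TRUE))
  expect_equal(As["a", "b"], ((1 + 0.5) / 2)^2, tolerance = 1e-12)
  expect_equal(As["a", "c"], 0, tolerance = 1e-12)
  # symmetry and unit diagonal on random input
  R <- adjacency(block_expr(3), network_params())
  expect_true(isSymmetric(unname(R)))
  expect_true(all(diag(R) == 1))
  expect_true(all(R >= 0 & R <= 1 + 1e-12))
  expect_error(adjacency(rbind(a = rep(1, 4), b = rnorm(4)), network_params()), "a")
})

test_that("TOM matches hand computation and the triple-loop oracle", {
  # 3-node toy: all off-diagonal adjacencies 0.5
  A3 <- matrix(0.5, 3, 3); diag(A3) <- 1
  T3 <- topological_overlap(A3)
  expect_equal(T3[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5), tolerance = 1e-12)
  # zero adjacency -> zero overlap
  expect_true(all(topological_overlap(diag(4))[upper.tri(diag(4))] == 0))
  # random case against the naive O(p^3) oracle
  set.seed(8)
  A <- abs(cor(matrix(rnorm(200), 20, 10)))
  diag(A) <- 1
  TOM <- topological_overlap(A)
  expect_equal(TOM, oracle_tom(A), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(TOM >= 0 & TOM <= 1 + 1e-12))
  expect_true(isSymmetric(unname(TOM)))
})

test_that("static tree cut recovers separated blocks and orders module ids", {
  # two perfectly separated blocks in TOM space
  T2 <- diag(10) * 0 + 0.0
  T2[1:6, 1:6] <- 0.9
  T2[7:10, 7:10] <- 0.9
  diag(T2) <- 1
  rownames(T2) <- colnames(T2) <- paste0("g", 1:10)
  mods <- cluster_modules(T2, network_params(cut_height = 0.5, min_module_size = 2))
  expect_identical(unname(as.vector(mods)), c(rep(1L, 6), rep(2L, 4)))  # sized-ordered
  expect_equal(sum(mods == 0), 0)
  # min size above n pushes everything to the gray module
  all_gray <- cluster_modules(T2, network_params(cut_height = 0.5, min_module_size = 11))
  expect_true(all(all_gray == 0))
  # ids contiguous and size-ordered on correlated random data
  expr <- block_expr(4)
  TOM <- topological_overlap(adjacency(expr, network_params(beta = 6)))
  m <- cluster_modules(TOM, network_params(beta = 6, cut_height = 0.9, min_module_size = 4))
  ids <- sort(unique(m[m > 0]))
  if (length(ids)) {
    expect_identical(ids, seq_along(ids))
    sz <- table(m[m > 0])
    expect_true(all(diff(as.vector(sz)) <= 0))
  }
})

test_that("module detection is equivariant to feature permutation", {
  expr <- block_expr(6)
  params <- network_params(beta = 6, cut_height = 0.95, min_module_size = 4)
  m1 <- cluster_modules(topological_overlap(adjacency(expr, params)), params)
  set.seed(2)
  perm <- sample(nrow(expr))
  m2 <- cluster_modules(topological_overlap(adjacency(expr[perm, ], params)), params)
  # same partition, feature-by-feature (ids may only renumber by size order)
  expect_identical(unname(m2[names(m1)] == 0), unname(m1 == 0))
  tab <- table(m1, m2[names(m1)])
  expect_true(all(colSums(tab > 0) <= 1) && all(rowSums(tab > 0) <= 1))
})

test_that("scale-free fit statistic and power selection behave", {
  # exact power-law degree sequence: freq(k) proportional to k^-2
  k <- rep(1:10 * 10, times = round(4000 / (1:10)^2))
  fit <- grcca:::scale_free_fit(k, n_bins = 10)
  expect_gt(fit$rsq, 0.99)
  expect_lt(fit$slope, 0)
  # candidate set of size one returns that power
  expr <- block_expr(2)
  expect_equal(pick_soft_threshold(expr, candidate_powers = 4)$power, 4)
  # all-equal correlations: degenerate fit must not crash
  dup <- outer(rep(1, 6), rnorm(20)) + 1e-8 * matrix(rnorm(120), 6, 20)
  expect_no_error(pick_soft_threshold(dup, candidate_powers = c(1, 2)))
  # higher powers improve scale-free fit on modular data
  sel <- pick_soft_threshold(expr, candidate_powers = c(1, 3, 6, 9))
  expect_true(sel$power %in% c(1, 3, 6, 9))
  expect_equal(nrow(sel$table), 4)
})

test_that("module eigengenes match an SVD reference and the sign convention", {
  expr <- block_expr(10)
  assignment <- c(rep(1L, 12), rep(2L, 10), rep(0L, 8))
  names(assignment) <- rownames(expr)
  me <- module_eigengene(expr, assignment)
  expect_identical(rownames(me), c("ME1", "ME2"))
  # independent reference: PC1 of the standardized submatrix via prcomp
  sub <- expr[assignment == 1, ]
  Z <- t(scale(t(sub)))
  ref <- prcomp(t(Z), center = FALSE)$x[, 1]
  ref <- ref / sqrt(sum(ref^2))
  if (cor(ref, colMeans(Z)) < 0) ref <- -ref
  expect_equal(unname(me["ME1", ]), unname(ref), tolerance = 1e-10)
  # sign convention: positive correlation with the module mean
  expect_gte(cor(me["ME1", ], colMeans(expr[assignment == 1, ])), 0)
  expect_gte(cor(me["ME2", ], colMeans(expr[assignment == 2, ])), 0)
  # module of identical features returns the standardized feature
  same <- rbind(a = expr[1, ], b = expr[1, ])
  me1 <- module_eigengene(same, c(a = 1L, b = 1L))
  expect_equal(abs(cor(me1["ME1", ], expr[1, ])), 1, tolerance = 1e-10)
})
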