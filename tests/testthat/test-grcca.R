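test_that("group metric reduces, decomposes and inverts as projection algebra", {
  set.seed(1)
  w <- rnorm(12)
  # singleton groups: B = I, so R w = mu w
  m_single <- group_metric(1:12, lambda = 0.9, mu = 0.1)
  expect_equal(apply_metric(m_single, w), 0.1 * w, tolerance = 1e-12)
  # one global group: w' R w = lambda * sum((w - wbar)^2) + mu * n * wbar^2
  m_global <- group_metric(rep(1, 12), lambda = 0.9, mu = 0.1)
  qf <- sum(w * apply_metric(m_global, w))
  expect_equal(qf, 0.9 * sum((w - mean(w))^2) + 0.1 * 12 * mean(w)^2,
               tolerance = 1e-12)
  # R^{-1/2} R^{-1/2} R = I on random groupings
  for (s in 1:5) {
    set.seed(s)
    g <- sample(1:4, 12, replace = TRUE)
    met <- group_metric(g, lambda = 1 - 1 / 12, mu = 0.1)
    out <- apply_metric(met, apply_metric(met, apply_metric(met, w, 1), -0.5), -0.5)
    expect_equal(out, w, tolerance = 1e-10)
  }
  expect_error(group_metric(1:3, lambda = 0, mu = 0.1), "lambda")
})

test_that("the identity problem attains latent correlation near one", {
  set.seed(3)
  Y <- matrix(rnorm(120), 40, 3)
  fit <- fit_grcca(Y, Y, groups = 1:3, f = 1, lambda = 1e-6, mu = 1e-6)
  expect_gt(fit$latent_correlation, 1 - 1e-6)
})

test_that("fit matches the dense penalized eigenproblem oracle at f = 1", {
  for (s in 1:20) {
    inst <- random_cca_instance(s, n = sample(30:60, 1), p = sample(10:50, 1),
                                q = sample(2:5, 1))
    lambda <- 1 - 1 / ncol(inst$X)
    fit <- fit_grcca(inst$X, inst$Y, inst$groups, f = 1, lambda = lambda, mu = 0.1)
    ref <- oracle_grcca(inst$X, inst$Y, inst$groups, lambda = lambda, mu = 0.1)
    expect_equal(abs(fit$latent_correlation), ref$correlation, tolerance = 1e-8)
    expect_gt(collinearity(fit$w_x, ref$w_x), 1 - 1e-6)
    expect_gt(collinearity(fit$w_y, ref$w_y), 1 - 1e-6)
  }
})

test_that("all-singleton grouping reduces to ridge-metric CCA", {
  for (s in 1:10) {
    inst <- random_cca_instance(100 + s, n = 50, p = 30, q = 3)
    fit <- fit_grcca(inst$X, inst$Y, groups = seq_len(30), f = 1,
                     lambda = 0.97, mu = 0.1)
    # oracle with every feature its own group has R = mu * I exactly
    ref <- oracle_grcca(inst$X, inst$Y, seq_len(30), lambda = 0.5, mu = 0.1)
    expect_equal(abs(fit$latent_correlation), ref$correlation, tolerance = 1e-8)
  }
})

test_that("the fit is invariant to positive rescaling of an X column", {
  inst <- random_cca_instance(77)
  X2 <- inst$X
  X2[, 5] <- X2[, 5] * 37.5
  f1 <- fit_grcca(inst$X, inst$Y, inst$groups, f = 0.8)
  f2 <- fit_grcca(X2, inst$Y, inst$groups, f = 0.8)
  expect_equal(f1$latent_correlation, f2$latent_correlation, tolerance = 1e-10)
  expect_equal(f1$w_x, f2$w_x, tolerance = 1e-8)
})

test_that("permutation p-values obey the add-one convention and its floor", {
  set.seed(5)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10)
  Y <- cbind(drv = rowMeans(X[, 1:4]) + 0.1 * rnorm(n), oth = rnorm(n))
  pt <- permutation_test(X, Y, groups = rep(1:2, each = 5), f = 1,
                         n_perm = 1000, seed = 2)
  # observed beats every null: p = 1/1001, i.e. 0.001 at three decimals
  expect_equal(pt$perm_p, 1 / 1001)
  expect_equal(round(pt$perm_p, 3), 0.001)
  expect_length(pt$null, 1000)
  # p is always within (0, 1] and reproducible under the same seed
  pt2 <- permutation_test(X, Y, groups = rep(1:2, each = 5), f = 1,
                          n_perm = 1000, seed = 2)
  expect_identical(pt$null, pt2$null)
})

test_that("variance-fraction selection follows the stated tie-break rules", {
  set.seed(6)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10)
  Y <- cbind(drv = rowMeans(X) + 0.05 * rnorm(n))
  sel <- optimize_variance_fraction(X, Y, groups = rep(1, 10),
                                    grid = c(0.5, 1), n_perm = 99, seed = 3)
  expect_equal(nrow(sel$table), 2)
  best_p <- min(sel$table$perm_p)
  cand <- sel$table[sel$table$perm_p == best_p, ]
  cand <- cand[order(-cand$correlation, cand$f), ]
  expect_equal(sel$chosen_f, cand$f[1])
  # grid of size one returns that fraction
  one <- optimize_variance_fraction(X, Y, groups = rep(1, 10), grid = 0.7,
                                    n_perm = 19, seed = 1)
  expect_equal(one$chosen_f, 0.7)
})

test_that("bootstrap Z-scores flag a planted covariate and align signs", {
  set.seed(8)
  n <- 80
  X <- matrix(rnorm(n * 15), n, 15)
  Y <- cbind(drv = rowMeans(X[, 1:5]) + 0.3 * rnorm(n), oth = rnorm(n))
  groups <- rep(1:3, each = 5)
  fit <- fit_grcca(X, Y, groups, f = 1)
  fit <- bootstrap_z(X, Y, groups, fit, n_boot = 200, seed = 4)
  expect_gte(abs(fit$Z_y[["drv"]]), 2)
  expect_gt(abs(fit$Z_y[["drv"]]), abs(fit$Z_y[["oth"]]))
  expect_true(all(is.finite(fit$Z_x)))
  expect_equal(fit$n_boot_used + fit$n_boot_degenerate, 200)
  # negating Y flips nothing observable: the sign convention re-orients the
  # fit and the bootstrap aligns to it
  fit2 <- fit_grcca(X, -Y, groups, f = 1)
  fit2 <- bootstrap_z(X, -Y, groups, fit2, n_boot = 200, seed = 4)
  expect_equal(unname(fit2$Z_y), unname(fit$Z_y), tolerance = 1e-8)
  expect_equal(fit2$latent_correlation, fit$latent_correlation, tolerance = 1e-12)
})

test_that("structure correlations match a per-column oracle and flag constants", {
  inst <- random_cca_instance(12, n = 30, p = 5, q = 3)
  fit <- fit_grcca(inst$X, inst$Y, groups = rep(1, 5), f = 1)
  sc <- structure_correlations(inst$X, inst$Y, fit)
  ref_x <- vapply(1:5, function(j) cor(inst$X[, j], fit$LV_x), numeric(1))
  ref_y <- vapply(1:3, function(j) cor(inst$Y[, j], fit$LV_y), numeric(1))
  expect_equal(sc$r_x$r, ref_x, tolerance = 1e-12)
  expect_equal(sc$r_y$r, ref_y, tolerance = 1e-12)
  # a feature proportional to LV_x correlates at exactly 1
  Xp <- cbind(inst$X, prop = 2 * fit$LV_x + 3)
  expect_equal(structure_correlations(Xp, inst$Y, fit)$r_x$r[6], 1, tolerance = 1e-12)
  # constant column flagged as NA
  Xc <- cbind(inst$X, const = 1)
  scc <- structure_correlations(Xc, inst$Y, fit)
  expect_true(scc$r_x$constant[6])
  expect_true(is.na(scc$r_x$r[6]))
})

test_that("dual significance criteria apply inclusive Z and strict FDR bounds", {
  fake <- structure(list(
    r_x = data.frame(feature_id = paste0("g", 1:5),
                     r = c(0.9, -0.8, 0.7, 0.6, 0.5),
                     p = rep(0.001, 5),
                     fdr = c(0.01, 0.05, 0.049, 0.01, 0.2),
                     stringsAsFactors = FALSE),
    Z_x = c(g1 = 2.0, g2 = 5, g3 = 1.99, g4 = -2.5, g5 = 4)),
    class = "grcca_fit")
  out <- significant_features(fake, z_thresh = 2, fdr = 0.05)
  # g1: |Z| = 2 exactly -> included; g2: FDR = 0.05 exactly -> excluded;
  # g3: |Z| below threshold; g5: FDR above; g4: both satisfied
  expect_identical(out$feature_id[out$significant], c("g1", "g4"))
  expect_identical(out$feature_id, paste0("g", 1:5))  # sorted by |r| desc here
})
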