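#' Group-structured regularization metric
#'
#' The X-side normalization metric for group-regularized CCA:
#' \deqn{R = \lambda (I - B) + \mu B}
#' where \code{B} is the block-averaging operator that replaces each
#' feature's weight by its group's mean. \code{I - B} and \code{B} are
#' orthogonal projections, so the quadratic form splits into
#' \code{lambda * sum_i (w_i - wbar_{g(i)})^2 + mu * sum_g n_g wbar_g^2}:
#' within-group deviations are shrunk heavily (\code{lambda} close to 1)
#' while group mean weights are shrunk lightly (\code{mu} small), letting
#' whole co-expression modules move together. The projection structure
#' gives the analytic inverse square root
#' \code{R^{-1/2} = lambda^{-1/2}(I - B) + mu^{-1/2} B}.
#'
#' The metric is held as an operator (group index + penalties), never as a
#' dense p x p matrix.
#'
#' @param groups group id per feature (any labels; group 0/"gray" is a
#'   group of its own).
#' @param lambda feature-level penalty, in (0, 1]; the convention
#'   \code{1 - 1/p} ties it to the feature count.
#' @param mu group-level penalty, > 0 (default 0.1).
#' @return object of class \code{"group_metric"}.
#' @export
group_metric <- function(groups, lambda, mu = 0.1) {
  stop_if(lambda <= 0, "lambda must be positive")
  stop_if(mu <= 0, "mu must be positive")
  g <- as.integer(factor(groups))
  stop_if(anyNA(g), "groups must not contain NA")
  structure(list(groups = g, sizes = tabulate(g), lambda = lambda, mu = mu),
            class = "group_metric")
}

# B w: replace each entry by its group mean
group_average <- function(w, metric) {
  means <- rowsum(w, metric$groups) / metric$sizes
  means[metric$groups]
}

#' Apply the metric or its inverse square root to a weight vector
#'
#' @param metric a \code{group_metric}.
#' @param w numeric vector over features.
#' @param power one of 1 (apply R), -0.5 (apply R^{-1/2}), 0.5, -1.
#' @return transformed vector.
#' @export
apply_metric <- function(metric, w, power = 1) {
  bw <- group_average(w, metric)
  metric$lambda^power * (w - bw) + metric$mu^power * bw
}

# X %*% R^{power} for samples-x-features X, exploiting symmetry of R
apply_metric_columns <- function(metric, X, power = -0.5) {
  gs <- t(rowsum(t(X), metric$groups) / metric$sizes)  # n x K group means
  XB <- gs[, metric$groups, drop = FALSE]
  metric$lambda^power * (X - XB) + metric$mu^power * XB
}

# Shared precomputation for fitting, permutation and model selection:
# standardizes X and Y, transforms X by R^{-1/2}, takes its SVD, and
# whitens Y. Everything downstream is cheap linear algebra in the reduced
# space.
grcca_design <- function(X, Y, groups, lambda = NULL, mu = 0.1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stop_if(nrow(X) != nrow(Y), "X and Y must have aligned rows")
  stop_if(length(groups) != ncol(X), "one group id per X column required")
  p <- ncol(X)
  if (is.null(lambda)) lambda <- 1 - 1 / p
  metric <- group_metric(groups, lambda = lambda, mu = mu)
  Xs <- standardize_columns(X)
  Ys <- standardize_columns(Y)
  n <- nrow(Xs)
  Xt <- apply_metric_columns(metric, Xs, power = -0.5)
  sv <- svd(Xt)
  pos <- sv$d > max(n, p) * .Machine$double.eps * sv$d[1]
  d <- sv$d[pos]
  var_share <- cumsum(d^2) / sum(d^2)
  Cyy <- crossprod(Ys) / (n - 1)
  ey <- eigen(Cyy, symmetric = TRUE)
  if (any(ey$values < ncol(Y) * .Machine$double.eps * max(ey$values))) {
    stop("Y is rank deficient after standardization", call. = FALSE)
  }
  Cyy_invhalf <- ey$vectors %*% (t(ey$vectors) / sqrt(ey$values))
  list(Xs = Xs, Ys = Ys, n = n, p = p, q = ncol(Y), metric = metric,
       U = sv$u[, pos, drop = FALSE], d = d, V = sv$v[, pos, drop = FALSE],
       var_share = var_share, Yw = Ys %*% Cyy_invhalf,
       Cyy_invhalf = Cyy_invhalf,
       feature_ids = colnames(X) %||% paste0("x", seq_len(p)),
       covariate_ids = colnames(Y) %||% paste0("y", seq_len(ncol(Y))))
}

# number of leading PCs with cumulative variance share >= f
components_for_fraction <- function(design, f) {
  stop_if(f <= 0 || f > 1, "variance fraction must lie in (0, 1]")
  match(TRUE, design$var_share >= f - 1e-12)
}

# Solve the reduced problem at a given number of components. Returns
# weights in the reduced space plus the latent correlation; shared by the
# point estimate and the permutation path (which passes permuted Yw).
solve_reduced <- function(design, k, Yw = design$Yw) {
  S <- design$U[, seq_len(k), drop = FALSE] * rep(design$d[seq_len(k)], each = design$n)
  M <- crossprod(S, Yw) / (design$n - 1)
  sv <- svd(M, nu = 1, nv = 1)
  alpha <- sv$u[, 1]
  b <- sv$v[, 1]
  lvx <- S %*% alpha
  lvy <- Yw %*% b
  list(alpha = alpha, b = b, sigma = sv$d[1],
       lvx = as.vector(lvx), lvy = as.vector(lvy),
       correlation = stats::cor(as.vector(lvx), as.vector(lvy)))
}

#' Fit group-regularized canonical correlation (first pair)
#'
#' Finds weight vectors \code{w_x}, \code{w_y} maximizing the covariance
#' \code{w_x' C_xy w_y} subject to \code{w_x' R w_x = 1} and
#' \code{w_y' C_yy w_y = 1}, where \code{R} is the group metric of
#' [group_metric()] — i.e. canonical correlation with the X-side
#' normalization replaced by the group-structured ridge metric. The
#' algorithm: (1) transform \code{X} by \code{R^{-1/2}}; (2) PCA of the
#' transformed matrix, retaining the smallest leading component set whose
#' cumulative variance share reaches \code{f}; (3) solve the reduced
#' problem against whitened \code{Y} by SVD; (4) map the X weights back
#' through \code{R^{-1/2}}; (5) fix the overall sign so the covariate with
#' the largest |structure correlation| is positive.
#'
#' Only the first canonical pair is estimated. Structure correlations
#' (per-column Pearson correlation with the opposite-side latent variable
#' is *not* used; each column is correlated with its own side's latent
#' variable) are attached with two-sided t-test p-values and BH FDR,
#' computed separately over features and covariates.
#'
#' @param X samples x features matrix (columns are standardized
#'   internally).
#' @param Y samples x covariates matrix (e.g. diagnosis indicator columns
#'   plus MCA dimensions); standardized internally; must be full column
#'   rank.
#' @param groups group id per feature (co-expression module assignment;
#'   module 0 is a group of its own).
#' @param f variance fraction of the transformed X to retain, in (0, 1].
#' @param lambda feature-level penalty; default \code{1 - 1/ncol(X)}.
#' @param mu group-level penalty (default 0.1).
#' @param design optional precomputed [grcca_design()] (internal reuse).
#' @return object of class \code{"grcca_fit"}: \code{w_x}, \code{w_y},
#'   \code{LV_x}, \code{LV_y}, \code{latent_correlation}, \code{r_x} and
#'   \code{r_y} data.frames (id, r, p, fdr), \code{chosen_f},
#'   \code{k_components}, penalties.
#' @export
fit_grcca <- function(X, Y, groups, f = 1, lambda = NULL, mu = 0.1,
                      design = NULL) {
  if (is.null(design)) design <- grcca_design(X, Y, groups, lambda, mu)
  k <- components_for_fraction(design, f)
  stop_if(is.na(k) || k < 1, "variance fraction retains no component")
  sol <- solve_reduced(design, k)
  a <- design$V[, seq_len(k), drop = FALSE] %*% sol$alpha
  w_x <- apply_metric(design$metric, as.vector(a), power = -0.5)
  w_y <- as.vector(design$Cyy_invhalf %*% sol$b)
  lvx <- as.vector(design$Xs %*% w_x)
  lvy <- as.vector(design$Ys %*% w_y)
  r_y <- as.vector(stats::cor(design$Ys, lvy))
  if (r_y[which.max(abs(r_y))] < 0) {       # sign convention
    w_x <- -w_x; w_y <- -w_y; lvx <- -lvx; lvy <- -lvy; r_y <- -r_y
  }
  r_x <- as.vector(stats::cor(design$Xs, lvx))
  n <- design$n
  fit <- structure(list(
    w_x = stats::setNames(w_x, design$feature_ids),
    w_y = stats::setNames(w_y, design$covariate_ids),
    LV_x = lvx, LV_y = lvy,
    latent_correlation = stats::cor(lvx, lvy),
    r_x = data.frame(feature_id = design$feature_ids, r = r_x,
                     p = cor_pvalue(r_x, n), fdr = bh_adjust(cor_pvalue(r_x, n)),
                     stringsAsFactors = FALSE),
    r_y = data.frame(covariate_id = design$covariate_ids, r = r_y,
                     p = cor_pvalue(r_y, n), fdr = bh_adjust(cor_pvalue(r_y, n)),
                     stringsAsFactors = FALSE),
    chosen_f = f, k_components = k,
    lambda = design$metric$lambda, mu = design$metric$mu, n = n),
    class = "grcca_fit")
  fit
}

#' Permutation test of the latent correlation
#'
#' Permutes the rows of Y uniformly at random \code{n_perm} times, refits
#' at the same variance fraction, and reports
#' \code{perm_p = (1 + #\{null >= observed\}) / (1 + n_perm)} — so with
#' 1000 permutations the smallest attainable p-value is 1/1001, which
#' rounds to 0.001. Row permutation of Y (rather than X) is equivalent
#' under the null of no X-Y association and leaves the X-side PCA
#' untouched, so each permutation costs only a small SVD in the reduced
#' space.
#'
#' @inheritParams fit_grcca
#' @param n_perm number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @return list: \code{perm_p}, \code{observed} (latent correlation),
#'   \code{null} (numeric vector of null correlations), \code{f}.
#' @export
permutation_test <- function(X, Y, groups, f = 1, lambda = NULL, mu = 0.1,
                             n_perm = 1000, seed = 1, design = NULL) {
  stop_if(n_perm < 1, "n_perm must be >= 1")
  if (is.null(design)) design <- grcca_design(X, Y, groups, lambda, mu)
  k <- components_for_fraction(design, f)
  stop_if(is.na(k) || k < 1, "variance fraction retains no component")
  observed <- solve_reduced(design, k)$correlation
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(design$n)
    solve_reduced(design, k, Yw = design$Yw[perm, , drop = FALSE])$correlation
  }, numeric(1))
  list(perm_p = (1 + sum(null >= observed)) / (1 + n_perm),
       observed = observed, null = null, f = f)
}

#' Select the retained-variance fraction by permutation
#'
#' Runs [permutation_test()] at every fraction in \code{grid} and selects
#' the fraction with the smallest permutation p-value; ties are broken by
#' the larger observed latent correlation, then by the smaller fraction
#' (the more parsimonious model).
#'
#' @inheritParams permutation_test
#' @param grid candidate variance fractions (default 0.1 to 1 by 0.1).
#' @return list: \code{chosen_f}, \code{table} (f, k_components,
#'   correlation, perm_p).
#' @export
optimize_variance_fraction <- function(X, Y, groups, grid = seq(0.1, 1, by = 0.1),
                                       lambda = NULL, mu = 0.1,
                                       n_perm = 1000, seed = 1, design = NULL) {
  stop_if(length(grid) == 0, "grid must be non-empty")
  if (is.null(design)) design <- grcca_design(X, Y, groups, lambda, mu)
  rows <- lapply(seq_along(grid), function(i) {
    pt <- permutation_test(design = design, f = grid[i], n_perm = n_perm,
                           seed = seed + i - 1, X = NULL, Y = NULL, groups = NULL)
    data.frame(f = grid[i], k_components = components_for_fraction(design, grid[i]),
               correlation = pt$observed, perm_p = pt$perm_p)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$perm_p, -tab$correlation, tab$f)
  list(chosen_f = tab$f[ord[1]], table = tab)
}

#' Bootstrap Z-scores for GRCCA weights
#'
#' Resamples samples with replacement \code{n_boot} times, refits at the
#' fixed hyperparameters (same variance fraction, lambda, mu), aligns each
#' replicate's sign with the point estimate via the sign of
#' \code{cor(LV_y_boot, LV_y)} on the resampled rows, and reports
#' \code{Z = weight / sd(bootstrap weights)}. Replicates in which the fit
#' is degenerate (a constant resampled column, or a zero-variance latent
#' variable) are dropped and counted; more than 10% degenerate replicates
#' is an error. A bootstrap standard deviation of zero yields an infinite
#' Z, reported as \code{+/- z_cap} with the \code{capped} flag set.
#'
#' @inheritParams fit_grcca
#' @param fit the point-estimate \code{grcca_fit}.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed.
#' @param z_cap sentinel magnitude replacing infinite Z-scores.
#' @return the fit, augmented with \code{Z_x}, \code{Z_y}, \code{Z_capped}
#'   (logical list over x and y), \code{n_boot_used},
#'   \code{n_boot_degenerate}.
#' @export
bootstrap_z <- function(X, Y, groups, fit, n_boot = 1000, seed = 1,
                        lambda = NULL, mu = 0.1, z_cap = 1e6) {
  stopifnot(inherits(fit, "grcca_fit"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  set.seed(seed)
  wx_boot <- matrix(NA_real_, ncol(X), n_boot)
  wy_boot <- matrix(NA_real_, ncol(Y), n_boot)
  degenerate <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    bf <- tryCatch({
      d <- grcca_design(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                        groups, lambda, mu)
      fit_grcca(design = d, f = fit$chosen_f, X = NULL, Y = NULL, groups = NULL)
    }, error = function(e) NULL)
    if (is.null(bf) || !is.finite(bf$latent_correlation)) {
      degenerate <- degenerate + 1L
      next
    }
    s <- stats::cor(bf$LV_y, fit$LV_y[idx])
    s <- if (is.na(s) || s == 0) 1 else sign(s)
    wx_boot[, b] <- s * bf$w_x
    wy_boot[, b] <- s * bf$w_y
  }
  if (degenerate > 0.1 * n_boot) {
    stop("more than 10% degenerate bootstrap replicates (",
         degenerate, "/", n_boot, ")", call. = FALSE)
  }
  cap_z <- function(w, boot) {
    sdv <- apply(boot, 1, stats::sd, na.rm = TRUE)
    z <- w / sdv
    capped <- !is.finite(z)
    z[capped] <- sign(w[capped]) * z_cap
    z[capped & w == 0] <- 0
    list(z = z, capped = capped)
  }
  zx <- cap_z(fit$w_x, wx_boot)
  zy <- cap_z(fit$w_y, wy_boot)
  fit$Z_x <- stats::setNames(zx$z, names(fit$w_x))
  fit$Z_y <- stats::setNames(zy$z, names(fit$w_y))
  fit$Z_capped <- list(x = zx$capped, y = zy$capped)
  fit$n_boot_used <- n_boot - degenerate
  fit$n_boot_degenerate <- degenerate
  fit
}

#' Structure correlations against the latent variables
#'
#' \code{r_x[j] = cor(X[, j], LV_x)} and \code{r_y[k] = cor(Y[, k], LV_y)}
#' with two-sided t-distribution p-values (n - 2 df) and BH FDR computed
#' separately over features and covariates. Constant columns yield NA and
#' are flagged.
#'
#' @param X samples x features matrix.
#' @param Y samples x covariates matrix.
#' @param fit a \code{grcca_fit}.
#' @return list of two data.frames, \code{r_x} and \code{r_y} (id, r, p,
#'   fdr, constant).
#' @export
structure_correlations <- function(X, Y, fit) {
  stopifnot(inherits(fit, "grcca_fit"))
  one_side <- function(M, lv, idcol) {
    M <- as.matrix(M)
    sdv <- apply(M, 2, stats::sd)
    r <- rep(NA_real_, ncol(M))
    r[sdv > 0] <- as.vector(stats::cor(M[, sdv > 0, drop = FALSE], lv))
    p <- cor_pvalue(r, nrow(M))
    out <- data.frame(id = colnames(M) %||% as.character(seq_len(ncol(M))),
                      r = r, p = p, fdr = bh_adjust(p), constant = sdv == 0,
                      stringsAsFactors = FALSE)
    names(out)[1] <- idcol
    out
  }
  list(r_x = one_side(X, fit$LV_x, "feature_id"),
       r_y = one_side(Y, fit$LV_y, "covariate_id"))
}

#' Features passing the dual significance criteria
#'
#' A feature is significant when (i) its bootstrap |Z| is at least
#' \code{z_thresh} (inclusive), showing a consistently non-zero weight
#' across resamples, and (ii) its structure-correlation FDR is strictly
#' below \code{fdr}, confirming correlation with the latent association.
#' The returned table is sorted by decreasing |r_x|.
#'
#' @param fit a \code{grcca_fit} augmented by [bootstrap_z()].
#' @param z_thresh bootstrap Z threshold (default 2; inclusive).
#' @param fdr structure-correlation FDR threshold (default 0.05; strict).
#' @return data.frame: feature_id, r, p, fdr, Z, significant (all
#'   features), ordered by |r| descending; the subset with
#'   \code{significant == TRUE} satisfies both criteria.
#' @export
significant_features <- function(fit, z_thresh = 2, fdr = 0.05) {
  stopifnot(inherits(fit, "grcca_fit"))
  stop_if(is.null(fit$Z_x), "run bootstrap_z() first")
  tab <- fit$r_x
  tab$Z <- unname(fit$Z_x[tab$feature_id])
  tab$significant <- abs(tab$Z) >= z_thresh & tab$fdr < fdr
  tab[order(-abs(tab$r)), ]
}

#' @export
print.grcca_fit <- function(x, ...) {
  cat("GRCCA fit: n =", x$n, ", p =", length(x$w_x), ", q =", length(x$w_y), "\n")
  cat(sprintf("latent correlation %.4f at f = %.2f (%d components); lambda = %.6g, mu = %.3g\n",
              x$latent_correlation, x$chosen_f, x$k_components, x$lambda, x$mu))
  top <- x$r_y[order(-abs(x$r_y$r)), ][1, ]
  cat(sprintf("top covariate: %s (r_y = %.3f)\n", top$covariate_id, top$r))
  invisible(x)
}
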