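#' Network parameters for co-expression module detection
#'
#' @param beta soft-threshold power applied to the correlation adjacency
#'   (typical values: 3 for gene-level, 2 for transcript-level networks).
#' @param signed use the signed adjacency \code{((1+cor)/2)^beta} instead of
#'   the unsigned \code{|cor|^beta}.
#' @param cut_height static tree-cut height on the 1 - TOM dendrogram
#'   (typical values: 0.980 genes, 0.988 transcripts).
#' @param min_module_size clusters smaller than this are merged into the
#'   unassigned (gray) module 0 (typical values: 40 genes, 35 transcripts).
#' @return list of class \code{"network_params"}.
#' @export
network_params <- function(beta = 3, signed = FALSE, cut_height = 0.980,
                           min_module_size = 40) {
  stop_if(beta < 1, "beta must be >= 1")
  stop_if(cut_height <= 0 || cut_height > 1, "cut_height must lie in (0, 1]")
  stop_if(min_module_size < 2, "min_module_size must be >= 2")
  structure(list(beta = beta, signed = signed, cut_height = cut_height,
                 min_module_size = as.integer(min_module_size)),
            class = "network_params")
}

#' Soft-threshold adjacency matrix
#'
#' Pearson-correlation adjacency raised to the soft-threshold power:
#' unsigned \code{|cor|^beta} or signed \code{((1+cor)/2)^beta}, with unit
#' diagonal. Soft thresholding suppresses weak correlations while keeping
#' the network continuous, pushing the degree distribution toward
#' approximate scale-free topology.
#'
#' @param expr numeric matrix, features x samples.
#' @param params a \code{network_params}.
#' @return symmetric adjacency matrix with entries in [0, 1].
#' @export
adjacency <- function(expr, params = network_params()) {
  sdv <- apply(expr, 1, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance feature(s): ",
         paste(rownames(expr)[sdv == 0] %||% which(sdv == 0), collapse = ", "),
         call. = FALSE)
  }
  C <- stats::cor(t(expr))
  A <- if (params$signed) ((1 + C) / 2)^params$beta else abs(C)^params$beta
  diag(A) <- 1
  A
}

#' Pick a soft-threshold power by scale-free fit
#'
#' For each candidate power, builds the adjacency, computes connectivity
#' \code{k_i = sum_j a_ij - 1}, bins \code{k} into \code{n_bins} equal-width
#' bins and fits \code{log10(freq)} on \code{log10(mean k)} over occupied
#' bins. Returns the smallest power whose fit R-squared reaches
#' \code{rsq_target}, falling back to the power maximizing R-squared when
#' none does.
#'
#' @param expr numeric matrix, features x samples (>= 3 non-constant
#'   features; constant features are excluded with a warning).
#' @param candidate_powers numeric vector of powers to assess.
#' @param rsq_target scale-free fit threshold (default 0.8).
#' @param n_bins histogram bins for the degree distribution (default 10).
#' @return list: \code{power} (selected), \code{table} (power, rsq, slope,
#'   mean_k).
#' @export
pick_soft_threshold <- function(expr, candidate_powers = c(1:10, 12, 14, 16),
                                rsq_target = 0.8, n_bins = 10) {
  sdv <- apply(expr, 1, stats::sd)
  if (any(sdv == 0)) {
    warning("excluding constant feature(s): ", sum(sdv == 0))
    expr <- expr[sdv > 0, , drop = FALSE]
  }
  stop_if(nrow(expr) < 3, "need >= 3 non-constant features")
  C <- abs(stats::cor(t(expr)))
  fits <- lapply(candidate_powers, function(b) {
    A <- C^b
    diag(A) <- 1
    k <- rowSums(A) - 1
    scale_free_fit(k, n_bins = n_bins)
  })
  tab <- data.frame(power = candidate_powers,
                    rsq = vapply(fits, `[[`, 1, "rsq"),
                    slope = vapply(fits, `[[`, 1, "slope"),
                    mean_k = vapply(fits, `[[`, 1, "mean_k"))
  ok <- which(!is.na(tab$rsq) & tab$rsq >= rsq_target)
  power <- if (length(ok)) tab$power[ok[1]] else tab$power[which.max(replace(tab$rsq, is.na(tab$rsq), -Inf))]
  list(power = power, table = tab)
}

# R^2 and slope of log10(freq) ~ log10(k) over equal-width bins of the
# connectivity vector; NA when fewer than 3 occupied bins or zero variance
scale_free_fit <- function(k, n_bins = 10) {
  out <- list(rsq = NA_real_, slope = NA_real_, mean_k = mean(k))
  if (diff(range(k)) < 1e-8 || any(k <= 0)) return(out)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  kmid <- tapply(k, bin, mean)
  occ <- which(freq > 0 & !is.na(kmid) & kmid > 0)
  if (length(occ) < 3) return(out)
  x <- log10(kmid[occ]); y <- log10(freq[occ] / length(k))
  if (stats::sd(x) == 0) return(out)
  fit <- stats::lm(y ~ x)
  out$rsq <- summary(fit)$r.squared
  out$slope <- unname(stats::coef(fit)[2])
  out
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)} with
#' \code{l_ij = sum_{u != i,j} a_iu a_uj} and \code{k_i = sum_{u != i}
#' a_iu}; the diagonal is 1. Two features overlap topologically when they
#' share strong connections to the same neighbors, which is more robust to
#' single spurious correlations than the raw adjacency.
#'
#' @param A symmetric adjacency with entries in [0, 1] and unit diagonal.
#' @return symmetric TOM matrix, entries in [0, 1], diagonal 1.
#' @export
topological_overlap <- function(A) {
  stop_if(!isSymmetric(unname(A), tol = 1e-10), "A must be symmetric")
  stop_if(any(A < 0 | A > 1), "A entries must lie in [0, 1]")
  # (A %*% A)_ij includes u = i and u = j terms a_ii a_ij + a_ij a_jj = 2 a_ij
  L <- A %*% A - 2 * A
  k <- rowSums(A) - 1
  denom <- outer(k, k, pmin) + 1 - A
  TOM <- (L + A) / denom
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(A)
  TOM
}

#' Cluster features into co-expression modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM,
#' cut statically at \code{cut_height}; clusters smaller than
#' \code{min_module_size} are merged into module 0 (the unassigned "gray"
#' module) and the remaining clusters are renumbered 1..K by decreasing
#' size (ties broken by first appearance in the cut).
#'
#' @param TOM topological overlap matrix from [topological_overlap()].
#' @param params a \code{network_params}.
#' @return object of class \code{"module_assignment"}: named integer vector
#'   (0 = unassigned) with a \code{"sizes"} attribute (table over module
#'   ids).
#' @export
cluster_modules <- function(TOM, params = network_params()) {
  d <- stats::as.dist(1 - TOM)
  hc <- stats::hclust(d, method = "average")
  raw <- if (params$cut_height >= max(hc$height)) {
    rep(1L, nrow(TOM))
  } else {
    stats::cutree(hc, h = params$cut_height)
  }
  sizes <- table(raw)
  big <- names(sizes)[sizes >= params$min_module_size]
  # renumber surviving clusters by decreasing size, ties by first appearance
  first_seen <- vapply(big, function(g) match(g, as.character(raw)), 1L)
  ord <- big[order(-as.vector(sizes[big]), first_seen)]
  modules <- integer(length(raw))
  for (i in seq_along(ord)) modules[raw == as.integer(ord[i])] <- i
  names(modules) <- rownames(TOM)
  structure(modules, sizes = table(modules), class = "module_assignment")
}

#' Module eigengenes
#'
#' For each module, the first principal component of the
#' feature-standardized module submatrix, i.e. the single sample-space
#' pattern explaining the most shared variance. Sign is fixed so that the
#' eigengene correlates positively with mean module expression. A singleton
#' module returns its standardized feature.
#'
#' @param expr numeric matrix, features x samples.
#' @param assignment a \code{module_assignment} (or named integer vector)
#'   over the rows of \code{expr}.
#' @param include_gray also compute an eigengene for module 0.
#' @return matrix, modules x samples, rownames \code{ME<k>}.
#' @export
module_eigengene <- function(expr, assignment, include_gray = FALSE) {
  ids <- sort(unique(assignment[assignment > 0 | include_gray]))
  me <- matrix(NA_real_, length(ids), ncol(expr),
               dimnames = list(paste0("ME", ids), colnames(expr)))
  for (i in seq_along(ids)) {
    sub <- expr[assignment == ids[i], , drop = FALSE]
    Z <- t(standardize_columns(t(sub)))
    v <- if (nrow(Z) == 1) as.vector(Z) else svd(Z, nu = 0, nv = 1)$v[, 1]
    if (stats::cor(v, colMeans(Z)) < 0) v <- -v
    me[i, ] <- v
  }
  me
}

#' @export
print.module_assignment <- function(x, ...) {
  sz <- attr(x, "sizes")
  cat("module assignment:", length(x), "features,",
      sum(names(sz) != "0"), "modules,",
      if ("0" %in% names(sz)) sz[["0"]] else 0, "unassigned\n")
  print(sz)
  invisible(x)
}
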