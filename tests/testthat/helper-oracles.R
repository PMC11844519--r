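# Independent oracles used across the suite. Each is written against the
# mathematical definition with the most naive possible code path, on
# purpose, so it shares nothing with the package implementation.

# dense solution of: maximize w_x' C_xy w_y  s.t.  w_x' R w_x = 1,
# w_y' C_yy w_y = 1, with R = lambda (I - B) + mu B built as an explicit
# p x p matrix and matrix square roots taken by eigendecomposition
oracle_grcca <- function(X, Y, groups, lambda, mu) {
  Xs <- scale(X)
  Ys <- scale(Y)
  n <- nrow(Xs)
  p <- ncol(Xs)
  g <- as.integer(factor(groups))
  B <- matrix(0, p, p)
  for (k in unique(g)) {
    idx <- which(g == k)
    B[idx, idx] <- 1 / length(idx)
  }
  R <- lambda * (diag(p) - B) + mu * B
  inv_sqrt <- function(M) {
    e <- eigen(M, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow(M)) %*% t(e$vectors)
  }
  Cxy <- crossprod(Xs, Ys) / (n - 1)
  Cyy <- crossprod(Ys) / (n - 1)
  Ri <- inv_sqrt(R)
  Cyi <- inv_sqrt(Cyy)
  K <- Ri %*% Cxy %*% Cyi
  sv <- svd(K, nu = 1, nv = 1)
  w_x <- as.vector(Ri %*% sv$u[, 1])
  w_y <- as.vector(Cyi %*% sv$v[, 1])
  list(w_x = w_x, w_y = w_y,
       correlation = abs(cor(Xs %*% w_x, Ys %*% w_y)[1, 1]))
}

# triple-loop topological overlap
oracle_tom <- function(A) {
  p <- nrow(A)
  TOM <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    ki <- sum(A[i, -i])
    kj <- sum(A[j, -j])
    TOM[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  TOM
}

# exhaustive running-sum GSEA enrichment score, walking every position
oracle_es <- function(scores, set, exponent = 1) {
  ord <- order(-scores, names(scores))
  ids <- names(scores)[ord]
  s <- abs(scores[ord])
  hit <- ids %in% set
  m <- sum(hit)
  N <- length(ids)
  gain <- s^exponent * hit
  gain <- if (sum(gain) > 0) gain / sum(gain) else gain
  steps <- ifelse(hit, gain, -1 / (N - m))
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

# independently coded indicator-matrix correspondence analysis
oracle_indicator_ca <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  blocks <- lapply(names(table), function(v) {
    f <- factor(as.character(table[[v]]), levels = sort(unique(as.character(table[[v]]))))
    stats::model.matrix(~ f - 1)
  })
  Z <- do.call(cbind, blocks)
  n_total <- sum(Z)
  P <- Z / n_total
  r <- rowSums(P)
  cm <- colSums(P)
  Dr <- diag(1 / sqrt(r))
  Dc <- diag(1 / sqrt(cm))
  S <- Dr %*% (P - outer(r, cm)) %*% Dc
  sv <- svd(S)
  keep <- sv$d > 1e-10
  list(coords = Dr %*% sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep)),
       eigenvalues = sv$d[keep]^2)
}

# small random GRCCA instance with a mild planted association
random_cca_instance <- function(seed, n = 40, p = 20, q = 3, k_groups = 4) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * q), n, q)
  Y[, 1] <- Y[, 1] + 0.5 * rowMeans(X[, 1:3, drop = FALSE])
  groups <- sample(seq_len(k_groups), p, replace = TRUE)
  list(X = X, Y = Y, groups = groups)
}

# agreement of two vectors up to overall sign and scale
collinearity <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
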