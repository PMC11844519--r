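#' Impute unknown exposure entries as absent
#'
#' Postmortem toxicology reports record each compound as present, absent or
#' unknown; the conservative convention adopted here treats an unknown
#' screen as no exposure, so that the table becomes binary before
#' correspondence analysis.
#'
#' @param table data.frame of character/factor columns with entries in
#'   \{present, absent, unknown\}.
#' @return the same table with every "unknown" replaced by "absent".
#' @export
impute_unknown <- function(table) {
  for (j in seq_along(table)) {
    col <- as.character(table[[j]])
    bad <- setdiff(unique(col), c("present", "absent", "unknown"))
    stop_if(length(bad) > 0, "unexpected level(s): ", paste(bad, collapse = ", "))
    col[col == "unknown"] <- "absent"
    table[[j]] <- col
  }
  table
}

#' Multiple correspondence analysis of a categorical table
#'
#' Indicator-matrix MCA: builds the 0/1 indicator matrix Z over all observed
#' category levels, forms the correspondence matrix P = Z/sum(Z), computes
#' the standardized residuals S = Dr^{-1/2} (P - r c') Dc^{-1/2} with row
#' and column mass vectors r and c, and takes the SVD of S. Sample
#' coordinates are Dr^{-1/2} U diag(d), category loadings Dc^{-1/2} V
#' diag(d), eigenvalues the squared singular values, and variance explained
#' each eigenvalue's share of total inertia. Per-dimension sign is fixed by
#' forcing the largest-|loading| category positive.
#'
#' Variables with a single observed level carry no information and are
#' dropped with a warning. No Benzecri/Greenacre inertia correction is
#' applied; variance shares follow the plain indicator-CA convention.
#'
#' @param table data.frame of categorical columns (binary after
#'   [impute_unknown()]; any level sets are accepted).
#' @param n_dims maximum number of dimensions to retain (default: all
#'   non-null dimensions).
#' @return object of class \code{"mca_result"}: list with
#'   \code{sample_coordinates}, \code{category_loadings},
#'   \code{eigenvalues}, \code{variance_explained}, \code{selected_dims}.
#' @export
mca <- function(table, n_dims = NULL) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  stop_if(ncol(table) == 0 || nrow(table) == 0, "empty table")
  nlev <- vapply(table, function(col) length(unique(as.character(col))), 1L)
  if (any(nlev < 2)) {
    warning("dropping constant variable(s): ",
            paste(colnames(table)[nlev < 2], collapse = ", "))
    table <- table[, nlev >= 2, drop = FALSE]
    stop_if(ncol(table) == 0, "no non-constant variables remain")
  }
  Z <- do.call(cbind, lapply(colnames(table), function(v) {
    col <- as.character(table[[v]])
    levs <- sort(unique(col))
    ind <- outer(col, levs, "==") * 1
    colnames(ind) <- paste(v, levs, sep = ".")
    ind
  }))
  rownames(Z) <- rownames(table)
  P <- Z / sum(Z)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- (P - r %o% cm) / sqrt(r %o% cm)
  sv <- svd(S)
  tol <- max(dim(S)) * .Machine$double.eps * sv$d[1]
  keep <- which(sv$d > max(tol, 1e-12))
  eig_all <- sv$d[keep]^2
  if (!is.null(n_dims)) keep <- keep[seq_len(min(n_dims, length(keep)))]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  Fc <- U * d[col(U)] / sqrt(r)
  G <- V * d[col(V)] / sqrt(cm)
  for (k in seq_along(d)) {                       # sign convention
    if (G[which.max(abs(G[, k])), k] < 0) {
      G[, k] <- -G[, k]
      Fc[, k] <- -Fc[, k]
    }
  }
  dimnames(Fc) <- list(rownames(Z), paste0("dim", seq_along(d)))
  dimnames(G) <- list(colnames(Z), paste0("dim", seq_along(d)))
  structure(list(sample_coordinates = Fc, category_loadings = G,
                 eigenvalues = d^2,
                 variance_explained = d^2 / sum(eig_all),
                 selected_dims = seq_along(d)),
            class = "mca_result")
}

#' Select MCA dimensions by individual and cumulative variance
#'
#' Chooses the smallest leading set of dimensions in which every member
#' individually explains more than \code{min_var} of total inertia and the
#' set cumulatively explains more than \code{cum_var}. When no prefix
#' satisfying the individual rule reaches the cumulative target, the
#' individual rule wins: all leading dimensions above \code{min_var} are
#' selected and a warning reports the cumulative shortfall.
#'
#' @param res an \code{mca_result}.
#' @param min_var minimum individual variance share (default 0.05).
#' @param cum_var cumulative variance target (default 0.75).
#' @return \code{res} with \code{selected_dims} replaced.
#' @export
select_dimensions <- function(res, min_var = 0.05, cum_var = 0.75) {
  stopifnot(inherits(res, "mca_result"))
  ve <- res$variance_explained
  k_ind <- match(FALSE, ve > min_var, nomatch = length(ve) + 1L) - 1L
  if (k_ind == 0L) {
    warning("no dimension exceeds min_var; empty selection")
    res$selected_dims <- integer(0)
    return(res)
  }
  cum <- cumsum(ve[seq_len(k_ind)])
  k <- match(TRUE, cum > cum_var, nomatch = NA_integer_)
  if (is.na(k)) {
    warning(sprintf(
      "individual-variance rule limits selection to %d dim(s) (cumulative %.3f <= %.3f)",
      k_ind, cum[k_ind], cum_var))
    k <- k_ind
  }
  res$selected_dims <- seq_len(k)
  res
}

#' Selected MCA sample coordinates
#'
#' @param res an \code{mca_result} (after [select_dimensions()] if
#'   selection is wanted).
#' @return matrix samples x selected dimensions.
#' @export
mca_scores <- function(res) {
  stopifnot(inherits(res, "mca_result"))
  res$sample_coordinates[, res$selected_dims, drop = FALSE]
}

#' @export
print.mca_result <- function(x, ...) {
  cat("MCA result:", nrow(x$sample_coordinates), "samples,",
      nrow(x$category_loadings), "categories,",
      length(x$eigenvalues), "dimensions\n")
  cat("variance explained:",
      paste(sprintf("%.3f", utils::head(x$variance_explained, 8)), collapse = " "), "\n")
  cat("selected:", paste(x$selected_dims, collapse = " "), "\n")
  invisible(x)
}
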