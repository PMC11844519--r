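#' Filter features by minimum count prevalence
#'
#' Keeps features observed at \code{>= min_count} counts in at least
#' \code{ceiling(min_fraction * n_samples)} samples, the standard prevalence
#' filter applied to bulk RNA-seq counts before normalization. Feature order
#' and the sample set are preserved; the filter is idempotent.
#'
#' @param counts integer matrix, features x samples.
#' @param min_count minimum count per sample (default 10).
#' @param min_fraction minimum fraction of samples meeting \code{min_count}
#'   (default 0.8).
#' @return the filtered count matrix.
#' @export
filter_min_counts <- function(counts, min_count = 10, min_fraction = 0.8) {
  stop_if(min_fraction <= 0 || min_fraction > 1, "min_fraction must lie in (0, 1]")
  stop_if(any(counts < 0), "counts must be non-negative")
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts >= min_count) >= need
  if (!any(keep)) warning("no features pass the count filter")
  counts[keep, , drop = FALSE]
}

#' Coefficient-of-variation filter
#'
#' Computes per-feature mean, variance and coefficient of variation
#' (sd/mean) and removes features whose CV falls below \code{cv_cutoff} —
#' i.e. features with minimal variation relative to their mean, which carry
#' little information for co-expression or covariate association analysis.
#' Unlike a plain variance filter, the CV criterion does not preferentially
#' discard lowly expressed features. Zero-mean features (CV undefined) are
#' flagged and removed.
#'
#' @param mat numeric matrix, features x samples (raw counts by default;
#'   any expression scale is accepted).
#' @param cv_cutoff non-negative CV threshold; features with CV strictly
#'   below it are removed. The reference pipeline for deep bulk data uses
#'   approximately 0.36.
#' @return list with \code{matrix} (kept features) and \code{stats}, a
#'   data.frame over all input features: \code{feature_id}, \code{mean},
#'   \code{variance}, \code{cv}, \code{kept}, \code{reason}.
#' @export
filter_by_cv <- function(mat, cv_cutoff = 0.36) {
  stop_if(cv_cutoff < 0, "cv_cutoff must be non-negative")
  mu <- rowMeans(mat)
  va <- apply(mat, 1, stats::var)
  cv <- ifelse(mu > 0, sqrt(va) / mu, NA_real_)
  reason <- rep("", nrow(mat))
  keep <- !is.na(cv) & cv >= cv_cutoff
  reason[is.na(cv)] <- "zero mean: CV undefined"
  reason[!is.na(cv) & cv < cv_cutoff] <- "CV below cutoff"
  stats <- data.frame(feature_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                      mean = mu, variance = va, cv = cv,
                      kept = keep, reason = reason, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(matrix = mat[keep, , drop = FALSE], stats = stats)
}

#' Median-of-ratios size factors
#'
#' Per-sample size factor: the median, over features with all-positive
#' counts, of the ratio of the sample's count to the feature's geometric
#' mean across samples. When no feature is positive in every sample the
#' factors fall back to library-size ratios (total count over its geometric
#' mean), with a warning.
#'
#' @param counts integer matrix, features x samples.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no feature with all-positive counts; using library-size-ratio factors")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  logref <- rowMeans(log(counts[pos, , drop = FALSE]))
  apply(counts[pos, , drop = FALSE], 2,
        function(col) exp(stats::median(log(col) - logref)))
}

#' Size-factor normalization and log transformation
#'
#' Divides each sample by its median-of-ratios size factor and applies
#' log2(x + 1). This is a light-weight variance-stabilizing step for
#' filtered bulk counts: after the prevalence filter most retained features
#' sit in the count range where the log transform is close to variance
#' stabilizing.
#'
#' @param counts integer matrix, features x samples (at least 2 samples).
#' @return a numeric matrix of transformed expression with a
#'   \code{"provenance"} attribute recording the applied transforms and a
#'   \code{"size_factors"} attribute.
#' @export
normalize_transform <- function(counts) {
  stop_if(ncol(counts) < 2, "at least 2 samples required")
  sf <- size_factors(counts)
  out <- log2(sweep(counts, 2, sf, "/") + 1)
  attr(out, "size_factors") <- sf
  attr(out, "provenance") <- c("size_factor_median_of_ratios", "log2_plus1")
  out
}

#' Residualize expression on covariates
#'
#' Replaces each feature by its ordinary-least-squares residuals after
#' regression on an intercept plus the supplied covariates. The residuals —
#' expression with known technical and biological nuisance variation
#' removed — are the working matrix for module detection, differential
#' expression and canonical correlation.
#'
#' @param expr numeric matrix, features x samples.
#' @param covariates numeric matrix or data.frame, samples x covariates;
#'   must be full column rank jointly with the intercept.
#' @return matrix of residuals with provenance extended.
#' @export
residualize <- function(expr, covariates) {
  covariates <- as.matrix(covariates)
  stop_if(nrow(covariates) != ncol(expr), "covariate rows must align with samples")
  design <- cbind(`(Intercept)` = 1, covariates)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- t(qr.resid(qrd, t(expr)))
  dimnames(res) <- dimnames(expr)
  attr(res, "provenance") <- c(attr(expr, "provenance"), "residualized")
  res
}

#' Screen covariates against expression principal components
#'
#' Computes sample-space principal components of the feature-standardized
#' expression matrix and tests each covariate for Pearson correlation with
#' every component explaining more than \code{var_threshold} of total
#' variance. P-values are Benjamini-Hochberg adjusted across all tested
#' (component, covariate) pairs; a covariate is flagged when any adjusted
#' p-value falls below \code{fdr}. Running this on residualized expression
#' against the covariates just regressed should flag nothing — the check
#' that covariate correction succeeded.
#'
#' @param expr numeric matrix, features x samples (>= 3 samples).
#' @param covariates numeric matrix or data.frame, samples x covariates;
#'   constant covariates are skipped with a warning.
#' @param var_threshold minimum variance share for a component to be
#'   screened (default 0.02).
#' @param fdr BH threshold for flagging (default 0.05).
#' @return list: \code{table} (pc, covariate, variance_explained, r, p,
#'   fdr), \code{flagged} (character vector of covariate names),
#'   \code{variance_explained} (all components).
#' @export
pc_covariate_screen <- function(expr, covariates, var_threshold = 0.02, fdr = 0.05) {
  stop_if(ncol(expr) < 3, "at least 3 samples required")
  covariates <- as.matrix(covariates)
  sdv <- apply(expr, 1, stats::sd)
  Z <- (expr[sdv > 0, , drop = FALSE] - rowMeans(expr[sdv > 0, , drop = FALSE])) / sdv[sdv > 0]
  sv <- svd(scale(t(Z), center = TRUE, scale = FALSE))
  ve <- sv$d^2 / sum(sv$d^2)
  use_pc <- which(ve > var_threshold)
  cov_ok <- apply(covariates, 2, stats::sd) > 0
  if (any(!cov_ok)) warning("skipping constant covariate(s): ",
                            paste(colnames(covariates)[!cov_ok], collapse = ", "))
  covariates <- covariates[, cov_ok, drop = FALSE]
  if (!length(use_pc) || !ncol(covariates)) {
    return(list(table = data.frame(), flagged = character(0), variance_explained = ve))
  }
  tab <- expand.grid(pc = use_pc, covariate = colnames(covariates) %||%
                       as.character(seq_len(ncol(covariates))),
                     stringsAsFactors = FALSE)
  tab$variance_explained <- ve[tab$pc]
  tab$r <- mapply(function(pc, cv) stats::cor(sv$u[, pc], covariates[, cv]),
                  tab$pc, tab$covariate)
  tab$p <- cor_pvalue(tab$r, nrow(covariates))
  tab$fdr <- bh_adjust(tab$p)
  list(table = tab,
       flagged = unique(tab$covariate[tab$fdr < fdr]),
       variance_explained = ve)
}
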