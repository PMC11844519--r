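#' Per-feature differential expression by linear model
#'
#' Ordinary least squares of each feature's processed expression on an
#' intercept, diagnosis indicators (control baseline) and the supplied MCA
#' toxicology dimensions, fitted via \code{limma::lmFit}. Reported
#' statistics are the ordinary (un-moderated) per-feature t-statistics:
#' coefficient / (unscaled standard deviation x residual standard error)
#' with residual df = n - rank, two-sided p-values and BH FDR. Because the
#' expression has already been normalized and residualized, a Gaussian
#' linear model per feature is the appropriate comparison arm; no
#' count-model dispersion machinery is involved.
#'
#' @param expr numeric matrix, features x samples (processed expression).
#' @param sample_table data.frame with a \code{diagnosis} factor aligned
#'   with the columns of \code{expr}; the first level is the baseline.
#' @param mca_dims optional numeric matrix, samples x dimensions, added as
#'   covariates.
#' @param contrast diagnosis level to report (default "SCZ").
#' @return object of class \code{"dge_result"}: data.frame with
#'   \code{feature_id}, \code{effect} (contrast-vs-baseline coefficient on
#'   the log2 scale), \code{t}, \code{p}, \code{fdr}; all diagnosis
#'   contrasts are kept in the \code{"all_contrasts"} attribute.
#' @export
fit_dge <- function(expr, sample_table, mca_dims = NULL, contrast = "SCZ") {
  stop_if(!"diagnosis" %in% names(sample_table), "sample_table needs a diagnosis column")
  diagnosis <- droplevels(as.factor(sample_table$diagnosis))
  stop_if(!contrast %in% levels(diagnosis), "contrast level not present in diagnosis")
  stop_if(nrow(sample_table) != ncol(expr), "sample_table rows must align with samples")
  design <- stats::model.matrix(~diagnosis)
  colnames(design) <- sub("^diagnosis", "", colnames(design))
  if (!is.null(mca_dims)) {
    mca_dims <- as.matrix(mca_dims)
    stop_if(nrow(mca_dims) != ncol(expr), "mca_dims rows must align with samples")
    design <- cbind(design, mca_dims)
  }
  if (qr(design)$rank < ncol(design)) {
    stop("design is rank deficient", call. = FALSE)
  }
  lf <- limma::lmFit(expr, design)
  tt <- lf$coefficients / (lf$stdev.unscaled * lf$sigma)
  pp <- 2 * stats::pt(-abs(tt), df = lf$df.residual)
  make_tab <- function(cn) {
    data.frame(feature_id = rownames(expr) %||% as.character(seq_len(nrow(expr))),
               effect = unname(lf$coefficients[, cn]),
               t = unname(tt[, cn]), p = unname(pp[, cn]),
               fdr = bh_adjust(unname(pp[, cn])),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- make_tab(contrast)
  others <- setdiff(levels(diagnosis)[-1], contrast)
  attr(out, "all_contrasts") <- stats::setNames(lapply(others, make_tab), others)
  attr(out, "df_residual") <- lf$df.residual[1]
  class(out) <- c("dge_result", "data.frame")
  out
}

#' Compare differential-expression statistics with GRCCA structure
#' correlations
#'
#' Pearson correlation of per-feature t-statistics with the GRCCA feature
#' structure correlations over the shared feature set. Agreement between
#' the two arms (a positive, substantial correlation) indicates that the
#' latent association recovered by GRCCA reflects the same expression
#' differences seen feature-by-feature, while the two remain methodically
#' independent.
#'
#' @param dge a \code{dge_result}.
#' @param fit a \code{grcca_fit}.
#' @return list: \code{correlation}, \code{p}, \code{n_shared},
#'   \code{table} (feature_id, t, r_x).
#' @export
compare_to_grcca <- function(dge, fit) {
  stopifnot(inherits(dge, "dge_result"), inherits(fit, "grcca_fit"))
  shared <- intersect(dge$feature_id, fit$r_x$feature_id)
  stop_if(length(shared) < 3, "fewer than 3 shared features")
  tab <- data.frame(feature_id = shared,
                    t = dge$t[match(shared, dge$feature_id)],
                    r_x = fit$r_x$r[match(shared, fit$r_x$feature_id)],
                    stringsAsFactors = FALSE)
  ct <- stats::cor.test(tab$t, tab$r_x)
  list(correlation = unname(ct$estimate), p = ct$p.value,
       n_shared = length(shared), table = tab)
}
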