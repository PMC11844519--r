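# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# column-standardize a matrix (mean 0, sd 1 with n-1 denominator);
# errors on constant columns unless allow_constant, in which case they are
# returned as all-zero with a "constant" attribute listing them
standardize_columns <- function(M, allow_constant = FALSE) {
  M <- as.matrix(M)
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  const <- which(sdv == 0 | !is.finite(sdv))
  if (length(const) && !allow_constant) {
    stop("constant column(s): ", paste(colnames(M)[const] %||% const, collapse = ", "),
         call. = FALSE)
  }
  sdv[const] <- 1
  Z <- sweep(sweep(M, 2, mu, "-"), 2, sdv, "/")
  if (length(const)) Z[, const] <- 0
  attr(Z, "constant") <- const
  Z
}

# two-sided p-value for a Pearson correlation at n samples
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}
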