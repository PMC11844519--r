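#' Benjamini-Hochberg adjustment with NA handling
#'
#' Standard step-up BH via \code{stats::p.adjust}, with NA/NaN p-values
#' propagated in place and excluded from the ranking (the effective number
#' of tests is the number of finite p-values).
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return adjusted values, order-preserving with the input.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- is.finite(p)
  stop_if(any(p[ok] < 0 | p[ok] > 1), "p-values must lie in [0, 1]")
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# running-sum enrichment score for one set given the descending-sorted
# absolute scores and the hit positions; O(n_set). Returns the signed
# extremum and the extremum position (for the leading edge).
es_from_positions <- function(abs_sorted, pos, exponent = 1) {
  m <- length(pos)
  N <- length(abs_sorted)
  g <- abs_sorted[pos]^exponent
  G <- sum(g)
  miss <- 1 / (N - m)
  if (G == 0) {                         # all-zero scores in the set: hits add 0
    hit_cum <- rep(0, m)
  } else {
    hit_cum <- cumsum(g) / G
  }
  after <- hit_cum - (pos - seq_len(m)) * miss        # value just after each hit
  before <- c(0, hit_cum[-m]) - (pos - seq_len(m)) * miss  # just before each hit
  hi <- max(after)
  lo <- min(c(before, 0))
  if (hi >= -lo) {
    list(es = hi, at = pos[which.max(after)])
  } else {
    list(es = lo, at = pos[which.min(before)])
  }
}

#' Preranked gene set enrichment (weighted Kolmogorov-Smirnov)
#'
#' Classic preranked GSEA: features are sorted by score descending (ties
#' broken deterministically by feature id); walking down the list, the
#' running sum gains \code{|score|^exponent / sum(|score in set|^exponent)}
#' at set members and loses \code{1/(N - n_set)} elsewhere; the enrichment
#' score ES is the signed extremum. The null is gene sampling: random
#' same-size sets drawn from the ranked universe. The p-value is one-sided
#' among same-sign null scores, \code{NES = ES / mean(|null ES| of the same
#' sign)}, and BH correction is applied across sets.
#'
#' @param scores named numeric vector (feature -> score); must be finite.
#' @param sets named list of character vectors of feature ids.
#' @param n_perm number of null sets per gene set (default 1000).
#' @param seed integer RNG seed.
#' @param min_size minimum intersection with the ranked universe
#'   (default 5).
#' @param exponent weighting exponent on |score| (default 1).
#' @return data.frame of class \code{"enrichment_result"}: set, size, ES,
#'   NES, p, fdr, leading_edge (comma-separated ids); skipped sets are
#'   recorded in the \code{"skipped"} attribute with reasons.
#' @export
gsea_preranked <- function(scores, sets, n_perm = 1000, seed = 1,
                           min_size = 5, exponent = 1) {
  stop_if(is.null(names(scores)), "scores must be named by feature id")
  stop_if(any(!is.finite(scores)), "scores must be finite")
  ord <- order(-scores, names(scores))
  ids <- names(scores)[ord]
  abs_sorted <- abs(scores[ord])
  N <- length(ids)
  set.seed(seed)
  skipped <- character(0)
  rows <- list()
  for (nm in names(sets)) {
    hits <- which(ids %in% sets[[nm]])
    m <- length(hits)
    if (m < min_size) {
      skipped[nm] <- sprintf("intersection size %d < %d", m, min_size)
      next
    }
    if (m >= N) {
      skipped[nm] <- "set covers the whole universe; ES degenerate"
      next
    }
    obs <- es_from_positions(abs_sorted, hits, exponent)
    null_es <- vapply(seq_len(n_perm), function(i) {
      es_from_positions(abs_sorted, sort(sample.int(N, m)), exponent)$es
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(obs$es)]
    if (obs$es == 0) same <- null_es
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    le <- if (obs$es >= 0) ids[hits[hits <= obs$at]] else ids[hits[hits >= obs$at]]
    rows[[nm]] <- data.frame(set = nm, size = m, ES = obs$es, NES = nes, p = p,
                             leading_edge = paste(le, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), size = integer(0), ES = numeric(0),
               NES = numeric(0), p = numeric(0), leading_edge = character(0))
  out$fdr <- bh_adjust(out$p)
  out <- out[, c("set", "size", "ES", "NES", "p", "fdr", "leading_edge")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Hypergeometric overlap enrichment
#'
#' One-sided upper-tail hypergeometric test of the overlap between a query
#' feature set and each collection set within a common universe, the
#' standard test for e.g. module/cell-type marker overlap. The odds ratio
#' comes from the 2x2 table (overlap, query-only, set-only, neither) with
#' Haldane 0.5 correction when any cell is zero; BH across sets.
#'
#' @param query character vector of feature ids; must be a subset of
#'   \code{universe}.
#' @param sets named list of character vectors.
#' @param universe character vector defining the feature background.
#' @return data.frame of class \code{"enrichment_result"}: set, set_size,
#'   overlap, expected, odds_ratio, p, fdr; sets with empty intersection
#'   with the universe are skipped (recorded in \code{"skipped"}).
#' @export
hypergeom_overlap <- function(query, sets, universe) {
  query <- unique(query)
  universe <- unique(universe)
  stop_if(!all(query %in% universe), "query must be a subset of the universe")
  N <- length(universe)
  m <- length(query)
  skipped <- character(0)
  rows <- list()
  for (nm in names(sets)) {
    s <- intersect(unique(sets[[nm]]), universe)
    K <- length(s)
    if (K == 0) {
      skipped[nm] <- "no overlap with universe"
      next
    }
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    a <- k; b <- m - k; cc <- K - k; d <- N - K - m + k
    if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    rows[[nm]] <- data.frame(set = nm, set_size = K, overlap = k,
                             expected = m * K / N, odds_ratio = (a * d) / (b * cc),
                             p = p, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), set_size = integer(0), overlap = integer(0),
               expected = numeric(0), odds_ratio = numeric(0), p = numeric(0))
  out$fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Decile trajectory summaries
#'
#' Splits a feature score vector (typically structure correlations) into
#' deciles by rank — decile 1 holds the most positive scores, decile 10
#' the most negative, ties broken by feature id — and summarizes an
#' external feature-by-stage matrix (e.g. normative developmental
#' expression) per decile and stage by median and mean.
#'
#' @param scores named numeric vector (feature -> score).
#' @param stage_matrix numeric matrix, features x stages, rownames are
#'   feature ids; features absent from \code{scores} are dropped (count
#'   reported in the \code{"n_dropped"} attribute).
#' @param n_bins number of bins (default 10).
#' @return data.frame: decile, stage, median, mean, n.
#' @export
decile_trajectories <- function(scores, stage_matrix, n_bins = 10) {
  stop_if(is.null(names(scores)), "scores must be named")
  stop_if(is.null(rownames(stage_matrix)), "stage_matrix must have rownames")
  shared <- intersect(names(scores), rownames(stage_matrix))
  stop_if(length(shared) < n_bins, "need at least n_bins shared features")
  n_dropped <- length(union(names(scores), rownames(stage_matrix))) - length(shared)
  s <- scores[shared]
  ord <- order(-s, names(s))
  dec <- ceiling(seq_along(ord) * n_bins / length(ord))
  M <- stage_matrix[shared[ord], , drop = FALSE]
  stages <- colnames(M) %||% as.character(seq_len(ncol(M)))
  out <- do.call(rbind, lapply(seq_len(n_bins), function(d) {
    sub <- M[dec == d, , drop = FALSE]
    data.frame(decile = d, stage = stages,
               median = apply(sub, 2, stats::median),
               mean = colMeans(sub), n = nrow(sub),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(out, "n_dropped") <- n_dropped
  out
}
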