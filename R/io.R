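#' @name io
#' @title Readers and writers for the pipeline's file formats
#'
#' @description Thin, lossless adapters: counts as TSV (features in rows,
#' first column \code{feature_id}, header = sample ids) or MatrixMarket
#' coordinate format with sidecar row/column name files; sample covariates
#' as CSV; gene set collections as GMT (tab-separated: name, description,
#' ids...); transcript-to-gene mappings and generic result tables as TSV.
#' \code{write_* \%>\% read_*} is the identity on the data model.
NULL

#' @rdname io
#' @param counts integer matrix, features x samples.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(names(df)[1] != "feature_id", "first column must be feature_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  stop_if(anyDuplicated(rownames(m)) > 0, "duplicate feature ids")
  m
}

#' @rdname io
#' @export
write_counts_mtx <- function(counts, path) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  writeLines(rownames(counts), paste0(path, ".rownames"))
  writeLines(colnames(counts), paste0(path, ".colnames"))
  invisible(path)
}

#' @rdname io
#' @export
read_counts_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(paste0(path, ".rownames"))
  colnames(m) <- readLines(paste0(path, ".colnames"))
  storage.mode(m) <- "integer"
  m
}

#' @rdname io
#' @param samples sample covariate data.frame.
#' @export
write_samples_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_samples_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("diagnosis" %in% names(df)) {
    df$diagnosis <- factor(df$diagnosis, levels = unique(df$diagnosis))
  }
  df
}

#' @rdname io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(parts)), call. = FALSE)
    }
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}

#' @rdname io
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' @rdname io
#' @export
read_mapping_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if(!all(c("transcript_id", "gene_id") %in% names(df)),
          "mapping must have transcript_id and gene_id columns")
  df
}

#' @rdname io
#' @param x data.frame to write.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map transcript-level scores to gene level
#'
#' Aggregates a transcript score vector to genes through a
#' transcript-to-gene mapping. The default rule keeps, per gene, the signed
#' value of the transcript with maximum absolute score (ties broken by
#' transcript id), recording the contributing transcript; the \code{mean}
#' rule averages all transcript scores of the gene. Applying the
#' aggregation to an already gene-level vector (one transcript per gene) is
#' the identity, so repeated application is idempotent.
#'
#' @param values named numeric vector, transcript -> score.
#' @param mapping data.frame with \code{transcript_id} and \code{gene_id}.
#' @param rule \code{"max_abs"} (default) or \code{"mean"}.
#' @return data.frame: gene_id, value, n_transcripts, source_transcript
#'   (NA under the mean rule); transcripts absent from the mapping are
#'   dropped (count in the \code{"n_unmapped"} attribute).
#' @export
map_transcripts_to_genes <- function(values, mapping, rule = c("max_abs", "mean")) {
  rule <- match.arg(rule)
  stop_if(is.null(names(values)), "values must be named by transcript id")
  idx <- match(names(values), mapping$transcript_id)
  unmapped <- sum(is.na(idx))
  keep <- !is.na(idx)
  df <- data.frame(transcript_id = names(values)[keep],
                   gene_id = mapping$gene_id[idx[keep]],
                   value = unname(values[keep]), stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, df$transcript_id), ]
  out <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
    if (rule == "max_abs") {
      j <- which.max(abs(g$value))     # ties: first in transcript-id order
      data.frame(gene_id = g$gene_id[1], value = g$value[j],
                 n_transcripts = nrow(g), source_transcript = g$transcript_id[j],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = g$gene_id[1], value = mean(g$value),
                 n_transcripts = nrow(g), source_transcript = NA_character_,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- unmapped
  out
}
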