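#' Remove low-expression genes
#'
#' Retains exactly the genes whose total count across all samples is
#' strictly greater than `threshold` (the boundary total equal to the
#' threshold is removed). Input gene order is preserved.
#'
#' @param cm a [count_matrix()].
#' @param threshold non-negative integer total-count threshold.
#' @return The filtered [count_matrix()].
#' @export
filter_genes <- function(cm, threshold) {
  stopifnot(inherits(cm, "count_matrix"), threshold >= 0)
  keep <- rowSums(cm$counts) > threshold
  if (!any(keep))
    stop("no gene exceeds total count ", threshold,
         "; reduce filter_threshold", call. = FALSE)
  out <- count_matrix(cm$counts[keep, , drop = FALSE],
                      cm$gene_ids[keep], cm$sample_ids)
  bl_log("filter_genes", sprintf("%d of %d genes retained (total count > %s)",
                                 sum(keep), length(keep), threshold))
  out
}

#' Median-of-ratios size factors
#'
#' Computes the per-sample size factor `s_j` as the median over reference
#' genes of `counts[i, j] / g_i`, where `g_i` is gene i's geometric mean
#' across samples. Genes containing any zero count are excluded from the
#' reference set, so at least one all-positive gene is required.
#'
#' @param cm a [count_matrix()].
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  pos <- rowSums(cm$counts == 0) == 0
  if (!any(pos))
    stop("no gene has all-positive counts; size factors are undefined",
         call. = FALSE)
  logc <- log(cm$counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  s <- apply(logc, 2, function(x) exp(median(x - loggeo)))
  names(s) <- cm$sample_ids
  bl_log("size_factors", sprintf("%d reference genes; range [%.3f, %.3f]",
                                 sum(pos), min(s), max(s)))
  s
}

#' Offset log2 normalization
#'
#' Divides each count by its sample's size factor, adds the offset and takes
#' log2: `values[i, j] = log2(counts[i, j] / s_j + offset)`. At the default
#' offset of 1 a zero count maps to exactly 0, preserving zeros as null.
#'
#' @param cm a [count_matrix()].
#' @param s positive size factors, one per sample (see [size_factors()]).
#' @param offset positive offset added before the log (default 1).
#' @return An object of class `normalized_matrix`: list with `gene_ids`,
#'   `sample_ids`, the log2 `values` matrix and the `size_factors` used.
#' @export
normalize_log <- function(cm, s, offset = 1) {
  stopifnot(inherits(cm, "count_matrix"), offset > 0, all(s > 0),
            length(s) == length(cm$sample_ids))
  vals <- log2(sweep(cm$counts, 2, s, `/`) + offset)
  dimnames(vals) <- list(cm$gene_ids, cm$sample_ids)
  bl_log("normalize_log", sprintf("%d x %d normalized (offset %s)",
                                  nrow(vals), ncol(vals), offset))
  structure(list(gene_ids = cm$gene_ids, sample_ids = cm$sample_ids,
                 values = vals, size_factors = s),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples (log2 scale)\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Write / read a normalized matrix as TSV with a size-factor sidecar
#'
#' `write_normalized()` writes the log2 values as a TSV (first column
#' `gene_id`) plus a two-column sidecar file `<path>.size_factors.tsv`;
#' `read_normalized()` is its inverse.
#'
#' @param nm a `normalized_matrix`.
#' @param path path of the values TSV; the sidecar lives next to it.
#' @return `path` (writer) or the reconstructed `normalized_matrix` (reader).
#' @export
write_normalized <- function(nm, path) {
  stopifnot(inherits(nm, "normalized_matrix"))
  df <- data.frame(gene_id = nm$gene_ids,
                   format(nm$values, trim = TRUE, digits = 15),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", nm$sample_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sf <- data.frame(sample_id = nm$sample_ids,
                   size_factor = format(nm$size_factors, digits = 15))
  write.table(sf, paste0(path, ".size_factors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_normalized
#' @export
read_normalized <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sf <- read.delim(paste0(path, ".size_factors.tsv"),
                   stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- list(df$gene_id, colnames(df)[-1])
  structure(list(gene_ids = df$gene_id, sample_ids = colnames(df)[-1],
                 values = vals,
                 size_factors = setNames(as.numeric(sf$size_factor),
                                         sf$sample_id)),
            class = "normalized_matrix")
}

#' Filter and normalize a count matrix in one step
#'
#' Runs [filter_genes()], [size_factors()] (on the post-filter matrix) and
#' [normalize_log()] with the thresholds in `config`.
#'
#' @param cm a [count_matrix()].
#' @param config a [pipeline_config()].
#' @return A `normalized_matrix`.
#' @export
preprocess <- function(cm, config = pipeline_config()) {
  cm <- filter_genes(cm, config$filter_threshold)
  s <- size_factors(cm)
  normalize_log(cm, s, config$log_offset)
}
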