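#' Construct a validated count matrix
#'
#' A `count_matrix` is the entry point of the pipeline: a dense gene x sample
#' table of non-negative integer read counts, as produced by feature-level
#' read counting of a bulk RNA-seq experiment.
#'
#' @param counts numeric matrix of non-negative integers, genes in rows.
#' @param gene_ids character vector of unique gene identifiers (row names).
#' @param sample_ids character vector of unique sample identifiers (columns).
#' @return An object of class `count_matrix`: a list with elements
#'   `gene_ids`, `sample_ids` and the integer `counts` matrix.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(sample_ids))
    stop("count matrix dimensions do not match the id lists", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(counts)))
    stop("counts contain missing or non-finite values", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 gene_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 gene_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(gene_ids = gene_ids, sample_ids = sample_ids,
                 counts = counts),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a gene x sample count table from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids; all
#' remaining cells must be non-negative integers. The input gene order is
#' preserved.
#'
#' @param path path to a tab-separated counts file.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("counts file needs a gene id column and at least one sample",
                         call. = FALSE)
  gene_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  m <- matrix(NA_real_, nrow(df), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   df[[j + 1]][i], gene_ids[i], sample_ids[j]), call. = FALSE)
    }
    m[, j] <- v
  }
  cm <- count_matrix(m, gene_ids, sample_ids)
  bl_log("read_counts", sprintf("%d genes x %d samples from %s",
                                nrow(m), ncol(m), path))
  cm
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_counts()]: first column `gene_id`, one column per sample.
#'
#' @param cm a [count_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = cm$gene_ids,
                   format(cm$counts, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", cm$sample_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

DIAGNOSIS_LEVELS <- c("control", "UC", "CD")
AGE_GROUP_LEVELS <- c("adult", "child")

#' Construct a validated sample metadata table
#'
#' Per-sample phenotype labels: diagnosis (`control`, `UC`, `CD`), age group
#' (`adult`, `child`) and a disease activity grade on an integer 0 (remission)
#' to 4 (active flare) scale. Controls must carry activity 0.
#'
#' @param df data.frame with columns `sample_id`, `diagnosis`, `age_group`,
#'   `activity`.
#' @param counts optional [count_matrix()]; every sample id must then be
#'   present in it.
#' @return A `sample_table`: the validated data.frame.
#' @export
sample_table <- function(df, counts = NULL) {
  req <- c("sample_id", "diagnosis", "age_group", "activity")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$diagnosis <- as.character(df$diagnosis)
  df$age_group <- as.character(df$age_group)
  df$activity <- as.integer(df$activity)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  bad <- setdiff(unique(df$diagnosis), DIAGNOSIS_LEVELS)
  if (length(bad))
    stop("unknown diagnosis label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(DIAGNOSIS_LEVELS, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$age_group), AGE_GROUP_LEVELS)
  if (length(bad))
    stop("unknown age_group label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(AGE_GROUP_LEVELS, collapse = ", "), call. = FALSE)
  if (anyNA(df$activity) || any(df$activity < 0 | df$activity > 4))
    stop("activity grades must be integers in [0, 4]", call. = FALSE)
  off <- df$diagnosis == "control" & df$activity > 0
  if (any(off))
    stop("control sample(s) with nonzero activity: ",
         paste(df$sample_id[off], collapse = ", "), call. = FALSE)
  if (!is.null(counts)) {
    unknown <- setdiff(df$sample_id, counts$sample_ids)
    if (length(unknown))
      stop("sample(s) absent from the count matrix: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample metadata TSV
#'
#' @inheritParams sample_table
#' @param path path to a tab-separated metadata file with columns
#'   `sample_id`, `diagnosis`, `age_group`, `activity`.
#' @return A [sample_table()].
#' @export
read_samples <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  st <- sample_table(df, counts = counts)
  bl_log("read_samples", sprintf("%d samples from %s", nrow(st), path))
  st
}

#' Write a sample metadata table as TSV
#'
#' @param st a [sample_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(st, path) {
  write.table(as.data.frame(st), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
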