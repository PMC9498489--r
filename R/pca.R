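#' Scale genes to zero mean and unit variance
#'
#' Each gene row is centred and divided by its standard deviation (n - 1
#' denominator). Zero-variance genes cannot be scaled and are dropped with a
#' logged warning.
#'
#' @param nm a `normalized_matrix` (see [normalize_log()]) or a plain numeric
#'   matrix with genes in rows.
#' @return List with `values` (the scaled matrix) and `dropped` (ids of
#'   zero-variance genes removed).
#' @export
scale_genes <- function(nm) {
  m <- if (inherits(nm, "normalized_matrix")) nm$values else as.matrix(nm)
  if (ncol(m) < 2) stop("scaling requires at least 2 samples", call. = FALSE)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  keep <- sdv > 0
  if (!any(keep))
    stop("all genes have zero variance; nothing to scale", call. = FALSE)
  if (any(!keep)) {
    bl_log("scale_genes", sprintf("dropped %d zero-variance gene(s)",
                                  sum(!keep)))
    warning(sum(!keep), " zero-variance gene(s) dropped before PCA",
            call. = FALSE)
  }
  scaled <- (m[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  list(values = scaled, dropped = rownames(m)[!keep])
}

#' PCA loadings of a gene-scaled expression matrix
#'
#' Runs a principal component analysis with samples as observations and
#' genes as variables (the input is already per-gene centred and scaled, so
#' this is a PCA of the gene-gene correlation structure), via singular value
#' decomposition. Loadings are unit-norm; each component's sign is fixed so
#' its largest-magnitude loading is positive, making results deterministic
#' across linear-algebra backends.
#'
#' @param scaled genes x samples matrix from [scale_genes()].
#' @param n_pcs number of leading components to keep.
#' @return List of class `pca_loadings` with `loadings` (genes x PCs,
#'   rownames = gene ids), `pc_variance` (explained-variance fractions of
#'   the kept PCs) and `n_pcs` actually available.
#' @export
pca_loadings <- function(scaled, n_pcs) {
  g <- nrow(scaled); n <- ncol(scaled)
  stopifnot(n_pcs >= 1)
  sv <- svd(t(scaled))                       # samples x genes
  ev <- sv$d^2
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (rank < n_pcs) {
    warning("matrix rank ", rank, " < requested ", n_pcs,
            " components; returning ", rank, call. = FALSE)
    n_pcs <- rank
  }
  load <- sv$v[, seq_len(n_pcs), drop = FALSE]
  for (k in seq_len(n_pcs)) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) load[, k] <- -load[, k]
  }
  rownames(load) <- rownames(scaled)
  colnames(load) <- paste0("PC", seq_len(n_pcs))
  structure(list(loadings = load,
                 pc_variance = ev[seq_len(n_pcs)] / sum(ev),
                 n_pcs = n_pcs),
            class = "pca_loadings")
}

#' Select top transcripts by per-component squared-loading mass
#'
#' For each component independently, genes are ranked by squared loading
#' (descending, ties broken by input gene order) and the shortest prefix
#' whose squared-loading sum reaches `fraction` of that component's total
#' squared-loading mass is taken. The selection is the union over
#' components, in original gene order.
#'
#' @param pca_out a `pca_loadings` object.
#' @param fraction squared-loading mass fraction per PC, in (0, 1].
#' @param n_pcs number of components to use (at most those available).
#' @return Object of class `pca_selection`: list with `selected_gene_ids`,
#'   `per_pc_selected` (ordered gene list per PC), `loadings` and
#'   `pc_variance`.
#' @export
select_top_transcripts <- function(pca_out, fraction, n_pcs = pca_out$n_pcs) {
  stopifnot(inherits(pca_out, "pca_loadings"),
            fraction > 0, fraction <= 1)
  n_pcs <- min(n_pcs, pca_out$n_pcs)
  gene_ids <- rownames(pca_out$loadings)
  per_pc <- vector("list", n_pcs)
  names(per_pc) <- colnames(pca_out$loadings)[seq_len(n_pcs)]
  for (k in seq_len(n_pcs)) {
    sq <- pca_out$loadings[, k]^2
    total <- sum(sq)
    ord <- order(-sq, seq_along(sq))        # stable: ties by input order
    cum <- cumsum(sq[ord])
    take <- which(cum >= fraction * total - 1e-12)[1]
    per_pc[[k]] <- gene_ids[ord[seq_len(take)]]
  }
  union_ids <- gene_ids[gene_ids %in% unique(unlist(per_pc))]
  bl_log("select_top_transcripts",
         sprintf("%d of %d genes selected over %d PCs at fraction %s",
                 length(union_ids), length(gene_ids), n_pcs, fraction))
  structure(list(selected_gene_ids = union_ids, per_pc_selected = per_pc,
                 loadings = pca_out$loadings,
                 pc_variance = pca_out$pc_variance),
            class = "pca_selection")
}

#' @export
print.pca_selection <- function(x, ...) {
  cat(sprintf("pca_selection: %d genes over %d PCs (variance fractions %s)\n",
              length(x$selected_gene_ids), length(x$per_pc_selected),
              paste(signif(x$pc_variance, 3), collapse = ", ")))
  invisible(x)
}

#' Run the full PCA preselection stage
#'
#' Scales genes, computes the leading components and selects the top
#' transcripts capturing `config$pc_variance_fraction` of the squared-loading
#' mass in the first `config$n_pcs` components.
#'
#' @param nm a `normalized_matrix`, typically subset to the samples of one
#'   contrast.
#' @param config a [pipeline_config()].
#' @param sample_ids optional subset of samples to run the PCA on.
#' @return A `pca_selection`.
#' @export
pca_preselect <- function(nm, config = pipeline_config(),
                          sample_ids = NULL) {
  m <- nm$values
  if (!is.null(sample_ids)) m <- m[, sample_ids, drop = FALSE]
  sc <- scale_genes(m)
  pl <- pca_loadings(sc$values, config$n_pcs)
  select_top_transcripts(pl, config$pc_variance_fraction)
}

#' Serialize a PCA selection to TSV
#'
#' One row per (gene, PC): gene id, component, squared loading and whether
#' the gene is in that component's selected prefix.
#'
#' @param sel a `pca_selection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pca_selection <- function(sel, path) {
  stopifnot(inherits(sel, "pca_selection"))
  rows <- do.call(rbind, lapply(names(sel$per_pc_selected), function(pc) {
    data.frame(gene = rownames(sel$loadings), pc = pc,
               squared_loading = sel$loadings[, pc]^2,
               selected = rownames(sel$loadings) %in% sel$per_pc_selected[[pc]],
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
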