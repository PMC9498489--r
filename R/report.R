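#' Write a contrast report to disk
#'
#' Emits three files into `outdir`: `model.tsv` (gene, coefficient,
#' occurrence_n), `cv.tsv` (fold, lambda, auc, n_active, converged) and
#' `summary.json` (contrast, selected lambda, AUC with confidence bounds,
#' intercept, model size). Output is byte-stable for identical inputs.
#'
#' @param report a `cv_report` (see [finalize()] / [run_contrast()]).
#' @param outdir output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "cv_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.table(report$model_table, file.path(outdir, "model.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cv <- report$records[, c("fold", "lambda", "auc", "n_active", "converged")]
  write.table(cv, file.path(outdir, "cv.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(contrast = if (is.null(report$contrast)) NA
               else report$contrast,
               selected_lambda = report$selected_lambda,
               auc = report$final_auc,
               ci_lower = report$ci_lower, ci_upper = report$ci_upper,
               intercept = report$final_fit$intercept,
               n_genes = nrow(report$model_table))
  jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Read a contrast report back from disk
#'
#' Inverse of [write_report()].
#'
#' @param outdir directory written by [write_report()].
#' @return List with `model` and `cv` data.frames and the `summary` list.
#' @export
read_report <- function(outdir) {
  list(model = read.delim(file.path(outdir, "model.tsv"), sep = "\t",
                          stringsAsFactors = FALSE),
       cv = read.delim(file.path(outdir, "cv.tsv"), sep = "\t",
                       stringsAsFactors = FALSE),
       summary = jsonlite::read_json(file.path(outdir, "summary.json"),
                                     simplifyVector = TRUE))
}

#' Run all contrasts and write every report
#'
#' Runs [run_pipeline()] over the requested contrasts, writes one
#' subdirectory of outputs per contrast, and a cross-contrast
#' `occurrence_matrix.tsv` tallying, for every gene that entered any final
#' model, its occurrence count per contrast — the basis for ranking the most
#' consistently selected transcripts.
#'
#' @inheritParams run_pipeline
#' @param outdir root output directory.
#' @return The list of `cv_report`s, invisibly.
#' @export
run_all <- function(counts, samples, config = pipeline_config(),
                    outdir, contrasts = contrast_names()) {
  reports <- run_pipeline(counts, samples, config, contrasts)
  for (nme in names(reports))
    write_report(reports[[nme]], file.path(outdir, nme))
  genes <- sort(unique(unlist(lapply(reports, function(r)
    r$model_table$gene))))
  if (length(genes)) {
    occ <- sapply(reports, function(r) {
      v <- setNames(rep(0L, length(genes)), genes)
      in_model <- intersect(genes, r$model_table$gene)
      v[in_model] <- r$occurrence_counts[in_model]
      v
    })
    occ <- data.frame(gene = genes, occ, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(occ, file.path(outdir, "occurrence_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(reports)
}
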