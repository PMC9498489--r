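#' Built-in contrast names
#'
#' Twelve binary classification contrasts: IBD, UC and CD versus controls in
#' the full cohort and in adults and children separately (nine), plus active
#' disease versus grouped controls and remission patients overall, in UC and
#' in CD (three).
#'
#' @return Character vector of contrast names.
#' @export
contrast_names <- function() {
  c("IBD_vs_control", "UC_vs_control", "CD_vs_control",
    "IBD_vs_control_adults", "UC_vs_control_adults", "CD_vs_control_adults",
    "IBD_vs_control_children", "UC_vs_control_children",
    "CD_vs_control_children",
    "active_IBD", "active_UC", "active_CD")
}

#' Build the binary labels of a named contrast
#'
#' Diagnosis contrasts label the given diagnosis (or both, for IBD) as 1 and
#' controls as 0; `_adults` / `_children` variants first restrict both
#' classes to that age group. Active-disease contrasts label active cases
#' (activity grades 3-4) as 1 and the union of controls and remission cases
#' (grades 0-1) of the relevant diagnosis as 0; grade 2 is excluded by
#' default (`config$grade2_policy`).
#'
#' @param samples a [sample_table()].
#' @param name a contrast name from [contrast_names()].
#' @param config a [pipeline_config()] (only `grade2_policy` is used).
#' @return Object of class `contrast`: list with `name` and `labels`, a
#'   named 0/1 vector over the included samples in table order.
#' @export
build_contrast <- function(samples, name, config = pipeline_config()) {
  stopifnot(inherits(samples, "sample_table"))
  if (!name %in% contrast_names())
    stop("unknown contrast '", name, "'; see contrast_names()",
         call. = FALSE)
  active_gr <- if (config$grade2_policy == "active") 2:4 else 3:4
  remission_gr <- if (config$grade2_policy == "remission") 0:2 else 0:1
  diag <- samples$diagnosis
  act <- samples$activity

  if (grepl("^active_", name)) {
    dx <- sub("^active_", "", name)
    dx_set <- if (dx == "IBD") c("UC", "CD") else dx
    case <- diag %in% dx_set & act %in% active_gr
    ctrl <- diag == "control" | (diag %in% dx_set & act %in% remission_gr)
  } else {
    dx <- sub("_vs_control.*$", "", name)
    dx_set <- if (dx == "IBD") c("UC", "CD") else dx
    in_age <- if (grepl("_adults$", name)) samples$age_group == "adult"
              else if (grepl("_children$", name)) samples$age_group == "child"
              else rep(TRUE, nrow(samples))
    case <- in_age & diag %in% dx_set
    ctrl <- in_age & diag == "control"
  }
  if (!any(case)) stop("contrast '", name, "' has no case samples",
                       call. = FALSE)
  if (!any(ctrl)) stop("contrast '", name, "' has no control samples",
                       call. = FALSE)
  keep <- case | ctrl
  labels <- setNames(as.numeric(case[keep]), samples$sample_id[keep])
  bl_log("build_contrast", sprintf("%s: %d cases vs %d in class 0", name,
                                   sum(labels == 1), sum(labels == 0)))
  structure(list(name = name, labels = labels), class = "contrast")
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `n_folds` folds so that per-fold class
#' counts are within one sample of the global proportion; deterministic
#' given `seed`.
#'
#' @param labels named binary vector.
#' @param n_folds number of folds; each class must have at least this many
#'   members.
#' @param seed integer RNG seed.
#' @return Named integer vector of fold indices in 1..n_folds.
#' @export
assign_folds <- function(labels, n_folds, seed) {
  stopifnot(!is.null(names(labels)))
  tab <- table(labels)
  if (length(tab) < 2) stop("labels must contain both classes", call. = FALSE)
  if (any(tab < n_folds))
    stop(sprintf(
      "smallest class has %d samples < %d folds; use fewer folds",
      min(tab), n_folds), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- which(labels == as.numeric(cl))
    folds[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  setNames(folds, names(labels))
}

#' Mann-Whitney area under the ROC curve
#'
#' The probability that a uniformly chosen case outscores a uniformly chosen
#' control, with ties counted one half (rank-sum formulation).
#'
#' @param scores numeric scores (larger = more case-like).
#' @param labels binary vector, 1 = case.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the cross-validated lambda grid
#'
#' For each fold, features are standardized on the training samples only,
#' the full lambda path is fitted with warm starts from the largest to the
#' smallest penalty, and held-out AUC is computed from the projected test
#' samples. With `config$nested_preselection = TRUE` the PCA preselection is
#' additionally re-run inside each training fold (leakage-free variant);
#' otherwise the supplied contrast-level `selection` is used throughout.
#'
#' @param nm a `normalized_matrix` covering at least the labelled samples.
#' @param selection a `pca_selection` (from [pca_preselect()]).
#' @param labels named binary vector (1 = case).
#' @param config a [pipeline_config()].
#' @param folds optional precomputed fold assignment (defaults to
#'   [assign_folds()] with `config$rng_seed`).
#' @return Object of class `cv_grid`: `records` (data.frame with fold,
#'   lambda, auc, n_active, converged and a coefficient checksum),
#'   `active_sets` (per fold, per lambda character vectors of active gene
#'   ids), `folds`, `feature_ids` (the feature universe for occurrence
#'   counting) and `lambda_grid`.
#' @export
run_cv_grid <- function(nm, selection, labels, config = pipeline_config(),
                        folds = NULL) {
  lambdas <- config$lambda_grid
  if (is.null(folds))
    folds <- assign_folds(labels, config$n_folds, config$rng_seed)
  stopifnot(identical(sort(names(folds)), sort(names(labels))))
  ctl <- config[c("coef_tol", "kkt_tol", "max_outer", "max_inner")]
  t0 <- proc.time()[3]

  feature_universe <- selection$selected_gene_ids
  records <- list()
  active_sets <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    train <- names(folds)[folds != f]
    test <- names(folds)[folds == f]
    feats <- if (isTRUE(config$nested_preselection)) {
      ps <- pca_preselect(nm, config, sample_ids = pca_sample_set(
        labels[train], config))
      feature_universe <- union(feature_universe, ps$selected_gene_ids)
      ps$selected_gene_ids
    } else selection$selected_gene_ids
    d <- design_matrix(nm, feats, labels[train])
    path <- fit_lasso_path(d, lambdas, config$coef_lower, config$coef_upper,
                           control = ctl)
    Xte <- project_design(d, nm, test)
    active_sets[[f]] <- vector("list", length(lambdas))
    names(active_sets[[f]]) <- as.character(lambdas)
    for (k in seq_along(lambdas)) {
      fit <- path[[k]]
      act <- fit$feature_ids[abs(fit$beta) > 1e-8]
      active_sets[[f]][[k]] <- act
      scores <- predict_proba(fit, Xte)
      records[[length(records) + 1]] <- data.frame(
        fold = f, lambda = lambdas[k], auc = auc(scores, labels[test]),
        n_active = length(act), converged = fit$converged,
        beta_checksum = sum(fit$beta) + fit$intercept)
    }
  }
  records <- do.call(rbind, records)
  n_bad <- sum(!records$converged)
  if (n_bad > 0)
    bl_log("run_cv_grid", sprintf(
      "%d non-converged fit(s); excluded from lambda selection, kept for occurrences",
      n_bad))
  bl_log("run_cv_grid", sprintf("%d fits (%d folds x %d lambdas) in %.1fs",
                                nrow(records), config$n_folds,
                                length(lambdas), proc.time()[3] - t0))
  structure(list(records = records, active_sets = active_sets,
                 folds = folds, feature_ids = feature_universe,
                 lambda_grid = lambdas),
            class = "cv_grid")
}

# Sample set the preselection PCA runs on: the whole contrast subset by
# default, cases only when configured.
pca_sample_set <- function(labels, config) {
  if (isTRUE(config$pca_cases_only)) names(labels)[labels == 1]
  else names(labels)
}

#' Median-AUC lambda selection
#'
#' For each lambda, the median held-out AUC is computed over the folds with
#' non-null discriminative value (AUC strictly above
#' `config$auc_null_cutoff`); lambdas with no qualifying fold, and
#' non-converged fits, are ineligible. The selected lambda is the largest
#' eligible one whose median AUC is within `config$lambda_tolerance` of the
#' best median — the strongest shrinkage that costs essentially no
#' cross-validated precision.
#'
#' @param grid a `cv_grid`.
#' @param config a [pipeline_config()].
#' @return List with `selected_lambda` and `median_table` (data.frame of
#'   lambda, n_qualifying folds, median AUC over them).
#' @export
select_lambda <- function(grid, config = pipeline_config()) {
  rec <- grid$records[grid$records$converged, , drop = FALSE]
  med <- vapply(grid$lambda_grid, function(l) {
    a <- rec$auc[rec$lambda == l & rec$auc > config$auc_null_cutoff]
    if (!length(a)) NA_real_ else median(a)
  }, numeric(1))
  nq <- vapply(grid$lambda_grid, function(l)
    sum(rec$lambda == l & rec$auc > config$auc_null_cutoff), integer(1))
  tab <- data.frame(lambda = grid$lambda_grid, n_qualifying = nq,
                    median_auc = med)
  if (all(is.na(med)))
    stop("no lambda has any fold with AUC above the null cutoff; ",
         "AUC range observed: [",
         paste(signif(range(grid$records$auc), 3), collapse = ", "), "]",
         call. = FALSE)
  best <- max(med, na.rm = TRUE)
  ok <- which(!is.na(med) & med >= best - config$lambda_tolerance)
  sel <- grid$lambda_grid[max(ok)]
  bl_log("select_lambda", sprintf("lambda = %g (median AUC %.3f, best %.3f)",
                                  sel, med[max(ok)], best))
  list(selected_lambda = sel, median_table = tab)
}

#' Per-transcript occurrence counts
#'
#' Counts, over all (fold, lambda) models of the grid, how often each
#' feature carries a nonzero coefficient (`|beta| > 1e-8`) — the stability
#' score of the pipeline. Features never active get 0. The ceiling is
#' `n_folds * length(lambda_grid)` (400 at the default configuration).
#'
#' @param grid a `cv_grid`.
#' @return Named integer vector over the grid's feature universe.
#' @export
occurrence_counts <- function(grid) {
  counts <- setNames(integer(length(grid$feature_ids)), grid$feature_ids)
  for (f in seq_along(grid$active_sets))
    for (act in grid$active_sets[[f]]) {
      counts[act] <- counts[act] + 1L
    }
  counts
}

#' Final refit and model table
#'
#' Refits on all contrast samples at the selected lambda (warm-started along
#' the grid from above) and assembles the report: the active genes with
#' their coefficients sorted descending (strongest positive at the top,
#' strongest negative at the bottom) and occurrence counts; the final AUC as
#' the median of the held-out fold AUCs at the selected lambda; and a
#' fold-percentile confidence interval at `config$ci_level`.
#'
#' @param nm a `normalized_matrix`.
#' @param selection the contrast's `pca_selection`.
#' @param labels named binary vector.
#' @param selected_lambda the penalty chosen by [select_lambda()].
#' @param grid the `cv_grid` the selection was made from.
#' @param config a [pipeline_config()].
#' @return Object of class `cv_report`: `model_table` (gene, coefficient,
#'   occurrence_n), `final_fit`, `final_auc`, `ci_lower`, `ci_upper`,
#'   `selected_lambda`, `median_table`, `occurrence_counts`, `fold_aucs`,
#'   `records`.
#' @export
finalize <- function(nm, selection, labels, selected_lambda, grid,
                     config = pipeline_config()) {
  d <- design_matrix(nm, grid$feature_ids, labels)
  lam_path <- grid$lambda_grid[grid$lambda_grid >= selected_lambda]
  path <- fit_lasso_path(d, lam_path, config$coef_lower, config$coef_upper,
                         control = config[c("coef_tol", "kkt_tol",
                                            "max_outer", "max_inner")])
  final_fit <- path[[as.character(selected_lambda)]]
  occ <- occurrence_counts(grid)

  act <- final_fit$feature_ids[abs(final_fit$beta) > 1e-8]
  coefs <- final_fit$beta[act]
  ord <- order(-coefs, seq_along(coefs))
  model_table <- data.frame(gene = act[ord],
                            coefficient = unname(coefs[ord]),
                            occurrence_n = unname(occ[act[ord]]),
                            stringsAsFactors = FALSE)

  fold_aucs <- grid$records$auc[grid$records$lambda == selected_lambda]
  alpha <- (1 - config$ci_level) / 2
  ci <- unname(quantile(fold_aucs, c(alpha, 1 - alpha)))
  med_tab <- select_lambda(grid, config)$median_table
  structure(list(model_table = model_table, final_fit = final_fit,
                 final_auc = median(fold_aucs), ci_lower = ci[1],
                 ci_upper = ci[2], selected_lambda = selected_lambda,
                 median_table = med_tab, occurrence_counts = occ,
                 fold_aucs = fold_aucs, records = grid$records),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "cv_report: lambda = %g, AUC = %.2f (%.2f-%.2f), %d genes in model\n",
    x$selected_lambda, x$final_auc, x$ci_lower, x$ci_upper,
    nrow(x$model_table)))
  invisible(x)
}

#' Run the whole pipeline for one contrast
#'
#' Subsets the normalized matrix to the contrast samples, runs the PCA
#' preselection (on cases plus controls of the contrast by default), the
#' cross-validated lambda grid, the median-AUC lambda selection and the
#' final refit.
#'
#' @param nm a `normalized_matrix` of the full, preprocessed cohort.
#' @param samples a [sample_table()].
#' @param name a contrast name from [contrast_names()].
#' @param config a [pipeline_config()].
#' @return A `cv_report` with the contrast name attached as `$contrast`.
#' @export
run_contrast <- function(nm, samples, name, config = pipeline_config()) {
  ctr <- build_contrast(samples, name, config)
  labels <- ctr$labels
  tab <- table(labels)
  if (any(tab < config$n_folds))
    stop(sprintf(
      "contrast '%s': smallest class (%d) is below n_folds (%d)",
      name, min(tab), config$n_folds), call. = FALSE)
  selection <- pca_preselect(nm, config,
                             sample_ids = pca_sample_set(labels, config))
  grid <- run_cv_grid(nm, selection, labels, config)
  sel <- select_lambda(grid, config)
  rep <- finalize(nm, selection, labels, sel$selected_lambda, grid, config)
  rep$contrast <- name
  rep
}

#' Run the full pipeline over several contrasts
#'
#' Preprocesses the counts once (filter, size factors, offset log2) and runs
#' every requested contrast on the shared normalized matrix. Contrasts whose
#' classes are too small for the configured fold count are skipped with a
#' logged message.
#'
#' @param counts a [count_matrix()].
#' @param samples a [sample_table()] paired with it.
#' @param config a [pipeline_config()].
#' @param contrasts contrast names (default: all twelve built-ins).
#' @return Named list of `cv_report`s (skipped contrasts absent).
#' @export
run_pipeline <- function(counts, samples, config = pipeline_config(),
                         contrasts = contrast_names()) {
  nm <- preprocess(counts, config)
  out <- list()
  for (nme in contrasts) {
    rep <- tryCatch(run_contrast(nm, samples, nme, config),
                    error = function(e) {
                      bl_log("run_pipeline",
                             sprintf("skipping %s: %s", nme,
                                     conditionMessage(e)))
                      NULL
                    })
    if (!is.null(rep)) out[[nme]] <- rep
  }
  out
}
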