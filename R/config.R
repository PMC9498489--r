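#' Pipeline configuration
#'
#' Every tunable of the analysis is a configuration key, so a run with an
#' empty configuration file reproduces the reference analysis settings:
#' low-expression filter at total count 10, offset-one log2 transform,
#' loading-mass preselection on the first 3 principal components at 95%,
#' pure lasso (alpha = 1) with coefficient bounds of +/-0.1, a lambda grid
#' from 0.01 to 0.40 in steps of 0.01, ten-fold cross-validation, the
#' AUC > 0.5 null cutoff and a 90% confidence level.
#'
#' @param ... named overrides of the defaults listed below.
#' @return An object of class `pipeline_config` (a named list).
#'
#' @section Keys:
#' \describe{
#'   \item{filter_threshold}{genes with total count <= this are removed (10).}
#'   \item{log_offset}{offset added before log2 (1; keeps zeros at zero).}
#'   \item{n_pcs}{number of leading principal components used (3).}
#'   \item{pc_variance_fraction}{per-PC squared-loading mass captured (0.95).}
#'   \item{alpha}{elastic-net mixing; fixed at 1 (pure lasso).}
#'   \item{lambda_grid}{increasing penalty grid (0.01 ... 0.40 by 0.01).}
#'   \item{coef_lower, coef_upper}{coefficient box bounds (-0.1, 0.1).}
#'   \item{n_folds}{cross-validation folds (10).}
#'   \item{auc_null_cutoff}{folds with AUC at or below this are non-null
#'     discriminators and excluded from the median (0.5).}
#'   \item{lambda_tolerance}{AUC slack for the largest-lambda rule (0.01).}
#'   \item{ci_level}{confidence level for the fold-percentile interval (0.90).}
#'   \item{rng_seed}{seed for fold assignment (1).}
#'   \item{nested_preselection}{re-run the PCA preselection inside every
#'     training fold instead of once per contrast (FALSE).}
#'   \item{pca_cases_only}{run the preselection PCA on case samples only
#'     instead of cases plus controls (FALSE).}
#'   \item{grade2_policy}{how activity grade 2 is treated in active-disease
#'     contrasts: "exclude" (default), "active" or "remission".}
#'   \item{coef_tol, kkt_tol, max_outer, max_inner}{solver controls: maximum
#'     coefficient change 1e-7, KKT residual 1e-6, 200 outer IRLS and 10000
#'     coordinate iterations.}
#' }
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    filter_threshold = 10L,
    log_offset = 1,
    n_pcs = 3L,
    pc_variance_fraction = 0.95,
    alpha = 1,
    lambda_grid = round(seq(0.01, 0.40, by = 0.01), 10),
    coef_lower = -0.1,
    coef_upper = 0.1,
    n_folds = 10L,
    auc_null_cutoff = 0.5,
    lambda_tolerance = 0.01,
    ci_level = 0.90,
    rng_seed = 1L,
    nested_preselection = FALSE,
    pca_cases_only = FALSE,
    grade2_policy = "exclude",
    coef_tol = 1e-7,
    kkt_tol = 1e-6,
    max_outer = 200L,
    max_inner = 10000L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, key, msg)
    if (!ok) stop(sprintf("config key '%s': %s", key, msg), call. = FALSE)
  cfg$filter_threshold <- as.integer(cfg$filter_threshold)
  chk(cfg$filter_threshold >= 0, "filter_threshold", "must be >= 0")
  chk(is.numeric(cfg$log_offset) && cfg$log_offset > 0, "log_offset",
      "must be > 0")
  cfg$n_pcs <- as.integer(cfg$n_pcs)
  chk(cfg$n_pcs >= 1, "n_pcs", "must be >= 1")
  chk(cfg$pc_variance_fraction > 0 && cfg$pc_variance_fraction <= 1,
      "pc_variance_fraction", "must be in (0, 1]")
  chk(identical(as.numeric(cfg$alpha), 1), "alpha",
      "only the pure lasso (alpha = 1) is supported")
  lg <- as.numeric(cfg$lambda_grid)
  chk(length(lg) >= 1 && all(lg > 0), "lambda_grid", "must be positive")
  chk(all(diff(lg) > 0), "lambda_grid", "must be strictly increasing")
  cfg$lambda_grid <- lg
  chk(cfg$coef_lower < 0, "coef_lower", "must be negative")
  chk(cfg$coef_upper > 0, "coef_upper", "must be positive")
  cfg$n_folds <- as.integer(cfg$n_folds)
  chk(cfg$n_folds >= 2, "n_folds", "must be >= 2")
  chk(cfg$auc_null_cutoff >= 0 && cfg$auc_null_cutoff < 1, "auc_null_cutoff",
      "must be in [0, 1)")
  chk(cfg$lambda_tolerance >= 0, "lambda_tolerance", "must be >= 0")
  chk(cfg$ci_level > 0 && cfg$ci_level < 1, "ci_level", "must be in (0, 1)")
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  chk(is.logical(cfg$nested_preselection), "nested_preselection",
      "must be true/false")
  chk(is.logical(cfg$pca_cases_only), "pca_cases_only", "must be true/false")
  chk(cfg$grade2_policy %in% c("exclude", "active", "remission"),
      "grade2_policy", "must be one of exclude/active/remission")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration file
#'
#' Reads a flat TOML-style file of `key = value` lines (numbers, booleans,
#' quoted strings and one-line `[a, b, c]` arrays; `#` comments and
#' `[section]` headers are ignored). Missing keys take the defaults of
#' [pipeline_config()], so an empty file is the reference configuration.
#'
#' @param path path to the configuration file.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- parse_flat_toml(path)
  do.call(pipeline_config, vals)
}

# Minimal flat TOML-subset reader (no TOML parser is available to R here and
# the configuration is a flat key/value list).
parse_flat_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[.*\\]$", lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- parse_toml_value(val, key)
  }
  out
}

parse_toml_value <- function(val, key) {
  if (grepl("^\\[.*\\]$", val)) {
    items <- strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]]
    items <- trimws(items)
    items <- items[nzchar(items)]
    return(vapply(items, parse_toml_scalar, numeric(1), key = key,
                  USE.NAMES = FALSE))
  }
  if (val %in% c("true", "false")) return(val == "true")
  if (grepl("^\".*\"$|^'.*'$", val)) return(gsub("^[\"']|[\"']$", "", val))
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num))
    stop(sprintf("config key '%s': cannot parse value '%s'", key, val),
         call. = FALSE)
  num
}

parse_toml_scalar <- function(x, key) {
  num <- suppressWarnings(as.numeric(x))
  if (is.na(num))
    stop(sprintf("config key '%s': non-numeric array element '%s'", key, x),
         call. = FALSE)
  num
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (length(v) > 6)
      v <- paste0(paste(utils::head(v, 3), collapse = ", "), ", ..., ",
                  v[length(v)], " (", length(v), " values)")
    else v <- paste(v, collapse = ", ")
    cat(sprintf("  %-22s %s\n", k, v))
  }
  invisible(x)
}
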