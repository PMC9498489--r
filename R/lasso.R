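#' Build a standardized design matrix for classification
#'
#' Standardizes the selected genes over the given (training) samples to
#' per-feature mean 0 and standard deviation 1 (n - 1 denominator), keeping
#' the centring/scaling parameters for projecting held-out samples. Features
#' with (near) zero training variance are dropped.
#'
#' @param nm a `normalized_matrix`.
#' @param feature_ids gene ids to use as features.
#' @param labels named binary vector (1 = case) over the samples to include.
#' @return Object of class `design_matrix`: list with `X` (samples x
#'   features), `y`, `feature_ids`, `center`, `scale`.
#' @export
design_matrix <- function(nm, feature_ids, labels) {
  stopifnot(!is.null(names(labels)), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2)
    stop("labels must contain both classes", call. = FALSE)
  missing <- setdiff(feature_ids, nm$gene_ids)
  if (length(missing))
    stop("feature id(s) absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  X <- t(nm$values[feature_ids, names(labels), drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- scl > 1e-12
  X <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], `/`)
  structure(list(X = X, y = as.numeric(labels),
                 feature_ids = feature_ids[keep],
                 center = ctr[keep], scale = scl[keep]),
            class = "design_matrix")
}

#' Project new samples onto a fitted design
#'
#' Applies the training centring and scaling of `d` to held-out samples.
#'
#' @param d a [design_matrix()].
#' @param nm the `normalized_matrix` holding the new samples.
#' @param sample_ids ids of the samples to project.
#' @return Samples x features matrix on the training standardized scale.
#' @export
project_design <- function(d, nm, sample_ids) {
  X <- t(nm$values[d$feature_ids, sample_ids, drop = FALSE])
  sweep(sweep(X, 2, d$center), 2, d$scale, `/`)
}

#' Soft-thresholding operator
#'
#' The lasso coordinate-update kernel: `sign(z) * max(|z| - gamma, 0)`.
#'
#' @param z numeric input.
#' @param gamma non-negative threshold.
#' @return Thresholded value(s).
#' @export
soft_threshold <- function(z, gamma) {
  stopifnot(all(gamma >= 0))
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Fit box-constrained L1-penalized logistic regression
#'
#' Minimizes the penalized average negative log-likelihood
#' `(1/n) * sum_i [-y_i eta_i + log(1 + exp(eta_i))] + lambda * sum_j |beta_j|`
#' subject to `lower <= beta_j <= upper`, with `eta_i = beta0 + x_i . beta`
#' and an unpenalized, unconstrained intercept. The solver is iteratively
#' reweighted least squares with inner cyclic coordinate descent; each
#' coordinate update is the soft-threshold solution of the weighted
#' quadratic subproblem clipped to the box, and a step-halving safeguard
#' keeps the objective non-increasing. Non-convergence within the iteration
#' budget yields a warning, never an error.
#'
#' @param d a [design_matrix()] (features standardized on the training set).
#' @param lambda non-negative L1 penalty weight.
#' @param lower,upper coefficient box bounds, `lower < 0 < upper`.
#' @param warm_start optional `lasso_fit` used to initialize the
#'   coefficients (warm start along a lambda path).
#' @param control list of solver controls: `coef_tol` (1e-7), `kkt_tol`
#'   (1e-6), `max_outer` (200), `max_inner` (10000).
#' @return Object of class `lasso_fit`: `intercept`, named `beta` (all
#'   within the box), `lambda`, `n_iter`, `converged`, `max_kkt_violation`,
#'   `objective`.
#' @export
fit_bounded_lasso <- function(d, lambda, lower = -0.1, upper = 0.1,
                              warm_start = NULL, control = list()) {
  stopifnot(inherits(d, "design_matrix"), lambda >= 0, lower < 0, upper > 0)
  ctl <- list(coef_tol = 1e-7, kkt_tol = 1e-6, max_outer = 200L,
              max_inner = 10000L)
  ctl[names(control)] <- control
  p <- ncol(d$X)
  if (is.null(warm_start)) {
    b0 <- qlogis(mean(d$y))
    beta <- rep(0, p)
  } else {
    b0 <- warm_start$intercept
    beta <- unname(warm_start$beta)
    stopifnot(length(beta) == p)
  }
  res <- .cd_bounded_logistic(d$X, d$y, lambda, lower, upper, b0, beta,
                              ctl$coef_tol, ctl$kkt_tol,
                              as.integer(ctl$max_outer),
                              as.integer(ctl$max_inner))
  if (!res$converged)
    warning(sprintf("lasso fit at lambda = %g did not converge (KKT %.2e)",
                    lambda, res$max_kkt_violation), call. = FALSE)
  structure(list(intercept = res$intercept,
                 beta = setNames(res$beta, d$feature_ids),
                 lambda = lambda, n_iter = res$n_iter,
                 converged = res$converged,
                 max_kkt_violation = res$max_kkt_violation,
                 objective = res$objective,
                 feature_ids = d$feature_ids),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf(
    "lasso_fit: lambda = %g, %d/%d active, intercept %.4f, %sconverged\n",
    x$lambda, sum(abs(x$beta) > 1e-8), length(x$beta), x$intercept,
    if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Fit a warm-started path over a lambda grid
#'
#' Fits from the largest to the smallest lambda, warm-starting each fit from
#' the previous solution.
#'
#' @inheritParams fit_bounded_lasso
#' @param lambdas lambda values (any order; fitted descending).
#' @return List of `lasso_fit` objects named by lambda, in the input order
#'   of `lambdas`.
#' @export
fit_lasso_path <- function(d, lambdas, lower = -0.1, upper = 0.1,
                           control = list()) {
  ord <- order(lambdas, decreasing = TRUE)
  fits <- vector("list", length(lambdas))
  warm <- NULL
  for (i in ord) {
    fits[[i]] <- suppressWarnings(
      fit_bounded_lasso(d, lambdas[i], lower, upper, warm_start = warm,
                        control = control))
    warm <- fits[[i]]
  }
  names(fits) <- as.character(lambdas)
  fits
}

#' Smallest lambda with an all-zero solution
#'
#' Returns `max_j |(1/n) x_j^T (y - mean(y))|`: with the intercept at
#' `logit(mean(y))`, the zero coefficient vector satisfies the KKT
#' conditions exactly for all `lambda >=` this value.
#'
#' @param d a [design_matrix()].
#' @return The critical penalty value.
#' @export
lambda_max <- function(d) {
  r <- d$y - mean(d$y)
  max(abs(crossprod(d$X, r)) / length(d$y))
}

#' Check first-order (KKT) optimality of a fit
#'
#' With `g_j = (1/n) x_j^T (p - y)` the smooth-loss gradient at the fit:
#' a zero coefficient requires `|g_j| <= lambda`; an interior nonzero
#' coefficient requires `g_j + lambda * sign(beta_j) = 0`; a coefficient at
#' a bound is violated only if the subgradient points inward. The intercept
#' gradient must vanish.
#'
#' @param d a [design_matrix()].
#' @param fit a `lasso_fit`.
#' @param lower,upper the box bounds the fit was computed under.
#' @return Maximum violation (non-negative scalar).
#' @export
kkt_check <- function(d, fit, lower = -0.1, upper = 0.1) {
  n <- nrow(d$X)
  eta <- fit$intercept + drop(d$X %*% fit$beta)
  p <- plogis(eta)
  g <- drop(crossprod(d$X, p - d$y)) / n
  lam <- fit$lambda
  beta <- unname(fit$beta)
  v <- numeric(length(beta))
  at_zero <- abs(beta) <= 1e-12
  at_up <- beta >= upper - 1e-10
  at_lo <- beta <= lower + 1e-10
  interior <- !at_zero & !at_up & !at_lo
  v[at_zero] <- pmax(abs(g[at_zero]) - lam, 0)
  v[at_up] <- pmax(g[at_up] + lam, 0)
  v[at_lo] <- pmax(lam - g[at_lo], 0)
  v[interior] <- abs(g[interior] + lam * sign(beta[interior]))
  max(c(v, abs(sum(p - d$y)) / n))
}

#' Predict class probabilities from a lasso fit
#'
#' @param fit a `lasso_fit`.
#' @param newX samples x features matrix on the training standardized scale
#'   (a [design_matrix()]'s `X` or a [project_design()] result). Column
#'   names, when present, must match the fit's features.
#' @return Per-sample probabilities in (0, 1).
#' @export
predict_proba <- function(fit, newX) {
  if (inherits(newX, "design_matrix")) newX <- newX$X
  if (!is.null(colnames(newX)) &&
      !identical(colnames(newX), fit$feature_ids))
    stop("feature ids of the new data do not match the fit", call. = FALSE)
  if (ncol(newX) != length(fit$beta))
    stop("feature count mismatch", call. = FALSE)
  plogis(fit$intercept + drop(newX %*% unname(fit$beta)))
}

#' Write / read a lasso fit as JSON
#'
#' Serializes the feature ids, coefficients, penalty and solver diagnostics.
#'
#' @param fit a `lasso_fit`.
#' @param path output JSON path.
#' @return `path` (writer) or the reconstructed `lasso_fit` (reader).
#' @export
write_lasso_fit <- function(fit, path) {
  stopifnot(inherits(fit, "lasso_fit"))
  jsonlite::write_json(
    list(feature_ids = fit$feature_ids, beta = unname(fit$beta),
         intercept = fit$intercept, lambda = fit$lambda,
         n_iter = fit$n_iter, converged = fit$converged,
         max_kkt_violation = fit$max_kkt_violation,
         objective = fit$objective),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lasso_fit
#' @export
read_lasso_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = x$intercept,
                 beta = setNames(as.numeric(x$beta), x$feature_ids),
                 lambda = x$lambda, n_iter = x$n_iter,
                 converged = x$converged,
                 max_kkt_violation = x$max_kkt_violation,
                 objective = x$objective, feature_ids = x$feature_ids),
            class = "lasso_fit")
}

# Penalized objective at a fit, for diagnostics and tests.
lasso_objective <- function(d, fit) {
  eta <- fit$intercept + drop(d$X %*% unname(fit$beta))
  log1pexp <- ifelse(eta > 35, eta, log1p(exp(pmin(eta, 35))))
  mean(-d$y * eta + log1pexp) + fit$lambda * sum(abs(fit$beta))
}
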