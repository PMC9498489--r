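test_that("soft thresholding follows the closed form", {
  expect_equal(soft_threshold(0.5, 0.2), 0.3)
  expect_identical(soft_threshold(-0.1, 0.2), 0)
  expect_equal(soft_threshold(-0.7, 0.2), -0.5)
  expect_equal(soft_threshold(c(-1, 0, 2), 0.5), c(-0.5, 0, 1.5))
})

test_that("design matrices standardize on the training samples", {
  set.seed(81)
  m <- matrix(rnorm(10 * 12, mean = 5), 10, 12,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  nm <- structure(list(gene_ids = rownames(m), sample_ids = colnames(m),
                       values = m, size_factors = rep(1, 12)),
                  class = "normalized_matrix")
  labels <- setNames(rep(c(1, 0), each = 4), paste0("s", 1:8))
  d <- design_matrix(nm, paste0("g", 1:10), labels)
  expect_true(all(abs(colMeans(d$X)) < 1e-8))
  expect_true(all(abs(apply(d$X, 2, sd) - 1) < 1e-8))
  # held-out projection uses the training parameters
  Xte <- project_design(d, nm, paste0("s", 9:12))
  expect_equal(Xte[1, 1],
               unname((m["g1", "s9"] - d$center[1]) / d$scale[1]))
  expect_error(design_matrix(nm, "g99", labels), "absent")
  expect_error(design_matrix(nm, "g1", setNames(rep(1, 4), paste0("s", 1:4))),
               "both classes")
})

test_that("lambda_max matches its closed form and zeroes the solution", {
  # single +/-1 feature aligned with balanced labels: (1/n) sum |x (y-1/2)|
  y <- rep(c(1, 0), each = 10)
  x <- ifelse(y == 1, 1, -1)
  d <- make_design(cbind(x), y)
  expect_equal(lambda_max(d), 0.5)
  # a feature orthogonal to y - mean(y) contributes nothing
  x2 <- rep(c(1, -1), 10)
  expect_equal(lambda_max(make_design(cbind(x2), y)), 0)

  fit <- fit_bounded_lasso(d, 1.01 * lambda_max(d))
  expect_identical(unname(fit$beta), 0)
  expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 1e-7)
  expect_lte(kkt_check(d, fit), 1e-8)
})

test_that("a separating feature pins its coefficient at the upper bound", {
  y <- rep(c(1, 0), each = 10)
  x <- scale(ifelse(y == 1, 1, -1))[, 1]
  d <- make_design(cbind(x), y)
  fit <- fit_bounded_lasso(d, 0.01, lower = -0.1, upper = 0.1)
  expect_equal(unname(fit$beta), 0.1, tolerance = 1e-8)

  # 1-D grid-search oracle over beta in [-0.1, 0.1] (step 1e-4), intercept
  # profiled out by 1-D optimization
  betas <- seq(-0.1, 0.1, by = 1e-4)
  prof <- vapply(betas, function(b) {
    optimize(function(b0) pg_objective(cbind(x), y, b0, b, 0.01),
             c(-5, 5), tol = 1e-10)$objective
  }, numeric(1))
  expect_equal(betas[which.min(prof)], 0.1)
})

test_that("coordinate descent matches the projected-gradient oracle", {
  set.seed(91)
  X <- matrix(rnorm(40 * 3), 40, 3)
  X <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), `/`)
  y <- rbinom(40, 1, plogis(X %*% c(1, -0.5, 0.2)))
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  d <- make_design(X, y)
  for (lam in c(0.01, 0.05, 0.2)) {
    fit <- fit_bounded_lasso(d, lam)
    ora <- pg_bounded_lasso(X, y, lam)
    expect_lt(abs(fit$objective - ora$objective), 1e-6)
    expect_lt(max(abs(unname(fit$beta) - ora$beta)), 1e-3)
    expect_lt(abs(fit$intercept - ora$intercept), 1e-3)
  }
})

test_that("fits agree with the reference penalized-regression package", {
  skip_if_not_installed("glmnet")
  set.seed(92)
  X <- matrix(rnorm(60 * 20), 60, 20)
  X <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), `/`)
  y <- rbinom(60, 1, plogis(X %*% c(rep(0.8, 4), rep(0, 16))))
  d <- make_design(X, y)
  for (lam in c(0.02, 0.1)) {
    fit <- fit_bounded_lasso(d, lam)
    gn <- glmnet::glmnet(X, y, family = "binomial", alpha = 1, lambda = lam,
                         lower.limits = -0.1, upper.limits = 0.1,
                         standardize = FALSE, thresh = 1e-14)
    expect_lt(max(abs(unname(fit$beta) - as.numeric(gn$beta))), 2e-3)
    expect_lt(abs(fit$intercept - gn$a0), 2e-3)
  }
})

test_that("every fit is feasible and converged fits certify KKT", {
  for (s in 1:20) {
    d <- rand_instance(100 + s)
    lam <- sample(seq(0.01, 0.4, by = 0.01), 1)
    fit <- fit_bounded_lasso(d, lam)
    expect_true(all(fit$beta >= -0.1 - 1e-12 & fit$beta <= 0.1 + 1e-12))
    if (fit$converged) expect_lt(kkt_check(d, fit), 1e-6)
    expect_equal(fit$max_kkt_violation, kkt_check(d, fit), tolerance = 1e-9)
  }
})

test_that("perturbing an interior coefficient breaks the KKT certificate", {
  set.seed(93)
  X <- matrix(rnorm(50 * 3), 50, 3)
  X <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), `/`)
  y <- rbinom(50, 1, plogis(X %*% c(0.6, -0.4, 0)))
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  d <- make_design(X, y)
  fit <- fit_bounded_lasso(d, 0.02)
  interior <- which(abs(fit$beta) > 1e-8 & abs(fit$beta) < 0.1 - 1e-8)
  expect_gt(length(interior), 0)
  base <- kkt_check(d, fit)
  fit$beta[interior[1]] <- fit$beta[interior[1]] + 0.05
  expect_gt(kkt_check(d, fit), max(base * 10, 1e-4))
})

test_that("warm-started paths never do worse than the null model", {
  d <- rand_instance(777, n_max = 50)
  lambdas <- seq(0.01, 0.4, by = 0.01)
  path <- fit_lasso_path(d, lambdas)
  null_fit <- list(intercept = qlogis(mean(d$y)),
                   beta = setNames(rep(0, ncol(d$X)), d$feature_ids))
  for (k in seq_along(lambdas)) {
    null_obj <- pg_objective(d$X, d$y, null_fit$intercept,
                             unname(null_fit$beta), lambdas[k])
    expect_lte(path[[k]]$objective, null_obj + 1e-10)
  }
  # support is empty beyond lambda_max
  lm <- lambda_max(d)
  for (k in which(lambdas >= lm))
    expect_identical(sum(abs(path[[k]]$beta)), 0)
})

test_that("lasso fits round-trip through JSON", {
  d <- rand_instance(66)
  fit <- fit_bounded_lasso(d, 0.03)
  f <- withr::local_tempfile(fileext = ".json")
  write_lasso_fit(fit, f)
  back <- read_lasso_fit(f)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$intercept, fit$intercept)
  expect_identical(back$lambda, fit$lambda)
  expect_identical(back$converged, fit$converged)
  expect_equal(back$objective, fit$objective)
})

test_that("probability predictions are consistent with the objective", {
  d <- rand_instance(55)
  fit <- fit_bounded_lasso(d, 0.05)
  p <- predict_proba(fit, d)
  expect_true(all(p > 0 & p < 1))
  eta <- fit$intercept + drop(d$X %*% unname(fit$beta))
  expect_equal(p, plogis(eta))
  obj <- mean(-d$y * eta + log1p(exp(eta))) + 0.05 * sum(abs(fit$beta))
  expect_equal(obj, fit$objective, tolerance = 1e-8)
  # degenerate fit: no signal, intercept zero -> probability one half
  fit0 <- fit
  fit0$beta[] <- 0; fit0$intercept <- 0
  expect_true(all(predict_proba(fit0, d) == 0.5))
  expect_error(predict_proba(fit, d$X[, -1, drop = FALSE]), "mismatch")
})
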