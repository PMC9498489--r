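# Independent oracles and fixture builders shared across the suite.
# The oracles deliberately avoid the package's solver path: the AUC oracle is
# a pairwise enumeration, the lasso oracle is accelerated projected proximal
# gradient on the same objective, and small worked examples are built by
# hand.

options(boxlasso.quiet = TRUE)

# O(n^2) pairwise Mann-Whitney AUC, ties counted one half
bf_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  s <- 0
  for (a in cs) for (b in ct) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cs) * length(ct))
}

pg_objective <- function(X, y, b0, beta, lambda) {
  eta <- b0 + drop(X %*% beta)
  l1p <- ifelse(eta > 35, eta, log1p(exp(pmin(eta, 35))))
  mean(-y * eta + l1p) + lambda * sum(abs(beta))
}

# Projected proximal-gradient (FISTA with adaptive restart) solver for the
# box-constrained L1 logistic objective; independent of the coordinate
# descent implementation under test.
pg_bounded_lasso <- function(X, y, lambda, lower = -0.1, upper = 0.1,
                             max_iter = 100000, step_tol = 1e-13) {
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(1, X)
  L <- max(eigen(crossprod(Xa) / (4 * n), symmetric = TRUE,
                 only.values = TRUE)$values)
  tt <- 1 / L
  b <- c(qlogis(mean(y)), rep(0, p))
  zb <- b; th <- 1
  f_old <- pg_objective(X, y, b[1], b[-1], lambda)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% zb)
    g <- drop(crossprod(Xa, plogis(eta) - y)) / n
    bn <- zb - tt * g
    bn[-1] <- pmin(pmax(sign(bn[-1]) * pmax(abs(bn[-1]) - tt * lambda, 0),
                        lower), upper)
    th_n <- (1 + sqrt(1 + 4 * th^2)) / 2
    zb <- bn + ((th - 1) / th_n) * (bn - b)
    f_new <- pg_objective(X, y, bn[1], bn[-1], lambda)
    if (f_new > f_old) { zb <- bn; th_n <- 1 }   # adaptive restart
    done <- sqrt(sum((bn - b)^2)) < step_tol
    b <- bn; th <- th_n; f_old <- f_new
    if (done) break
  }
  list(intercept = b[1], beta = b[-1],
       objective = pg_objective(X, y, b[1], b[-1], lambda))
}

# wrap a raw standardized matrix as a design_matrix without re-scaling
make_design <- function(X, y, feature_ids = paste0("f", seq_len(ncol(X)))) {
  structure(list(X = X, y = as.numeric(y), feature_ids = feature_ids,
                 center = rep(0, ncol(X)), scale = rep(1, ncol(X))),
            class = "design_matrix")
}

# random small standardized classification instance
rand_instance <- function(seed, n_max = 50, p_max = 3) {
  set.seed(seed)
  n <- sample(10:n_max, 1)
  p <- sample(seq_len(p_max), 1)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), `/`)
  y <- rbinom(n, 1, plogis(drop(X %*% runif(p, -1.5, 1.5)) +
                             rnorm(1, 0, 0.5)))
  if (length(unique(y)) < 2) { y[1] <- 0; y[2] <- 1 }
  make_design(X, y)
}

# small count fixture: 3 genes x 2 samples
tiny_counts <- function() {
  count_matrix(matrix(c(1, 2, 1, 2, 1, 2), 3, 2, byrow = TRUE),
               gene_ids = c("g1", "g2", "g3"), sample_ids = c("s1", "s2"))
}

# hand-built cv_grid for rule-application tests
toy_cv_grid <- function(records, active_sets, feature_ids, lambda_grid) {
  structure(list(records = records, active_sets = active_sets,
                 folds = NULL, feature_ids = feature_ids,
                 lambda_grid = lambda_grid),
            class = "cv_grid")
}
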