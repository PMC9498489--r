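make_samples <- function() {
  sample_table(data.frame(
    sample_id = sprintf("s%02d", 1:24),
    diagnosis = rep(c("control", "UC", "CD"), each = 8),
    age_group = rep(c("adult", "child"), 12),
    activity = c(rep(0, 8), rep(c(0, 1, 3, 4), 2), rep(c(0, 1, 3, 4), 2))))
}

test_that("diagnosis contrasts pick the right classes and age groups", {
  st <- make_samples()
  uc <- build_contrast(st, "UC_vs_control")
  expect_setequal(names(uc$labels)[uc$labels == 1],
                  st$sample_id[st$diagnosis == "UC"])
  expect_setequal(names(uc$labels)[uc$labels == 0],
                  st$sample_id[st$diagnosis == "control"])
  expect_false(any(st$sample_id[st$diagnosis == "CD"] %in% names(uc$labels)))

  kids <- build_contrast(st, "IBD_vs_control_children")
  expect_true(all(st$age_group[match(names(kids$labels),
                                     st$sample_id)] == "child"))
  expect_identical(sum(kids$labels == 1), 8L)  # all UC+CD children

  expect_error(build_contrast(st, "bogus"), "unknown contrast")
})

test_that("active contrasts pool controls with remission patients", {
  st <- make_samples()
  act <- build_contrast(st, "active_IBD")
  lab <- act$labels
  df <- st[match(names(lab), st$sample_id), ]
  expect_true(all(df$activity[lab == 1] >= 3))
  expect_true(all(df$diagnosis[lab == 1] != "control"))
  # class 0 = controls plus grade 0-1 patients; grade 2 excluded entirely
  expect_true(all(df$diagnosis[lab == 0] == "control" |
                    df$activity[lab == 0] <= 1))
  expect_false(any(st$sample_id[st$activity == 2] %in% names(lab)))

  # all cases active -> class 0 is controls only
  st2 <- st
  st2$activity[st2$diagnosis != "control"] <- 3L
  act2 <- build_contrast(st2, "active_UC")
  expect_true(all(st2$diagnosis[match(names(act2$labels)[act2$labels == 0],
                                      st2$sample_id)] == "control"))

  # no active cases at all -> empty case class
  st3 <- st
  st3$activity[st3$diagnosis != "control"] <- 0L
  expect_error(build_contrast(st3, "active_CD"), "no case samples")
})

test_that("fold assignment is stratified, exact and deterministic", {
  lab <- setNames(rep(c(1, 0), c(50, 50)), sprintf("x%03d", 1:100))
  f <- assign_folds(lab, 10, seed = 4)
  per <- table(f, lab)
  expect_true(all(per == 5))

  lab2 <- setNames(rep(c(1, 0), c(52, 48)), sprintf("x%03d", 1:100))
  f2 <- assign_folds(lab2, 10, seed = 4)
  per2 <- table(f2, lab2)
  expect_true(all(per2[, "1"] %in% 5:6) && all(per2[, "0"] %in% 4:5))

  expect_identical(f, assign_folds(lab, 10, seed = 4))
  expect_false(identical(f, assign_folds(lab, 10, seed = 5)))
  expect_error(assign_folds(lab, 60, seed = 1), "fewer folds")
})

test_that("AUC equals the pairwise probability with ties at one half", {
  expect_identical(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auc(c(0.3, 0.7), c(1, 0)), 0)
  expect_equal(auc(c(0.9, 0.5, 0.5, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_error(auc(c(1, 2), c(1, 1)), "both classes")
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) lb[1:2] <- 0:1
    expect_equal(auc(sc, lb), bf_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("lambda selection follows the largest-within-tolerance rule", {
  rec <- expand.grid(fold = 1:3, lambda = c(0.1, 0.2, 0.3))
  rec$auc <- c(0.80, 0.85, 0.90,   # lambda 0.1 -> median 0.85
               0.84, 0.85, 0.86,   # lambda 0.2 -> median 0.85
               0.79, 0.80, 0.81)   # lambda 0.3 -> median 0.80
  rec$converged <- TRUE
  grid <- toy_cv_grid(rec, list(), "g1", c(0.1, 0.2, 0.3))
  cfg <- pipeline_config(lambda_tolerance = 0.01)
  out <- select_lambda(grid, cfg)
  expect_identical(out$selected_lambda, 0.2)
  expect_equal(out$median_table$median_auc, c(0.85, 0.85, 0.80))

  # folds at or below the null cutoff are dropped from the median
  rec2 <- data.frame(fold = 1:3, lambda = 0.1, auc = c(0.4, 0.6, 0.8),
                     converged = TRUE)
  grid2 <- toy_cv_grid(rec2, list(), "g1", 0.1)
  out2 <- select_lambda(grid2, cfg)
  expect_identical(out2$selected_lambda, 0.1)
  expect_equal(out2$median_table$median_auc, 0.7)
  expect_identical(out2$median_table$n_qualifying, 2L)

  # a lambda with no qualifying fold is ineligible
  rec3 <- data.frame(fold = rep(1:2, 2), lambda = rep(c(0.1, 0.2), each = 2),
                     auc = c(0.9, 0.8, 0.45, 0.5), converged = TRUE)
  grid3 <- toy_cv_grid(rec3, list(), "g1", c(0.1, 0.2))
  expect_identical(select_lambda(grid3, cfg)$selected_lambda, 0.1)

  # nothing above the cutoff anywhere -> informative error
  rec4 <- data.frame(fold = 1:2, lambda = 0.1, auc = c(0.3, 0.5),
                     converged = TRUE)
  expect_error(select_lambda(toy_cv_grid(rec4, list(), "g1", 0.1), cfg),
               "null cutoff")
})

test_that("occurrence counts equal a hand tally of active sets", {
  active <- list(
    list("0.1" = c("gA", "gB"), "0.2" = "gA"),
    list("0.1" = c("gA", "gC"), "0.2" = character(0)))
  grid <- toy_cv_grid(data.frame(), active, c("gA", "gB", "gC", "gD"),
                      c(0.1, 0.2))
  occ <- occurrence_counts(grid)
  expect_identical(occ, c(gA = 3L, gB = 1L, gC = 1L, gD = 0L))
})

test_that("the cv grid covers folds x lambdas and null fits score 0.5", {
  sp <- simulation_spec(n_genes = 150, n_cases = 25, n_controls = 25,
                        n_signal_genes = 5, n_blocks = 2, block_size = 10,
                        seed = 19)
  ds <- simulate_dataset(sp)
  cfg <- pipeline_config(n_folds = 5, rng_seed = 2)
  nm <- preprocess(ds$counts, cfg)
  ct <- build_contrast(ds$samples, "IBD_vs_control", cfg)
  sel <- pca_preselect(nm, cfg, sample_ids = names(ct$labels))
  grid <- run_cv_grid(nm, sel, ct$labels, cfg)
  expect_identical(nrow(grid$records), 5L * 40L)
  expect_identical(sort(unique(grid$records$fold)), 1:5)
  # empty active set -> constant scores -> ties-at-half AUC of exactly 0.5
  empty <- grid$records$n_active == 0
  if (any(empty)) expect_true(all(grid$records$auc[empty] == 0.5))
  # occurrence counts never exceed the (fold x lambda) ceiling
  occ <- occurrence_counts(grid)
  expect_true(all(occ >= 0 & occ <= 5 * 40))
})

test_that("held-out samples never influence training fits", {
  sp <- simulation_spec(n_genes = 100, n_cases = 20, n_controls = 20,
                        n_signal_genes = 5, n_blocks = 0, block_size = 0,
                        seed = 29)
  ds <- simulate_dataset(sp)
  cfg <- pipeline_config(n_folds = 4, rng_seed = 7,
                         lambda_grid = c(0.02, 0.05, 0.1, 0.2))
  nm <- preprocess(ds$counts, cfg)
  ct <- build_contrast(ds$samples, "IBD_vs_control", cfg)
  sel <- pca_preselect(nm, cfg, sample_ids = names(ct$labels))
  folds <- assign_folds(ct$labels, cfg$n_folds, cfg$rng_seed)
  grid <- run_cv_grid(nm, sel, ct$labels, cfg, folds = folds)

  flip <- names(folds)[folds == 2][1]      # flip one fold-2 test label
  labs2 <- ct$labels
  labs2[flip] <- 1 - labs2[flip]
  grid2 <- run_cv_grid(nm, sel, labs2, cfg, folds = folds)

  r1 <- grid$records; r2 <- grid2$records
  in2 <- r1$fold == 2
  # fold-2 training data is unchanged: identical fits, different AUC
  expect_identical(r1$beta_checksum[in2], r2$beta_checksum[in2])
  expect_false(all(r1$auc[in2] == r2$auc[in2]))
  expect_identical(lapply(grid$active_sets[[2]], identity),
                   lapply(grid2$active_sets[[2]], identity))
})

test_that("permuted labels give near-chance AUC across the grid", {
  sp <- simulation_spec(n_genes = 150, n_cases = 50, n_controls = 50,
                        n_signal_genes = 10, n_blocks = 2, block_size = 10,
                        seed = 37)
  ds <- simulate_dataset(sp)
  cfg <- pipeline_config(n_folds = 5, rng_seed = 3)
  nm <- preprocess(ds$counts, cfg)
  ct <- build_contrast(ds$samples, "IBD_vs_control", cfg)
  sel <- pca_preselect(nm, cfg, sample_ids = names(ct$labels))
  set.seed(101)
  labs <- setNames(sample(ct$labels), names(ct$labels))
  grid <- run_cv_grid(nm, sel, labs, cfg)
  med <- tapply(grid$records$auc, grid$records$lambda, median)
  expect_true(all(med >= 0.3 & med <= 0.7))
})

test_that("reports are well formed, recoverable and byte-stable", {
  sp <- simulation_spec(n_genes = 200, n_cases = 30, n_controls = 30,
                        n_signal_genes = 10, n_blocks = 2, block_size = 10,
                        seed = 43)
  ds <- simulate_dataset(sp)
  cfg <- pipeline_config(n_folds = 5, rng_seed = 11)
  rep1 <- run_pipeline(ds$counts, ds$samples, cfg,
                       contrasts = "IBD_vs_control")$IBD_vs_control

  expect_true(all(abs(rep1$model_table$coefficient) <= cfg$coef_upper + 1e-12))
  expect_true(all(rep1$model_table$occurrence_n >= 1))
  expect_true(all(diff(rep1$model_table$coefficient) <= 0))  # sorted desc
  expect_lte(rep1$ci_lower, rep1$final_auc)
  expect_gte(rep1$ci_upper, rep1$final_auc)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep1, d1)
  rep2 <- run_pipeline(ds$counts, ds$samples, cfg,
                       contrasts = "IBD_vs_control")$IBD_vs_control
  write_report(rep2, d2)
  for (f in c("model.tsv", "cv.tsv", "summary.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  back <- read_report(d1)
  expect_equal(back$model$coefficient, rep1$model_table$coefficient)
  expect_equal(back$model$gene, rep1$model_table$gene)
  expect_equal(back$summary$auc, rep1$final_auc)
  expect_equal(back$summary$selected_lambda, rep1$selected_lambda)
  expect_equal(nrow(back$cv), nrow(rep1$records))
})

test_that("planted signal genes dominate the occurrence ranking", {
  sp <- simulation_spec(n_genes = 300, n_cases = 40, n_controls = 40,
                        n_signal_genes = 10, n_blocks = 3, block_size = 10,
                        seed = 53)
  ds <- simulate_dataset(sp)
  cfg <- pipeline_config(n_folds = 5, rng_seed = 13)
  rep <- run_pipeline(ds$counts, ds$samples, cfg,
                      contrasts = "IBD_vs_control")$IBD_vs_control
  occ_all <- setNames(rep(0, length(ds$counts$gene_ids)),
                      ds$counts$gene_ids)
  occ_all[names(rep$occurrence_counts)] <- rep$occurrence_counts
  sig <- occ_all[ds$signal_genes]
  noise <- occ_all[setdiff(names(occ_all), ds$signal_genes)]
  expect_gt(mean(sig), quantile(noise, 0.9))
})
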