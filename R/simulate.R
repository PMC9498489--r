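#' Specification of a synthetic case-control RNA-seq cohort
#'
#' Describes the generative model used by [simulate_dataset()]: overdispersed
#' negative-binomial counts with per-sample library-size factors, a planted
#' subset of case/control differential ("signal") genes, and correlated
#' co-expression blocks driven by a shared latent factor — the structure the
#' PCA preselection stage is designed to summarize.
#'
#' The default cohort is 2,000 genes over 100 cases and 100 controls with 20
#' signal genes at a log2 fold change of 1.5 and dispersion 0.2.
#'
#' @param n_genes total number of genes.
#' @param n_cases,n_controls samples per class.
#' @param n_signal_genes number of planted differential genes.
#' @param log2_fold_change log2 effect added to cases for signal genes.
#' @param baseline_log2_mean_range uniform sampling range of per-gene
#'   baseline log2 mean expression.
#' @param nb_dispersion negative-binomial dispersion phi in
#'   `variance = mu + phi * mu^2`.
#' @param size_factor_log_sd standard deviation of per-sample natural-log
#'   library-size factors (log-normal, median 1).
#' @param n_blocks,block_size number and size of co-expression blocks; the
#'   first `n_blocks * block_size` genes form consecutive blocks.
#' @param block_rho within-block latent correlation weight in `[0, 1)`; each
#'   block shares a standard-normal factor per sample with weight
#'   `sqrt(block_rho)` on the log2 scale.
#' @param activity_fraction fraction of cases labelled active (grades 3-4).
#' @param signal_in_blocks plant signal genes inside blocks instead of
#'   disjointly from them.
#' @param seed integer RNG seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 2000L, n_cases = 100L,
                            n_controls = 100L, n_signal_genes = 20L,
                            log2_fold_change = 1.5,
                            baseline_log2_mean_range = c(3, 9),
                            nb_dispersion = 0.2, size_factor_log_sd = 0.25,
                            n_blocks = 10L, block_size = 20L,
                            block_rho = 0.7, activity_fraction = 0.5,
                            signal_in_blocks = FALSE, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_cases = as.integer(n_cases),
               n_controls = as.integer(n_controls),
               n_signal_genes = as.integer(n_signal_genes),
               log2_fold_change = log2_fold_change,
               baseline_log2_mean_range = as.numeric(baseline_log2_mean_range),
               nb_dispersion = nb_dispersion,
               size_factor_log_sd = size_factor_log_sd,
               n_blocks = as.integer(n_blocks),
               block_size = as.integer(block_size), block_rho = block_rho,
               activity_fraction = activity_fraction,
               signal_in_blocks = isTRUE(signal_in_blocks),
               seed = as.integer(seed))
  stopifnot(spec$n_genes >= 1, spec$n_cases >= 1, spec$n_controls >= 1,
            spec$n_signal_genes >= 0, spec$n_signal_genes <= spec$n_genes,
            length(spec$baseline_log2_mean_range) == 2,
            diff(spec$baseline_log2_mean_range) >= 0,
            spec$nb_dispersion > 0, spec$size_factor_log_sd >= 0,
            spec$n_blocks >= 0, spec$block_size >= 0,
            spec$n_blocks * spec$block_size <= spec$n_genes,
            spec$block_rho >= 0, spec$block_rho < 1,
            spec$activity_fraction >= 0, spec$activity_fraction <= 1)
  n_block_genes <- spec$n_blocks * spec$block_size
  if (!spec$signal_in_blocks &&
      spec$n_signal_genes > spec$n_genes - n_block_genes)
    stop("not enough genes outside blocks to place the signal genes",
         call. = FALSE)
  if (spec$signal_in_blocks && spec$n_signal_genes > n_block_genes)
    stop("not enough block genes to place the signal genes", call. = FALSE)
  structure(spec, class = "simulation_spec")
}

#' Simulate a case-control count matrix with planted structure
#'
#' Counts are drawn as `NB(mean = s_j * 2^(m_i + delta_i * case_j + b_ij),
#' dispersion = phi)` where `s_j` is the sample size factor, `m_i` the
#' per-gene baseline, `delta_i` the planted log2 fold change (nonzero for
#' signal genes only) and `b_ij = sqrt(rho) * f_bj` a shared-block latent
#' effect. The draw is deterministic given `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return A list of class `simulated_dataset` with elements `counts`
#'   (a [count_matrix()]), `samples` (a [sample_table()]; cases alternate
#'   UC/CD diagnoses and adult/child age groups, activity graded by
#'   [split_activity()]), `signal_genes` (character, the planted truth) and
#'   `size_factors` (the true library-size factors).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n_samples <- spec$n_cases + spec$n_controls
  gene_ids <- sprintf("gene_%05d", seq_len(spec$n_genes))
  sample_ids <- c(sprintf("case_%03d", seq_len(spec$n_cases)),
                  sprintf("ctrl_%03d", seq_len(spec$n_controls)))
  is_case <- c(rep(1, spec$n_cases), rep(0, spec$n_controls))

  s <- exp(rnorm(n_samples, 0, spec$size_factor_log_sd))
  m <- runif(spec$n_genes, spec$baseline_log2_mean_range[1],
             spec$baseline_log2_mean_range[2])

  n_block_genes <- spec$n_blocks * spec$block_size
  block_of <- rep(NA_integer_, spec$n_genes)
  if (n_block_genes > 0)
    block_of[seq_len(n_block_genes)] <- rep(seq_len(spec$n_blocks),
                                            each = spec$block_size)
  eligible <- if (spec$signal_in_blocks) which(!is.na(block_of))
              else which(is.na(block_of))
  signal_idx <- sort(sample(eligible, spec$n_signal_genes))
  delta <- rep(0, spec$n_genes)
  delta[signal_idx] <- spec$log2_fold_change

  log2mu <- matrix(m, spec$n_genes, n_samples) +
    outer(delta, is_case)
  if (n_block_genes > 0 && spec$block_rho > 0) {
    f <- matrix(rnorm(spec$n_blocks * n_samples), spec$n_blocks, n_samples)
    idx <- which(!is.na(block_of))
    log2mu[idx, ] <- log2mu[idx, ] +
      sqrt(spec$block_rho) * f[block_of[idx], , drop = FALSE]
  }
  mu <- sweep(2^log2mu, 2, s, `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$nb_dispersion),
                   spec$n_genes, n_samples)
  cm <- count_matrix(counts, gene_ids, sample_ids)

  st <- data.frame(
    sample_id = sample_ids,
    diagnosis = c(rep_len(c("UC", "CD"), spec$n_cases),
                  rep("control", spec$n_controls)),
    age_group = rep_len(c("adult", "child"), n_samples),
    activity = 0L,
    stringsAsFactors = FALSE)
  st <- sample_table(st, counts = cm)
  st <- split_activity(st, spec$activity_fraction,
                       seed = spec$seed + 1L)
  bl_log("simulate_dataset",
         sprintf("%d genes x %d samples, %d signal genes, %d blocks",
                 spec$n_genes, n_samples, spec$n_signal_genes, spec$n_blocks))
  structure(list(counts = cm, samples = st,
                 signal_genes = gene_ids[signal_idx], size_factors = s),
            class = "simulated_dataset")
}

#' Assign disease activity grades to a fraction of cases
#'
#' Marks `round(fraction * n_cases)` cases, chosen uniformly at random with
#' the given seed, as active (grade 3 or 4) and the remaining cases as
#' non-active (grade 0-2); controls keep activity 0.
#'
#' @param table a [sample_table()].
#' @param fraction fraction of cases to label active, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return The updated `sample_table`.
#' @export
split_activity <- function(table, fraction, seed) {
  stopifnot(inherits(table, "sample_table"))
  if (fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]", call. = FALSE)
  case_idx <- which(table$diagnosis != "control")
  if (!length(case_idx)) stop("table contains no case samples", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_active <- round(fraction * length(case_idx))
  active <- if (n_active > 0) sample(case_idx, n_active) else integer(0)
  rest <- setdiff(case_idx, active)
  table$activity[active] <- sample(3:4, length(active), replace = TRUE)
  table$activity[rest] <- sample(0:2, length(rest), replace = TRUE)
  table
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
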