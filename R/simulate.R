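#' Raise the mode of a Beta distribution by a percentage
#'
#' For `Beta(alpha, beta)` with `alpha, beta > 1` the mode is
#' `m = (alpha - 1) / (alpha + beta - 2)`. Keeping `beta` fixed, returns
#' the `alpha'` whose mode is `(1 + l/100) * m`:
#' `alpha' = (1 + m2 (beta - 2)) / (1 - m2)` with `m2 = (1 + l/100) m`.
#'
#' @param alpha,beta base shape parameters, both > 1.
#' @param l percent increase of the mode (>= 0).
#' @return The shifted `alpha'`.
#' @export
beta_mode_shift <- function(alpha, beta, l) {
  if (!is_scalar_number(alpha) || !is_scalar_number(beta) ||
      alpha <= 1 || beta <= 1)
    md_stop("mode-shift designs need alpha > 1 and beta > 1",
            "markerdens_parameter_error")
  if (!is_scalar_number(l) || l < 0)
    md_stop("mode shift l must be >= 0", "markerdens_parameter_error")
  m1 <- (alpha - 1) / (alpha + beta - 2)
  m2 <- (1 + l / 100) * m1
  if (m2 >= 1)
    md_stop(sprintf("shifted mode %.3f >= 1: infeasible shift", m2),
            "markerdens_infeasible_shift_error")
  a2 <- (1 + m2 * (beta - 2)) / (1 - m2)
  stopifnot(abs((a2 - 1) / (a2 + beta - 2) - m2) < 1e-10)
  a2
}

#' Simulate a two-group cohort with a Beta mode-shift contrast
#'
#' Generates per-cell marker intensities for a cohort of two subject
#' groups: `n_shift` subjects drawn i.i.d. from the mode-raised
#' `Beta(alpha', beta)` (with `alpha'` from [beta_mode_shift()]) and
#' `n_base` subjects from the base `Beta(alpha, beta)`; `n_cells` cells
#' per subject. The default sizes put the larger group (60 of 100) on the
#' elevated-mode distribution, mirroring the lung-cohort structure the
#' design emulates (the larger of the two observed clusters had the
#' higher-mode expression profile). Draws are already in \[0, 1\]; no
#' rescaling is applied.
#'
#' @param n_cells cells per subject.
#' @param l percent mode shift of the elevated group.
#' @param alpha,beta base Beta parameters (design A: 2.17, 300; design B:
#'   1.78, 45).
#' @param n_shift,n_base group sizes (defaults 60 shifted, 40 base).
#' @return List with `samples` (named list of intensity vectors, subjects
#'   `s001...`), `truth` (integer group labels: 1 = shifted, 2 = base) and
#'   the resolved `alpha_shift`.
#' @export
simulate_beta_cohort <- function(n_cells, l, alpha = 2.17, beta = 300,
                                 n_shift = 60L, n_base = 40L) {
  stopifnot(n_cells >= 1, n_shift >= 1, n_base >= 1)
  a2 <- beta_mode_shift(alpha, beta, l)
  truth <- rep(c(1L, 2L), c(n_shift, n_base))
  samples <- lapply(truth, function(g)
    stats::rbeta(n_cells, if (g == 1L) a2 else alpha, beta))
  names(samples) <- sprintf("s%03d", seq_along(samples))
  names(truth) <- names(samples)
  list(samples = samples, truth = truth, alpha_shift = a2)
}

#' Simulate a cohort under the two-threshold positivity mechanism
#'
#' Generates data for which the classical thresholding rule with the true
#' `(t1, t2)` is the oracle: group-1 subjects have exactly
#' `round(t2 * n_cells)` positive cells (intensity above `t1`), group-2
#' subjects a strictly larger positive count, drawn as
#' `ceiling(f * n_cells)` with `f ~ U(t2, 3 t2]` capped at 1. Positive
#' intensities are uniform on `(t1, 1]`, negative on `[0, t1]`.
#'
#' @param n_cells cells per subject.
#' @param t1 positivity cutoff in (0, 1).
#' @param t2 baseline positive proportion in (0, 1).
#' @param n_exact,n_elevated group sizes (defaults 60 at exactly `t2`,
#'   40 above).
#' @return List with `samples`, `truth` (1 = exact-`t2` group,
#'   2 = elevated), `t1`, `t2`.
#' @export
simulate_threshold_cohort <- function(n_cells, t1 = 0.05, t2 = 0.01,
                                      n_exact = 60L, n_elevated = 40L) {
  stopifnot(n_cells >= 1, t1 > 0, t1 < 1, t2 > 0, t2 < 1)
  k1 <- round(t2 * n_cells)
  if (k1 == 0)
    warning("round(t2 * n_cells) is 0: group-1 positivity vanishes")
  truth <- rep(c(1L, 2L), c(n_exact, n_elevated))
  draw <- function(k) {
    x <- c(stats::runif(k, t1, 1), stats::runif(n_cells - k, 0, t1))
    # ensure the k 'positive' draws are strictly above t1
    sample(x)
  }
  samples <- lapply(truth, function(g) {
    if (g == 1L) draw(k1)
    else {
      f <- min(stats::runif(1, t2, 3 * t2), 1)
      draw(min(n_cells, max(ceiling(f * n_cells), k1 + 1L)))
    }
  })
  names(samples) <- sprintf("s%03d", seq_along(samples))
  names(truth) <- names(samples)
  list(samples = samples, truth = truth, t1 = t1, t2 = t2)
}

# the four clustering strategies compared in the replication study
eval_methods_once <- function(samples, truth, R = 1024L,
                              linkage = "ward.D2",
                              true_thresholds = NULL) {
  dens <- estimate_densities(samples, R = R)
  D <- jsd_matrix(dens)
  res <- c(
    jsd = rand_indices(hierarchical_cluster(D, k = 2, linkage = linkage),
                       truth)[["ARI"]],
    threshold95 = rand_indices(threshold_cluster(samples, "q95", 0.01),
                               truth)[["ARI"]],
    threshold97.5 = rand_indices(threshold_cluster(samples, "q97.5", 0.01),
                                 truth)[["ARI"]],
    quantile_kmeans = rand_indices(
      quantile_cluster(samples, c(0.975, 0.99, 0.995), k = 2), truth)[["ARI"]]
  )
  if (!is.null(true_thresholds))
    res <- c(res, threshold_true = rand_indices(
      threshold_cluster(samples, true_thresholds[1], true_thresholds[2]),
      truth)[["ARI"]])
  res
}

#' Monte-Carlo replication study of clustering accuracy
#'
#' Replicates one simulation design `reps` times; on each replication the
#' cohort is clustered into two groups by (a) KDE + Jensen-Shannon
#' distances + hierarchical clustering, (b) 95%-quantile thresholding
#' (`t2 = 0.01`), (c) 97.5%-quantile thresholding, (d) K-means on the
#' (97.5%, 99%, 99.5%) quantile vectors — and, for the threshold design,
#' (e) thresholding with the true `(t1, t2)` — and scored by adjusted Rand
#' index against the generating groups. A master seed spawns one
#' sub-stream per replication, so all methods within a replication see the
#' same cohort and runs are reproducible.
#'
#' @param design `"beta-shift-A"` (base Beta(2.17, 300)),
#'   `"beta-shift-B"` (base Beta(1.78, 45)) or `"threshold"`.
#' @param n_cells cells per subject.
#' @param l percent mode shift (beta designs).
#' @param t1,t2 thresholds (threshold design).
#' @param reps number of replications (default 100).
#' @param seed master seed.
#' @param R density grid size.
#' @param linkage linkage rule for the density-based clustering.
#' @param n_g1,n_g2 group sizes (defaults 60 / 40; for the beta designs
#'   group 1 is the mode-raised group, see [simulate_beta_cohort()]).
#' @param progress_file optional CSV path; per-replication rows are
#'   appended as they complete and an existing file is resumed.
#' @return A `replication_study`: list with `results` (data frame rep x
#'   method x ari), `summary` (mean ARI and Monte-Carlo SE per method) and
#'   the configuration.
#' @export
run_study <- function(design = c("beta-shift-A", "beta-shift-B", "threshold"),
                      n_cells = 200L, l = 50, t1 = 0.05, t2 = 0.01,
                      reps = 100L, seed = 1L, R = 1024L,
                      linkage = "ward.D2",
                      n_g1 = 60L, n_g2 = 40L,
                      progress_file = NULL) {
  design <- match.arg(design)
  stopifnot(reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)

  done <- NULL
  if (!is.null(progress_file) && file.exists(progress_file)) {
    done <- utils::read.csv(progress_file, stringsAsFactors = FALSE)
    done <- done[done$rep <= reps, , drop = FALSE]
  }
  rows <- list()
  failures <- 0L
  for (r in seq_len(reps)) {
    if (!is.null(done) && r %in% done$rep) {
      rows[[r]] <- done[done$rep == r, , drop = FALSE]
      next
    }
    set.seed(rep_seeds[r])
    ari <- tryCatch({
      if (design == "threshold") {
        sim <- simulate_threshold_cohort(n_cells, t1, t2, n_g1, n_g2)
        eval_methods_once(sim$samples, sim$truth, R = R, linkage = linkage,
                          true_thresholds = c(t1, t2))
      } else {
        ab <- if (design == "beta-shift-A") c(2.17, 300) else c(1.78, 45)
        sim <- simulate_beta_cohort(n_cells, l, ab[1], ab[2], n_g1, n_g2)
        eval_methods_once(sim$samples, sim$truth, R = R, linkage = linkage)
      }
    }, error = function(e) {
      warning(sprintf("replication %d failed: %s", r, conditionMessage(e)))
      NULL
    })
    if (is.null(ari)) { failures <- failures + 1L; next }
    row <- data.frame(rep = r, method = names(ari), ari = unname(ari))
    rows[[r]] <- row
    if (!is.null(progress_file))
      utils::write.table(row, progress_file, sep = ",", append = file.exists(progress_file),
                         col.names = !file.exists(progress_file),
                         row.names = FALSE, quote = FALSE)
  }
  results <- do.call(rbind, rows)
  agg_mean <- tapply(results$ari, results$method, mean)
  agg_se <- tapply(results$ari, results$method,
                   function(x) stats::sd(x) / sqrt(length(x)))
  summary <- data.frame(method = names(agg_mean),
                        mean_ari = as.numeric(agg_mean),
                        mc_se = as.numeric(agg_se),
                        reps = as.integer(table(results$method)[names(agg_mean)]),
                        row.names = NULL)
  structure(list(results = results, summary = summary, failures = failures,
                 config = list(design = design, n_cells = n_cells, l = l,
                               t1 = t1, t2 = t2, reps = reps, seed = seed,
                               R = R, linkage = linkage,
                               n_g1 = n_g1, n_g2 = n_g2)),
            class = "replication_study")
}

#' @export
print.replication_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<replication_study> %s, n=%d, %s reps=%d, seed=%d\n",
              cfg$design, cfg$n_cells,
              if (cfg$design == "threshold")
                sprintf("t1=%.3g t2=%.3g,", cfg$t1, cfg$t2)
              else sprintf("l=%g,", cfg$l),
              cfg$reps, cfg$seed))
  if (x$failures > 0) cat(sprintf("  %d failed replication(s)\n", x$failures))
  print(x$summary, digits = 4)
  invisible(x)
}
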