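# End-to-end wiring: cells -> densities -> distances -> clusters -> tests.
# These functions back the command-line front end (inst/cli/markerdens.R)
# but are equally usable interactively.

#' Distance-matrix stage of the analysis pipeline
#'
#' Reads a cell table, optionally restricts it to a cell-type compartment,
#' min-max scales the chosen marker over the pooled (post-filter) cohort,
#' estimates per-subject densities and writes/returns the pairwise
#' Jensen-Shannon distance matrix.
#'
#' @param cells path to a cell-table CSV, or a `cell_table`.
#' @param marker marker column to analyze.
#' @param cell_type optional cell-type filter.
#' @param out optional output CSV path for the square distance matrix.
#' @param R density grid size.
#' @param scale_before_filter scale on the full table instead of the
#'   filtered compartment (default `FALSE`: the compartment under analysis
#'   defines the intensity range).
#' @param subject_col,cell_type_col column names used when `cells` is a
#'   path.
#' @return The `jsd_dist` matrix, invisibly if `out` is given.
#' @export
cmd_distance <- function(cells, marker, cell_type = NULL, out = NULL,
                         R = 1024L, scale_before_filter = FALSE,
                         subject_col = "subject_id",
                         cell_type_col = if (is.character(cells)) "cell_type" else NULL) {
  tab <- if (is.character(cells))
    read_cell_table(cells, subject_col = subject_col,
                    cell_type_col = cell_type_col)
  else cells
  if (scale_before_filter && !is.null(cell_type)) {
    samples_all <- scale_marker(tab, marker)
    keep <- split(tab$cell_type %in% cell_type, tab$subject_id)
    samples <- Map(function(v, k) v[k], samples_all, keep[names(samples_all)])
    empty <- names(samples)[lengths(samples) == 0]
    if (length(empty))
      warning(sprintf("%d subject(s) dropped (no matching cells): %s",
                      length(empty), paste(empty, collapse = ", ")))
    samples <- samples[lengths(samples) > 0]
    if (!length(samples))
      md_stop("no cells remain after cell-type filtering",
              "markerdens_empty_input_error")
    attr(samples, "marker") <- marker
    class(samples) <- "subject_samples"
  } else {
    if (!is.null(cell_type)) tab <- filter_cells(tab, cell_type)
    samples <- scale_marker(tab, marker)
  }
  dens <- estimate_densities(samples, R = R)
  D <- jsd_matrix(dens)
  message(sprintf("distance matrix: %d subjects, median cells/subject %d, bandwidths [%.4g, %.4g]",
                  ncol(dens$mass), stats::median(lengths(samples)),
                  min(dens$bandwidths), max(dens$bandwidths)))
  if (!is.null(out)) {
    write_distance_matrix(D, out)
    return(invisible(D))
  }
  D
}

#' Clustering + association stage of the analysis pipeline
#'
#' Clusters subjects on a distance matrix, joins a subject-level outcome
#' table, runs the requested association test and optionally writes labels
#' CSV, results JSON and a Kaplan-Meier plot.
#'
#' @param distance `jsd_dist` matrix or path to its square CSV.
#' @param outcome outcome data frame (see [read_outcome_table()]) or path.
#' @param model `"auto"` picks the label test matching the outcome kind
#'   (`coxph` for survival, `wald` for continuous); `"lmm"` and
#'   `"frailty"` use the similarity matrix directly instead of labels.
#' @param k,linkage clustering parameters.
#' @param labels_out,results_out,km_plot optional output paths.
#' @return List with `labels`, `test` and (survival outcomes) `km`.
#' @export
cmd_cluster_test <- function(distance, outcome,
                             model = c("auto", "wald", "coxph", "lmm", "frailty"),
                             k = 2L, linkage = "ward.D2",
                             labels_out = NULL, results_out = NULL,
                             km_plot = NULL) {
  model <- match.arg(model)
  D <- if (is.character(distance)) read_distance_matrix(distance) else distance
  oc <- if (is.character(outcome)) read_outcome_table(outcome) else outcome
  kind <- attr(oc, "outcome_kind") %||%
    if (all(c("time", "event") %in% names(oc))) "survival" else "continuous"

  ids <- rownames(D)
  orphan_o <- setdiff(oc$subject_id, ids)
  orphan_d <- setdiff(ids, oc$subject_id)
  if (length(orphan_o) || length(orphan_d))
    md_stop(sprintf("subject ids do not match (only in outcomes: %s; only in distances: %s)",
                    paste(orphan_o, collapse = ",") %|e|% "-",
                    paste(orphan_d, collapse = ",") %|e|% "-"),
            "markerdens_join_error")
  oc <- oc[match(ids, oc$subject_id), , drop = FALSE]
  covs <- attr(oc, "covariates")
  C <- if (length(covs)) as.matrix(oc[, covs, drop = FALSE]) else NULL

  labels <- hierarchical_cluster(D, k = k, linkage = linkage)
  if (model == "auto") model <- if (kind == "survival") "coxph" else "wald"
  test <- switch(model,
    wald = linear_wald_test(stats::setNames(oc$y, ids), labels, C),
    coxph = coxph_label_lrt(stats::setNames(oc$time, ids),
                            oc$event, labels, C),
    lmm = lmm_variance_lrt(stats::setNames(oc$y, ids), to_similarity(D), C),
    frailty = cox_frailty_lrt(stats::setNames(oc$time, ids), oc$event,
                              to_similarity(D), C))
  out <- list(labels = labels, test = test)
  if (kind == "survival") {
    out$km <- kaplan_meier_by_group(oc$time, oc$event, labels)
    if (!is.null(km_plot)) {
      grDevices::png(km_plot, width = 640, height = 480)
      plot(out$km)
      grDevices::dev.off()
    }
  }
  if (!is.null(labels_out)) write_cluster_labels(labels, labels_out)
  if (!is.null(results_out)) write_test_results(test, results_out)
  out
}

`%|e|%` <- function(a, b) if (nzchar(a)) a else b

#' Simulation stage of the analysis pipeline
#'
#' Runs [run_study()] from a configuration list and writes tidy
#' per-replication results plus a one-row summary in the layout of the
#' benchmark tables (one column per method).
#'
#' @param config named list of [run_study()] arguments (`design`,
#'   `n_cells`, `l`, `t1`, `t2`, `reps`, `seed`, ...), or a path to a JSON
#'   file holding one.
#' @param out_dir output directory (created if needed); writes
#'   `replications.csv` and `summary.csv`.
#' @return The `replication_study`, invisibly.
#' @export
cmd_simulate <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  study <- do.call(run_study, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(study$results, file.path(out_dir, "replications.csv"),
                     row.names = FALSE)
    wide <- stats::setNames(as.list(study$summary$mean_ari), study$summary$method)
    utils::write.csv(
      data.frame(design = study$config$design, n_cells = study$config$n_cells,
                 l = study$config$l, wide, check.names = FALSE),
      file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  invisible(study)
}

#' Write small deterministic example datasets
#'
#' Generates a toy cohort (12 subjects, two cell types, two markers, one
#' of which differs in density between two latent groups), a matching
#' survival + continuous outcome table, and the precomputed distance
#' matrix, as plain CSV. Used by the documentation examples and tests.
#'
#' @param dir output directory.
#' @param seed RNG seed (default 42).
#' @return Named character vector of the files written.
#' @export
make_fixtures <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  n_sub <- 12L
  n_cells <- 80L
  group <- rep(1:2, each = n_sub / 2)
  rows <- lapply(seq_len(n_sub), function(j) {
    a <- if (group[j] == 1) 2 else 6
    data.frame(
      subject_id = sprintf("P%02d", j),
      cell_id = seq_len(n_cells),
      cell_type = sample(c("CK+", "CD8+"), n_cells, replace = TRUE,
                         prob = c(0.7, 0.3)),
      HLA_DR = round(stats::rbeta(n_cells, a, 20), 6),
      PD1 = round(stats::rbeta(n_cells, 2, 30), 6))
  })
  cells <- do.call(rbind, rows)
  cells_path <- file.path(dir, "example_cells.csv")
  utils::write.csv(cells, cells_path, row.names = FALSE, quote = FALSE)

  lp <- ifelse(group == 1, 0, 0.9)
  time <- round(stats::rexp(n_sub, rate = 0.1 * exp(lp)), 3)
  cens <- round(stats::runif(n_sub, 2, 15), 3)
  outcome <- data.frame(
    subject_id = sprintf("P%02d", seq_len(n_sub)),
    time = pmin(time, cens),
    event = as.integer(time <= cens),
    y = round(lp + stats::rnorm(n_sub, sd = 0.5), 4),
    age = round(stats::runif(n_sub, 45, 80), 1))
  outcome_path <- file.path(dir, "example_outcomes.csv")
  utils::write.csv(outcome, outcome_path, row.names = FALSE, quote = FALSE)

  tab <- as_cell_table(cells, cell_id_col = "cell_id",
                       cell_type_col = "cell_type")
  D <- cmd_distance(tab, "HLA_DR", cell_type = "CK+", R = 512L)
  dist_path <- file.path(dir, "example_distances.csv")
  write_distance_matrix(round(D, 8), dist_path)
  c(cells = cells_path, outcomes = outcome_path, distances = dist_path)
}
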