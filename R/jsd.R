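#' Jensen-Shannon distance between two grid densities
#'
#' Discrete Jensen-Shannon divergence of the two probability-mass vectors
#' on their shared grid,
#' `sum_r p_r log(2 p_r / (p_r + q_r)) + q_r log(2 q_r / (p_r + q_r))`,
#' with natural logarithms and the `0 * log 0 = 0` convention (no epsilon
#' flooring, so identical inputs give exactly 0). The value lies in
#' \[0, 2 log 2\]; its square root is a metric.
#'
#' @param a,b `marker_density` objects sharing an identical grid.
#' @return A non-negative scalar.
#' @export
jsd_pair <- function(a, b) {
  stopifnot(inherits(a, "marker_density"), inherits(b, "marker_density"))
  if (length(a$grid) != length(b$grid) || any(a$grid != b$grid))
    md_stop("densities are not on the same grid", "markerdens_grid_mismatch_error")
  p <- a$mass
  q <- b$mass
  m <- (p + q) / 2
  d <- sum(xlogx(p)) + sum(xlogx(q)) - 2 * sum(xlogx(m))
  max(d, 0)
}

#' Pairwise Jensen-Shannon distance matrix for a cohort
#'
#' Symmetric N x N matrix of [jsd_pair()] values over all subject pairs of
#' a density set; only the upper triangle is computed and mirrored. The
#' computation is vectorized through the identity
#' `JSD(p, q) = sum p log p + sum q log q - 2 sum m log m`, `m = (p+q)/2`.
#'
#' @param densities a `marker_density_set` (or list of `marker_density`).
#' @return A symmetric matrix of class `jsd_dist` with zero diagonal and
#'   subject ids as dimnames.
#' @export
jsd_matrix <- function(densities) {
  if (is.list(densities) && !inherits(densities, "marker_density_set") &&
      all(vapply(densities, inherits, TRUE, "marker_density"))) {
    grid <- densities[[1]]$grid
    for (d in densities)
      if (length(d$grid) != length(grid) || any(d$grid != grid))
        md_stop("densities are not on the same grid",
                "markerdens_grid_mismatch_error")
    mass <- vapply(densities, `[[`, numeric(length(grid)), "mass")
    ids <- vapply(seq_along(densities),
                  function(j) densities[[j]]$subject_id %||% as.character(j), "")
    densities <- structure(list(grid = grid, mass = mass, subject_ids = ids),
                           class = "marker_density_set")
  }
  stopifnot(inherits(densities, "marker_density_set"))
  F <- densities$mass
  N <- ncol(F)
  if (N < 2)
    md_stop("need at least 2 subjects for a distance matrix",
            "markerdens_insufficient_subjects_error")
  S <- colSums(xlogx(F))
  D <- matrix(0, N, N, dimnames = list(densities$subject_ids,
                                       densities$subject_ids))
  for (j in seq_len(N - 1)) {
    rest <- (j + 1):N
    M <- (F[, j] + F[, rest, drop = FALSE]) / 2
    d <- S[j] + S[rest] - 2 * colSums(xlogx(M))
    D[j, rest] <- D[rest, j] <- pmax(d, 0)
  }
  structure(D, class = c("jsd_dist", "matrix", "array"))
}

#' Similarity transform of a distance matrix
#'
#' Elementwise `G = exp(-D)`. Because `exp(-D)` is not guaranteed positive
#' semidefinite, an optional repair (default on) clips negative eigenvalues
#' at zero so `G` is a valid covariance kernel for the mixed-model tests;
#' the amount clipped is recorded in attribute `"clipped"`.
#'
#' @param D a symmetric non-negative distance matrix (class `jsd_dist` or
#'   plain matrix) with zero diagonal.
#' @param repair clip negative eigenvalues at 0 (default `TRUE`).
#' @return Symmetric similarity matrix of class `jsd_similarity` with
#'   attributes `min_eigenvalue` (before repair) and `clipped`.
#' @export
to_similarity <- function(D, repair = TRUE) {
  D <- unclass(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0) || any(D < 0))
    md_stop("D must be symmetric, non-negative, with zero diagonal",
            "markerdens_parameter_error")
  G <- exp(-D)
  ev <- eigen(G, symmetric = TRUE)
  min_ev <- min(ev$values)
  clipped <- 0
  if (repair && min_ev < 0) {
    lam <- pmax(ev$values, 0)
    clipped <- sum(ev$values < 0)
    G <- ev$vectors %*% (lam * t(ev$vectors))
    G <- (G + t(G)) / 2
    dimnames(G) <- dimnames(D)
  }
  structure(G, min_eigenvalue = min_ev, clipped = clipped,
            class = c("jsd_similarity", "matrix", "array"))
}

#' Write / read a square distance (or similarity) matrix as CSV
#'
#' Square layout with subject ids as both header and first column.
#'
#' @param D matrix with dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(subject_id = rownames(D), unclass(D), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path))
    md_stop(sprintf("file not found: %s", path), "markerdens_io_error")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- list(ids, colnames(M))
  if (!identical(rownames(M), colnames(M)))
    md_stop("matrix CSV is not square with matching ids",
            "markerdens_schema_error")
  structure(M, class = c("jsd_dist", "matrix", "array"))
}
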