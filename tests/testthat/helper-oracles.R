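# Independent oracles used across the suite. Each re-derives a quantity by
# a route different from the package implementation (quadrature, brute
# force, enumeration, hand formulas).

# continuous Jensen-Shannon divergence of two density FUNCTIONS on [0, 1]
# by fine Riemann quadrature (midpoint rule); densities renormalized on
# the interval first
oracle_jsd_quadrature <- function(f, g, R = 2^17) {
  x <- (seq_len(R) - 0.5) / R
  dx <- 1 / R
  p <- f(x); q <- g(x)
  p <- p / sum(p * dx)
  q <- q / sum(q * dx)
  xlx <- function(v) ifelse(v > 0, v * log(v), 0)
  sum(xlx(p) + xlx(q) - 2 * xlx((p + q) / 2)) * dx
}

# a KDE mixture as a plain density function (truncated to [0,1] by the
# later renormalization in the quadrature oracle)
kde_mixture_fun <- function(samples, h) {
  function(x) vapply(x, function(v) mean(dnorm(v - samples, sd = h)), 1)
}

# discretize an analytic density onto the package grid as a mass vector
discretize_density <- function(f, R = 1024L) {
  grid <- seq(0, 1, length.out = R)
  m <- f(grid)
  structure(list(grid = grid, mass = m / sum(m), bandwidth = NA_real_,
                 subject_id = NULL),
            class = "marker_density")
}

# naive O(N^3) agglomerative clustering on a distance matrix, complete
# linkage; returns the flat partition at each number of clusters
oracle_agglomerate_complete <- function(D, k) {
  groups <- as.list(seq_len(nrow(D)))
  while (length(groups) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      d <- max(D[groups[[i]], groups[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  labels <- integer(nrow(D))
  for (g in seq_along(groups)) labels[groups[[g]]] <- g
  labels
}

# exhaustive minimizer of within-cluster sum of squares over all
# 2-partitions of the rows of Q
oracle_best_2partition <- function(Q) {
  n <- nrow(Q)
  best <- list(wss = Inf, labels = NULL)
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    wss <- 0
    for (g in 1:2) {
      rows <- Q[lab == g, , drop = FALSE]
      ctr <- colMeans(rows)
      wss <- wss + sum(sweep(rows, 2, ctr)^2)
    }
    if (wss < best$wss) best <- list(wss = wss, labels = lab)
  }
  best
}

# solve the Beta mode-shift equation numerically instead of in closed form
oracle_mode_shift_root <- function(alpha, beta, l) {
  target <- (1 + l / 100) * (alpha - 1) / (alpha + beta - 2)
  uniroot(function(a) (a - 1) / (a + beta - 2) - target,
          c(1 + 1e-9, 1e6), tol = 1e-12)$root
}

# hand product-limit estimator: returns survival after each event time
oracle_product_limit <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ev_times <- unique(time[event == 1])
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (i in seq_along(ev_times)) {
    at_risk <- sum(time >= ev_times[i])
    d <- sum(time == ev_times[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# direct (unrotated) maximum-likelihood evaluation of the one-component
# LMM log-likelihood at given variance parameters
oracle_lmm_loglik <- function(y, X, G, sigma2_g, sigma2_e) {
  V <- sigma2_g * G + sigma2_e * diag(length(y))
  cV <- chol(V)
  Vinv_y <- backsolve(cV, forwardsolve(t(cV), y))
  Vinv_X <- backsolve(cV, forwardsolve(t(cV), X))
  beta <- solve(crossprod(X, Vinv_X), crossprod(X, Vinv_y))
  r <- y - drop(X %*% beta)
  Vinv_r <- backsolve(cV, forwardsolve(t(cV), r))
  -0.5 * (2 * sum(log(diag(cV))) + sum(r * Vinv_r) +
            length(y) * log(2 * pi))
}

# small helper: random probability-mass vectors on an R-point grid
random_mass <- function(R, concentration = 1) {
  m <- rgamma(R, concentration)
  m / sum(m)
}

mass_density <- function(mass, grid = seq(0, 1, length.out = length(mass))) {
  structure(list(grid = grid, mass = mass, bandwidth = NA_real_,
                 subject_id = NULL), class = "marker_density")
}

# cohort fixture reused by several files
make_test_cells <- function(n_sub = 3L, n_cells = 100L, seed = 7L,
                            na_rows = 0L) {
  set.seed(seed)
  df <- data.frame(
    subject_id = rep(sprintf("S%d", seq_len(n_sub)), each = n_cells),
    cell_id = rep(seq_len(n_cells), n_sub),
    cell_type = sample(c("CK+", "CD8+"), n_sub * n_cells, replace = TRUE),
    m1 = rbeta(n_sub * n_cells, 2, 10))
  if (na_rows > 0) df$m1[sample(nrow(df), na_rows)] <- NA
  df
}
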