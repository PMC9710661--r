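test_that("JSD identity, symmetry and range hold on random mass pairs", {
  set.seed(13)
  d0 <- mass_density(random_mass(128))
  expect_identical(jsd_pair(d0, d0), 0)

  for (i in 1:200) {
    a <- mass_density(random_mass(128, concentration = runif(1, 0.2, 5)))
    b <- mass_density(random_mass(128, concentration = runif(1, 0.2, 5)))
    d_ab <- jsd_pair(a, b)
    expect_identical(d_ab, jsd_pair(b, a))
    expect_gte(d_ab, 0)
    expect_lte(d_ab, 2 * log(2) + 1e-9)
  }
})

test_that("disjoint supports attain the maximal divergence 2 log 2", {
  R <- 100
  left <- c(rep(1 / 50, 50), rep(0, 50))
  right <- rev(left)
  expect_equal(jsd_pair(mass_density(left), mass_density(right)), 2 * log(2))
})

test_that("mismatched grids are rejected", {
  a <- mass_density(random_mass(64))
  b <- mass_density(random_mass(128))
  expect_error(jsd_pair(a, b), class = "markerdens_grid_mismatch_error")
})

test_that("grid JSD of analytic Beta densities matches fine quadrature", {
  # the two expression profiles underpinning the benchmark designs
  f1 <- function(x) dbeta(x, 2.17, 300)
  f2 <- function(x) dbeta(x, 1.78, 45)
  grid_val <- jsd_pair(discretize_density(f1), discretize_density(f2))
  oracle <- oracle_jsd_quadrature(f1, f2)
  expect_equal(grid_val, oracle, tolerance = 1e-3)
})

test_that("grid JSD of KDE mixtures matches quadrature of the mixtures", {
  set.seed(17)
  for (i in 1:3) {
    xa <- rbeta(150, 2, 6)
    xb <- rbeta(200, 4, 4)
    da <- estimate_density(xa, R = 1024)
    db <- estimate_density(xb, R = 1024)
    oracle <- oracle_jsd_quadrature(kde_mixture_fun(xa, da$bandwidth),
                                    kde_mixture_fun(xb, db$bandwidth),
                                    R = 2^15)
    expect_equal(jsd_pair(da, db), oracle, tolerance = 1e-3)
  }
})

test_that("JSD estimates are stable under grid refinement", {
  f1 <- function(x) dbeta(x, 2, 5)
  f2 <- function(x) dbeta(x, 4, 3)
  v1024 <- jsd_pair(discretize_density(f1, 1024), discretize_density(f2, 1024))
  v4096 <- jsd_pair(discretize_density(f1, 4096), discretize_density(f2, 4096))
  expect_lt(abs(v1024 - v4096), 1e-4)
})

test_that("the square root of JSD satisfies the triangle inequality", {
  set.seed(23)
  n_triples <- 2000
  R <- 64
  for (i in seq_len(n_triples)) {
    p <- random_mass(R, 0.5); q <- random_mass(R, 0.5); r <- random_mass(R, 0.5)
    dpq <- sqrt(jsd_pair(mass_density(p), mass_density(q)))
    dqr <- sqrt(jsd_pair(mass_density(q), mass_density(r)))
    dpr <- sqrt(jsd_pair(mass_density(p), mass_density(r)))
    expect_lte(dpr, dpq + dqr + 1e-12)
  }
})

test_that("the distance matrix equals brute-force pairwise calls", {
  set.seed(29)
  sim <- simulate_beta_cohort(100, 100, n_shift = 3, n_base = 2)
  ds <- estimate_densities(sim$samples, R = 512)
  D <- jsd_matrix(ds)
  singles <- lapply(seq_along(sim$samples), function(j)
    estimate_density(sim$samples[[j]], R = 512, subject_id = names(sim$samples)[j]))
  for (j in 1:4) for (k in (j + 1):5)
    expect_equal(D[j, k], jsd_pair(singles[[j]], singles[[k]]), tolerance = 1e-12)
  expect_identical(unclass(D), t(unclass(D)))
  expect_identical(unname(diag(D)), rep(0, 5))
})

test_that("distance matrices of identical densities are zero and permutation-equivariant", {
  m <- random_mass(128)
  same <- structure(list(grid = seq(0, 1, length.out = 128),
                         mass = cbind(a = m, b = m, c = m),
                         subject_ids = c("a", "b", "c")),
                    class = "marker_density_set")
  expect_equal(max(jsd_matrix(same)), 0)

  set.seed(31)
  M <- sapply(1:6, function(i) random_mass(128))
  colnames(M) <- paste0("s", 1:6)
  ds <- structure(list(grid = seq(0, 1, length.out = 128), mass = M,
                       subject_ids = colnames(M)),
                  class = "marker_density_set")
  D <- jsd_matrix(ds)
  perm <- c(4, 2, 6, 1, 3, 5)
  ds_p <- structure(list(grid = ds$grid, mass = M[, perm],
                         subject_ids = colnames(M)[perm]),
                    class = "marker_density_set")
  expect_equal(unclass(jsd_matrix(ds_p)), unclass(D)[perm, perm])

  expect_error(jsd_matrix(structure(list(grid = ds$grid,
                                         mass = M[, 1, drop = FALSE],
                                         subject_ids = "s1"),
                                    class = "marker_density_set")),
               class = "markerdens_insufficient_subjects_error")
})

test_that("similarity transform is exp(-D) with PSD repair", {
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(unclass(to_similarity(Z)), matrix(1, 4, 4,
               dimnames = dimnames(Z)), ignore_attr = TRUE)

  Dm <- matrix(2 * log(2), 3, 3); diag(Dm) <- 0
  G <- to_similarity(Dm, repair = FALSE)
  expect_equal(unique(G[upper.tri(G)]), 0.25)
  expect_equal(unname(diag(G)), rep(1, 3))

  # random valid distance matrix: after repair no meaningful negative spectrum
  set.seed(37)
  A <- matrix(runif(64, 0, 2 * log(2)), 8)
  Dr <- (A + t(A)) / 2; diag(Dr) <- 0
  Gr <- to_similarity(Dr, repair = TRUE)
  expect_gte(min(eigen(unclass(Gr), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  expect_identical(unclass(Gr), t(unclass(Gr)))
})

test_that("distance matrices round-trip through square CSV", {
  set.seed(41)
  sim <- simulate_beta_cohort(50, 50, n_shift = 2, n_base = 2)
  D <- jsd_matrix(estimate_densities(sim$samples, R = 128))
  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_matrix(D, path)
  back <- read_distance_matrix(path)
  expect_equal(unclass(back), unclass(D), tolerance = 1e-12)
  expect_identical(rownames(back), names(sim$samples))
})
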