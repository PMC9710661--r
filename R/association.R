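#' @importFrom survival Surv coxph survfit
NULL

new_assoc_test <- function(test, statistic, null_dist, p.value, effect = NULL,
                           converged = TRUE, details = list()) {
  structure(list(test = test, statistic = statistic, null_dist = null_dist,
                 p.value = p.value, effect = effect, converged = converged,
                 details = details),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("<assoc_test> %s\n  statistic = %.4g  (%s)\n  p-value   = %.4g\n",
              x$test, x$statistic, x$null_dist, x$p.value))
  if (!is.null(x$effect))
    cat(sprintf("  effect    = %s\n",
                paste(sprintf("%s=%.4g", names(x$effect), x$effect),
                      collapse = ", ")))
  if (!x$converged) cat("  (fit did not converge; interpret with caution)\n")
  invisible(x)
}

check_alignment <- function(y_names, z_names) {
  if (!is.null(y_names) && !is.null(z_names) && !identical(y_names, z_names))
    md_stop("subject ids of outcome and labels do not match",
            "markerdens_join_error")
}

build_design <- function(n, C) {
  if (is.null(C)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  C <- as.matrix(C)
  if (nrow(C) != n)
    md_stop("covariate rows do not match the outcome length",
            "markerdens_parameter_error")
  cbind("(Intercept)" = 1, C)
}

#' Wald test of a cluster label in a linear model
#'
#' Ordinary least squares of a continuous outcome on covariates plus the
#' group label (as dummies); Wald chi-square test that all group
#' coefficients are zero.
#'
#' @param y continuous outcome vector.
#' @param labels group labels (`subject_clusters` or vector).
#' @param C optional covariate matrix / data frame (one row per subject).
#' @return An `assoc_test` with the group-difference estimate(s) as effect.
#' @export
linear_wald_test <- function(y, labels, C = NULL) {
  z <- factor(unclass(labels))
  check_alignment(names(y), names(labels))
  if (nlevels(droplevels(z)) < 2)
    md_stop("need at least 2 non-empty groups", "markerdens_no_contrast_error")
  X0 <- build_design(length(y), C)
  Z <- stats::model.matrix(~z)[, -1, drop = FALSE]
  X <- cbind(X0, Z)
  if (qr(X)$rank < ncol(X))
    md_stop("design matrix is rank deficient (collinear covariates?)",
            "markerdens_rank_deficiency_error")
  fit <- stats::lm.fit(X, y)
  df_res <- length(y) - ncol(X)
  if (df_res < 1)
    md_stop("too few subjects for the requested model",
            "markerdens_parameter_error")
  sigma2 <- sum(fit$residuals^2) / df_res
  XtXinv <- chol2inv(chol(crossprod(X)))
  idx <- (ncol(X0) + 1):ncol(X)
  gamma <- fit$coefficients[idx]
  V <- sigma2 * XtXinv[idx, idx, drop = FALSE]
  stat <- drop(t(gamma) %*% solve(V, gamma))
  df <- length(idx)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  new_assoc_test("linear model Wald test (cluster label)",
                 stat, sprintf("chi-square(%d)", df), p,
                 effect = stats::setNames(gamma, colnames(Z)))
}

#' Likelihood-ratio test of a cluster label in a Cox model
#'
#' Cox proportional-hazards fit (Efron ties) of survival on covariates
#' plus the group label; LRT against the covariate-only model. For two
#' groups the hazard ratio `exp(gamma)` of group 2 vs group 1 is reported.
#'
#' @param time,event right-censored outcome (event = 1 observed, 0
#'   censored).
#' @param labels group labels.
#' @param C optional covariates.
#' @return An `assoc_test` with `effect = c(HR = ...)` for two groups.
#' @export
coxph_label_lrt <- function(time, event, labels, C = NULL) {
  z <- factor(unclass(labels))
  check_alignment(names(time), names(labels))
  if (sum(event) == 0)
    md_stop("no events observed; the partial likelihood is undefined",
            "markerdens_no_events_error")
  if (nlevels(droplevels(z)) < 2)
    md_stop("need at least 2 non-empty groups", "markerdens_no_contrast_error")
  ev_per_group <- tapply(event, z, sum)
  if (any(ev_per_group == 0))
    warning("group(s) with zero events; the hazard ratio may be unstable")
  dat <- data.frame(time = time, event = event, z = z)
  rhs0 <- "1"
  if (!is.null(C)) {
    C <- as.data.frame(C)
    names(C) <- paste0("c", seq_along(C))
    dat <- cbind(dat, C)
    rhs0 <- paste(names(C), collapse = " + ")
  }
  f1 <- stats::as.formula(paste("Surv(time, event) ~", rhs0, "+ z"))
  f0 <- stats::as.formula(paste("Surv(time, event) ~", rhs0))
  fit1 <- survival::coxph(f1, data = dat)
  ll0 <- if (is.null(C)) fit1$loglik[1] else
    survival::coxph(f0, data = dat)$loglik[2]
  stat <- max(0, 2 * (fit1$loglik[2] - ll0))
  df <- nlevels(droplevels(z)) - 1
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  gamma <- fit1$coefficients[grep("^z", names(fit1$coefficients))]
  eff <- if (df == 1) c(HR = unname(exp(gamma))) else exp(gamma)
  conv <- is.null(fit1$info) && all(is.finite(fit1$coefficients))
  if (any(abs(gamma) > 15))
    warning("monotone likelihood suspected (complete separation of groups)")
  new_assoc_test("Cox PH likelihood-ratio test (cluster label)",
                 stat, sprintf("chi-square(%d)", df), p,
                 effect = eff, converged = conv,
                 details = list(coef = gamma, n_events = sum(event)))
}

#' Variance-component LRT with a similarity-matrix random effect
#'
#' Fits, by maximum likelihood, the linear mixed model
#' `Y = C beta + g + e` with `g ~ MVN(0, sigma_g^2 G)` and
#' `e ~ MVN(0, sigma^2 I)`, where `G = exp(-D)` is the similarity transform
#' of the subject distance matrix, and tests `H0: sigma_g^2 = 0` by a
#' likelihood-ratio statistic referred to the boundary-corrected 50:50
#' mixture of a point mass at zero and chi-square(1) (Self-Liang).
#'
#' Estimation profiles the likelihood over the variance ratio
#' `lambda = sigma_g^2 / sigma^2` after rotating by the eigenvectors of
#' `G`, so each evaluation is closed-form.
#'
#' @param y continuous outcome.
#' @param G similarity matrix (`jsd_similarity` or PSD matrix).
#' @param C optional covariates.
#' @param lambda_max upper bound of the profiled variance ratio.
#' @return An `assoc_test` with `effect = c(sigma2_g = ..., sigma2_e = ...)`.
#' @export
lmm_variance_lrt <- function(y, G, C = NULL, lambda_max = 1e4) {
  G <- unclass(G)
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  n <- length(y)
  if (nrow(G) != n)
    md_stop("G dimension does not match the outcome length",
            "markerdens_parameter_error")
  check_alignment(names(y), rownames(G))
  off <- G[upper.tri(G)]
  if (max(abs(off)) < 1e-8)
    warning("G is (near) diagonal: the random effect is confounded with the residual")
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-6)
    md_stop("G is not positive semidefinite; use to_similarity(..., repair = TRUE)",
            "markerdens_covariance_error")
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  X <- build_design(n, C)
  Xs <- crossprod(U, X)

  prof_ll <- function(lambda) {
    v <- lambda * lam + 1
    XtVX <- crossprod(Xs / v, Xs)
    beta <- solve(XtVX, crossprod(Xs / v, ys))
    r <- ys - drop(Xs %*% beta)
    rss <- sum(r^2 / v)
    sigma2 <- rss / n
    -0.5 * (n * log(2 * pi * sigma2) + sum(log(v)) + n)
  }
  ll0 <- prof_ll(0)
  opt <- stats::optimize(function(loglam) -prof_ll(exp(loglam)),
                         c(log(1e-8), log(lambda_max)), tol = 1e-8)
  lambda_hat <- exp(opt$minimum)
  ll1 <- -opt$objective
  if (ll0 >= ll1) {  # boundary solution
    lambda_hat <- 0
    ll1 <- ll0
  }
  stat <- max(0, 2 * (ll1 - ll0))
  p <- if (stat <= 1e-10) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
  v <- lambda_hat * lam + 1
  XtVX <- crossprod(Xs / v, Xs)
  beta <- solve(XtVX, crossprod(Xs / v, ys))
  sigma2 <- sum((ys - drop(Xs %*% beta))^2 / v) / n
  new_assoc_test("LMM variance-component LRT (similarity kernel)",
                 stat, "50:50 mixture of point mass at 0 and chi-square(1)", p,
                 effect = c(sigma2_g = lambda_hat * sigma2, sigma2_e = sigma2),
                 details = list(lambda = lambda_hat, loglik = ll1,
                                loglik_null = ll0))
}

#' Kaplan-Meier curves by cluster group
#'
#' Product-limit survival estimates per group, with an optional annotated
#' base-graphics plot (hazard ratio and LRT p-value from
#' [coxph_label_lrt()] when two groups are present).
#'
#' @param time,event right-censored outcome.
#' @param labels group labels.
#' @return A list of class `km_by_group` with elements `fit` (a
#'   [survival::survfit] object), `table` (tidy per-group step table) and
#'   `test` (the label LRT, or `NULL` for a single group).
#' @export
kaplan_meier_by_group <- function(time, event, labels) {
  z <- factor(unclass(labels))
  keep_lv <- levels(droplevels(z))
  if (length(keep_lv) < nlevels(z))
    warning("empty group(s) dropped from the survival curves")
  z <- droplevels(z)
  dat <- data.frame(time = time, event = event, group = z)
  fit <- survival::survfit(Surv(time, event) ~ group, data = dat)
  s <- summary(fit, censored = TRUE)
  strata <- if (is.null(s$strata)) rep(keep_lv[1], length(s$time)) else
    sub("^group=", "", as.character(s$strata))
  tab <- data.frame(group = strata, time = s$time, n.risk = s$n.risk,
                    n.event = s$n.event, surv = s$surv)
  test <- if (length(keep_lv) >= 2 && sum(event) > 0)
    coxph_label_lrt(time, event, z) else NULL
  structure(list(fit = fit, table = tab, test = test), class = "km_by_group")
}

#' @export
print.km_by_group <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$test)) print(x$test)
  invisible(x)
}

#' @export
plot.km_by_group <- function(x, main = "Kaplan-Meier by cluster", ...) {
  ngrp <- max(1L, length(x$fit$strata))
  graphics::plot(x$fit, col = seq_len(ngrp), mark.time = TRUE,
                 xlab = "time", ylab = "survival probability", main = main, ...)
  if (!is.null(x$test) && !is.null(x$test$effect))
    graphics::legend("bottomleft", bty = "n",
                     legend = sprintf("HR = %.3f, p = %.4f",
                                      x$test$effect[["HR"]], x$test$p.value))
  invisible(x)
}

#' Serialize association-test results to JSON
#'
#' @param results an `assoc_test` or list of them.
#' @param path output path.
#' @export
write_test_results <- function(results, path) {
  if (inherits(results, "assoc_test")) results <- list(results)
  rec <- lapply(results, function(r) {
    list(test = r$test, statistic = r$statistic, null_distribution = r$null_dist,
         p_value = r$p.value, effect = as.list(r$effect), converged = r$converged)
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
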