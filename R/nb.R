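# Negative binomial double regression: log link on the mean (with offset)
# and log link on the dispersion phi, canonical parametrization
# Var(Y) = mu + phi * mu^2 (NB size = 1/phi).

PHI_MIN <- 1e-8
PHI_MAX <- 1e4

nb2_negloglik <- function(par, y, X, Z, offset) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)]) + offset
  g <- drop(Z %*% par[-seq_len(p)])
  mu <- exp(pmin(eta, 30))
  phi <- exp(pmin(pmax(g, log(PHI_MIN)), log(PHI_MAX)))
  s <- 1 / phi
  -sum(lgamma(y + s) - lgamma(s) - lgamma(y + 1) +
         s * log(s / (s + mu)) + y * log(mu / (s + mu)))
}

nb2_neggrad <- function(par, y, X, Z, offset) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)]) + offset
  g <- drop(Z %*% par[-seq_len(p)])
  mu <- exp(pmin(eta, 30))
  phi <- exp(pmin(pmax(g, log(PHI_MIN)), log(PHI_MAX)))
  s <- 1 / phi
  dl_dmu <- y / mu - (y + s) / (s + mu)
  dl_ds <- digamma(y + s) - digamma(s) + log(s / (s + mu)) + 1 -
    (y + s) / (s + mu)
  gb <- drop(crossprod(X, dl_dmu * mu))
  gg <- drop(crossprod(Z, dl_ds * (-s)))
  -c(gb, gg)
}

#' Fit a negative binomial double regression to one gene
#'
#' Maximizes the canonical NB log-likelihood with a log-linear submodel for
#' the mean (plus offset) and a log-linear submodel for the dispersion.
#' Initialization is Poisson-regression means plus a method-of-moments
#' dispersion; up to two restarts with perturbed dispersion intercepts are
#' tried before flagging non-convergence. The dispersion is clamped to
#' `[1e-8, 1e4]` via box constraints on its log.
#'
#' @param y non-negative integer counts for one gene.
#' @param X mean design matrix (with intercept).
#' @param Z dispersion design matrix (with intercept).
#' @param offset per-sample log offset (log relative effective library size).
#' @return list with `coef_mean`, `coef_disp`, `loglik`, `se_mean`,
#'   `se_disp` (observed-information standard errors), `converged`.
#' @export
fit_nb_double_regression <- function(y, X, Z = X, offset = rep(0, length(y))) {
  if (any(y < 0) || any(y != round(y))) stop_msg("'y' must be non-negative integers")
  X <- as.matrix(X); Z <- as.matrix(Z)
  p <- ncol(X); q <- ncol(Z)
  beta0 <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                    offset = offset)$coefficients),
    error = function(e) NULL)
  if (is.null(beta0) || any(!is.finite(beta0)))
    beta0 <- c(log(mean(y) + 0.1), rep(0, p - 1L))
  mu0 <- exp(pmin(drop(X %*% beta0) + offset, 30))
  phi0 <- max(sum((y - mu0)^2 - mu0) / sum(mu0^2), 1e-4)
  starts <- list(c(beta0, log(phi0), rep(0, q - 1L)),
                 c(beta0, log(phi0) + 1, rep(0, q - 1L)),
                 c(beta0, log(phi0) - 1, rep(0, q - 1L)))
  lower <- c(rep(-30, p), rep(log(PHI_MIN), q))
  upper <- c(rep(30, p), rep(log(PHI_MAX), q))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, nb2_negloglik, nb2_neggrad, y = y, X = X, Z = Z,
                   offset = offset, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value - 1e-10)) {
      fit$ok <- fit$convergence == 0
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (!is.null(best) && isTRUE(best$ok)) break
  }
  if (is.null(best)) {
    return(list(coef_mean = rep(NA_real_, p), coef_disp = rep(NA_real_, q),
                loglik = NA_real_, se_mean = rep(NA_real_, p),
                se_disp = rep(NA_real_, q), converged = FALSE))
  }
  H <- tryCatch(
    stats::optimHess(best$par, nb2_negloglik, nb2_neggrad, y = y, X = X,
                     Z = Z, offset = offset),
    error = function(e) NULL)
  se <- rep(NA_real_, p + q)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)
      se <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
    }
  }
  list(coef_mean = best$par[seq_len(p)],
       coef_disp = best$par[p + seq_len(q)],
       loglik = -best$value,
       se_mean = se[seq_len(p)],
       se_disp = se[p + seq_len(q)],
       converged = isTRUE(best$ok))
}

#' Likelihood-ratio test for condition-dependent dispersion (double NB GLM)
#'
#' For every gene, fits the full double NB regression (condition and batch
#' covariates in both the mean and dispersion submodels) and a reduced model
#' with constant dispersion across conditions; twice the log-likelihood
#' difference is referred to a chi-squared distribution with 1 degree of
#' freedom. The analogous reduction of the mean submodel gives the mean
#' p-value. Non-converged genes are flagged and carry p = 1.
#'
#' @param dataset a filtered [count_dataset()].
#' @param design a [group_design()].
#' @return a detector result data.frame (`method = "gamlss"`).
#' @export
gamlss_dispersion_lrt <- function(dataset, design) {
  stopifnot(inherits(dataset, "count_dataset"), inherits(design, "group_design"))
  counts <- dataset$counts
  n_genes <- nrow(counts)
  X <- design$X; Z <- design$Z; off <- design$offset
  cond_col <- which(colnames(X) == "condition")
  Xr <- X[, -cond_col, drop = FALSE]
  Zr <- Z[, -cond_col, drop = FALSE]
  l2mfc <- l2dfc <- stat_m <- stat_d <- p_m <- p_d <- rep(NA_real_, n_genes)
  conv <- logical(n_genes)
  for (i in seq_len(n_genes)) {
    y <- counts[i, ]
    full <- fit_nb_double_regression(y, X, Z, off)
    red_d <- fit_nb_double_regression(y, X, Zr, off)
    red_m <- fit_nb_double_regression(y, Xr, Z, off)
    ok <- full$converged && red_d$converged && red_m$converged &&
      is.finite(full$loglik) && is.finite(red_d$loglik) &&
      is.finite(red_m$loglik)
    conv[i] <- ok
    if (!ok) { p_m[i] <- 1; p_d[i] <- 1; next }
    l2mfc[i] <- full$coef_mean[cond_col] / log(2)
    l2dfc[i] <- full$coef_disp[cond_col] / log(2)
    stat_d[i] <- max(2 * (full$loglik - red_d$loglik), 0)
    stat_m[i] <- max(2 * (full$loglik - red_m$loglik), 0)
    p_d[i] <- stats::pchisq(stat_d[i], df = 1, lower.tail = FALSE)
    p_m[i] <- stats::pchisq(stat_m[i], df = 1, lower.tail = FALSE)
  }
  detector_result(dataset$gene_ids, l2mfc, l2dfc, stat_m, stat_d,
                  p_m, p_d, conv, "gamlss")
}
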