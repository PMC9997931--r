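# Mean/variance reparameterized negative binomial Wald test ("MDSeq-style"):
# Var(Y) = phi * mu with phi > 1, log-linear submodels for mu and phi,
# maximized under linear inequality constraints by an adaptive-barrier
# BFGS scheme (constrOptim), Wald tests against a fold-change threshold.

# negative log-likelihood in the linear parametrization: size = mu/(phi-1)
nblin_negloglik <- function(par, y, X, Z, offset) {
  p <- ncol(X)
  mu <- exp(pmin(drop(X %*% par[seq_len(p)]) + offset, 30))
  phi <- exp(pmin(drop(Z %*% par[-seq_len(p)]), 30))
  if (any(phi <= 1)) return(Inf)
  s <- mu / (phi - 1)
  -sum(lgamma(y + s) - lgamma(s) - lgamma(y + 1) +
         s * log(s / (s + mu)) + y * log(mu / (s + mu)))
}

nblin_neggrad <- function(par, y, X, Z, offset) {
  p <- ncol(X)
  mu <- exp(pmin(drop(X %*% par[seq_len(p)]) + offset, 30))
  phi <- exp(pmin(drop(Z %*% par[-seq_len(p)]), 30))
  s <- mu / (phi - 1)
  dl_dmu <- y / mu - (y + s) / (s + mu)
  dl_ds <- digamma(y + s) - digamma(s) + log(s / (s + mu)) + 1 -
    (y + s) / (s + mu)
  gb <- drop(crossprod(X, (dl_dmu + dl_ds / (phi - 1)) * mu))
  gg <- drop(crossprod(Z, dl_ds * (-mu * phi / (phi - 1)^2)))
  -c(gb, gg)
}

#' Robust outlier trimming before the reparameterized NB fit
#'
#' Per condition, removes normalized counts exceeding
#' `median + mad_k * MAD` provided at least `min_retained` samples remain
#' in that condition (the least extreme flagged values are kept when the
#' floor would be violated). The rule is plumbing ahead of the Wald test,
#' not part of the statistical model.
#'
#' @param y raw counts for one gene.
#' @param design a [group_design()] (supplies condition labels and offsets).
#' @param min_retained minimum samples kept per condition (default 1).
#' @param mad_k MAD multiplier (default 5).
#' @return logical vector: TRUE for retained samples.
#' @export
mdseq_outlier_trim <- function(y, design, min_retained = 1L, mad_k = 5) {
  stopifnot(inherits(design, "group_design"), min_retained >= 1L)
  norm <- y / exp(design$offset)
  keep <- rep(TRUE, length(y))
  for (g in c(0L, 1L)) {
    idx <- which(design$condition == g)
    v <- norm[idx]
    thr <- stats::median(v) + mad_k * stats::mad(v)
    flag <- v > thr
    if (sum(!flag) < min_retained && any(flag)) {
      ord <- order(v[flag])
      need <- min_retained - sum(!flag)
      flag[which(flag)[ord[seq_len(need)]]] <- FALSE
    }
    keep[idx[flag]] <- FALSE
  }
  keep
}

fit_nblin_constrained <- function(y, X, Z, offset) {
  p <- ncol(X); q <- ncol(Z)
  beta0 <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                    offset = offset)$coefficients),
    error = function(e) NULL)
  if (is.null(beta0) || any(!is.finite(beta0)))
    beta0 <- c(log(mean(y) + 0.1), rep(0, p - 1L))
  mu0 <- exp(pmin(drop(X %*% beta0) + offset, 30))
  phi0 <- max(sum((y - mu0)^2 / pmax(mu0, 1e-8)) / length(y), 1.1)
  theta0 <- c(beta0, log(phi0), rep(0, q - 1L))
  # feasibility: phi > 1 at every observed dispersion-design row
  zu <- unique(Z)
  ui <- cbind(matrix(0, nrow(zu), p), zu)
  ci <- rep(1e-6, nrow(zu))
  if (any(ui %*% theta0 <= ci))
    theta0 <- c(beta0, log(1.5), rep(0, q - 1L))
  fit <- tryCatch(
    stats::constrOptim(theta0, nblin_negloglik, nblin_neggrad,
                       ui = ui, ci = ci, method = "BFGS",
                       y = y, X = X, Z = Z, offset = offset,
                       control = list(maxit = 200, reltol = 1e-10),
                       outer.iterations = 30),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value))
    return(list(converged = FALSE))
  H <- tryCatch(
    stats::optimHess(fit$par, nblin_negloglik, nblin_neggrad, y = y,
                     X = X, Z = Z, offset = offset),
    error = function(e) NULL)
  se <- rep(NA_real_, p + q)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) { d <- diag(V); se <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_) }
  }
  list(coef_mean = fit$par[seq_len(p)], coef_disp = fit$par[p + seq_len(q)],
       se_mean = se[seq_len(p)], se_disp = se[p + seq_len(q)],
       loglik = -fit$value,
       boundary = any(drop(zu %*% fit$par[p + seq_len(q)]) < 0.01),
       converged = fit$convergence == 0)
}

# threshold Wald p-value: tau = 1 reduces to the two-sided zero-null test
threshold_wald_p <- function(coef, se, tau) {
  lt <- log(tau)
  p_up <- stats::pnorm((coef - lt) / se, lower.tail = FALSE)
  p_dn <- stats::pnorm((-coef - lt) / se, lower.tail = FALSE)
  pmin(2 * pmin(p_up, p_dn), 1)
}

#' Wald tests for mean and variance/mean-ratio differences ("MDSeq-style")
#'
#' Fits, per gene, the negative binomial reparameterized with a linear
#' mean-variance relationship Var(Y) = \eqn{\phi\mu} (equivalently canonical
#' dispersion \eqn{\alpha = (\phi-1)/\mu}), with log-linear submodels for
#' \eqn{\mu} and \eqn{\phi} over condition and batch covariates, maximized
#' under the constraint \eqn{\phi > 1} by an adaptive-barrier BFGS scheme.
#' Condition coefficients are tested by Wald tests against
#' `log(fc_threshold)` (threshold 1 = standard two-sided test). The
#' dispersion effect `log2_disp_fc` is reported on the \eqn{\phi}
#' (variance/mean) scale. Outlier trimming via [mdseq_outlier_trim()] is
#' applied per gene first.
#'
#' @param dataset a filtered [count_dataset()].
#' @param design a [group_design()].
#' @param fc_threshold_mean,fc_threshold_disp Wald fold-change thresholds
#'   (>= 1, default 1).
#' @param trim apply the outlier-removal rule (default TRUE).
#' @param min_retained minimum samples kept per condition when trimming.
#' @return a detector result data.frame (`method = "mdseq"`).
#' @export
mdseq_mean_dispersion_test <- function(dataset, design,
                                       fc_threshold_mean = 1,
                                       fc_threshold_disp = 1,
                                       trim = TRUE, min_retained = 1L) {
  stopifnot(inherits(dataset, "count_dataset"), inherits(design, "group_design"))
  if (fc_threshold_mean < 1 || fc_threshold_disp < 1)
    stop_msg("fold-change thresholds must be >= 1")
  counts <- dataset$counts
  n_genes <- nrow(counts)
  X <- design$X; Z <- design$Z; off <- design$offset
  cond_col <- which(colnames(X) == "condition")
  l2mfc <- l2dfc <- stat_m <- stat_d <- p_m <- p_d <- rep(NA_real_, n_genes)
  conv <- logical(n_genes); bound <- logical(n_genes)
  for (i in seq_len(n_genes)) {
    y <- counts[i, ]
    keep <- if (trim) mdseq_outlier_trim(y, design, min_retained) else
      rep(TRUE, length(y))
    fit <- fit_nblin_constrained(y[keep], X[keep, , drop = FALSE],
                                 Z[keep, , drop = FALSE], off[keep])
    if (!isTRUE(fit$converged) || !is.finite(fit$se_mean[cond_col]) ||
        !is.finite(fit$se_disp[cond_col])) {
      conv[i] <- FALSE; p_m[i] <- 1; p_d[i] <- 1; next
    }
    conv[i] <- TRUE
    bound[i] <- fit$boundary
    l2mfc[i] <- fit$coef_mean[cond_col] / log(2)
    l2dfc[i] <- fit$coef_disp[cond_col] / log(2)
    stat_m[i] <- fit$coef_mean[cond_col] / fit$se_mean[cond_col]
    stat_d[i] <- fit$coef_disp[cond_col] / fit$se_disp[cond_col]
    p_m[i] <- threshold_wald_p(fit$coef_mean[cond_col], fit$se_mean[cond_col],
                               fc_threshold_mean)
    p_d[i] <- threshold_wald_p(fit$coef_disp[cond_col], fit$se_disp[cond_col],
                               fc_threshold_disp)
  }
  detector_result(dataset$gene_ids, l2mfc, l2dfc, stat_m, stat_d,
                  p_m, p_d, conv, "mdseq", boundary = bound)
}
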