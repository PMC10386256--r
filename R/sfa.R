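#' Fit a stochastic frontier regression to input slacks
#'
#' Second-stage environmental adjustment: regress one input's DEA slack values
#' on the environmental covariates with a composed error
#' \eqn{S = Z\beta + \nu + \mu}, where \eqn{\nu ~ N(0, \sigma_\nu^2)} is
#' statistical noise and \eqn{\mu ~ N^+(0, \sigma_\mu^2)} is half-normal
#' managerial inefficiency entering with positive sign (slack is a "bad": more
#' slack means more inefficiency, the cost-frontier orientation). Estimation
#' is by maximum likelihood in the \eqn{(\sigma^2, \gamma)} parameterization,
#' \eqn{\sigma^2 = \sigma_\nu^2 + \sigma_\mu^2},
#' \eqn{\gamma = \sigma_\mu^2 / \sigma^2}, with multi-start BFGS from the OLS
#' fit plus method-of-moments and grid starting points.
#'
#' @param slacks numeric vector of nonnegative input slacks (one observation
#'   per DMU-period).
#' @param Z environmental covariate matrix (one row per observation, no
#'   intercept column; an intercept is added internally).
#' @param input_index optional index/name of the input this fit belongs to.
#' @param n_starts number of multi-start points (the OLS-anchored starts are
#'   always included).
#' @return object of class \code{slack_frontier_fit}: coefficient vector
#'   \code{beta} (intercept first) with standard errors \code{se_beta},
#'   \code{sigma2}, \code{gamma}, \code{sigma_u}, \code{sigma_v},
#'   \code{sfa_lambda} (\eqn{\sigma_\mu/\sigma_\nu}), \code{loglik}, the
#'   pure-noise \code{loglik_ols}, the one-sided LR statistic \code{lr_stat},
#'   per-observation \code{fitted}, residuals \code{eps}, conditional
#'   inefficiency \code{mu_hat} and noise \code{nu_hat} (so
#'   \code{fitted + nu_hat + mu_hat} reproduces the observed slacks exactly),
#'   and a \code{boundary} flag set when \eqn{\gamma} is pinned at 0 or 1.
#' @export
fit_slack_frontier <- function(slacks, Z, input_index = NULL, n_starts = 5L) {
  slacks <- as.numeric(slacks)
  Z <- as.matrix(Z)
  n <- length(slacks); p <- ncol(Z)
  if (nrow(Z) != n) stop("slacks and Z disagree on the number of observations")
  if (n <= p + 3) stop("too few observations to fit the slack frontier")
  if (anyNA(slacks) || anyNA(Z)) stop("missing values in slack regression data")
  ## DEA input slacks are nonnegative by construction, but the composed-error
  ## model itself places no sign restriction on the response, so none is
  ## enforced (simulated data may legitimately go negative).
  D <- cbind(`(Intercept)` = 1, Z)
  if (is.null(colnames(Z))) colnames(D)[-1] <- paste0("z", seq_len(p))

  ## gamma = 0 null: plain normal regression, ML variance
  ols <- stats::lm.fit(D, slacks)
  beta_ols <- ols$coefficients
  res_ols <- ols$residuals
  s2_ols <- mean(res_ols^2)
  loglik_ols <- -n / 2 * (log(2 * pi * s2_ols) + 1)

  negll <- function(par) {
    beta <- par[seq_len(p + 1)]
    s2 <- exp(par[p + 2])
    g <- stats::plogis(par[p + 3])
    eps <- slacks - drop(D %*% beta)
    s <- sqrt(s2)
    lam <- sqrt(g / (1 - g))
    ll <- sum(log(2) - log(s) + stats::dnorm(eps / s, log = TRUE) +
                stats::pnorm(lam * eps / s, log.p = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }

  ## method-of-moments start from OLS residual skew (half-normal third moment)
  m3 <- mean(res_ols^3)
  su_mom <- if (m3 > 0) (m3 / (sqrt(2 / pi) * (1 - 4 / pi) * -1))^(1 / 3) else sqrt(s2_ols) / 2
  g_mom <- min(0.95, max(0.05, su_mom^2 / (su_mom^2 + max(s2_ols - su_mom^2 * (1 - 2 / pi), 1e-8))))
  g_grid <- unique(c(g_mom, 0.1, 0.4, 0.7, 0.9))[seq_len(max(2L, n_starts))]
  g_grid <- g_grid[!is.na(g_grid)]

  best <- NULL
  for (g0 in g_grid) {
    su0 <- sqrt(g0 * s2_ols / (1 - g0 * (1 - 2 / pi)))
    beta0 <- beta_ols
    beta0[1] <- beta0[1] - su0 * sqrt(2 / pi)  # OLS intercept absorbs E[mu]
    par0 <- c(beta0, log(s2_ols + su0^2 * 2 / pi), stats::qlogis(g0))
    fit <- tryCatch(
      stats::optim(par0, negll, method = "BFGS", hessian = FALSE,
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("slack frontier estimation failed to converge from all starts")

  ## polish + curvature at the optimum
  best <- tryCatch(
    stats::optim(best$par, negll, method = "BFGS", hessian = TRUE,
                 control = list(maxit = 500, reltol = 1e-13)),
    error = function(e) best)

  par <- best$par
  beta <- par[seq_len(p + 1)]; names(beta) <- colnames(D)
  sigma2 <- exp(par[p + 2])
  gamma <- stats::plogis(par[p + 3])
  loglik <- -best$value
  if (loglik < loglik_ols - 1e-6) {
    ## likelihood should never fall below the gamma = 0 submodel
    beta <- beta_ols; names(beta) <- colnames(D)
    sigma2 <- s2_ols; gamma <- 0; loglik <- loglik_ols
  }
  sigma_u <- sqrt(gamma * sigma2)
  sigma_v <- sqrt((1 - gamma) * sigma2)
  boundary <- gamma < 1e-4 || gamma > 1 - 1e-4

  se_beta <- rep(NA_real_, p + 1)
  H <- best$hessian
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)[seq_len(p + 1)]
      se_beta[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  names(se_beta) <- colnames(D)

  fitted <- drop(D %*% beta)
  eps <- slacks - fitted
  mu_hat <- if (gamma <= 1e-12) rep(0, n) else
    jondrow_separate(eps, sigma_u, max(sigma_v, 1e-12))
  nu_hat <- eps - mu_hat

  structure(list(input_index = input_index, beta = beta, se_beta = se_beta,
                 sigma2 = sigma2, gamma = gamma, sigma_u = sigma_u,
                 sigma_v = sigma_v,
                 sfa_lambda = if (sigma_v > 0) sigma_u / sigma_v else Inf,
                 loglik = loglik, loglik_ols = loglik_ols,
                 lr_stat = max(0, 2 * (loglik - loglik_ols)),
                 fitted = fitted, eps = eps, mu_hat = mu_hat, nu_hat = nu_hat,
                 boundary = boundary, n = n, convergence = best$convergence),
            class = "slack_frontier_fit")
}

#' @export
print.slack_frontier_fit <- function(x, ...) {
  cat("Normal/half-normal slack frontier fit",
      if (!is.null(x$input_index)) sprintf("(input %s)", x$input_index), "\n")
  tab <- cbind(Estimate = x$beta, `Std. error` = x$se_beta)
  print(round(tab, 4))
  cat(sprintf("sigma^2 = %.4f  gamma = %.4f  logLik = %.4f  LR(gamma=0) = %.4f\n",
              x$sigma2, x$gamma, x$loglik, x$lr_stat))
  if (x$boundary) cat("note: gamma at parameter-space boundary\n")
  invisible(x)
}

#' Conditional mean inefficiency given a composed residual
#'
#' Separates managerial inefficiency from a composed residual
#' \eqn{\varepsilon = \nu + \mu} by the Jondrow conditional expectation for
#' the normal/half-normal pair:
#' \deqn{E[\mu|\varepsilon] = \sigma_* [\phi(z)/\Phi(z) + z], \quad
#'       z = \lambda\varepsilon/\sigma,}
#' with \eqn{\sigma_* = \sigma_\mu \sigma_\nu / \sigma},
#' \eqn{\sigma = \sqrt{\sigma_\mu^2 + \sigma_\nu^2}} and
#' \eqn{\lambda = \sigma_\mu/\sigma_\nu}. The result is strictly positive for
#' finite inputs with \eqn{\sigma_\mu > 0} and non-decreasing in
#' \eqn{\varepsilon}.
#'
#' @param eps numeric vector of composed residuals.
#' @param sigma_u inefficiency scale \eqn{\sigma_\mu \ge 0}.
#' @param sigma_v noise scale \eqn{\sigma_\nu > 0}; zero noise makes the
#'   conditional distribution degenerate (\eqn{\mu = \max(\varepsilon, 0)} in
#'   the limit) and is rejected rather than silently applied.
#' @return numeric vector \eqn{E[\mu|\varepsilon]}.
#' @export
jondrow_separate <- function(eps, sigma_u, sigma_v) {
  if (length(sigma_u) != 1 || length(sigma_v) != 1 || sigma_u < 0)
    stop("sigma_u must be a single nonnegative value")
  if (sigma_v <= 0)
    stop("sigma_v must be strictly positive (the sigma_v = 0 limit is mu = max(eps, 0))")
  if (sigma_u == 0) return(rep(0, length(eps)))
  sigma <- sqrt(sigma_u^2 + sigma_v^2)
  sstar <- sigma_u * sigma_v / sigma
  z <- (sigma_u / sigma_v) * eps / sigma
  ## inverse Mills ratio, computed on the log scale for far-tail stability
  mills <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  sstar * (mills + z)
}

#' Adjust inputs to a common environment and common luck
#'
#' Applies the second-stage correction
#' \deqn{X^A_{ni} = X_{ni} + [\max_i f(Z_i;\hat\beta_n) - f(Z_i;\hat\beta_n)]
#'       + [\max_i \hat\nu_{ni} - \hat\nu_{ni}]}
#' per input: every unit is moved to the least favourable observed
#' environment and the best observed luck, so adjusted inputs never fall
#' below the originals and the observation attaining both maxima is left
#' unchanged. Maxima are taken over all observations of the pooled panel.
#'
#' @param x a [panel_dataset()] (adjusted copy returned) or a numeric input
#'   matrix (adjusted matrix returned).
#' @param fits list with one [fit_slack_frontier()] result per input column,
#'   in column order; a \code{NULL} element leaves that input unadjusted
#'   (used when a slack channel was degenerate, e.g. all units efficient).
#' @return same shape as \code{x}, with inputs replaced by \eqn{X^A}.
#' @export
adjust_inputs <- function(x, fits) {
  X <- if (inherits(x, "panel_dataset")) x$X else as.matrix(x)
  if (length(fits) != ncol(X))
    stop("need exactly one slack frontier fit per input column")
  XA <- X
  for (j in seq_len(ncol(X))) {
    f <- fits[[j]]
    if (is.null(f)) next
    if (!inherits(f, "slack_frontier_fit")) stop("fits must be slack_frontier_fit objects")
    if (length(f$fitted) != nrow(X))
      stop("fit dimensions do not match the panel")
    XA[, j] <- X[, j] + (max(f$fitted) - f$fitted) + (max(f$nu_hat) - f$nu_hat)
  }
  if (inherits(x, "panel_dataset")) {
    out <- x
    out$X <- XA
    out$data[, colnames(XA)] <- XA
    attr(out, "adjusted") <- TRUE
    out
  } else XA
}

#' One-sided likelihood-ratio test for the inefficiency share
#'
#' Tests H0: \eqn{\gamma = 0} (pure noise, no one-sided inefficiency) against
#' \eqn{\gamma > 0}. Because \eqn{\gamma = 0} lies on the boundary of the
#' parameter space, the LR statistic is referred to the 50:50 mixture of a
#' point mass at zero and \eqn{\chi^2_1}; the critical value at level
#' \eqn{\alpha < 0.5} is the \eqn{1 - 2\alpha} quantile of \eqn{\chi^2_1}.
#'
#' @param fit a [fit_slack_frontier()] result.
#' @param alpha significance level, in (0, 0.5).
#' @return list of class \code{lr_gamma_test}: \code{statistic},
#'   \code{critical}, \code{p_value}, \code{alpha}, \code{reject}.
#' @export
lr_test_gamma <- function(fit, alpha = 0.01) {
  stopifnot(inherits(fit, "slack_frontier_fit"), alpha > 0, alpha < 0.5)
  stat <- fit$lr_stat
  critical <- stats::qchisq(1 - 2 * alpha, df = 1)
  p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(statistic = stat, critical = critical, p_value = p,
                 alpha = alpha, reject = stat > critical),
            class = "lr_gamma_test")
}

#' @export
print.lr_gamma_test <- function(x, ...) {
  cat(sprintf("one-sided LR test of gamma = 0 (mixed chi-square null)\n"))
  cat(sprintf("LR = %.4f, critical value at alpha = %g: %.4f, p = %.4g -> %s\n",
              x$statistic, x$alpha, x$critical, x$p_value,
              if (x$reject) "reject" else "do not reject"))
  invisible(x)
}

#' Tabulate slack-frontier fits
#'
#' Assembles the per-input regression report (coefficients with standard
#' errors, \eqn{\sigma^2}, \eqn{\gamma}, log-likelihood and the one-sided LR
#' statistic), one column per input, mirroring the conventional published
#' layout for three-stage adjustments.
#'
#' @param fits list of [fit_slack_frontier()] results (NULL entries skipped).
#' @param input_names optional column labels.
#' @return data.frame with one row per coefficient/summary statistic.
#' @export
sfa_report <- function(fits, input_names = NULL) {
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]
  if (!length(fits)) stop("no fits to report")
  if (is.null(input_names))
    input_names <- vapply(seq_along(fits), function(i)
      as.character(fits[[i]]$input_index %||% paste0("input_", i)), character(1))
  else input_names <- input_names[keep]
  rows <- names(fits[[1]]$beta)
  out <- data.frame(term = c(rows, "sigma_squared", "gamma",
                             "log_likelihood", "lr_statistic"))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    out[[input_names[i]]] <- c(f$beta, f$sigma2, f$gamma, f$loglik, f$lr_stat)
    out[[paste0(input_names[i], "_se")]] <- c(f$se_beta, NA, NA, NA, NA)
  }
  out
}
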