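#' Configuration for the synthetic panel generator
#'
#' Describes a panel with a known Cobb-Douglas (log-linear, constant-returns)
#' frontier, a planted efficient subset, environment-driven slack
#' contamination with known coefficients, and a known per-period frontier
#' drift — so that every stage of the three-stage pipeline can be validated
#' against planted truth.
#'
#' @param n_dmu,n_periods panel dimensions (default 31 DMUs x 13 periods,
#'   the provincial-panel shape the package targets).
#' @param m,q1,q2,p numbers of inputs, desirable outputs, undesirable outputs
#'   and environmental covariates (defaults 3/3/1/4).
#' @param frontier_coeffs list with \code{alpha} (input elasticities, summing
#'   to 1 for constant returns), \code{shares} (desirable-output split) and
#'   \code{tfp} (base productivity); sensible defaults derived from the
#'   dimensions when \code{NULL}.
#' @param inefficiency_scale \eqn{\sigma_\mu} of the half-normal managerial
#'   slack component, recycled over input channels.
#' @param noise_scale \eqn{\sigma_\nu} of the Gaussian slack noise.
#' @param env_effects \eqn{(p+1) \times m} coefficient matrix (intercept row
#'   first) driving the environmental slack component; a fixed alternating
#'   pattern with intercept 2 when \code{NULL}.
#' @param bad_output_ratio undesirable output per unit of total desirable
#'   output.
#' @param drift multiplicative per-period frontier shift (1.03 = 3 percent
#'   technical progress per period).
#' @param frac_efficient fraction of DMUs planted exactly on the frontier
#'   (zero slack in every period).
#' @param env_time_varying if \code{FALSE}, environmental covariates are drawn
#'   once per DMU and repeated across periods.
#' @param seed integer seed; a fixed seed makes the generated panel
#'   bit-identical across calls.
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_dmu = 31L, n_periods = 13L, m = 3L, q1 = 3L,
                             q2 = 1L, p = 4L, frontier_coeffs = NULL,
                             inefficiency_scale = 1, noise_scale = 0.3,
                             env_effects = NULL, bad_output_ratio = 0.1,
                             drift = 1.03, frac_efficient = 0.2,
                             env_time_varying = TRUE, seed = 1L) {
  stopifnot(n_dmu >= 1, n_periods >= 1, m >= 1, q1 >= 1, q2 >= 0, p >= 0,
            all(inefficiency_scale >= 0), noise_scale >= 0,
            bad_output_ratio >= 0, drift > 0,
            frac_efficient >= 0, frac_efficient <= 1)
  if (is.null(frontier_coeffs)) {
    alpha <- rev(seq_len(m)); alpha <- alpha / sum(alpha)
    shares <- rev(seq_len(q1)); shares <- shares / sum(shares)
    frontier_coeffs <- list(alpha = alpha, shares = shares, tfp = 1)
  }
  stopifnot(length(frontier_coeffs$alpha) == m,
            length(frontier_coeffs$shares) == q1)
  frontier_coeffs$alpha <- frontier_coeffs$alpha / sum(frontier_coeffs$alpha)
  frontier_coeffs$shares <- frontier_coeffs$shares / sum(frontier_coeffs$shares)
  if (is.null(env_effects)) {
    env_effects <- matrix(0, p + 1, m)
    env_effects[1, ] <- 2
    if (p > 0) for (j in seq_len(m))
      env_effects[-1, j] <- 0.7 * (-1)^(seq_len(p) + j)
  }
  stopifnot(nrow(env_effects) == p + 1, ncol(env_effects) == m)
  structure(list(n_dmu = as.integer(n_dmu), n_periods = as.integer(n_periods),
                 m = as.integer(m), q1 = as.integer(q1), q2 = as.integer(q2),
                 p = as.integer(p), frontier_coeffs = frontier_coeffs,
                 inefficiency_scale = rep_len(inefficiency_scale, m),
                 noise_scale = noise_scale, env_effects = env_effects,
                 bad_output_ratio = bad_output_ratio, drift = drift,
                 frac_efficient = frac_efficient,
                 env_time_varying = isTRUE(env_time_varying),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic panel with known truth
#'
#' Draws DMUs around the configured Cobb-Douglas frontier. The planted
#' efficient subset sits exactly on the frontier in every period; the
#' remaining observations have their inputs inflated by an additive slack
#' \eqn{S = Z\beta + \mu + \nu} per input channel (environment + half-normal
#' inefficiency + Gaussian noise, floored at zero so inputs stay positive),
#' matching the structure the second-stage regression assumes. Undesirable
#' output is coupled to total desirable output (ratio plus positive noise for
#' contaminated units). The frontier's total factor productivity drifts by the
#' configured factor each period. DMUs are assigned to three synthetic regions
#' in near-equal blocks for exercising the regional reporting conventions.
#'
#' @param config a [synthetic_config()].
#' @return list with \code{panel} (a [panel_dataset()]) and \code{truth}: the
#'   efficient-observation mask, planted slack matrix and its three
#'   components, the coefficient matrix, scales, drift and frontier
#'   parameters.
#' @export
generate_panel <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  n_obs <- cf$n_dmu * cf$n_periods
  dmu_ids <- sprintf("dmu%02d", seq_len(cf$n_dmu))
  periods <- sprintf("t%02d", seq_len(cf$n_periods))
  region <- rep(c("east", "central", "west"),
                length.out = 3)[ceiling(seq_len(cf$n_dmu) / (cf$n_dmu / 3))]
  region <- region[seq_len(cf$n_dmu)]

  ## rows in (period, dmu) order, matching the panel normalization
  dmu <- rep(dmu_ids, times = cf$n_periods)
  per <- rep(periods, each = cf$n_dmu)
  ti <- rep(seq_len(cf$n_periods), each = cf$n_dmu)

  out <- with_seed(cf$seed, {
    Z <- if (cf$env_time_varying) {
      matrix(stats::rnorm(n_obs * cf$p), n_obs, cf$p)
    } else {
      Zd <- matrix(stats::rnorm(cf$n_dmu * cf$p), cf$n_dmu, cf$p)
      Zd[rep(seq_len(cf$n_dmu), times = cf$n_periods), , drop = FALSE]
    }
    X0 <- matrix(stats::rlnorm(n_obs * cf$m, log(5), 0.4), n_obs, cf$m)
    n_eff <- ceiling(cf$frac_efficient * cf$n_dmu)
    eff_dmu <- dmu_ids[seq_len(n_eff)]
    efficient <- dmu %in% eff_dmu

    mu <- matrix(abs(stats::rnorm(n_obs * cf$m)), n_obs, cf$m) *
      rep(cf$inefficiency_scale, each = n_obs)
    nu <- matrix(stats::rnorm(n_obs * cf$m), n_obs, cf$m) * cf$noise_scale
    env <- cbind(1, Z) %*% cf$env_effects
    ## the planted-efficient subset is managerially efficient (mu = 0) but
    ## environment and luck are external: they contaminate every unit alike.
    ## When all contamination scales are zero the subset distinction is moot
    ## and every observation sits exactly on the frontier.
    mu[efficient, ] <- 0
    S <- pmax(env + mu + nu, 0)
    bad_noise <- abs(stats::rnorm(n_obs))
    list(Z = Z, X0 = X0, efficient = efficient, mu = mu, nu = nu, env = env,
         S = S, bad_noise = bad_noise)
  })

  tfp <- cf$frontier_coeffs$tfp * cf$drift^(ti - 1)
  ytot <- tfp * exp(log(out$X0) %*% cf$frontier_coeffs$alpha)[, 1]
  Y <- outer(ytot, cf$frontier_coeffs$shares)
  X <- out$X0 + out$S
  B <- if (cf$q2 > 0) {
    b0 <- cf$bad_output_ratio * ytot
    noise <- 0.1 * b0 * out$bad_noise
    noise[out$efficient] <- 0
    matrix(rep(b0 + noise, cf$q2), n_obs, cf$q2)
  } else matrix(numeric(0), n_obs, 0)

  df <- data.frame(dmu = dmu, period = per, region = region[match(dmu, dmu_ids)],
                   stringsAsFactors = FALSE)
  add <- function(df, M, prefix) {
    if (ncol(M) == 0) return(df)
    colnames(M) <- paste0(prefix, seq_len(ncol(M)))
    cbind(df, M)
  }
  df <- add(df, X, "x"); df <- add(df, Y, "y"); df <- add(df, B, "b")
  df <- add(df, out$Z, "z")
  schema <- list(dmu = "dmu", period = "period", region = "region",
                 input = paste0("x", seq_len(cf$m)),
                 desirable = paste0("y", seq_len(cf$q1)),
                 undesirable = if (cf$q2) paste0("b", seq_len(cf$q2)) else character(0),
                 environment = if (cf$p) paste0("z", seq_len(cf$p)) else character(0),
                 period_order = periods)
  panel <- panel_dataset(df, schema)

  truth <- list(efficient = out$efficient, dmu = dmu, period = per,
                slack = out$S, mu = out$mu, nu = out$nu,
                env_component = out$env, env_effects = cf$env_effects,
                sigma_mu = cf$inefficiency_scale, sigma_nu = cf$noise_scale,
                drift = cf$drift, frontier = cf$frontier_coeffs,
                frontier_inputs = out$X0, total_output = ytot)
  list(panel = panel, truth = truth)
}

#' Simulate raw slack-regression data
#'
#' Direct draw from the composed-error model the second stage estimates:
#' \eqn{S = Z\beta + \nu + \mu} with Gaussian noise and half-normal
#' inefficiency. Used to validate parameter recovery of
#' [fit_slack_frontier()] independently of any DEA step.
#'
#' @param n number of observations.
#' @param beta coefficient vector, intercept first (length p + 1).
#' @param sigma_u,sigma_v inefficiency and noise scales.
#' @param seed integer seed.
#' @return list with \code{slacks}, \code{Z} (n x p), and the planted
#'   \code{mu} and \code{nu} components.
#' @export
simulate_slack_data <- function(n, beta, sigma_u, sigma_v, seed = 1L) {
  p <- length(beta) - 1L
  with_seed(seed, {
    Z <- if (p > 0) matrix(stats::rnorm(n * p), n, p) else
      matrix(numeric(0), n, 0)
    mu <- abs(stats::rnorm(n)) * sigma_u
    nu <- stats::rnorm(n) * sigma_v
    slacks <- drop(cbind(1, Z) %*% beta) + mu + nu
    list(slacks = slacks, Z = Z, mu = mu, nu = nu)
  })
}
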