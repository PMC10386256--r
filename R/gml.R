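#' Efficiency distance of one observation to a reference technology
#'
#' Output-distance value of an observation against a reference set under
#' constant returns to scale (the convention for global productivity
#' indices: the pooled benchmark guarantees feasibility and index
#' circularity). Two measures are available:
#' \describe{
#'   \item{\code{"sbm"}}{the slack-based efficiency score of [solve_sbm()]
#'     (default; consistent with the stage scoring).}
#'   \item{\code{"radial_output"}}{the reciprocal of the largest radial
#'     desirable-output expansion feasible inside the technology, with
#'     undesirable outputs held by the same slack-augmented constraints as
#'     the SBM model.}
#' }
#' Both lie in (0, 1] whenever the observation belongs to the reference set.
#'
#' @param x0,y0,b0 evaluated observation.
#' @param X_ref,Y_ref,B_ref reference technology (rows are observations).
#' @param measure \code{"sbm"} or \code{"radial_output"}.
#' @param backend LP backend, see [solve_lp()].
#' @return a positive scalar distance value.
#' @export
dea_distance <- function(x0, y0, b0 = numeric(0), X_ref, Y_ref, B_ref = NULL,
                         measure = c("sbm", "radial_output"),
                         backend = getOption("frontier3.lp_backend", "internal")) {
  measure <- match.arg(measure)
  if (is.null(B_ref)) B_ref <- matrix(numeric(0), NROW(X_ref), length(b0))
  if (measure == "sbm") {
    r <- sbm_lp(x0, y0, b0, as.matrix(X_ref), as.matrix(Y_ref), as.matrix(B_ref),
                vrs = FALSE, super = FALSE, backend = backend)
    if (r$status != "optimal") stop("distance program ", r$status,
                                    " (observation outside the reference technology?)")
    return(min(max(r$rho, 1e-12), 1 + 1e-9))
  }
  ## radial output expansion: max theta s.t. X'lam <= x0, Y'lam >= theta*y0,
  ## B'lam <= b0, lam >= 0 (CRS); distance = 1/theta
  X_ref <- as.matrix(X_ref); Y_ref <- as.matrix(Y_ref); B_ref <- as.matrix(B_ref)
  n_ref <- nrow(X_ref); m <- length(x0); q1 <- length(y0); q2 <- length(b0)
  A <- rbind(cbind(rep(0, m), t(X_ref)),
             cbind(-y0, t(Y_ref)),
             if (q2) cbind(rep(0, q2), t(B_ref)))
  dir <- c(rep("<=", m), rep(">=", q1), rep("<=", q2))
  rhs <- c(x0, rep(0, q1), b0)
  objv <- c(1, rep(0, n_ref))
  sol <- solve_lp(objv, A, dir, rhs, maximize = TRUE, backend = backend)
  if (sol$status != 0L) stop("radial distance program infeasible or unbounded")
  theta <- sol$value
  if (theta <= 0) stop("degenerate radial distance (theta <= 0)")
  min(1 / theta, 1 + 1e-9)
}

#' Global Malmquist-Luenberger productivity index of a panel
#'
#' For every DMU and every consecutive period pair computes the
#' global-frontier productivity index
#' \deqn{GML = D^G(x^{t+1}, y^{t+1}, b^{t+1}) / D^G(x^t, y^t, b^t)}
#' and its decomposition into the catch-up effect
#' \eqn{EC = D^{t+1}(t+1)/D^t(t)} (movement relative to the contemporaneous
#' frontier) and the best-practice-gap change \eqn{BPC = GML / EC} (shift of
#' the contemporaneous frontier relative to the pooled global frontier, the
#' innovation effect). All distances are constant-returns values of
#' [dea_distance()]; because every observation belongs to the global
#' reference set, no distance program can be infeasible, and the global index
#' is circular (indices over consecutive transitions multiply to the direct
#' multi-period index).
#'
#' @param panel a [panel_dataset()] with at least two periods.
#' @param measure distance measure, see [dea_distance()].
#' @param backend LP backend, see [solve_lp()].
#' @return data.frame of class \code{gml_records}: \code{dmu},
#'   \code{from_period}, \code{to_period}, \code{hsgi}, \code{ec}, \code{bpc}
#'   (with \code{hsgi = ec * bpc} exactly), and the four underlying distances
#'   \code{d_contemp_t}, \code{d_contemp_t1}, \code{d_global_t},
#'   \code{d_global_t1}.
#' @export
gml_panel <- function(panel, measure = c("sbm", "radial_output"),
                      backend = getOption("frontier3.lp_backend", "internal")) {
  stopifnot(inherits(panel, "panel_dataset"))
  measure <- match.arg(measure)
  periods <- panel$periods
  if (length(periods) < 2) stop("need at least two periods for a productivity index")
  X <- panel$X; Y <- panel$Y; B <- panel$B
  n_obs <- nrow(X)

  dist_to <- function(j, ref) {
    d <- dea_distance(X[j, ], Y[j, ], B[j, ], X[ref, , drop = FALSE],
                      Y[ref, , drop = FALSE], B[ref, , drop = FALSE],
                      measure = measure, backend = backend)
    if (d <= 1e-12)
      stop(sprintf("zero distance for dmu '%s', period '%s': degenerate data",
                   panel$dmu[j], panel$period[j]))
    d
  }
  all_idx <- seq_len(n_obs)
  d_global <- vapply(all_idx, dist_to, numeric(1), ref = all_idx)
  per_idx <- split(all_idx, match(panel$period, periods))
  d_contemp <- numeric(n_obs)
  for (g in per_idx) d_contemp[g] <- vapply(g, dist_to, numeric(1), ref = g)

  key <- function(d, p) match(paste(p, d), paste(panel$period, panel$dmu))
  recs <- do.call(rbind, lapply(seq_len(length(periods) - 1), function(ti) {
    t0 <- periods[ti]; t1 <- periods[ti + 1]
    j0 <- key(panel$dmu_ids, t0); j1 <- key(panel$dmu_ids, t1)
    hsgi <- d_global[j1] / d_global[j0]
    ec <- d_contemp[j1] / d_contemp[j0]
    data.frame(dmu = panel$dmu_ids, from_period = t0, to_period = t1,
               hsgi = hsgi, ec = ec, bpc = hsgi / ec,
               d_contemp_t = d_contemp[j0], d_contemp_t1 = d_contemp[j1],
               d_global_t = d_global[j0], d_global_t1 = d_global[j1],
               stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  class(recs) <- c("gml_records", "data.frame")
  recs
}

#' Aggregate productivity records by region and transition
#'
#' Means of the productivity index and its two factors per group and
#' transition, plus a study-period \code{"mean"} row per group (the mean over
#' the per-transition group means, the convention of published regional
#' decomposition tables). Under arithmetic aggregation the identity
#' \code{hsgi = ec * bpc} does not survive averaging (the product of the mean
#' factors need not equal the mean index); a note attribute records this.
#'
#' @param records a \code{gml_records} data.frame from [gml_panel()].
#' @param groups named character vector mapping DMU id to group label (see
#'   [read_region_map()]); \code{NULL} puts every DMU in one
#'   \code{"national"} group. DMUs missing from the map are an error.
#' @param scheme \code{"arithmetic"} (default) or \code{"geometric"} means.
#' @return data.frame with columns \code{group}, \code{transition} (labels
#'   "from/to", or "mean" for the study-period row), \code{hsgi}, \code{ec},
#'   \code{bpc}, and \code{n} (records behind the cell). Attribute
#'   \code{note} documents the aggregation caveat.
#' @export
aggregate_gml <- function(records, groups = NULL,
                          scheme = c("arithmetic", "geometric")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(records))
  if (is.null(groups)) {
    groups <- stats::setNames(rep("national", length(unique(records$dmu))),
                              unique(records$dmu))
  }
  unknown <- setdiff(unique(records$dmu), names(groups))
  if (length(unknown)) stop("DMU(s) missing from the group map: ",
                            paste(unknown, collapse = ", "))
  g <- unname(groups[records$dmu])
  trans <- paste(records$from_period, records$to_period, sep = "/")
  trans_levels <- unique(trans[order(match(records$from_period,
                                           unique(records$from_period)))])
  mfun <- if (scheme == "arithmetic") mean else function(v) exp(mean(log(v)))

  out <- list()
  for (grp in unique(g)) {
    sel <- g == grp
    if (!any(sel)) stop("empty group: ", grp)
    rows <- lapply(trans_levels, function(tr) {
      s <- sel & trans == tr
      data.frame(group = grp, transition = tr,
                 hsgi = mfun(records$hsgi[s]), ec = mfun(records$ec[s]),
                 bpc = mfun(records$bpc[s]), n = sum(s),
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    out[[grp]] <- rbind(rows,
                        data.frame(group = grp, transition = "mean",
                                   hsgi = mfun(rows$hsgi), ec = mfun(rows$ec),
                                   bpc = mfun(rows$bpc), n = sum(rows$n),
                                   stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "note") <- if (scheme == "arithmetic")
    "arithmetic aggregation: mean(hsgi) differs from mean(ec) * mean(bpc)" else
      "geometric aggregation: the ec * bpc identity survives averaging"
  res
}
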