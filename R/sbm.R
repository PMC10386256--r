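#' Specify a slack-based measure (SBM) program
#'
#' Bundles the data of one SBM evaluation: the evaluated unit's input vector
#' \code{x0}, desirable outputs \code{y0} and undesirable outputs \code{b0},
#' the reference technology (rows of \code{X_ref}, \code{Y_ref}, \code{B_ref}
#' are observations), the returns-to-scale assumption and whether the
#' evaluated unit is excluded from its own reference set (super-efficiency).
#'
#' @param x0,y0,b0 numeric vectors for the evaluated unit (\code{b0} may be
#'   length zero for the classic SBM without undesirable outputs).
#' @param X_ref,Y_ref,B_ref reference matrices, one row per reference
#'   observation; column counts must match \code{x0}, \code{y0}, \code{b0}.
#' @param rts \code{"crs"} (constant returns) or \code{"vrs"} (adds the
#'   convexity constraint on the intensity weights).
#' @param exclude_self logical; \code{TRUE} for super-efficiency programs,
#'   in which case the reference matrices must already exclude the evaluated
#'   observation.
#' @param evaluated,reference optional bookkeeping indices (evaluated
#'   observation and reference observation indices in some enclosing panel).
#' @return an object of class \code{sbm_program}.
#' @export
sbm_program <- function(x0, y0, b0 = numeric(0), X_ref, Y_ref,
                        B_ref = NULL, rts = c("crs", "vrs"),
                        exclude_self = FALSE,
                        evaluated = NULL, reference = NULL) {
  rts <- match.arg(rts)
  X_ref <- as_ref_matrix(X_ref, length(x0), "X_ref")
  Y_ref <- as_ref_matrix(Y_ref, length(y0), "Y_ref")
  if (is.null(B_ref)) B_ref <- matrix(numeric(0), nrow(X_ref), length(b0))
  B_ref <- as_ref_matrix(B_ref, length(b0), "B_ref")
  if (nrow(X_ref) == 0) stop("reference set is empty")
  if (nrow(Y_ref) != nrow(X_ref) || nrow(B_ref) != nrow(X_ref))
    stop("reference matrices disagree on the number of observations")
  if (any(x0 <= 0)) stop("evaluated inputs must be strictly positive")
  if (any(y0 < 0) || any(b0 < 0)) stop("outputs must be nonnegative")
  if (exclude_self && !is.null(evaluated) && !is.null(reference) &&
      evaluated %in% reference)
    stop("evaluated observation must not be in the reference set when exclude_self")
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0), b0 = as.numeric(b0),
                 X_ref = X_ref, Y_ref = Y_ref, B_ref = B_ref, rts = rts,
                 exclude_self = exclude_self, evaluated = evaluated,
                 reference = reference),
            class = "sbm_program")
}

as_ref_matrix <- function(M, p, what) {
  M <- as.matrix(M)
  if (p == 0 && ncol(M) != 0 && nrow(M) > 0 && length(M) == 0) return(M)
  if (ncol(M) != p) {
    ## allow a column vector supplied for a single dimension
    if (p == 1 && nrow(M) == 1) M <- t(M)
    if (ncol(M) != p) stop(what, " must have ", p, " column(s)")
  }
  storage.mode(M) <- "double"
  M
}

## Core LP assembly/solve shared by the plain and super-efficiency SBM.
##
## Both fractional programs are linearized exactly with the Charnes-Cooper
## transform: introduce t > 0, scale intensities and slacks by t, and pin the
## (positive) fractional denominator to 1. The LP optimum then equals the
## fractional optimum, and the denominator-positivity side constraint of the
## super-efficiency model holds by construction.
##
## Terms of the objective average whose evaluated output (y0 or b0) is zero
## would divide by zero; they are dropped and the averaging count reduced
## accordingly (documented convention).
sbm_lp <- function(x0, y0, b0, X_ref, Y_ref, B_ref, vrs, super, backend) {
  m <- length(x0); q1 <- length(y0); q2 <- length(b0)
  n_ref <- nrow(X_ref)
  Lblk <- -t(cbind(X_ref, Y_ref, B_ref))       # (m+q1+q2) x n_ref intensity block
  obs <- c(x0, y0, b0)
  k_rows <- m + q1 + q2

  ssign <- c(rep(if (super) 1 else -1, m),     # input slack columns
             rep(if (super) -1 else 1, q1),    # desirable output slacks
             rep(if (super) 1 else -1, q2))    # undesirable output slacks
  Sblk <- diag(ssign, k_rows, k_rows)

  ok_y <- y0 > 0; ok_b <- b0 > 0
  q_eff <- sum(ok_y) + sum(ok_b)
  wy <- ifelse(ok_y, 1 / (q_eff * y0), 0)
  wb <- ifelse(ok_b, 1 / (q_eff * b0), 0)
  dsign <- if (super) -1 else 1                # denominator slack sign
  norm_row <- c(1, rep(0, n_ref), rep(0, m), dsign * wy, dsign * wb)

  A <- cbind(obs, Lblk, Sblk, deparse.level = 0)
  A <- rbind(A, norm_row, deparse.level = 0)
  dir <- c(if (super) c(rep(">=", m), rep("<=", q1), rep(">=", q2))
           else rep("==", k_rows), "==")
  rhs <- c(rep(0, k_rows), 1)
  if (vrs) {
    A <- rbind(A, c(-1, rep(1, n_ref), rep(0, k_rows)), deparse.level = 0)
    dir <- c(dir, "=="); rhs <- c(rhs, 0)
  }
  osign <- if (super) 1 else -1
  objv <- c(1, rep(0, n_ref), osign / (m * x0), rep(0, q1 + q2))

  sol <- solve_lp(objv, A, dir, rhs, maximize = FALSE, backend = backend)
  if (sol$status == 3L) stop("SBM program unbounded: modelling error")
  if (sol$status != 0L) return(list(status = "infeasible"))
  t_cc <- sol$x[1]
  if (t_cc <= 1e-10) return(list(status = "degenerate"))
  lam <- pmax(sol$x[1 + seq_len(n_ref)] / t_cc, 0)   # clamp solver dust
  sl <- pmax(sol$x[1 + n_ref + seq_len(k_rows)] / t_cc, 0)
  list(status = "optimal", rho = sol$value, lambda = lam,
       s_in = sl[seq_len(m)], s_out = sl[m + seq_len(q1)],
       s_bad = if (q2) sl[m + q1 + seq_len(q2)] else numeric(0))
}

#' Solve the undesirable-output SBM efficiency program
#'
#' Minimizes the ratio of one minus the mean proportional input slack to one
#' plus the mean proportional (desirable and undesirable) output slack against
#' the reference technology, with undesirable outputs entering through
#' slack-augmented constraint rows. The fractional program is linearized
#' exactly (Charnes-Cooper), so the returned score equals the fractional
#' optimum to solver tolerance. The score lies in (0, 1], and equals 1 with
#' all-zero slacks exactly when the unit is on the weakly efficient frontier
#' of its reference set.
#'
#' @param program an [sbm_program()] with \code{exclude_self = FALSE}.
#' @param backend LP backend, see [solve_lp()].
#' @return list with \code{te} (the score), slack vectors \code{input_slacks},
#'   \code{output_slacks}, \code{bad_slacks}, the intensity weights
#'   \code{lambda}, and \code{status}.
#' @export
solve_sbm <- function(program, backend = getOption("frontier3.lp_backend", "internal")) {
  stopifnot(inherits(program, "sbm_program"))
  if (program$exclude_self) stop("solve_sbm expects exclude_self = FALSE; use solve_super_sbm")
  r <- sbm_lp(program$x0, program$y0, program$b0, program$X_ref,
              program$Y_ref, program$B_ref, vrs = program$rts == "vrs",
              super = FALSE, backend = backend)
  if (r$status != "optimal")
    stop("SBM program reported ", r$status,
         ": internal inconsistency (the evaluated unit should envelop itself)")
  list(te = min(max(r$rho, 1e-12), 1 + 1e-9), input_slacks = r$s_in,
       output_slacks = r$s_out, bad_slacks = r$s_bad,
       lambda = r$lambda, status = "optimal")
}

#' Solve the super-efficiency SBM program
#'
#' Scores a unit that is efficient under [solve_sbm()] against the frontier of
#' all *other* reference observations, yielding a score of at least 1 that
#' ranks efficient units. The denominator-positivity constraint of the
#' fractional program is enforced by the linearization (the denominator is
#' pinned to 1). Under variable returns to scale the program can be
#' infeasible; this is reported as \code{status = "super_infeasible"} with a
#' score of exactly 1 rather than an error, so panels stay balanced.
#'
#' @param program an [sbm_program()] with \code{exclude_self = TRUE} and the
#'   evaluated observation absent from the reference matrices.
#' @param nonsuper_te optional plain SBM score of the evaluated unit; if
#'   supplied and below 1 (tolerance 1e-6) a contract error is raised, since
#'   super-efficiency scoring applies only to efficient units.
#' @param backend LP backend, see [solve_lp()].
#' @return list as in [solve_sbm()] with \code{te} the super score.
#' @export
solve_super_sbm <- function(program, nonsuper_te = NULL,
                            backend = getOption("frontier3.lp_backend", "internal")) {
  stopifnot(inherits(program, "sbm_program"))
  if (!program$exclude_self) stop("solve_super_sbm expects exclude_self = TRUE")
  if (!is.null(nonsuper_te) && nonsuper_te < 1 - 1e-6)
    stop("contract error: super-efficiency scoring applies only to units with SBM score 1")
  r <- sbm_lp(program$x0, program$y0, program$b0, program$X_ref,
              program$Y_ref, program$B_ref, vrs = program$rts == "vrs",
              super = TRUE, backend = backend)
  if (r$status != "optimal") {
    return(list(te = 1, input_slacks = rep(NA_real_, length(program$x0)),
                output_slacks = rep(NA_real_, length(program$y0)),
                bad_slacks = rep(NA_real_, length(program$b0)),
                lambda = NULL, status = "super_infeasible"))
  }
  list(te = max(r$rho, 1 - 1e-9), input_slacks = r$s_in,
       output_slacks = r$s_out, bad_slacks = r$s_bad,
       lambda = r$lambda, status = "optimal")
}

#' Describe the benchmark technology
#'
#' @param returns_to_scale \code{"crs"} or \code{"vrs"}.
#' @param frontier \code{"global"} pools every period's observations into one
#'   benchmark (each province-year treated as a distinct DMU, so scores are
#'   comparable across years); \code{"contemporaneous"} restricts the
#'   reference set to the evaluated observation's own period.
#' @param super_efficiency logical; re-score efficient units against the
#'   frontier of the remaining observations.
#' @return an object of class \code{technology_spec}.
#' @export
technology_spec <- function(returns_to_scale = c("crs", "vrs"),
                            frontier = c("global", "contemporaneous"),
                            super_efficiency = FALSE) {
  structure(list(returns_to_scale = match.arg(returns_to_scale),
                 frontier = match.arg(frontier),
                 super_efficiency = isTRUE(super_efficiency)),
            class = "technology_spec")
}

#' Score every observation of a panel
#'
#' Runs the SBM program under constant returns (giving comprehensive technical
#' efficiency, \code{te}) and variable returns (pure technical efficiency,
#' \code{pte}) for every observation, and forms scale efficiency
#' \code{se = te / pte}, so \code{te = pte * se} holds exactly on the
#' unrounded values. With \code{super_efficiency}, units whose plain score
#' reaches 1 (tolerance 1e-6) are re-scored by [solve_super_sbm()] under the
#' corresponding returns-to-scale assumption, and \code{te} / \code{pte} are
#' replaced by the super score. Under the global frontier the super-efficiency
#' exclusion removes only the evaluated (dmu, period) observation, not the
#' same DMU's other years.
#'
#' The reported slack columns are always those of the plain (non-super)
#' constant-returns run; these are the slacks the second-stage environmental
#' regression consumes.
#'
#' @param panel a [panel_dataset()].
#' @param tech a [technology_spec()]; \code{returns_to_scale} is ignored here
#'   because both assumptions are needed for the te/pte/se decomposition.
#' @param backend LP backend, see [solve_lp()].
#' @return data.frame of class \code{efficiency_records} with one row per
#'   observation: \code{dmu}, \code{period}, \code{te}, \code{pte}, \code{se},
#'   the plain scores \code{te_nonsuper} / \code{pte_nonsuper}, solver
#'   \code{status}, and slack columns \code{s_in_*}, \code{s_out_*},
#'   \code{s_bad_*}.
#' @export
score_panel <- function(panel, tech = technology_spec(),
                        backend = getOption("frontier3.lp_backend", "internal")) {
  stopifnot(inherits(panel, "panel_dataset"), inherits(tech, "technology_spec"))
  X <- panel$X; Y <- panel$Y; B <- panel$B
  if (ncol(B)) {
    dead <- which(colSums(B) == 0)
    if (length(dead)) {
      warning("undesirable output column(s) all zero, dropped for scoring: ",
              paste(colnames(B)[dead], collapse = ", "))
      B <- B[, -dead, drop = FALSE]
    }
  }
  n_obs <- nrow(X)
  ref_of <- if (tech$frontier == "global") rep(1L, n_obs) else
    match(panel$period, panel$periods)
  ref_idx <- split(seq_len(n_obs), ref_of)

  eff_tol <- 1e-6
  solve_one <- function(j, ref, vrs, super) {
    sbm_lp(X[j, ], Y[j, ], B[j, ], X[ref, , drop = FALSE],
           Y[ref, , drop = FALSE], B[ref, , drop = FALSE],
           vrs = vrs, super = super, backend = backend)
  }

  res <- vector("list", n_obs)
  for (g in ref_idx) {
    for (j in g) {
      crs <- solve_one(j, g, vrs = FALSE, super = FALSE)
      vrsr <- solve_one(j, g, vrs = TRUE, super = FALSE)
      if (crs$status != "optimal" || vrsr$status != "optimal")
        stop(sprintf("SBM solve failed for dmu '%s', period '%s' (%s)",
                     panel$dmu[j], panel$period[j],
                     paste(crs$status, vrsr$status)))
      te <- min(max(crs$rho, 1e-12), 1 + 1e-9)
      pte <- min(max(vrsr$rho, 1e-12), 1 + 1e-9)
      status <- "optimal"
      if (tech$super_efficiency) {
        ref_ex <- setdiff(g, j)
        if (length(ref_ex)) {
          if (te >= 1 - eff_tol) {
            sc <- sbm_lp(X[j, ], Y[j, ], B[j, ], X[ref_ex, , drop = FALSE],
                         Y[ref_ex, , drop = FALSE], B[ref_ex, , drop = FALSE],
                         vrs = FALSE, super = TRUE, backend = backend)
            te <- if (sc$status == "optimal") max(sc$rho, 1 - 1e-9) else 1
            if (sc$status != "optimal") status <- "super_infeasible"
          }
          if (pte >= 1 - eff_tol) {
            sv <- sbm_lp(X[j, ], Y[j, ], B[j, ], X[ref_ex, , drop = FALSE],
                         Y[ref_ex, , drop = FALSE], B[ref_ex, , drop = FALSE],
                         vrs = TRUE, super = TRUE, backend = backend)
            pte <- if (sv$status == "optimal") max(sv$rho, 1 - 1e-9) else 1
            if (sv$status != "optimal") status <- "super_infeasible"
          }
        }
      }
      res[[j]] <- list(te = te, pte = pte,
                       te_ns = min(max(crs$rho, 1e-12), 1),
                       pte_ns = min(max(vrsr$rho, 1e-12), 1),
                       s_in = crs$s_in, s_out = crs$s_out, s_bad = crs$s_bad,
                       status = status)
    }
  }

  te <- vapply(res, `[[`, numeric(1), "te")
  pte <- vapply(res, `[[`, numeric(1), "pte")
  out <- data.frame(dmu = panel$dmu, period = panel$period,
                    te = te, pte = pte, se = te / pte,
                    te_nonsuper = vapply(res, `[[`, numeric(1), "te_ns"),
                    pte_nonsuper = vapply(res, `[[`, numeric(1), "pte_ns"),
                    status = vapply(res, `[[`, character(1), "status"),
                    stringsAsFactors = FALSE)
  sl <- function(field, prefix, names) {
    M <- do.call(rbind, lapply(res, `[[`, field))
    if (is.null(M) || ncol(M) == 0) return(NULL)
    colnames(M) <- paste0(prefix, names)
    M
  }
  blocks <- Filter(Negate(is.null),
                   list(sl("s_in", "s_in_", colnames(X)),
                        sl("s_out", "s_out_", colnames(Y)),
                        if (ncol(B)) sl("s_bad", "s_bad_", colnames(B))))
  out <- do.call(cbind, c(list(out), blocks))
  class(out) <- c("efficiency_records", "data.frame")
  out
}
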