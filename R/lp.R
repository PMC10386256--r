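#' Solve a linear program
#'
#' Dense two-phase primal simplex for the small, wide linear programs that
#' slack-based DEA scoring produces (a handful of constraint rows, hundreds of
#' columns). All structural variables are nonnegative. Constraints may mix
#' directions. The implementation uses Dantzig pricing with an automatic
#' switch to Bland's rule to guarantee termination on the highly degenerate
#' programs DEA generates (most right-hand sides are zero).
#'
#' @param obj numeric objective coefficient vector (length n).
#' @param A constraint matrix (k x n).
#' @param dir character vector of constraint directions, each one of
#'   \code{"<="}, \code{">="}, \code{"=="}.
#' @param rhs numeric right-hand side (length k).
#' @param maximize logical; minimizes by default.
#' @param tol pivot / feasibility tolerance.
#' @param backend \code{"internal"} (default) or \code{"boot"} to route the
#'   standardized program through \code{boot::simplex} instead; both honor the
#'   same tolerances and are interchangeable (the boot backend is slower and
#'   kept as an independent cross-check).
#' @return list with \code{status} (0 optimal, 2 infeasible, 3 unbounded),
#'   \code{x} (primal solution, length n) and \code{value} (objective).
#' @export
solve_lp <- function(obj, A, dir, rhs, maximize = FALSE, tol = 1e-9,
                     backend = getOption("frontier3.lp_backend", "internal")) {
  A <- as.matrix(A)
  k <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == k, length(rhs) == k,
            all(dir %in% c("<=", ">=", "==")))
  if (backend == "boot") {
    return(lp_boot(obj, A, dir, rhs, maximize, tol))
  }
  cvec <- if (maximize) -obj else obj

  ## normalize rhs >= 0
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[neg]]
  }

  n_le <- sum(dir == "<="); n_ge <- sum(dir == ">=")
  ## columns: structural | slack(<=) | surplus(>=) | artificial(>= and ==)
  art_rows <- which(dir != "<=")
  n_art <- length(art_rows)
  ncol_tot <- n + n_le + n_ge + n_art
  Tb <- matrix(0, k, ncol_tot)
  Tb[, seq_len(n)] <- A
  j <- n
  slack_col <- integer(k)
  for (i in which(dir == "<=")) { j <- j + 1; Tb[i, j] <- 1; slack_col[i] <- j }
  for (i in which(dir == ">=")) { j <- j + 1; Tb[i, j] <- -1 }
  art_col <- integer(k)
  for (i in art_rows) { j <- j + 1; Tb[i, j] <- 1; art_col[i] <- j }

  basis <- ifelse(dir == "<=", slack_col, art_col)
  is_art <- logical(ncol_tot); is_art[art_col[art_col > 0]] <- TRUE

  ## working tableau: k constraint rows, then phase-1 and phase-2 reduced-cost
  ## rows; last column is the rhs. A pivot is one rank-1 update on the block.
  rz1 <- k + 1L; rz2 <- k + 2L; cr <- ncol_tot + 1L
  M <- matrix(0, k + 2L, cr)
  M[seq_len(k), seq_len(ncol_tot)] <- Tb
  M[seq_len(k), cr] <- rhs
  M[rz1, is_art] <- 1
  M[rz2, seq_len(n)] <- cvec
  for (i in seq_len(k)) {          # price out the initial basis
    if (is_art[basis[i]]) M[rz1, ] <- M[rz1, ] - M[i, ]
  }
  maxit <- 50L * (k + ncol_tot)
  bland_after <- 30L * (k + 5L)
  it <- 0L

  do_pivot <- function(M, p, q, basis) {
    M[p, ] <- M[p, ] / M[p, q]
    col <- M[, q]; col[p] <- 0
    M <- M - tcrossprod(col, M[p, ])
    M[, q] <- 0; M[p, q] <- 1     # clamp numerical dust on the pivot column
    basis[p] <- q
    list(M = M, basis = basis)
  }

  run_phase <- function(zrow) {
    repeat {
      it <<- it + 1L
      if (it > maxit) stop("simplex iteration limit reached")
      z <- M[zrow, seq_len(ncol_tot)]
      if (zrow == rz2) z[is_art] <- 0
      cand <- which(z < -tol)
      if (!length(cand)) return(0L)
      q <- if (it > bland_after) cand[1L] else cand[which.min(z[cand])]
      colq <- M[seq_len(k), q]
      ok <- which(colq > tol)
      if (!length(ok)) return(3L)
      ratio <- M[ok, cr] / colq[ok]
      rmin <- min(ratio)
      tie <- ok[ratio <= rmin + tol]
      p <- tie[which.min(basis[tie])]  # smallest-basis-index tie-break (anti-cycling)
      up <- do_pivot(M, p, q, basis)
      M <<- up$M; basis <<- up$basis
    }
  }

  if (n_art > 0) {
    st <- run_phase(rz1)
    if (st != 0L || -M[rz1, cr] > 1e-7 * max(1, max(abs(rhs)))) {
      return(list(status = 2L, x = rep(NA_real_, n), value = NA_real_))
    }
    for (i in which(is_art[basis])) {  # drive residual artificials out
      row <- M[i, seq_len(ncol_tot)]; row[is_art] <- 0
      q <- which(abs(row) > tol)[1L]
      if (!is.na(q)) { up <- do_pivot(M, i, q, basis); M <- up$M; basis <- up$basis }
      ## else: redundant row; harmless (rhs ~ 0, artificial stays at 0)
    }
  }
  st <- run_phase(rz2)
  if (st == 3L) return(list(status = 3L, x = rep(NA_real_, n), value = NA_real_))

  x <- numeric(ncol_tot)
  x[basis] <- M[seq_len(k), cr]
  x <- x[seq_len(n)]
  val <- sum(cvec * x)
  list(status = 0L, x = x, value = if (maximize) -val else val)
}

## boot::simplex backend: same interface, used as an independent cross-check.
lp_boot <- function(obj, A, dir, rhs, maximize, tol) {
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[neg]]
  }
  le <- dir == "<="; ge <- dir == ">="; eq <- dir == "=="
  res <- tryCatch(
    boot::simplex(a = obj,
                  A1 = if (any(le)) A[le, , drop = FALSE], b1 = if (any(le)) rhs[le],
                  A2 = if (any(ge)) A[ge, , drop = FALSE], b2 = if (any(ge)) rhs[ge],
                  A3 = if (any(eq)) A[eq, , drop = FALSE], b3 = if (any(eq)) rhs[eq],
                  maxi = maximize, eps = tol),
    error = function(e) NULL)
  if (is.null(res)) return(list(status = 2L, x = rep(NA_real_, ncol(A)), value = NA_real_))
  status <- if (res$solved == 1) 0L else if (res$solved == 0) 3L else 2L
  list(status = status,
       x = if (status == 0L) as.numeric(res$soln) else rep(NA_real_, ncol(A)),
       value = if (status == 0L) unname(res$value) else NA_real_)
}
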