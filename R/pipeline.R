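#' Run the full three-stage efficiency analysis
#'
#' Stage 1 scores every observation with the undesirable-output SBM model on
#' the chosen frontier (constant and variable returns, optionally with
#' super-efficiency re-scoring of efficient units). Stage 2 fits one
#' normal/half-normal slack frontier per input to the stage-1
#' constant-returns input slacks and adjusts the inputs to a common
#' environment and common luck. Stage 3 re-scores the adjusted panel with the
#' same SBM models. Optionally the global Malmquist-Luenberger index is
#' computed on the adjusted (default) or raw data.
#'
#' A slack channel with (numerically) no variation — e.g. when every unit is
#' efficient in that input — cannot support a frontier regression; that input
#' is left unadjusted and recorded as \code{NULL} in the fit list.
#'
#' @param panel a [panel_dataset()] with environmental covariates.
#' @param super_efficiency re-score efficient units (stage 1 and 3).
#' @param frontier \code{"global"} (default) or \code{"contemporaneous"}
#'   benchmark for the stage scoring.
#' @param gml compute the productivity index (needs >= 2 periods).
#' @param gml_measure distance measure for the index, see [dea_distance()].
#' @param gml_stage \code{"adjusted"} (default) or \code{"raw"}: which inputs
#'   feed the productivity index.
#' @param alpha significance level for the gamma LR tests.
#' @param backend LP backend, see [solve_lp()].
#' @param verbose print stage progress.
#' @return list of class \code{three_stage_bundle}: \code{stage1} and
#'   \code{stage3} efficiency records, \code{sfa_fits} (one per input, maybe
#'   NULL), \code{sfa_tests}, \code{adjusted_panel}, \code{gml} records (or
#'   NULL), and a \code{log} of solver statuses and convergence notes.
#' @export
run_three_stage <- function(panel, super_efficiency = TRUE,
                            frontier = c("global", "contemporaneous"),
                            gml = TRUE, gml_measure = c("sbm", "radial_output"),
                            gml_stage = c("adjusted", "raw"), alpha = 0.01,
                            backend = getOption("frontier3.lp_backend", "internal"),
                            verbose = FALSE) {
  stopifnot(inherits(panel, "panel_dataset"))
  frontier <- match.arg(frontier)
  gml_measure <- match.arg(gml_measure)
  gml_stage <- match.arg(gml_stage)
  if (ncol(panel$Z) == 0) stop("three-stage adjustment needs environmental covariates")
  say <- function(...) if (verbose) message(...)
  logl <- list()

  say("stage 1: SBM scoring (", frontier, " frontier)")
  tech <- technology_spec(frontier = frontier,
                          super_efficiency = super_efficiency)
  stage1 <- score_panel(panel, tech, backend = backend)
  logl$stage1_status <- table(stage1$status)

  say("stage 2: slack frontier regressions")
  m <- ncol(panel$X)
  slack_cols <- paste0("s_in_", colnames(panel$X))
  fits <- vector("list", m)
  tests <- vector("list", m)
  for (j in seq_len(m)) {
    s <- stage1[[slack_cols[j]]]
    if (stats::var(s) < 1e-12) {
      logl[[paste0("sfa_", colnames(panel$X)[j])]] <-
        "degenerate slack channel (no variation); input left unadjusted"
      next
    }
    fits[[j]] <- fit_slack_frontier(s, panel$Z, input_index = colnames(panel$X)[j])
    tests[[j]] <- lr_test_gamma(fits[[j]], alpha = alpha)
    logl[[paste0("sfa_", colnames(panel$X)[j])]] <-
      sprintf("gamma = %.4f, LR = %.3f, convergence = %d%s",
              fits[[j]]$gamma, fits[[j]]$lr_stat, fits[[j]]$convergence,
              if (fits[[j]]$boundary) " (boundary)" else "")
  }
  adjusted <- adjust_inputs(panel, fits)

  say("stage 3: SBM re-scoring on adjusted inputs")
  stage3 <- score_panel(adjusted, tech, backend = backend)
  logl$stage3_status <- table(stage3$status)

  gml_rec <- NULL
  if (gml && length(panel$periods) >= 2) {
    say("productivity: global Malmquist-Luenberger index")
    gml_rec <- gml_panel(if (gml_stage == "adjusted") adjusted else panel,
                         measure = gml_measure, backend = backend)
  }

  structure(list(stage1 = stage1, sfa_fits = fits, sfa_tests = tests,
                 adjusted_panel = adjusted, stage3 = stage3, gml = gml_rec,
                 panel = panel, frontier = frontier,
                 super_efficiency = super_efficiency, log = logl),
            class = "three_stage_bundle")
}

#' @export
print.three_stage_bundle <- function(x, ...) {
  cat(sprintf("three-stage SBM bundle: %d DMUs x %d periods, %s frontier%s\n",
              length(x$panel$dmu_ids), length(x$panel$periods), x$frontier,
              if (x$super_efficiency) ", super-efficiency" else ""))
  cat(sprintf("  stage 1 mean te = %.4f -> stage 3 mean te = %.4f\n",
              mean(x$stage1$te), mean(x$stage3$te)))
  fitted <- !vapply(x$sfa_fits, is.null, logical(1))
  cat(sprintf("  slack frontiers fitted for %d/%d inputs\n",
              sum(fitted), length(fitted)))
  if (!is.null(x$gml))
    cat(sprintf("  mean productivity index = %.4f (ec %.4f, bpc %.4f)\n",
                mean(x$gml$hsgi), mean(x$gml$ec), mean(x$gml$bpc)))
  invisible(x)
}

#' Study-period mean scores per DMU
#'
#' @param records an \code{efficiency_records} data.frame.
#' @param cols score columns to average.
#' @return data.frame with one row per DMU (arithmetic mean over periods).
#' @export
province_means <- function(records, cols = c("te", "pte", "se")) {
  stopifnot(is.data.frame(records), all(cols %in% names(records)))
  out <- stats::aggregate(records[cols], by = list(dmu = records$dmu), FUN = mean)
  out[match(unique(records$dmu), out$dmu), , drop = FALSE]
}

#' Regional and national means of per-DMU values
#'
#' Averages per-DMU values within each region and nationally (the national
#' figure is the mean over all DMU values, i.e. provinces weigh equally).
#'
#' @param dmu_values data.frame with a \code{dmu} column and numeric columns.
#' @param region_map named character vector DMU -> region.
#' @return data.frame with one row per region plus a \code{"national"} row.
#' @export
regional_means <- function(dmu_values, region_map) {
  stopifnot(is.data.frame(dmu_values), "dmu" %in% names(dmu_values))
  unknown <- setdiff(dmu_values$dmu, names(region_map))
  if (length(unknown)) stop("DMU(s) missing from the region map: ",
                            paste(unknown, collapse = ", "))
  reg <- unname(region_map[dmu_values$dmu])
  num <- dmu_values[vapply(dmu_values, is.numeric, logical(1))]
  out <- stats::aggregate(num, by = list(region = reg), FUN = mean)
  nat <- data.frame(region = "national", lapply(num, mean))
  out <- rbind(out[match(unique(reg), out$region), , drop = FALSE], nat)
  rownames(out) <- NULL
  out
}

#' Per-period regional mean scores
#'
#' @param records an \code{efficiency_records} data.frame.
#' @param region_map named character vector DMU -> region; \code{NULL} for a
#'   national series only.
#' @param col score column.
#' @return data.frame period x region (wide), including a national column.
#' @export
annual_means <- function(records, region_map = NULL, col = "te") {
  stopifnot(is.data.frame(records), col %in% names(records))
  periods <- unique(records$period)
  nat <- tapply(records[[col]], records$period, mean)[periods]
  out <- data.frame(period = periods, national = as.numeric(nat),
                    stringsAsFactors = FALSE)
  if (!is.null(region_map)) {
    reg <- unname(region_map[records$dmu])
    for (r in unique(reg)) {
      sel <- reg == r
      out[[r]] <- as.numeric(tapply(records[[col]][sel],
                                    records$period[sel], mean)[periods])
    }
  }
  out
}

#' Period-over-period percentage change
#'
#' The growth convention \eqn{(new - old)/old \times 100}, reported at one
#' decimal.
#'
#' @param x numeric series in period order.
#' @return vector of length \code{length(x) - 1}.
#' @export
pct_change <- function(x) {
  round((x[-1] - x[-length(x)]) / x[-length(x)] * 100, 1)
}

#' Assemble the standard report set from a pipeline bundle
#'
#' Reproduces the reporting conventions of published three-stage provincial
#' studies: per-province study-period means for stage 1 and stage 3 (six
#' score columns), regional/national means of those province means, annual
#' regional mean series with period-over-period percentage changes, and the
#' regional productivity decomposition table.
#'
#' @param bundle a [run_three_stage()] result.
#' @param region_map named character vector DMU -> region; defaults to the
#'   panel's own region labels when present.
#' @return list of data.frames: \code{province}, \code{regional},
#'   \code{annual}, \code{annual_pct_change}, and (when the bundle has
#'   productivity records) \code{gml_regional}.
#' @export
report_tables <- function(bundle, region_map = NULL) {
  stopifnot(inherits(bundle, "three_stage_bundle"))
  if (is.null(region_map)) {
    if (is.null(bundle$panel$region))
      stop("no region map supplied and the panel carries no region labels")
    region_map <- bundle$panel$region
  }
  p1 <- province_means(bundle$stage1)
  p3 <- province_means(bundle$stage3)
  names(p1)[-1] <- paste0(names(p1)[-1], "_stage1")
  names(p3)[-1] <- paste0(names(p3)[-1], "_stage3")
  prov <- merge(p1, p3, by = "dmu", sort = FALSE)
  reg <- regional_means(prov, region_map)
  ann <- annual_means(bundle$stage3, region_map)
  pct <- data.frame(transition = paste(ann$period[-nrow(ann)],
                                       ann$period[-1], sep = "/"))
  for (cn in setdiff(names(ann), "period")) pct[[cn]] <- pct_change(ann[[cn]])
  out <- list(province = prov, regional = reg, annual = ann,
              annual_pct_change = pct)
  if (!is.null(bundle$gml))
    out$gml_regional <- aggregate_gml(bundle$gml, groups = region_map)
  out
}
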