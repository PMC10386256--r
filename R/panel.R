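#' Construct a balanced DMU-by-period panel
#'
#' The central data container: a balanced panel of decision-making units
#' (DMUs, e.g. provinces) observed over an ordered set of periods, with input,
#' desirable-output, undesirable-output and environmental-covariate columns.
#' Rows are normalized to (period, dmu) lexicographic order with periods in
#' their supplied order.
#'
#' @param data data.frame holding one row per (dmu, period) pair.
#' @param schema column-role map: a list with elements \code{dmu}, \code{period}
#'   (single column names), \code{input}, \code{desirable} (character vectors,
#'   at least one each), and optionally \code{undesirable}, \code{environment}
#'   (character vectors) and \code{region} (single column name). An optional
#'   \code{period_order} element gives the period labels in panel order;
#'   otherwise first-appearance order is used (never a lexical sort, which
#'   mis-orders labels like "2009/2010").
#' @return An object of class \code{panel_dataset}: a list with the normalized
#'   \code{data}, \code{dmu_ids}, \code{periods}, matrices \code{X}, \code{Y},
#'   \code{B}, \code{Z} (n_obs rows each), an optional per-DMU \code{region}
#'   vector, and the \code{schema}.
#' @details Inputs must be strictly positive (the SBM objective divides by
#'   them); desirable and undesirable outputs must be nonnegative. The panel
#'   must be balanced: every (dmu, period) pair present exactly once.
#' @examples
#' d <- expand.grid(prov = c("A", "B"), year = 2009:2010)
#' d$beds <- c(2, 3, 2.5, 3.5); d$visits <- c(4, 5, 4.5, 6)
#' p <- panel_dataset(d, list(dmu = "prov", period = "year",
#'                            input = "beds", desirable = "visits"))
#' @export
panel_dataset <- function(data, schema) {
  schema <- normalize_schema(schema, names(data))
  data <- as.data.frame(data)

  dmu <- as.character(data[[schema$dmu]])
  per_raw <- as.character(data[[schema$period]])
  periods <- if (!is.null(schema$period_order)) {
    as.character(schema$period_order)
  } else {
    unique(per_raw)
  }
  if (!all(per_raw %in% periods)) {
    stop("period labels not covered by period_order: ",
         paste(setdiff(per_raw, periods), collapse = ", "))
  }
  dmu_ids <- unique(dmu)

  ## balance check: every (dmu, period) exactly once
  key <- paste(per_raw, dmu, sep = "\r")
  full <- as.vector(outer(dmu_ids, periods,
                          function(d, p) paste(p, d, sep = "\r")))
  if (anyDuplicated(key)) {
    stop("unbalanced panel: duplicated (dmu, period) cell(s): ",
         paste(utils::head(sub("\r", " / ", key[duplicated(key)]), 3), collapse = "; "))
  }
  if (length(key) != length(full) || !all(full %in% key)) {
    miss <- setdiff(full, key)
    stop("unbalanced panel: missing (dmu, period) cell(s): ",
         paste(utils::head(sub("\r", " / ", miss), 3), collapse = "; "))
  }

  ## normalize row order to (period, dmu), periods in panel order
  ord <- order(match(per_raw, periods), match(dmu, dmu_ids))
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  dmu <- dmu[ord]; per_raw <- per_raw[ord]

  get_mat <- function(cols) {
    m <- as.matrix(data[, cols, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric values in columns: ",
                             paste(cols, collapse = ", "))
    storage.mode(m) <- "double"
    m
  }
  X <- get_mat(schema$input)
  Y <- get_mat(schema$desirable)
  B <- if (length(schema$undesirable)) get_mat(schema$undesirable) else
    matrix(numeric(0), nrow(data), 0)
  Z <- if (length(schema$environment)) get_mat(schema$environment) else
    matrix(numeric(0), nrow(data), 0)

  if (anyNA(X) || anyNA(Y) || anyNA(B) || anyNA(Z)) stop("missing values in panel columns")
  bad <- which(X <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive input in column '%s' for dmu '%s', period '%s'",
                 colnames(X)[bad[1, 2]], dmu[bad[1, 1]], per_raw[bad[1, 1]]))
  }
  if (any(Y < 0)) stop("negative desirable output value(s)")
  if (ncol(B) && any(B < 0)) stop("negative undesirable output value(s)")

  region <- NULL
  if (!is.null(schema$region)) {
    rg <- as.character(data[[schema$region]])
    region <- tapply(rg, dmu, function(v) {
      u <- unique(v)
      if (length(u) > 1) stop("region label varies within a DMU")
      u
    })
    region <- stats::setNames(as.character(region), names(region))[dmu_ids]
  }

  structure(list(data = data, dmu_ids = dmu_ids, periods = periods,
                 dmu = dmu, period = per_raw,
                 X = X, Y = Y, B = B, Z = Z, region = region,
                 schema = schema),
            class = "panel_dataset")
}

normalize_schema <- function(schema, cols) {
  if (is.character(schema) && length(schema) == 1) schema <- yaml::read_yaml(schema)
  if (!is.list(schema)) stop("schema must be a list or a YAML file path")
  known <- c("dmu", "period", "input", "desirable", "undesirable",
             "environment", "region", "period_order")
  extra <- setdiff(names(schema), known)
  if (length(extra)) stop("unknown schema role(s): ", paste(extra, collapse = ", "))
  for (f in c("dmu", "period")) {
    if (length(schema[[f]]) != 1) stop("schema must name exactly one ", f, " column")
  }
  schema$input <- as.character(schema$input %||% character(0))
  schema$desirable <- as.character(schema$desirable %||% character(0))
  schema$undesirable <- as.character(schema$undesirable %||% character(0))
  schema$environment <- as.character(schema$environment %||% character(0))
  if (length(schema$input) < 1) stop("schema needs at least one input column")
  if (length(schema$desirable) < 1) stop("schema needs at least one desirable output column")
  used <- c(schema$dmu, schema$period, schema$input, schema$desirable,
            schema$undesirable, schema$environment, schema$region)
  missing <- setdiff(used, cols)
  if (length(missing)) stop("schema names absent column(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(used)) stop("schema assigns a column more than one role: ",
                                paste(used[duplicated(used)], collapse = ", "))
  schema
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a panel from a delimited file
#'
#' @param path CSV file (RFC-4180, UTF-8, "." decimal).
#' @param schema column-role map (list) or path to a YAML schema file; see
#'   [panel_dataset()].
#' @return a validated [panel_dataset()].
#' @export
read_panel <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  panel_dataset(df, schema)
}

#' Write a panel to CSV
#'
#' Writes the normalized (period, dmu)-ordered table. Numeric columns are
#' serialized at full double precision so that a read/write/read cycle is an
#' identity.
#'
#' @param panel a [panel_dataset()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_dataset"))
  df <- panel$data
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("panel_dataset: %d DMUs x %d periods (%d observations)\n",
              length(x$dmu_ids), length(x$periods), nrow(x$X)))
  cat(sprintf("  inputs (m=%d): %s\n", ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  cat(sprintf("  desirable outputs (q1=%d): %s\n", ncol(x$Y),
              paste(colnames(x$Y), collapse = ", ")))
  if (ncol(x$B)) cat(sprintf("  undesirable outputs (q2=%d): %s\n", ncol(x$B),
                             paste(colnames(x$B), collapse = ", ")))
  if (ncol(x$Z)) cat(sprintf("  environment (p=%d): %s\n", ncol(x$Z),
                             paste(colnames(x$Z), collapse = ", ")))
  if (!is.null(x$region)) cat("  regions:", paste(unique(x$region), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.panel_dataset <- function(x, ...) x$data

#' Write result records to CSV
#'
#' Serializes a homogeneous collection of efficiency or productivity records.
#' Every numeric score column is written twice: at full double precision and,
#' under a \code{<name>_3dp} suffix, rounded half-even to three decimals (the
#' presentation convention used in published efficiency tables).
#'
#' @param records a data.frame of class \code{efficiency_records} or
#'   \code{gml_records} (as returned by [score_panel()] / [gml_panel()]), or a
#'   list of such data.frames of one single type.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_results <- function(records, path) {
  if (is.data.frame(records)) records <- list(records)
  if (!length(records)) stop("no records to write")
  type <- function(r) {
    if (inherits(r, "efficiency_records")) "efficiency_records"
    else if (inherits(r, "gml_records")) "gml_records"
    else stop("records must be efficiency_records or gml_records")
  }
  types <- vapply(records, type, character(1))
  if (length(unique(types)) > 1) stop("mixed record types cannot be written together")
  df <- do.call(rbind, lapply(records, as.data.frame))
  out <- df
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      out[[nm]] <- sprintf("%.17g", df[[nm]])
      out[[paste0(nm, "_3dp")]] <- format_score(df[[nm]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read result records written by [write_results()]
#'
#' Restores full-precision numeric columns and drops the presentation columns.
#'
#' @param path CSV file produced by [write_results()].
#' @return data.frame with numeric columns restored bit-for-bit.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df <- df[, !grepl("_3dp$", names(df)), drop = FALSE]
  for (nm in names(df)) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (!anyNA(v) && nm %in% c("te", "pte", "se", "hsgi", "ec", "bpc") ||
        grepl("^(s_|d_)", nm)) df[[nm]] <- v
  }
  df
}

## presentation rounding: three decimals, round-half-even (IEC 60559, as in
## base round())
format_score <- function(x) formatC(round(x, 3), format = "f", digits = 3)

#' Built-in east/central/west region partition
#'
#' Loads a DMU-to-region map from a YAML file with one entry per region
#' listing its DMUs. The shipped default reproduces the 11/8/12
#' eastern/central/western partition of China's 31 provinces used by the
#' National Bureau of Statistics.
#'
#' @param path YAML file; defaults to the fixture shipped with the package.
#' @return named character vector mapping DMU id to region label.
#' @export
read_region_map <- function(path = system.file("extdata", "region_map.yaml",
                                               package = "frontier3")) {
  m <- yaml::read_yaml(path)
  unlist(lapply(names(m), function(r) stats::setNames(rep(r, length(m[[r]])), m[[r]])))
}
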