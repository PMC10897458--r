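#' Read a localization table from CSV
#'
#' Reads a comma-separated table of single-molecule localizations and maps its
#' columns onto the canonical names `x`, `y` and (optionally) `t`.  `x` and `y`
#' are positions in nanometres; `t` is a non-negative integer frame index.
#' Localization software exports under many headers (e.g. ThunderSTORM's
#' `"x [nm]"`), so the mapping is explicit.
#'
#' @param path Path to a CSV file with a header row (UTF-8).
#' @param column_map Named character vector mapping canonical names to file
#'   headers, e.g. `c(x = "x [nm]", y = "y [nm]", t = "frame")`.  Entries for
#'   `assembly_id` and `class` are honoured when present (labelled simulated
#'   data).  If `t` is unmapped or absent the table is static.
#' @return A `data.frame` with columns `x`, `y` and optionally `t`,
#'   `assembly_id`, `class`; attribute `static` is `TRUE` when no frame column
#'   was mapped.
#' @export
read_localizations <- function(path,
                               column_map = c(x = "x", y = "y", t = "t")) {
  if (!file.exists(path)) stop("localization file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (ax in c("x", "y")) {
    if (!ax %in% names(column_map) || !column_map[[ax]] %in% names(raw))
      stop("schema error: required column '", ax, "' (mapped to '",
           if (ax %in% names(column_map)) column_map[[ax]] else "<unmapped>",
           "') not found in ", path)
  }
  out <- data.frame(x = raw[[column_map[["x"]]]], y = raw[[column_map[["y"]]]])
  has_t <- "t" %in% names(column_map) && column_map[["t"]] %in% names(raw)
  if (has_t) out$t <- raw[[column_map[["t"]]]]
  for (extra in c("assembly_id", "class")) {
    if (extra %in% names(column_map) && column_map[[extra]] %in% names(raw))
      out[[extra]] <- raw[[column_map[[extra]]]]
  }
  for (col in intersect(c("x", "y", "t"), names(out))) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]))
    if (length(bad))
      stop("parse error: non-numeric value in column '", col,
           "' at data row ", bad[1])
    out[[col]] <- v
  }
  validate_localizations(out)
  attr(out, "static") <- !has_t
  out
}

#' Validate a localization table
#'
#' @param table A data.frame with columns `x`, `y` and optionally `t`.
#' @return The table, invisibly; errors describe the first violation.
#' @export
validate_localizations <- function(table) {
  stopifnot(is.data.frame(table), all(c("x", "y") %in% names(table)))
  if (nrow(table)) {
    if (!all(is.finite(table$x)) || !all(is.finite(table$y)))
      stop("x and y must be finite")
    if ("t" %in% names(table)) {
      t <- table$t
      if (!all(is.finite(t)) || any(t < 0) || any(t != floor(t)))
        stop("t must contain non-negative integer frame indices")
    }
  }
  invisible(table)
}

axis_cols <- function(table, with_t = TRUE) {
  cols <- c("x", "y")
  if (with_t && "t" %in% names(table)) cols <- c(cols, "t")
  cols
}

new_scaling <- function(kind, offset, scale) {
  structure(list(kind = kind, offset = offset, scale = scale),
            class = "scaling_transform")
}

#' @export
print.scaling_transform <- function(x, ...) {
  cat(sprintf("<scaling_transform: %s over %s>\n", x$kind,
              paste(names(x$offset), collapse = ", ")))
  invisible(x)
}

check_degenerate <- function(table, cols, what) {
  for (cc in cols) {
    v <- table[[cc]]
    if (length(unique(v)) < 2)
      stop("degenerate axis '", cc, "': ", what,
           " requires >= 2 distinct values (axis carries no information)")
  }
}

#' Standardize localization axes (z-score)
#'
#' Transforms each axis to mean 0 and sample standard deviation 1
#' (denominator n - 1).  The time axis is included exactly when present, so
#' spatiotemporal input is standardized in all three dimensions, making every
#' downstream density step scale invariant.
#'
#' @param table Localization table.
#' @param with_t Include the `t` axis when present (default `TRUE`).
#' @return A list with `table` (transformed copy) and `transform`
#'   (invertible `scaling_transform`).
#' @export
standardize <- function(table, with_t = TRUE) {
  validate_localizations(table)
  cols <- axis_cols(table, with_t)
  check_degenerate(table, cols, "standardization")
  mu <- vapply(table[cols], mean, 0)
  sdv <- vapply(table[cols], stats::sd, 0)
  out <- table
  for (cc in cols) out[[cc]] <- (table[[cc]] - mu[[cc]]) / sdv[[cc]]
  list(table = out, transform = new_scaling("standardized", mu, sdv))
}

#' MinMax-scale localization axes to the unit interval
#'
#' @inheritParams standardize
#' @return A list with `table` and `transform`, as [standardize()].
#' @export
minmax_scale <- function(table, with_t = TRUE) {
  validate_localizations(table)
  cols <- axis_cols(table, with_t)
  check_degenerate(table, cols, "minmax scaling")
  lo <- vapply(table[cols], min, 0)
  rng <- vapply(table[cols], function(v) diff(range(v)), 0)
  out <- table
  for (cc in cols) out[[cc]] <- (table[[cc]] - lo[[cc]]) / rng[[cc]]
  list(table = out, transform = new_scaling("minmax", lo, rng))
}

#' Invert a scaling transform
#'
#' @param table Transformed localization table.
#' @param transform A `scaling_transform` from [standardize()] or
#'   [minmax_scale()].
#' @return Table on the original scale.
#' @export
inverse_scale <- function(table, transform) {
  stopifnot(inherits(transform, "scaling_transform"))
  out <- table
  for (cc in names(transform$offset))
    out[[cc]] <- table[[cc]] * transform$scale[[cc]] + transform$offset[[cc]]
  out
}

#' Euclidean distance between two points
#'
#' @param p,q Numeric vectors of equal length.
#' @return The Euclidean distance.
#' @export
euclidean_distance <- function(p, q) {
  if (length(p) != length(q))
    stop("dimension mismatch: ", length(p), " vs ", length(q))
  sqrt(sum((p - q)^2))
}

#' Write a localization table to CSV
#'
#' @param table Localization table (optionally labelled).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
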