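#' Read and write case-control point data
#'
#' Datasets are exchanged as delimited text with header `x,y,outcome`.
#' `read_points()` validates column names, coordinate bounds and binary
#' outcomes; when no region is supplied one is inferred from the bounding
#' geometry and flagged as inferred.
#'
#' @param path File path.
#' @param region Optional `study_region`; inferred (and marked as such via
#'   the `region_inferred` attribute) when absent.
#' @return A `point_dataset`.
#' @export
read_points <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path)
  if (nrow(df) == 0) stop("empty dataset: ", path)
  need <- c("x", "y", "outcome")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!(df$outcome %in% c(0, 1)))
  if (length(bad) > 0)
    stop(sprintf("outcome must be 0/1; offending row %d has value %s",
                 bad[1], df$outcome[bad[1]]))
  inferred <- is.null(region)
  if (inferred) {
    # bounding square, padded so boundary points validate
    cx <- mean(range(df$x)); cy <- mean(range(df$y))
    h <- max(diff(range(df$x)), diff(range(df$y))) / 2
    region <- region_square(h * (1 + 1e-6) + 1e-12, c(cx, cy))
  }
  out <- point_dataset(cbind(df$x, df$y), df$outcome, region)
  attr(out, "region_inferred") <- inferred
  out
}

#' @rdname read_points
#' @param data A `point_dataset`.
#' @export
write_points <- function(data, path) {
  stopifnot(inherits(data, "point_dataset"))
  df <- data.frame(x = data$coords[, 1], y = data$coords[, 2],
                   outcome = data$outcome)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a test result or study to disk
#'
#' JSON gives a lossless dump of statistics, p-values, flags and zone
#' membership; CSV is available for the tabular components of a
#' `power_study` (the power and sensitivity tables).
#'
#' @param result A `gam_perm_test`, `scan_test`, `power_study` or plain
#'   list.
#' @param path Output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- if (inherits(result, "power_study")) result$power
           else if (is.data.frame(result)) result
           else stop("csv format requires a power_study or data frame")
    write.csv(tab, path, row.names = FALSE)
    return(invisible(path))
  }
  jsonlite::write_json(serialize_result(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

serialize_result <- function(x) {
  if (inherits(x, "gam_perm_test")) {
    return(list(
      method = x$method, spans = x$spans, chosen_span = x$chosen_span,
      statistic = x$statistic, p_value = x$p_value, cutoff = x$cutoff,
      reject = x$reject, n_perm = x$n_perm, n_completed = x$n_completed,
      n_failed = x$n_failed,
      pointwise = if (!is.null(x$pointwise)) lapply(x$pointwise, function(pw)
        list(flags = as.character(pw$flags), p_hot = pw$p_hot,
             p_cold = pw$p_cold, tail = pw$tail))))
  }
  if (inherits(x, "scan_test")) {
    return(list(
      method = "bernoulli_scan", directions = x$directions,
      center_index = x$mlc$center_index, radius = x$mlc$radius,
      n_z = x$mlc$n_z, c_z = x$mlc$c_z, direction = x$mlc$direction,
      llr = x$mlc$llr, members = x$mlc$members, p_value = x$p_value,
      n_mc = x$n_mc, reject = x$reject))
  }
  if (inherits(x, "power_study")) {
    return(list(config = unclass(x$config),
                power = x$power, sensitivity = x$sensitivity,
                results = x$results))
  }
  x
}

#' Parse a serialized report back into a list
#'
#' @param path JSON file written by [write_report()].
#' @return A plain list mirroring the serialized fields.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
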