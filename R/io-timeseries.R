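#' Read and write kinetic trace CSVs
#'
#' One abscissa column first (time in seconds for FRAP, lag in seconds for
#' FCS autocorrelation, competitor concentration for titrations) followed by
#' one numeric column per trace. Each trace is returned as a two-column
#' tibble (`x`, `y`) named after its column header.
#'
#' For `kind = "frap"` and `kind = "fcs_curve"` the abscissa must be strictly
#' increasing; for `kind = "titration"` rows are reordered by ascending
#' concentration with values kept paired. Traces with fewer than 4 points are
#' rejected because the downstream fits are under-determined.
#'
#' @param path Path to the CSV file.
#' @param kind One of `"frap"`, `"fcs_curve"`, `"titration"`.
#' @param traces Named list of two-column data frames sharing one abscissa.
#' @param digits Significant digits used when writing (default 12).
#' @return `read_timeseries_csv()` returns a named list of tibbles with
#'   columns `x` and `y`; `write_timeseries_csv()` returns `path` invisibly.
#' @export
read_timeseries_csv <- function(path, kind = c("frap", "fcs_curve",
                                               "titration")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "d"),
                         progress = FALSE)
  if (ncol(raw) < 2L) stopf("%s: need an abscissa column plus >= 1 trace", path)
  x <- raw[[1L]]
  if (anyNA(x)) stopf("%s: abscissa column contains missing values", path)
  if (nrow(raw) < 4L) {
    stopf("%s: only %d points per trace; at least 4 are required for fitting",
          path, nrow(raw))
  }
  if (kind == "titration") {
    ord <- order(x)
    raw <- raw[ord, ]
    x <- x[ord]
    if (any(diff(x) == 0)) stopf("%s: duplicated concentrations", path)
  } else if (any(diff(x) <= 0)) {
    stopf("%s: %s column must be strictly increasing", path, names(raw)[1L])
  }
  traces <- lapply(names(raw)[-1L], function(col) {
    tibble::tibble(x = x, y = raw[[col]])
  })
  setNames(traces, names(raw)[-1L])
}

#' @rdname read_timeseries_csv
#' @export
write_timeseries_csv <- function(traces, path, kind = c("frap", "fcs_curve",
                                                        "titration"),
                                 digits = 12L) {
  kind <- match.arg(kind)
  if (length(traces) == 0L) stopf("`traces` is empty")
  x <- traces[[1L]][[1L]]
  same_x <- vapply(traces, function(tr) isTRUE(all.equal(tr[[1L]], x)), TRUE)
  if (!all(same_x)) stopf("all traces must share one abscissa vector")
  xname <- switch(kind, frap = "t", fcs_curve = "lag", titration = "conc")
  out <- c(list(x), lapply(traces, function(tr) tr[[2L]]))
  names(out) <- c(xname, names(traces) %||% paste0("trace", seq_along(traces)))
  out <- lapply(out, function(v) formatC(v, digits = digits, format = "g"))
  readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}
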