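#' Construct a validated time series
#'
#' The basic data container of the package: a sampled trace `d(t_i)` at `N`
#' time points. Sampling may be non-uniform; nothing downstream assumes a
#' constant interval except the Fourier comparators, which check for it.
#'
#' @param times Numeric vector of sampling times in the native time unit of
#'   the experiment (seconds for calcium traces, hours for circadian data).
#'   Must be strictly increasing, length at least 3.
#' @param values Numeric vector of signal values (arbitrary units, e.g. a
#'   fluorescence ratio or an expression level), same length as `times`.
#' @param label Free-text label carried through result tables.
#' @return An object of class `bsa_ts`: a list with elements `times`,
#'   `values` and `label`.
#' @examples
#' ts <- bsa_ts(0:19, sin(0.5 * 0:19))
#' ts
#' @export
bsa_ts <- function(times, values, label = "trace") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    bsa_stop("bsa_size_error", "`times` and `values` must have equal length")
  }
  if (length(times) < 3L) {
    bsa_stop("bsa_size_error", sprintf(
      "need at least 3 time points, got %d", length(times)))
  }
  if (anyNA(times) || anyNA(values)) {
    bsa_stop("bsa_validation_error", "missing values are not allowed")
  }
  bad <- which(diff(times) <= 0)
  if (length(bad) > 0L) {
    bsa_stop("bsa_validation_error", sprintf(
      "times must be strictly increasing; first violation at index %d",
      bad[1L] + 1L))
  }
  structure(list(times = times, values = values, label = as.character(label)[1L]),
            class = "bsa_ts")
}

#' @export
print.bsa_ts <- function(x, ...) {
  dt <- diff(x$times)
  uni <- if (max(dt) - min(dt) < 1e-9 * mean(dt)) "uniform" else "non-uniform"
  cat(sprintf("<bsa_ts> '%s': %d points, t in [%g, %g] (%s sampling)\n",
              x$label, length(x$times), x$times[1L],
              x$times[length(x$times)], uni))
  invisible(x)
}

#' @export
length.bsa_ts <- function(x) length(x$times)

#' Extract a contiguous window of a time series
#'
#' @param ts A [bsa_ts()] object.
#' @param from,to Integer point indices (inclusive).
#' @return A `bsa_ts` covering `times[from:to]`.
#' @keywords internal
ts_window <- function(ts, from, to) {
  idx <- seq.int(from, to)
  bsa_ts(ts$times[idx], ts$values[idx],
         label = sprintf("%s[%d:%d]", ts$label, from, to))
}

# Detect the field separator of a delimited text file from its first
# non-empty line: tab wins over comma, comma over whitespace.
detect_sep <- function(path) {
  lines <- readLines(path, n = 25L, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) bsa_stop("bsa_io_error", sprintf("'%s' is empty", path))
  if (grepl("\t", lines[[1L]])) "\t" else if (grepl(",", lines[[1L]])) "," else ""
}

#' Read a two-column time series from a delimited text file
#'
#' Accepts comma- or tab-delimited files (auto-detected), with or without a
#' header line. Columns can be addressed by name (requires a header) or by
#' 1-based index. Rows with non-numeric entries in either column are
#' rejected with their row numbers reported.
#'
#' @param path Path to a CSV/TSV file.
#' @param time_column,value_column Column name or 1-based index; defaults to
#'   the first and second column.
#' @param label Trace label; defaults to the file name.
#' @return A [bsa_ts()] object.
#' @export
read_timeseries <- function(path, time_column = 1L, value_column = 2L,
                            label = NULL) {
  if (!file.exists(path)) bsa_stop("bsa_io_error", sprintf("no such file: '%s'", path))
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L, warn = FALSE),
                    if (sep == "") "[[:space:]]+" else sep)[[1L]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first))))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, comment.char = "#",
                          blank.lines.skip = TRUE)
  pick <- function(col, what) {
    if (is.character(col)) {
      if (!col %in% names(df)) {
        bsa_stop("bsa_io_error", sprintf("no column '%s' for %s", col, what))
      }
      df[[col]]
    } else {
      if (col > ncol(df)) {
        bsa_stop("bsa_io_error", sprintf("%s index %d exceeds %d columns",
                                         what, col, ncol(df)))
      }
      df[[col]]
    }
  }
  tcol <- pick(time_column, "time column")
  vcol <- pick(value_column, "value column")
  tnum <- suppressWarnings(as.numeric(tcol))
  vnum <- suppressWarnings(as.numeric(vcol))
  bad <- which(is.na(tnum) | is.na(vnum))
  if (length(bad) > 0L) {
    bsa_stop("bsa_validation_error", sprintf(
      "non-numeric entries at data row(s) %s", paste(bad, collapse = ", ")))
  }
  if (is.null(label)) label <- basename(path)
  bsa_ts(tnum, vnum, label = label)
}

#' Write a time series to a delimited text file
#'
#' Values are written with full double precision (17 significant digits) so
#' that `read_timeseries(write_timeseries(ts))` reproduces `ts` bit-exactly.
#'
#' @param ts A [bsa_ts()] object.
#' @param path Output path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, sep = ",") {
  stopifnot(inherits(ts, "bsa_ts"))
  lines <- c(paste("time", "value", sep = sep),
             paste(sprintf("%.17g", ts$times), sprintf("%.17g", ts$values),
                   sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Write a table of per-trace analysis summaries
#'
#' One row per (trace, method): trace label, method tag (`BSA`, `BSA-NS`,
#' `FFT`, ...), period `2*pi/omega` in the native time unit, its posterior
#' standard deviation, the recovered angular frequency and its standard
#' deviation, signal-to-noise ratio, and log-evidence where available.
#'
#' @param results A list of summary lists; each must carry `trace`, `method`,
#'   `omega` and `sigma_omega`, optionally `snr` and `log_evidence`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(results, path) {
  cols <- c("trace", "method", "period", "period_sigma", "omega", "sigma",
            "snr", "logZ")
  rows <- lapply(results, function(r) {
    omega <- r$omega[1L]
    sig <- r$sigma_omega[1L]
    data.frame(
      trace = r$trace, method = r$method,
      period = 2 * pi / omega,
      period_sigma = 2 * pi * sig / omega^2,
      omega = omega, sigma = sig,
      snr = if (is.null(r$snr)) NA_real_ else r$snr,
      logZ = if (is.null(r$log_evidence)) NA_real_ else r$log_evidence,
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows) == 0L) {
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  } else {
    do.call(rbind, rows)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Condition helper: all package errors are classed so callers can
# distinguish validation, size, degeneracy and I/O failures.
bsa_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(class = c(class, "bsa_error", "error", "condition"),
                 list(message = msg, call = call)))
}

bsa_warn <- function(class, msg) {
  warning(structure(class = c(class, "bsa_warning", "warning", "condition"),
                    list(message = msg, call = NULL)))
}
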