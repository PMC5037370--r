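#' Sampled time series of strain, stress, or force
#'
#' A lightweight container for a uniformly or irregularly sampled record:
#' strictly increasing times in seconds and finite values, tagged with what
#' the values are (`kind`) and their units.
#'
#' @param times Numeric vector of sample times, seconds, strictly increasing.
#' @param values Numeric vector, same length, all finite.
#' @param kind One of `"strain"`, `"stress"`, `"force"`, `"load"`.
#' @param units Unit string, e.g. `""` (strain), `"kPa"`, `"uN"`, `"nN"`,
#'   `"mN"`.
#' @return A `time_series` object (data.frame with columns `t_s`, `value`).
#' @examples
#' time_series(0:10, sin(0:10), kind = "strain")
#' @export
time_series <- function(times, values, kind = "strain", units = "") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have the same length", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)))
    stop("times must be finite", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  kind <- match.arg(kind, c("strain", "stress", "force", "load"))
  ts <- data.frame(t_s = times, value = values)
  attr(ts, "kind") <- kind
  attr(ts, "units") <- units
  class(ts) <- c("time_series", "data.frame")
  ts
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("time_series: %s [%s], %d samples, t = %g..%g s\n",
              attr(x, "kind"), attr(x, "units"), nrow(x),
              x$t_s[1], x$t_s[nrow(x)]))
  invisible(x)
}

# identical time grids, with a tight relative tolerance
.same_grid <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) &&
    max(abs(a$t_s - b$t_s)) <= tol * max(1, max(abs(a$t_s)))
}

#' Read a time series from delimited text
#'
#' Expects the package dialect: comma-separated, UTF-8, header `t_s,value`,
#' `.` decimal point. Malformed rows are reported with their line number.
#'
#' @param path File path.
#' @param kind,units Tags for the returned series (see [time_series()]).
#' @return A `time_series` object.
#' @export
read_time_series <- function(path, kind = "strain", units = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), c("t_s", "value")))
    stop("expected header 't_s,value' in ", path, call. = FALSE)
  t <- suppressWarnings(as.numeric(raw$t_s))
  v <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(t) | is.na(v))
  if (length(bad) > 0)
    stop(sprintf("malformed numeric value in %s at line %d", path,
                 bad[1] + 1L), call. = FALSE)
  time_series(t, v, kind = kind, units = units)
}

#' Write a time series as delimited text
#'
#' Writes the package dialect (`t_s,value`, 12 significant digits, LF line
#' endings); [read_time_series()] round-trips the result to 12 significant
#' digits.
#'
#' @param ts A `time_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("t_s,value", con, sep = "\n")
  writeLines(paste(formatC(ts$t_s, digits = 12, format = "g"),
                   formatC(ts$value, digits = 12, format = "g"), sep = ","),
             con, sep = "\n")
  invisible(path)
}

#' Incremental series relative to a baseline
#'
#' Subtracts the pre-actuation baseline from an absolute record, giving the
#' incremental quantity (e.g. incremental stress = stress - baseline stress).
#' Adding the baseline back restores the input exactly.
#'
#' @param absolute A `time_series` of absolute values.
#' @param baseline Finite scalar baseline.
#' @return A `time_series` of the same kind with `baseline` subtracted.
#' @export
incremental_series <- function(absolute, baseline) {
  stopifnot(inherits(absolute, "time_series"))
  if (!is.numeric(baseline) || length(baseline) != 1 || !is.finite(baseline))
    stop("baseline must be a finite scalar", call. = FALSE)
  time_series(absolute$t_s, absolute$value - baseline,
              kind = attr(absolute, "kind"), units = attr(absolute, "units"))
}
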