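#' Triaxial acceleration signal
#'
#' Container for a uniformly sampled triaxial accelerometer recording, the
#' basic data object of the package. The axis convention follows the
#' body-worn lower-back (L5) sensor placement customary in fall research:
#' \code{x} sagittal (forward/backward), \code{y} mediolateral, \code{z}
#' vertical. Acceleration is stored in units of g; sample \code{i} (0-based)
#' is taken at time \code{start_time_s + i / sampling_rate_hz}.
#'
#' @param x,y,z numeric vectors of equal length; per-axis acceleration in g.
#' @param sampling_rate_hz positive sampling rate in Hz (default 100, the
#'   usual smartphone accelerometer rate).
#' @param start_time_s time of the first sample in seconds (default 0).
#' @return An object of class \code{accsignal}: a list with elements
#'   \code{data} (n x 3 matrix, columns \code{x}, \code{y}, \code{z}),
#'   \code{sampling_rate_hz} and \code{start_time_s}.
#' @examples
#' sig <- accsignal(x = rep(0, 100), y = rep(0, 100), z = rep(1, 100))
#' sig
#' @export
accsignal <- function(x, y, z, sampling_rate_hz = 100, start_time_s = 0) {
  if (length(x) != length(y) || length(x) != length(z))
    stop("x, y and z must have equal length")
  m <- cbind(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  new_accsignal(m, sampling_rate_hz, start_time_s)
}

new_accsignal <- function(data, sampling_rate_hz, start_time_s = 0) {
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a single positive number")
  if (!is.matrix(data) || ncol(data) != 3L)
    stop("data must be an n x 3 matrix")
  if (nrow(data) > 0 && !all(is.finite(data)))
    stop("acceleration values must all be finite")
  colnames(data) <- c("x", "y", "z")
  structure(
    list(data = data,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         start_time_s = as.numeric(start_time_s)),
    class = "accsignal")
}

#' @export
length.accsignal <- function(x) nrow(x$data)

#' Sample times of a signal
#'
#' @param signal an \code{\link{accsignal}}.
#' @return numeric vector of sample times in seconds, on the uniform grid.
#' @export
signal_times <- function(signal) {
  stopifnot(inherits(signal, "accsignal"))
  n <- nrow(signal$data)
  if (n == 0L) return(numeric(0))
  signal$start_time_s + (seq_len(n) - 1) / signal$sampling_rate_hz
}

#' @export
print.accsignal <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf("Triaxial acceleration signal: %d samples @ %g Hz (%.2f s)\n",
              n, x$sampling_rate_hz, n / x$sampling_rate_hz))
  if (n > 0) {
    rng <- apply(x$data, 2, range)
    cat(sprintf("  range [g]: x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' @export
as.data.frame.accsignal <- function(x, ...) {
  data.frame(time = signal_times(x),
             x = x$data[, "x"], y = x$data[, "y"], z = x$data[, "z"])
}

#' @export
plot.accsignal <- function(x, main = "Triaxial acceleration", ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  tt <- signal_times(x)
  for (ax in c("z", "y", "x")) {
    graphics::plot(tt, x$data[, ax], type = "l", xlab = "time [s]",
                   ylab = sprintf("%s [g]", ax),
                   main = if (ax == "z") main else "", ...)
  }
  invisible(x)
}

# uniform-grid check shared by the readers: every gap must sit within 1% of
# the median gap, otherwise the file is not a constant-rate recording
check_uniform_times <- function(times) {
  if (length(times) < 2L) return(invisible(NULL))
  gaps <- diff(times)
  med <- stats::median(gaps)
  if (med <= 0) stop("timestamps must be strictly increasing")
  if (max(abs(gaps - med)) > 0.01 * med)
    stop("non-uniform timestamps: sample grid deviates by more than 1% of the median interval")
  invisible(med)
}

#' Read a triaxial signal from CSV
#'
#' Reads a comma-separated file with a header naming columns \code{time},
#' \code{x}, \code{y}, \code{z} (case-insensitive, any order). Time is in
#' seconds, acceleration in g. The sample grid must be uniform: any
#' inter-sample gap deviating from the median gap by more than 1% is
#' rejected.
#'
#' @param path path to the CSV file.
#' @param sampling_rate_hz the sampling rate in Hz, or \code{"infer"} to take
#'   it as 1 / median inter-row time difference (requires at least 2 rows).
#' @return an \code{\link{accsignal}}.
#' @export
read_signal_csv <- function(path, sampling_rate_hz = "infer") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("time", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  df <- df[need]
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(as.character(v)))
      if (anyNA(v)) stop("non-numeric value in column '", col, "'")
      df[[col]] <- v
    }
    if (anyNA(df[[col]])) stop("missing value in column '", col, "'")
  }
  n <- nrow(df)
  check_uniform_times(df$time)
  if (identical(sampling_rate_hz, "infer")) {
    if (n < 2L)
      stop("cannot infer sampling rate from fewer than 2 rows")
    sampling_rate_hz <- 1 / stats::median(diff(df$time))
  }
  new_accsignal(cbind(x = df$x, y = df$y, z = df$z),
                sampling_rate_hz,
                if (n > 0) df$time[1] else 0)
}

#' Write a triaxial signal to CSV
#'
#' Writes header \code{time,x,y,z} and one row per sample, with times on the
#' uniform grid and values at full double precision, so that
#' \code{read_signal_csv(path, signal$sampling_rate_hz)} recovers the signal
#' exactly.
#'
#' @param signal an \code{\link{accsignal}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "accsignal"))
  n <- nrow(signal$data)
  lines <- "time,x,y,z"
  if (n > 0) {
    tt <- signal_times(signal)
    lines <- c(lines,
               sprintf("%.17g,%.17g,%.17g,%.17g",
                       tt, signal$data[, "x"], signal$data[, "y"],
                       signal$data[, "z"]))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Resample a signal by linear interpolation
#'
#' Interpolates each axis linearly onto a new uniform grid at
#' \code{target_hz}, spanning the same time range as the input (a trailing
#' partial interval is dropped). Resampling at the original rate returns the
#' input unchanged.
#'
#' @param signal an \code{\link{accsignal}} with at least 2 samples.
#' @param target_hz positive target rate in Hz.
#' @return a new \code{\link{accsignal}} at \code{target_hz}.
#' @export
resample_signal <- function(signal, target_hz) {
  stopifnot(inherits(signal, "accsignal"))
  if (!is.numeric(target_hz) || length(target_hz) != 1L || target_hz <= 0)
    stop("target_hz must be a single positive number")
  n <- nrow(signal$data)
  if (n < 2L) stop("resampling requires at least 2 samples")
  if (target_hz == signal$sampling_rate_hz) return(signal)
  span <- (n - 1) / signal$sampling_rate_hz
  n_out <- floor(span * target_hz) + 1L
  t_in <- (seq_len(n) - 1) / signal$sampling_rate_hz
  t_out <- (seq_len(n_out) - 1) / target_hz
  out <- vapply(c("x", "y", "z"), function(ax)
    stats::approx(t_in, signal$data[, ax], xout = t_out)$y,
    numeric(n_out))
  if (n_out == 1L) out <- matrix(out, nrow = 1L)
  new_accsignal(out, target_hz, signal$start_time_s)
}
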