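#' Binned photon-count trace
#'
#' The sole observable of the method: assessment times \code{t_1 < ... < t_K}
#' (seconds, taken as the end of each counting bin) and the non-negative
#' integer photon counts \code{w_1, ..., w_K} recorded in the bins.
#'
#' @param times strictly increasing bin end times, seconds.
#' @param counts non-negative integer photon counts, same length.
#' @return an object of class \code{photon_trace}.
#' @export
photon_trace <- function(times, counts) {
  times <- as.numeric(times)
  if (length(times) != length(counts))
    stop("'times' and 'counts' must have the same length")
  if (length(times) > 0) {
    if (any(!is.finite(times))) stop("'times' must be finite")
    if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
    if (any(!is.finite(counts)) || any(counts < 0) ||
        any(counts != round(counts)))
      stop("'counts' must be non-negative integers")
  }
  structure(list(times = times, counts = as.integer(counts)),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  K <- length(x$counts)
  cat("Photon trace: ", K, " bins", sep = "")
  if (K > 1) {
    dt <- median(diff(x$times))
    cat(sprintf(", dt = %.3g s, duration = %.4g s, mean counts/bin = %.3g",
                dt, K * dt, mean(x$counts)))
  }
  cat("\n")
  invisible(x)
}

# Bin widths t_k - t_{k-1}; the width of the first bin is taken equal to the
# first observed spacing (uniform binning is the package-wide convention).
trace_dt <- function(trace) {
  K <- length(trace$times)
  if (K == 0) return(numeric(0))
  if (K == 1) {
    dt1 <- attr(trace, "dt")
    return(if (is.null(dt1)) trace$times[1] else dt1)
  }
  d <- diff(trace$times)
  c(d[1], d)
}

trace_duration <- function(trace) sum(trace_dt(trace))

#' Bin photon arrival timestamps into a count trace
#'
#' Counts timestamps into \code{K} contiguous bins of width \code{dt}
#' starting at \code{t0}, using half-open intervals
#' \code{[t0 + (k-1) dt, t0 + k dt)}: a photon falling exactly on a bin
#' boundary is counted in the later bin.  Timestamps outside
#' \code{[t0, t0 + K dt)} are ignored.
#'
#' @param ts non-decreasing photon arrival times, seconds.
#' @param dt bin width, seconds (> 0); detectors in this regime are typically
#'   read out at 1e-4 s.
#' @param t0 start of the first bin, seconds.
#' @param K number of bins.
#' @return a \code{\link{photon_trace}} with times \code{t0 + dt * (1:K)}.
#' @export
bin_timestamps <- function(ts, dt, t0 = 0, K = NULL) {
  ts <- as.numeric(ts)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  if (is.unsorted(ts)) stop("timestamps must be non-decreasing")
  if (is.null(K)) {
    K <- if (length(ts) == 0) 0L else max(1L, ceiling((max(ts) - t0) / dt))
  }
  K <- as.integer(K)
  idx <- floor((ts - t0) / dt) + 1
  idx <- idx[idx >= 1 & idx <= K]
  counts <- tabulate(idx, nbins = K)
  photon_trace(times = t0 + dt * seq_len(K), counts = counts)
}

#' Sum two photon traces bin by bin
#'
#' Mimics the artificial mixing of recordings from separate experiments:
#' because photon detections are additive Poisson streams, the bin-wise sum
#' of two traces is a realistic trace of both species diffusing in the same
#' volume.  Note the summed trace carries the background of both inputs, so
#' downstream inference should treat the background rate as free.
#'
#' @param trace_a,trace_b \code{\link{photon_trace}} objects on identical
#'   bin times.
#' @return a \code{\link{photon_trace}}.
#' @export
mix_traces <- function(trace_a, trace_b) {
  stopifnot(inherits(trace_a, "photon_trace"), inherits(trace_b, "photon_trace"))
  if (length(trace_a$times) != length(trace_b$times))
    stop("traces have different lengths and cannot be mixed")
  if (length(trace_a$times) > 0 &&
      max(abs(trace_a$times - trace_b$times)) > 1e-9 * max(trace_a$times))
    stop("traces have different bin times and cannot be mixed")
  photon_trace(trace_a$times, trace_a$counts + trace_b$counts)
}

#' Write / read a photon trace as two-column delimited text
#'
#' The on-disk format is plain text: '#'-prefixed header lines carrying the
#' bin width, the number of bins and any generation parameters, followed by
#' two whitespace-separated columns \code{time_s} and \code{counts}.
#' \code{read_trace(write_trace(x))} restores the trace exactly.
#'
#' @param trace a \code{\link{photon_trace}}.
#' @param path file path.
#' @param header named list or character vector of extra header fields.
#' @return \code{write_trace} returns \code{path} invisibly;
#'   \code{read_trace} returns a \code{\link{photon_trace}}.
#' @export
write_trace <- function(trace, path, header = list()) {
  stopifnot(inherits(trace, "photon_trace"))
  K <- length(trace$counts)
  dt <- if (K > 1) median(diff(trace$times)) else NA_real_
  lines <- c("# bnpfcs photon trace",
             sprintf("# K = %d", K),
             sprintf("# dt_s = %.17g", dt))
  for (nm in names(header))
    lines <- c(lines, sprintf("# %s = %s", nm, format(header[[nm]])))
  lines <- c(lines, "# time_s counts")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  if (K > 0)
    writeLines(sprintf("%.17g %d", trace$times, trace$counts), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_data <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(is_data))
    stop("no data rows found in '", path, "' (header-only or empty file)")
  rows <- which(is_data)
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) > 0)
    stop("line ", rows[bad[1]], " of '", path, "': expected two columns")
  times <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  counts <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(!is.finite(times) | !is.finite(counts))
  if (length(bad) > 0)
    stop("line ", rows[bad[1]], " of '", path, "': non-numeric entry")
  bad <- which(counts < 0 | counts != round(counts))
  if (length(bad) > 0)
    stop("line ", rows[bad[1]], " of '", path,
         "': counts must be non-negative integers")
  photon_trace(times, counts)
}
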