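# zero-phase low-pass filtering ----------------------------------------------

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (zero net phase, squared magnitude response). To suppress startup
#' transients the signal is first detrended by the straight line through
#' its endpoints, extended at both ends by odd reflection, filtered in both
#' directions, trimmed, and re-trended. Constants and straight lines
#' therefore pass exactly (DC gain 1), and event timing is preserved.
#'
#' @param x Numeric signal sampled on a uniform grid; must contain no
#'   missing values.
#' @param rate Sampling rate in Hz.
#' @param cutoff Cut-off frequency in Hz; must be below the Nyquist
#'   frequency `rate / 2`.
#' @param order Filter order per pass (default 4).
#' @param padlen Reflection padding length in samples; defaults to
#'   `2 * rate / cutoff` capped at `length(x) - 1`.
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' lowpass_filter(rep(10, 100), rate = 100, cutoff = 5)  # unchanged
lowpass_filter <- function(x, rate, cutoff, order = 4, padlen = NULL) {
  assert_number(rate, "rate", lower = 0, strict_lower = TRUE)
  assert_number(cutoff, "cutoff", lower = 0, strict_lower = TRUE)
  if (cutoff >= rate / 2) {
    stop_portalsim(
      sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
              cutoff, rate / 2),
      class = "portalsim_invalid_cutoff"
    )
  }
  if (anyNA(x)) {
    stop_portalsim("signal contains missing samples; filter valid spans only",
                   class = "portalsim_missing_samples"
    )
  }
  n <- length(x)
  if (n < 4L) return(x)
  if (is.null(padlen)) padlen <- round(2 * rate / cutoff)
  padlen <- max(1L, min(n - 1L, as.integer(padlen)))

  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  # endpoint-line detrend: lines are passed exactly and edges start near 0
  line <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  r <- x - line
  pre <- 2 * r[1] - r[(padlen + 1L):2L]
  post <- 2 * r[n] - r[(n - 1L):(n - padlen)]
  xe <- c(pre, r, post)
  y <- as.numeric(signal::filter(bf, xe))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(padlen + 1L):(padlen + n)] + line
}

# filter a signal separately over contiguous index segments; segments are
# delimited by `breaks` (last index of each segment except the final one)
filter_by_segment <- function(x, rate, cutoff, breaks) {
  n <- length(x)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  out <- x
  for (s in seq_along(starts)) {
    idx <- starts[s]:ends[s]
    if (length(idx) >= 4L && !anyNA(x[idx])) {
      out[idx] <- lowpass_filter(x[idx], rate, cutoff)
    }
  }
  out
}
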