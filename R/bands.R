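#' Frequency band
#'
#' A half-open frequency interval \code{[low, high)} in Hz. Band membership of
#' a discrete-Fourier-transform (DFT) bin frequency f is \code{low <= f < high};
#' when \code{closed_high = TRUE} the upper edge is included
#' (\code{low <= f <= high}). The broad 0.01-0.1 Hz band and the ninth narrow
#' bin close their upper edge so that the nine narrow bins tile the broad band
#' exactly once on DFT bin frequencies.
#'
#' @param low Lower edge in Hz (> 0).
#' @param high Upper edge in Hz (> low).
#' @param name Stable band name; defaults to \code{"<low>-<high>"}.
#' @param closed_high Include the upper edge?
#' @return A `frequency_band` object.
#' @export
frequency_band <- function(low, high, name = NULL, closed_high = FALSE) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L, length(high) == 1L)
  if (!(low > 0 && high > low)) {
    stop("frequency band requires 0 < low < high, got [", low, ", ", high, ")")
  }
  if (is.null(name)) name <- sprintf("%.2f-%.2f", low, high)
  structure(
    list(low = low, high = high, name = name, closed_high = isTRUE(closed_high)),
    class = "frequency_band"
  )
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf(
    "<frequency_band> %s: [%g, %g%s Hz\n",
    x$name, x$low, x$high, if (x$closed_high) "]" else ")"
  ))
  invisible(x)
}

nyquist_hz <- function(tr) 1 / (2 * tr)

check_band_valid <- function(band, tr) {
  ny <- nyquist_hz(tr)
  if (band$high > ny + 1e-12) {
    stop(
      "band '", band$name, "' [", band$low, ", ", band$high,
      ") exceeds the Nyquist frequency ", signif(ny, 6), " Hz at TR = ", tr, " s"
    )
  }
  invisible(TRUE)
}

#' The ten-band analysis set
#'
#' The broad low-frequency band \code{[0.01, 0.10]} Hz plus nine contiguous
#' 0.01-Hz-wide narrow bins \code{[0.01, 0.02), [0.02, 0.03), ..., [0.09, 0.10]}.
#' The narrow bins tile the broad band exactly; names are stable and ordered
#' (broad band first, then bins by ascending frequency).
#'
#' @param tr Repetition time in seconds; 0.1 Hz must lie at or below Nyquist.
#' @return A list of 10 [frequency_band] objects.
#' @export
make_band_set <- function(tr = 1.0) {
  stopifnot(is.numeric(tr), length(tr) == 1L, tr > 0)
  if (0.1 > nyquist_hz(tr) + 1e-12) {
    stop(
      "TR = ", tr, " s gives Nyquist ", signif(nyquist_hz(tr), 6),
      " Hz; the 0.01-0.1 Hz analysis range is unresolvable"
    )
  }
  broad <- frequency_band(0.01, 0.10, name = "0.01-0.10", closed_high = TRUE)
  edges <- seq(0.01, 0.10, by = 0.01)
  bins <- lapply(seq_len(9L), function(i) {
    frequency_band(
      edges[i], edges[i + 1L],
      name = sprintf("%.2f-%.2f", edges[i], edges[i + 1L]),
      closed_high = (i == 9L)
    )
  })
  c(list(broad), bins)
}

#' DFT bin indices covered by a band
#'
#' For a length-`n` series sampled at interval `tr`, returns the indices `k`
#' (1-based, `k = 1` meaning frequency `1/(n*tr)`; DC excluded) whose
#' frequencies fall inside `band`.
#'
#' @param n Number of time points.
#' @param tr Sampling interval in seconds.
#' @param band A [frequency_band].
#' @return Integer vector of positive-frequency bin indices (possibly empty).
#' @export
band_bin_indices <- function(n, tr, band) {
  k <- seq_len(floor(n / 2))
  f <- k / (n * tr)
  eps <- 1e-9
  keep <- f >= band$low - eps &
    (if (band$closed_high) f <= band$high + eps else f < band$high - eps)
  k[keep]
}
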