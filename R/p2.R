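# Bipolar-cell (P2) component: peak measurement on the low-pass-filtered
# P2-OP complex.

#' Measure the P2 peak amplitude and time
#'
#' Measures the positive-going bipolar-cell component on the filtered
#' trace: amplitude is the maximum over the search window minus the mean
#' of the pre-stimulus segment; peak time is the location of that
#' maximum. Because the photoreceptoral P3 has already been subtracted,
#' the amplitude convention is baseline-to-peak (not trough-to-peak).
#'
#' @param filtered_uV Numeric vector: the low-pass-filtered P2 trace, on
#'   the same time grid as `w`.
#' @param w The originating [erg_waveform()] (supplies the time grid and
#'   pre-stimulus window).
#' @param search_window_s Length-2 window (seconds after the flash) in
#'   which the peak is sought; default `(0, 0.250)`.
#' @return An object of class `p2_result`: `p2_trace_uV`,
#'   `peak_amplitude_uV`, `peak_time_ms`, and `boundary_flag` (TRUE when
#'   the peak lies on the search-window boundary, which usually indicates
#'   a degenerate trace).
#' @export
measure_p2 <- function(filtered_uV, w, search_window_s = c(0, 0.250)) {
  stopifnot(inherits(w, "erg_waveform"),
            length(filtered_uV) == length(w$samples_uV))
  t <- erg_times(w)
  pre <- t < 0
  if (!any(pre)) stop("pre-stimulus window absent: cannot reference the P2 amplitude")
  base <- mean(filtered_uV[pre])
  idx <- which(t > search_window_s[1] & t <= search_window_s[2])
  if (!length(idx)) stop("search window contains no samples")
  k <- idx[which.max(filtered_uV[idx])]
  amp <- filtered_uV[k] - base
  boundary <- (k == idx[1] || k == idx[length(idx)]) || amp <= 0
  structure(list(p2_trace_uV = filtered_uV,
                 peak_amplitude_uV = amp,
                 peak_time_ms = 1000 * t[k],
                 boundary_flag = boundary),
            class = "p2_result")
}

#' @export
print.p2_result <- function(x, ...) {
  cat(sprintf("<p2_result> peak %.1f uV at %.1f ms%s\n",
              x$peak_amplitude_uV, x$peak_time_ms,
              if (x$boundary_flag) " [boundary flag]" else ""))
  invisible(x)
}
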