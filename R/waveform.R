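#' Acquisition settings for a flash ERG recording
#'
#' Describes how a full-field flash electroretinogram is digitised:
#' sampling rate, record duration, the analogue band-pass corner
#' frequencies (-3 dB points) and the length of the pre-stimulus
#' baseline segment preceding the flash.
#'
#' @param fs_hz Sampling rate in Hz.
#' @param duration_s Record duration in seconds.
#' @param hp_cutoff_hz High-pass -3 dB corner in Hz.
#' @param lp_cutoff_hz Low-pass -3 dB corner in Hz.
#' @param pre_stimulus_s Length of the pre-stimulus segment in seconds;
#'   the first sample of the record sits at `-pre_stimulus_s` relative
#'   to flash onset.
#' @return An object of class `acquisition_spec`.
#' @examples
#' acq <- acquisition_spec()
#' acq$fs_hz
#' @export
acquisition_spec <- function(fs_hz = 4000, duration_s = 0.640,
                             hp_cutoff_hz = 0.3, lp_cutoff_hz = 1000,
                             pre_stimulus_s = 0.020) {
  stopifnot(is.numeric(fs_hz), fs_hz > 0, is.numeric(duration_s), duration_s > 0,
            pre_stimulus_s >= 0, pre_stimulus_s < duration_s)
  if (!(hp_cutoff_hz > 0 && hp_cutoff_hz < lp_cutoff_hz && lp_cutoff_hz < fs_hz / 2))
    stop("require 0 < hp_cutoff_hz < lp_cutoff_hz < fs_hz/2")
  structure(list(fs_hz = fs_hz, duration_s = duration_s,
                 hp_cutoff_hz = hp_cutoff_hz, lp_cutoff_hz = lp_cutoff_hz,
                 pre_stimulus_s = pre_stimulus_s),
            class = "acquisition_spec")
}

#' Construct a single-flash ERG waveform
#'
#' Container for one dark-adapted flash response: a vector of voltage
#' samples on a uniform time grid, the sampling rate, the time of the
#' first sample relative to flash onset (negative when a pre-stimulus
#' baseline was recorded) and the flash energy.
#'
#' @param samples_uV Numeric vector of voltages in microvolts.
#' @param fs_hz Sampling rate in Hz.
#' @param t0_s Time of the first sample relative to the flash, seconds.
#' @param flash_energy_log Flash energy in log cd.s/m^2.
#' @param meta Named list of record metadata (subject, genotype,
#'   treatment, time_min, eye, ...).
#' @return An object of class `erg_waveform`.
#' @examples
#' w <- erg_waveform(rnorm(2560, sd = 5))
#' length(erg_times(w))
#' @export
erg_waveform <- function(samples_uV, fs_hz = 4000, t0_s = -0.020,
                         flash_energy_log = 2.07, meta = list()) {
  samples_uV <- as.numeric(samples_uV)
  if (length(samples_uV) < 2L) stop("waveform needs at least 2 samples")
  if (!all(is.finite(samples_uV))) stop("samples_uV must be finite")
  stopifnot(is.numeric(fs_hz), fs_hz > 0, is.numeric(t0_s),
            is.numeric(flash_energy_log), is.list(meta))
  structure(list(samples_uV = samples_uV, fs_hz = fs_hz, t0_s = t0_s,
                 flash_energy_log = flash_energy_log, meta = meta),
            class = "erg_waveform")
}

#' Time grid of an ERG waveform
#'
#' @param w An `erg_waveform`.
#' @return Numeric vector of sample times in seconds relative to the flash.
#' @export
erg_times <- function(w) {
  stopifnot(inherits(w, "erg_waveform"))
  w$t0_s + (seq_along(w$samples_uV) - 1) / w$fs_hz
}

#' @export
print.erg_waveform <- function(x, ...) {
  t <- erg_times(x)
  cat(sprintf("<erg_waveform> %d samples @ %g Hz, t = [%.3f, %.3f] s, flash %.2f log cd.s/m^2\n",
              length(x$samples_uV), x$fs_hz, t[1], t[length(t)], x$flash_energy_log))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("<acquisition_spec> %g Hz, %.0f ms, band-pass %.1f-%.0f Hz (-3 dB), prestim %.0f ms\n",
              x$fs_hz, 1000 * x$duration_s, x$hp_cutoff_hz, x$lp_cutoff_hz,
              1000 * x$pre_stimulus_s))
  invisible(x)
}
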