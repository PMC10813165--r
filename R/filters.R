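# Zero-phase frequency-domain filtering. All filters in this package are
# realised by multiplying the DFT of the record by a real, non-negative,
# frequency-symmetric transfer function and inverting; this leaves every
# component's phase (and therefore peak times) untouched.

#' Apply a zero-phase frequency-domain filter
#'
#' Multiplies the DFT of `x` by `gain_fun(|f|)` evaluated at the folded bin
#' frequencies and inverts. Because the transfer is real and symmetric the
#' operation is zero-phase and returns a real signal of the same length.
#'
#' @param x Numeric vector.
#' @param fs_hz Sampling rate in Hz.
#' @param gain_fun Function mapping frequency (Hz, >= 0) to gain in [0, 1].
#' @return Filtered numeric vector, same length as `x`.
#' @export
fft_filter <- function(x, fs_hz, gain_fun) {
  stopifnot(is.numeric(x), length(x) >= 2L, fs_hz > 0, is.function(gain_fun))
  n <- length(x)
  f <- (seq_len(n) - 1) * fs_hz / n
  f_folded <- pmin(f, fs_hz - f)
  h <- gain_fun(f_folded)
  if (any(!is.finite(h)) || any(h < 0)) stop("transfer function must be finite and non-negative")
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

#' Magnitude response of the P2 isolation low-pass filter
#'
#' Raised-cosine low-pass used to isolate the ON-bipolar P2 from the P2-OP
#' complex. The pass band has unit gain; over a transition band of width
#' `transition_hz` the gain falls as a raised cosine to zero, positioned so
#' that the gain at `cutoff_hz` is exactly 1/sqrt(2) (-3 dB). Gain is
#' monotone non-increasing in frequency and exactly 1 at DC.
#'
#' @param f Frequency (Hz), vectorised.
#' @param cutoff_hz -3 dB frequency, default 46.9 Hz.
#' @param transition_hz Full width of the raised-cosine transition band.
#' @return Gain values in [0, 1].
#' @examples
#' p2_filter_gain(c(0, 46.9, 130))
#' @export
p2_filter_gain <- function(f, cutoff_hz = 46.9, transition_hz = 50) {
  stopifnot(cutoff_hz > 0, transition_hz > 0)
  # u* solves 0.5 * (1 + cos(pi * u)) = 1/sqrt(2) on the transition ramp
  u_star <- acos(sqrt(2) - 1) / pi
  f1 <- cutoff_hz - transition_hz * u_star
  if (f1 < 0) stop("transition band extends below DC; reduce transition_hz")
  f2 <- f1 + transition_hz
  u <- (f - f1) / transition_hz
  g <- ifelse(f <= f1, 1, ifelse(f >= f2, 0, 0.5 * (1 + cos(pi * pmin(pmax(u, 0), 1)))))
  g
}

#' Isolate the P2 component by zero-phase low-pass filtering
#'
#' Removes the high-frequency oscillatory potentials (~70-200 Hz) from the
#' P2-OP complex, leaving the bipolar-cell-driven P2. Implemented as a
#' discrete Fourier transform, multiplication by [p2_filter_gain()] and
#' inverse transform; the DC component is preserved exactly and no phase
#' shift is introduced.
#'
#' @param complex_uV Numeric vector: the P2-OP complex (raw minus fitted P3).
#' @param fs_hz Sampling rate in Hz.
#' @param cutoff_hz -3 dB cutoff, default 46.9 Hz.
#' @param transition_hz Transition-band width passed to [p2_filter_gain()].
#' @return Filtered vector, same length.
#' @export
lowpass_p2 <- function(complex_uV, fs_hz, cutoff_hz = 46.9, transition_hz = 50) {
  if (length(complex_uV) < 16L) stop("input must have at least 16 samples")
  if (cutoff_hz >= fs_hz / 2) stop("cutoff_hz must be below the Nyquist frequency")
  fft_filter(complex_uV, fs_hz,
             function(f) p2_filter_gain(f, cutoff_hz = cutoff_hz,
                                        transition_hz = transition_hz))
}

#' Magnitude response of the acquisition band-pass
#'
#' Second-order Butterworth-style magnitude on each skirt, with -3 dB
#' points at the high-pass and low-pass corners of the acquisition spec
#' (defaults 0.3 and 1000 Hz). Gain at DC is 0.
#'
#' @param f Frequency (Hz), vectorised.
#' @param acq An [acquisition_spec()].
#' @return Gain values in [0, 1].
#' @examples
#' acquisition_gain(c(0.3, 100, 1000))
#' @export
acquisition_gain <- function(f, acq = acquisition_spec()) {
  stopifnot(inherits(acq, "acquisition_spec"))
  hp <- acq$hp_cutoff_hz
  lp <- acq$lp_cutoff_hz
  g <- numeric(length(f))
  pos <- f > 0
  g[pos] <- 1 / sqrt(1 + (hp / f[pos])^4) / sqrt(1 + (f[pos] / lp)^4)
  g
}

#' Simulate the recording system's band-pass on a signal
#'
#' Zero-phase application of [acquisition_gain()]; emulates the
#' instrument's analogue band-pass (0.3-1000 Hz, -3 dB by default) on a
#' synthetic signal. Because a flash response ends far from where it
#' started, the record is edge-padded (endpoint hold, 0.5 s per side)
#' before the circular DFT filter and cropped afterwards, so wrap-around
#' ringing lands in the discarded padding rather than in the
#' pre-stimulus baseline.
#'
#' @param x Numeric vector.
#' @param acq An [acquisition_spec()]; `acq$fs_hz` is used as the rate.
#' @return Filtered vector, same length as `x`.
#' @export
acquisition_bandpass <- function(x, acq = acquisition_spec()) {
  n_pad <- round(0.5 * acq$fs_hz)
  xp <- c(rep(x[1], n_pad), x, rep(x[length(x)], n_pad))
  yp <- fft_filter(xp, acq$fs_hz, function(f) acquisition_gain(f, acq))
  yp[n_pad + seq_along(x)]
}
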