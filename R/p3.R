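# Photoreceptoral (P3) component: delayed-Gaussian phototransduction model.
# P3(t) = -RmP3 * (1 - exp(-E * S * (t - td)^2)) for t > td, 0 otherwise,
# with E the flash energy in cd.s/m^2 (linearised from log units). RmP3 is
# the saturated photoreceptoral amplitude (uV), S the sensitivity scaling
# flash energy x time^2, td a short transduction delay.

#' Parameters of the delayed-Gaussian P3 model
#'
#' @param rm_p3_uV Saturated photoreceptoral amplitude magnitude (uV), > 0.
#' @param sensitivity_S Sensitivity in (cd.s.m^-2)^-1 s^-2, > 0.
#' @param t_delay_s Transduction delay td in seconds, >= 0.
#' @param sse Residual sum of squares of the fit (NA for constructed sets).
#' @param baseline_uV Pre-stimulus baseline voltage subtracted before
#'   fitting (0 for constructed sets).
#' @return An object of class `p3_params`.
#' @export
p3_params <- function(rm_p3_uV, sensitivity_S, t_delay_s, sse = NA_real_,
                      baseline_uV = 0) {
  stopifnot(is.numeric(rm_p3_uV), rm_p3_uV >= 0, is.finite(rm_p3_uV),
            is.numeric(sensitivity_S), sensitivity_S > 0, is.finite(sensitivity_S),
            is.numeric(t_delay_s), t_delay_s >= 0, is.finite(t_delay_s))
  structure(list(rm_p3_uV = rm_p3_uV, sensitivity_S = sensitivity_S,
                 t_delay_s = t_delay_s, sse = sse, baseline_uV = baseline_uV),
            class = "p3_params")
}

#' Evaluate the P3 model trace
#'
#' Returns the modelled photoreceptoral response on a time grid:
#' `-rm_p3_uV * (1 - exp(-E * S * (t - td)^2))` for `t > td` and 0
#' otherwise, where `E = 10^flash_energy_log`. The trace is 0 at and
#' before the delay, monotonically non-increasing afterwards, and bounded
#' below by `-rm_p3_uV`.
#'
#' @param p A [p3_params()] object (or a fit from [fit_p3()]).
#' @param t_s Numeric time grid in seconds (monotone).
#' @param flash_energy_log Flash energy in log cd.s/m^2.
#' @return Numeric vector of model voltages (uV).
#' @examples
#' p <- p3_params(400, 40, 0.004)
#' p3_model_trace(p, c(0.004, 0.02, 0.2))
#' @export
p3_model_trace <- function(p, t_s, flash_energy_log = 2.07) {
  stopifnot(inherits(p, "p3_params") || inherits(p, "p3_fit"))
  if (is.unsorted(t_s)) stop("time grid must be monotone non-decreasing")
  E <- 10^flash_energy_log
  d <- t_s - p$t_delay_s
  out <- numeric(length(t_s))
  pos <- d > 0
  out[pos] <- -p$rm_p3_uV * (1 - exp(-E * p$sensitivity_S * d[pos]^2))
  out
}

#' Fit the delayed-Gaussian P3 model to the a-wave leading edge
#'
#' Least-squares fit of (RmP3, S, td) to the leading edge of the a-wave.
#' The record is first re-referenced to its pre-stimulus mean (the
#' acquisition chain is AC-coupled, so absolute DC is arbitrary). The
#' default fit window runs from 3 ms after the flash to the a-wave
#' trough, capped at 11 ms: the region where the photoreceptoral
#' component dominates before the rising post-receptoral P2 intrudes. A multi-start strategy (grid over td and S
#' with RmP3 profiled linearly, followed by bounded quasi-Newton polishing
#' from the best starts) guards against local minima; the returned SSE is
#' never worse than the best grid start.
#'
#' @param w An [erg_waveform()].
#' @param fit_window_s Numeric length-2 `(start, end)` in seconds, or NULL
#'   for the default `(0.003, min(a-wave trough time, 0.011))`.
#' @param flash_energy_log Flash energy; defaults to the waveform's.
#' @param td_grid_s Grid of delay starts (seconds).
#' @param s_grid Grid of sensitivity starts.
#' @param bounds List with elements `rm`, `S`, `td` giving `(lower, upper)`
#'   box constraints for the polish stage.
#' @return An object of class `p3_fit` (also `p3_params`): fields
#'   `rm_p3_uV`, `sensitivity_S`, `t_delay_s`, `sse`, `baseline_uV`,
#'   `fit_window_s`, `n_points`, `converged`, plus the waveform grid
#'   (`fs_hz`, `t0_s`, `n_samples`) so residual computation can verify
#'   grid identity.
#' @export
fit_p3 <- function(w, fit_window_s = NULL, flash_energy_log = NULL,
                   td_grid_s = seq(0.002, 0.008, by = 0.001),
                   s_grid = c(5, 15, 40, 120, 400),
                   bounds = list(rm = c(1, 5000), S = c(1, 1e5),
                                 td = c(0.001, 0.012))) {
  stopifnot(inherits(w, "erg_waveform"))
  if (is.null(flash_energy_log)) flash_energy_log <- w$flash_energy_log
  t <- erg_times(w)
  pre <- t < 0
  baseline <- if (any(pre)) mean(w$samples_uV[pre]) else 0
  y <- w$samples_uV - baseline
  noise_sd <- if (sum(pre) >= 2) stats::sd(y[pre]) else 0

  if (is.null(fit_window_s)) {
    sr <- t > 0.003 & t < 0.150
    if (!any(sr)) stop("record too short to locate the a-wave trough")
    t_trough <- t[sr][which.min(y[sr])]
    # leading edge only: stop at the a-wave trough, and never later than
    # 11 ms, where the rising b-wave starts to intrude at this flash
    # energy; keep at least 9 samples so degenerate records reach the
    # a-wave amplitude check below rather than a window-size error
    fit_window_s <- c(0.003, max(min(t_trough, 0.011), 0.003 + 9 / w$fs_hz))
  }
  stopifnot(length(fit_window_s) == 2, fit_window_s[1] < fit_window_s[2])
  win <- t >= fit_window_s[1] & t <= fit_window_s[2]
  if (sum(win) < 8L) stop("fit window must contain at least 8 samples")
  tw <- t[win]
  yw <- y[win]

  if (min(yw) > -3 * max(noise_sd, 1e-9))
    stop("no measurable a-wave: no negative deflection beyond 3x pre-stimulus noise SD in the fit window")

  E <- 10^flash_energy_log
  # RmP3 enters the model linearly, so it is profiled in closed form and
  # the search runs over (S, td) only.
  profile_rm <- function(S, td) {
    d <- tw - td
    b <- ifelse(d > 0, 1 - exp(-E * S * d^2), 0)
    bb <- sum(b^2)
    if (bb == 0) return(NULL)
    rm <- min(max(-sum(b * yw) / bb, bounds$rm[1]), bounds$rm[2])
    list(par = c(rm, S, td), sse = sum((yw + rm * b)^2))
  }
  # polish works on (log S, td in ms) so both coordinates are O(1) and the
  # finite-difference gradient steps are sensible
  sse_of2 <- function(par) {
    pr <- profile_rm(exp(par[1]), par[2] / 1000)
    if (is.null(pr)) return(sum(yw^2))
    pr$sse
  }

  starts <- expand.grid(td = td_grid_s, S = s_grid)
  grid <- lapply(seq_len(nrow(starts)),
                 function(i) profile_rm(starts$S[i], starts$td[i]))
  grid <- Filter(Negate(is.null), grid)
  if (!length(grid)) stop("P3 fit failed: empty start grid")
  sses <- vapply(grid, `[[`, numeric(1), "sse")
  ord <- order(sses)
  best <- grid[[ord[1]]]
  converged <- FALSE
  for (i in ord[seq_len(min(3, length(ord)))]) {
    st <- grid[[i]]
    opt <- tryCatch(
      stats::optim(c(log(st$par[2]), 1000 * st$par[3]), sse_of2,
                   method = "L-BFGS-B",
                   lower = c(log(bounds$S[1]), 1000 * bounds$td[1]),
                   upper = c(log(bounds$S[2]), 1000 * bounds$td[2]),
                   control = list(maxit = 500, factr = 1e3)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value < best$sse) {
      pr <- profile_rm(exp(opt$par[1]), opt$par[2] / 1000)
      if (!is.null(pr) && pr$sse <= best$sse) {
        best <- pr
        converged <- converged || opt$convergence == 0
      }
    }
  }
  structure(list(rm_p3_uV = best$par[1], sensitivity_S = best$par[2],
                 t_delay_s = best$par[3], sse = best$sse,
                 baseline_uV = baseline, fit_window_s = fit_window_s,
                 n_points = sum(win), converged = converged,
                 flash_energy_log = flash_energy_log,
                 fs_hz = w$fs_hz, t0_s = w$t0_s,
                 n_samples = length(w$samples_uV)),
            class = c("p3_fit", "p3_params"))
}

#' Subtract the fitted P3 from the raw waveform
#'
#' Removes the modelled photoreceptoral component (and the pre-stimulus
#' baseline estimated during fitting) from the record, yielding the P2-OP
#' complex: the bipolar-cell P2 plus high-frequency oscillatory
#' potentials.
#'
#' @param w The [erg_waveform()] the model was fitted to.
#' @param p A `p3_fit` or [p3_params()] object. When `p` carries grid
#'   information (a fit), it must match `w`'s grid.
#' @return Numeric vector (uV), same length as the record.
#' @export
subtract_p3 <- function(w, p) {
  stopifnot(inherits(w, "erg_waveform"),
            inherits(p, "p3_params") || inherits(p, "p3_fit"))
  if (!is.null(p$n_samples)) {
    if (p$n_samples != length(w$samples_uV) || p$fs_hz != w$fs_hz ||
        abs(p$t0_s - w$t0_s) > 1e-12)
      stop("grid mismatch: P3 parameters were fitted on a different time grid")
  }
  fe <- if (!is.null(p$flash_energy_log)) p$flash_energy_log else w$flash_energy_log
  model <- p3_model_trace(p, erg_times(w), flash_energy_log = fe)
  bl <- if (!is.null(p$baseline_uV)) p$baseline_uV else 0
  w$samples_uV - bl - model
}

#' @export
print.p3_fit <- function(x, ...) {
  cat(sprintf("<p3_fit> RmP3 = %.1f uV, S = %.3g, td = %.2f ms, SSE = %.3g (n = %d)\n",
              x$rm_p3_uV, x$sensitivity_S, 1000 * x$t_delay_s, x$sse, x$n_points))
  invisible(x)
}
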