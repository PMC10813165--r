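# Synthetic scotopic flash ERG generator. Each record is the sum of a
# delayed-Gaussian photoreceptoral P3, a unit-peak gamma-kernel P2,
# Gabor-atom oscillatory potentials, a slow baseline drift and white
# noise, passed through the acquisition band-pass. Ground truth for
# every generated record is retained so decomposition accuracy can be
# measured exactly.

#' Generative parameters for one synthetic ERG waveform
#'
#' @param rm_p3_uV Saturated photoreceptoral amplitude (uV), > 0.
#' @param sensitivity_S P3 sensitivity, (cd.s.m^-2)^-1 s^-2.
#' @param t_delay_s P3 delay (s).
#' @param p2_amp_uV Peak amplitude of the P2 gamma kernel (uV), > 0.
#' @param p2_tau_s Time constant of the gamma kernel (s); the kernel
#'   `(t/tp)^(n-1) exp((n-1)(1 - t/tp))` peaks with unit height at
#'   `tp = (n-1) * tau`.
#' @param p2_shape Integer gamma order n >= 2.
#' @param op_atoms data.frame of Gabor atoms emulating oscillatory
#'   potentials: columns `center_s`, `freq_hz` (in [60, 200]), `amp_uV`,
#'   `width_s`. Atoms are gated to t > 0.
#' @param drift_amp_uV Amplitude of a slow (0.25 Hz) baseline sinusoid.
#' @param noise_sd_uV White-noise SD before band-passing, >= 0.
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(rm_p3_uV = 450, sensitivity_S = 450,
                            t_delay_s = 0.0035,
                            p2_amp_uV = 700, p2_tau_s = 0.020, p2_shape = 5L,
                            op_atoms = default_op_atoms(),
                            drift_amp_uV = 5, noise_sd_uV = 10) {
  num1 <- function(x, nm, min = -Inf, strict_min = NULL) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop(sprintf("field '%s' must be a single finite number", nm))
    if (!is.null(strict_min) && x <= strict_min)
      stop(sprintf("field '%s' must be > %g", nm, strict_min))
    if (x < min) stop(sprintf("field '%s' must be >= %g", nm, min))
    x
  }
  rm_p3_uV <- num1(rm_p3_uV, "rm_p3_uV", strict_min = 0)
  sensitivity_S <- num1(sensitivity_S, "sensitivity_S", strict_min = 0)
  t_delay_s <- num1(t_delay_s, "t_delay_s", min = 0)
  p2_amp_uV <- num1(p2_amp_uV, "p2_amp_uV", strict_min = 0)
  p2_tau_s <- num1(p2_tau_s, "p2_tau_s", strict_min = 0)
  drift_amp_uV <- num1(drift_amp_uV, "drift_amp_uV")
  noise_sd_uV <- num1(noise_sd_uV, "noise_sd_uV", min = 0)
  if (!is.numeric(p2_shape) || p2_shape < 2) stop("field 'p2_shape' must be an integer >= 2")
  stopifnot(is.data.frame(op_atoms))
  if (nrow(op_atoms)) {
    need <- c("center_s", "freq_hz", "amp_uV", "width_s")
    if (!all(need %in% names(op_atoms)))
      stop("op_atoms needs columns center_s, freq_hz, amp_uV, width_s")
    if (!all(is.finite(as.matrix(op_atoms[need]))))
      stop("field 'op_atoms' must be finite")
    if (any(op_atoms$freq_hz < 60 | op_atoms$freq_hz > 200))
      stop("field 'op_atoms': freq_hz must lie in [60, 200]")
  }
  structure(list(rm_p3_uV = rm_p3_uV, sensitivity_S = sensitivity_S,
                 t_delay_s = t_delay_s, p2_amp_uV = p2_amp_uV,
                 p2_tau_s = p2_tau_s, p2_shape = as.integer(p2_shape),
                 op_atoms = op_atoms, drift_amp_uV = drift_amp_uV,
                 noise_sd_uV = noise_sd_uV),
            class = "waveform_params")
}

#' Default oscillatory-potential Gabor atoms
#'
#' Three bursts at 110-130 Hz centred 20-36 ms after the flash, removable
#' by the 46.9 Hz P2 low-pass.
#' @return data.frame with columns center_s, freq_hz, amp_uV, width_s.
#' @export
default_op_atoms <- function() {
  data.frame(center_s = c(0.020, 0.028, 0.036),
             freq_hz = c(110, 120, 130),
             amp_uV = c(30, 40, 25),
             width_s = c(0.004, 0.004, 0.004))
}

#' Unit-peak gamma kernel used as the generative P2 shape
#'
#' @param t_s Time grid (s).
#' @param tau_s Time constant (s).
#' @param shape Gamma order n >= 2; the kernel peaks at `(n-1)*tau` with
#'   height 1 and is 0 for `t <= 0`.
#' @return Numeric vector.
#' @export
p2_kernel <- function(t_s, tau_s, shape) {
  tp <- (shape - 1) * tau_s
  out <- numeric(length(t_s))
  pos <- t_s > 0
  x <- t_s[pos] / tp
  out[pos] <- x^(shape - 1) * exp((shape - 1) * (1 - x))
  out
}

#' Noise-free generative components of a synthetic waveform
#'
#' Evaluates the deterministic part of the generative sum (P3 + P2 +
#' oscillatory potentials) on a time grid, before drift, noise and the
#' acquisition band-pass. Serves as the analytic oracle for ground-truth
#' consistency checks.
#'
#' @inheritParams simulate_waveform
#' @param t_s Time grid (s).
#' @return Numeric vector (uV).
#' @export
waveform_clean_components <- function(params, t_s, flash_energy_log = 2.07) {
  stopifnot(inherits(params, "waveform_params"))
  p3 <- p3_model_trace(p3_params(params$rm_p3_uV, params$sensitivity_S,
                                 params$t_delay_s),
                       t_s, flash_energy_log = flash_energy_log)
  p2 <- params$p2_amp_uV * p2_kernel(t_s, params$p2_tau_s, params$p2_shape)
  ops <- numeric(length(t_s))
  if (nrow(params$op_atoms)) {
    for (i in seq_len(nrow(params$op_atoms))) {
      a <- params$op_atoms[i, ]
      ops <- ops + (t_s > 0) * a$amp_uV *
        exp(-(t_s - a$center_s)^2 / (2 * a$width_s^2)) *
        cos(2 * pi * a$freq_hz * (t_s - a$center_s))
    }
  }
  p3 + p2 + ops
}

#' Simulate one scotopic flash ERG record
#'
#' Generates `P3 + P2 + OPs + drift + noise` on the acquisition grid and
#' passes the sum through the acquisition band-pass. The pre-stimulus
#' segment (t < 0) contains drift and noise only: all response components
#' are gated to t > 0. Deterministic for a fixed seed. The drift is a
#' slow sinusoid starting at phase zero at the beginning of the record,
#' so records with `noise_sd_uV = 0` and equal parameters are identical.
#'
#' @param params A [waveform_params()] object.
#' @param flash_energy_log Flash energy in log cd.s/m^2 (default 2.07).
#' @param acq An [acquisition_spec()].
#' @param seed Integer seed for the noise draw.
#' @param meta Metadata list attached to the waveform.
#' @return An [erg_waveform()].
#' @examples
#' w <- simulate_waveform(waveform_params(), seed = 7)
#' @export
simulate_waveform <- function(params, flash_energy_log = 2.07,
                              acq = acquisition_spec(), seed = 1,
                              meta = list()) {
  stopifnot(inherits(params, "waveform_params"), inherits(acq, "acquisition_spec"))
  n <- round(acq$duration_s * acq$fs_hz)
  t0 <- -acq$pre_stimulus_s
  t <- t0 + (seq_len(n) - 1) / acq$fs_hz
  clean <- waveform_clean_components(params, t, flash_energy_log)
  drift <- params$drift_amp_uV * sin(2 * pi * 0.25 * (t - t0))
  noise <- if (params$noise_sd_uV > 0)
    with_seed(seed, stats::rnorm(n, 0, params$noise_sd_uV)) else numeric(n)
  samples <- acquisition_bandpass(clean + drift + noise, acq)
  # the AC-coupled chain loses absolute DC; like the acquisition software,
  # display the record referenced to its pre-stimulus baseline
  pre <- t < 0
  if (any(pre)) samples <- samples - mean(samples[pre])
  erg_waveform(samples, fs_hz = acq$fs_hz, t0_s = t0,
               flash_energy_log = flash_energy_log, meta = meta)
}

#' Design of a synthetic four-group longitudinal ERG cohort
#'
#' Encodes the study conditions the generator emulates: four groups
#' (WT/HOM x VEH/LDOPA), recordings at baseline and every 5 min to
#' 30 min, genotype-specific baseline attenuation, group-specific
#' amplitude-growth trajectories and two sources of between-subject
#' variability (baseline scale and drug-response slope).
#'
#' @param n_per_group Named integer vector over
#'   `WT_VEH, WT_LDOPA, HOM_VEH, HOM_LDOPA`; each >= 2.
#' @param timepoints_min Strictly increasing timepoints starting at 0.
#' @param genotype_scale Multiplicative attenuation (< 1) of RmP3 and P2
#'   amplitude in HOM animals at baseline.
#' @param growth_30min Named vector of the multiplicative amplitude
#'   growth factor reached at the final timepoint, per group; the
#'   trajectory is `G(t) = 1 + (G_end - 1) * s(t)` with the saturating
#'   time course `s(t) = (1 - exp(-t/tau)) / (1 - exp(-t_end/tau))`, so
#'   every curve is exactly 1 at t = 0.
#' @param growth_tau_min Time constant of the saturating course (min).
#' @param growth_sd SD of the per-subject additive deviation of the
#'   growth factor at the final timepoint (same time course), carrying
#'   between-subject heterogeneity of drug response.
#' @param between_subject_cv Coefficient of variation of the per-subject
#'   lognormal baseline amplitude scaler (applied to both RmP3 and P2,
#'   drawn once per subject and reused across timepoints).
#' @param seed Integer seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = c(WT_VEH = 11, WT_LDOPA = 11,
                                          HOM_VEH = 13, HOM_LDOPA = 11),
                          timepoints_min = seq(0, 30, by = 5),
                          genotype_scale = 0.75,
                          growth_30min = c(WT_VEH = 1.19, WT_LDOPA = 1.16,
                                           HOM_VEH = 1.25, HOM_LDOPA = 1.47),
                          growth_tau_min = 12,
                          growth_sd = 0.26,
                          between_subject_cv = 0.20,
                          seed = 1) {
  groups <- c("WT_VEH", "WT_LDOPA", "HOM_VEH", "HOM_LDOPA")
  if (!all(groups %in% names(n_per_group)))
    stop("n_per_group must name all of: ", paste(groups, collapse = ", "))
  if (any(n_per_group[groups] < 2)) stop("every group needs n >= 2 subjects")
  stopifnot(length(timepoints_min) >= 2, timepoints_min[1] == 0,
            all(diff(timepoints_min) > 0))
  if (!all(groups %in% names(growth_30min)))
    stop("growth_30min must name all four groups")
  stopifnot(genotype_scale > 0, genotype_scale <= 1,
            growth_tau_min > 0, growth_sd >= 0, between_subject_cv >= 0)
  structure(list(n_per_group = n_per_group[groups],
                 timepoints_min = timepoints_min,
                 genotype_scale = genotype_scale,
                 growth_30min = growth_30min[groups],
                 growth_tau_min = growth_tau_min,
                 growth_sd = growth_sd,
                 between_subject_cv = between_subject_cv,
                 seed = seed),
            class = "cohort_design")
}

#' Saturating growth time course
#'
#' `s(t) = (1 - exp(-t/tau)) / (1 - exp(-t_end/tau))`: 0 at t = 0, 1 at
#' the final timepoint.
#' @param t_min Time (min).
#' @param tau_min Time constant (min).
#' @param t_end_min Final timepoint (min).
#' @return Numeric vector in [0, 1].
#' @export
growth_shape <- function(t_min, tau_min = 12, t_end_min = 30) {
  (1 - exp(-t_min / tau_min)) / (1 - exp(-t_end_min / tau_min))
}

#' Group growth factor at given times
#' @param design A [cohort_design()].
#' @param group Group label.
#' @param t_min Times (min).
#' @return Multiplicative growth factors (1 at t = 0).
#' @export
growth_factor <- function(design, group, t_min) {
  s <- growth_shape(t_min, design$growth_tau_min, max(design$timepoints_min))
  1 + (design$growth_30min[[group]] - 1) * s
}

# Draw the per-subject structure (scaler + response slope) for a design.
# Returns a data.frame with one row per subject.
draw_subjects <- function(design) {
  groups <- names(design$n_per_group)
  subj <- do.call(rbind, lapply(groups, function(g) {
    n <- design$n_per_group[[g]]
    geno <- sub("_.*", "", g)
    trt <- sub(".*_", "", g)
    data.frame(subject = sprintf("%s_%02d", g, seq_len(n)),
               group = g, genotype = geno, treatment = trt,
               stringsAsFactors = FALSE)
  }))
  cv <- design$between_subject_cv
  sdlog <- sqrt(log(1 + cv^2))
  subj$scaler <- if (cv > 0)
    stats::rlnorm(nrow(subj), meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
  subj$slope <- if (design$growth_sd > 0)
    stats::rnorm(nrow(subj), 0, design$growth_sd) else 0
  subj
}

# True amplitude multiplier for a subject row at time t (relative to the
# group baseline mean): scaler x (group growth + subject slope x shape).
subject_growth <- function(design, subj_row, t_min) {
  s <- growth_shape(t_min, design$growth_tau_min, max(design$timepoints_min))
  pmax(growth_factor(design, subj_row$group, t_min) + subj_row$slope * s, 0.05)
}

#' Simulate a full longitudinal ERG cohort with ground truth
#'
#' Generates one waveform per subject per timepoint under the design's
#' group structure. Per-subject baseline scalers and response slopes are
#' drawn once and reused across timepoints (repeated-measures
#' structure). Returns both the waveforms and a ground-truth table of
#' the true generative RmP3 and P2 amplitude for every record.
#'
#' @param design A [cohort_design()].
#' @param base A [waveform_params()] object giving the WT baseline
#'   generative parameters.
#' @param acq An [acquisition_spec()].
#' @param flash_energy_log Flash energy in log cd.s/m^2.
#' @return List with `waveforms` (list of [erg_waveform()]) and `truth`
#'   (data.frame: subject, group, genotype, treatment, time_min, scaler,
#'   growth, true_rm_p3_uV, true_p2_amp_uV, record_seed).
#' @export
simulate_cohort <- function(design, base = waveform_params(),
                            acq = acquisition_spec(),
                            flash_energy_log = 2.07) {
  stopifnot(inherits(design, "cohort_design"), inherits(base, "waveform_params"))
  with_seed(design$seed, {
    subj <- draw_subjects(design)
    tps <- design$timepoints_min
    n_rec <- nrow(subj) * length(tps)
    rec_seeds <- sample.int(.Machine$integer.max - 1L, n_rec)
    truth <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i) {
      gscale <- if (subj$genotype[i] == "HOM") design$genotype_scale else 1
      g <- subject_growth(design, subj[i, ], tps)
      data.frame(subject = subj$subject[i], group = subj$group[i],
                 genotype = subj$genotype[i], treatment = subj$treatment[i],
                 time_min = tps, scaler = subj$scaler[i], growth = g,
                 true_rm_p3_uV = base$rm_p3_uV * gscale * subj$scaler[i] * g,
                 true_p2_amp_uV = base$p2_amp_uV * gscale * subj$scaler[i] * g,
                 stringsAsFactors = FALSE)
    }))
    truth$record_seed <- rec_seeds
    waveforms <- lapply(seq_len(nrow(truth)), function(k) {
      p <- base
      p$rm_p3_uV <- truth$true_rm_p3_uV[k]
      p$p2_amp_uV <- truth$true_p2_amp_uV[k]
      simulate_waveform(p, flash_energy_log = flash_energy_log, acq = acq,
                        seed = truth$record_seed[k],
                        meta = list(subject = truth$subject[k],
                                    genotype = truth$genotype[k],
                                    treatment = truth$treatment[k],
                                    time_min = truth$time_min[k],
                                    eye = "OD"))
    })
    list(waveforms = waveforms, truth = truth)
  })
}

#' Simulate a cohort at the measure level
#'
#' Fast amplitude-level counterpart of [simulate_cohort()] +
#' [decompose_cohort()]: generates the true per-record RmP3 and P2
#' amplitudes under the same subject structure and adds multiplicative
#' measurement error emulating the decomposition step. Used for
#' large-replicate statistical calibration where full waveform synthesis
#' would be needlessly expensive.
#'
#' @param design A [cohort_design()].
#' @param base_rm_p3_uV,base_p2_uV WT baseline means (uV).
#' @param meas_cv Coefficient of variation of the multiplicative
#'   measurement error per record (default 0.02, matching the
#'   decomposition error observed at the default record noise).
#' @return A measure table data.frame: subject, group, genotype,
#'   treatment, time_min, measure, value.
#' @export
simulate_measure_cohort <- function(design, base_rm_p3_uV = 450,
                                    base_p2_uV = 700, meas_cv = 0.02) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    subj <- draw_subjects(design)
    tps <- design$timepoints_min
    rows <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i) {
      gscale <- if (subj$genotype[i] == "HOM") design$genotype_scale else 1
      g <- subject_growth(design, subj[i, ], tps)
      amp <- gscale * subj$scaler[i] * g
      data.frame(subject = subj$subject[i], group = subj$group[i],
                 genotype = subj$genotype[i], treatment = subj$treatment[i],
                 time_min = rep(tps, 2),
                 measure = rep(c("rm_p3_uV", "p2_peak_uV"), each = length(tps)),
                 true_value = c(base_rm_p3_uV * amp, base_p2_uV * amp),
                 stringsAsFactors = FALSE)
    }))
    err <- stats::rnorm(nrow(rows), 0, meas_cv)
    rows$value <- rows$true_value * (1 + err)
    rows
  })
}

#' Simulate compound-symmetric null data for ANOVA calibration
#'
#' Generates measure tables with no group, time or interaction effects:
#' `y = mean + subject intercept + iid noise`. Used to verify the type-I
#' error of the repeated-measures interaction test.
#'
#' @param n_per_group Subjects per group.
#' @param n_groups Number of between-subject groups.
#' @param timepoints_min Within-subject timepoints.
#' @param mean,sd_subject,sd_noise Gaussian components.
#' @param seed Integer seed.
#' @return data.frame: subject, group, time_min, value.
#' @export
simulate_null_measures <- function(n_per_group = 10, n_groups = 2,
                                   timepoints_min = seq(0, 30, by = 5),
                                   mean = 100, sd_subject = 15, sd_noise = 10,
                                   seed = 1) {
  with_seed(seed, {
    n_t <- length(timepoints_min)
    n_s <- n_per_group * n_groups
    b <- rep(stats::rnorm(n_s, 0, sd_subject), each = n_t)
    data.frame(subject = rep(sprintf("s%03d", seq_len(n_s)), each = n_t),
               group = rep(sprintf("g%d", rep(seq_len(n_groups), each = n_per_group)),
                           each = n_t),
               time_min = rep(timepoints_min, n_s),
               value = mean + b + stats::rnorm(n_s * n_t, 0, sd_noise),
               stringsAsFactors = FALSE)
  })
}
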