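test_that("waveform generator is deterministic and gates components to t > 0", {
  params <- waveform_params()
  w1 <- simulate_waveform(params, seed = 42)
  w2 <- simulate_waveform(params, seed = 42)
  expect_identical(w1$samples_uV, w2$samples_uV)
  expect_false(identical(w1$samples_uV,
                         simulate_waveform(params, seed = 43)$samples_uV))

  # pre-stimulus region carries noise + drift only: with both silenced the
  # pre-stimulus segment of the band-passed record stays at numerical zero
  quiet <- waveform_params(noise_sd_uV = 0, drift_amp_uV = 0)
  wq <- simulate_waveform(quiet, seed = 1)
  t <- erg_times(wq)
  expect_lt(max(abs(wq$samples_uV[t < -0.005])), 2)
})

test_that("single-component generation reduces to the filtered P3 model", {
  p <- waveform_params(p2_amp_uV = 1e-9, drift_amp_uV = 0, noise_sd_uV = 0,
                       op_atoms = default_op_atoms()[0, ])
  w <- simulate_waveform(p, seed = 1)
  t <- erg_times(w)
  pure <- p3_model_trace(p3_params(p$rm_p3_uV, p$sensitivity_S, p$t_delay_s), t)
  d <- abs(w$samples_uV - pure)
  # distortion over the analysis region is well under 2% of the component;
  # high-pass sag over the sustained late plateau stays under 3%
  expect_lt(max(d[t < 0.2]), 0.02 * p$rm_p3_uV)
  expect_lt(max(d), 0.03 * p$rm_p3_uV)
})

test_that("the early leading edge of the full model is negative", {
  p <- waveform_params(noise_sd_uV = 0)
  # oracle: evaluate the generative sum directly at td + 2 ms
  direct <- waveform_clean_components(p, p$t_delay_s + 0.002)
  expect_lt(direct, 0)
  w <- simulate_waveform(p, seed = 1)
  t <- erg_times(w)
  expect_lt(w$samples_uV[which.min(abs(t - (p$t_delay_s + 0.002)))], 0)
})

test_that("parameter validation names the offending field", {
  expect_error(waveform_params(rm_p3_uV = NaN), "rm_p3_uV")
  expect_error(waveform_params(noise_sd_uV = -1), "noise_sd_uV")
  expect_error(waveform_params(p2_amp_uV = 0), "p2_amp_uV")
  ops <- default_op_atoms(); ops$freq_hz[1] <- 20
  expect_error(waveform_params(op_atoms = ops), "\\[60, 200\\]")
})

test_that("cohort ground truth encodes the designed group structure exactly", {
  design <- cohort_design(n_per_group = c(WT_VEH = 12, WT_LDOPA = 12,
                                          HOM_VEH = 12, HOM_LDOPA = 12),
                          between_subject_cv = 0, growth_sd = 0, seed = 3)
  cohort <- simulate_cohort(design)
  truth <- cohort$truth
  expect_equal(nrow(truth), 4 * 12 * 7)
  expect_equal(length(cohort$waveforms), 4 * 12 * 7)
  # growth ratios at 30 min are the designed factors, exactly
  for (g in c("HOM_LDOPA", "WT_LDOPA")) {
    r <- truth[truth$group == g, ]
    ratio <- r$true_rm_p3_uV[r$time_min == 30] / r$true_rm_p3_uV[r$time_min == 0]
    expect_equal(ratio, rep(design$growth_30min[[g]], 12), tolerance = 1e-12)
  }
  # genotype attenuation at baseline
  b <- truth[truth$time_min == 0, ]
  expect_equal(mean(b$true_rm_p3_uV[b$genotype == "HOM"]) /
                 mean(b$true_rm_p3_uV[b$genotype == "WT"]),
               design$genotype_scale, tolerance = 1e-12)
})

test_that("ground truth matches the decomposition-free analytic oracle", {
  design <- cohort_design(seed = 8)
  cohort <- simulate_cohort(design)
  truth <- cohort$truth
  gscale <- ifelse(truth$genotype == "HOM", design$genotype_scale, 1)
  expect_equal(truth$true_rm_p3_uV, 450 * gscale * truth$scaler * truth$growth)
  expect_equal(truth$true_p2_amp_uV, 700 * gscale * truth$scaler * truth$growth)
})

test_that("flat designs produce identical records across timepoints", {
  design <- cohort_design(n_per_group = c(WT_VEH = 2, WT_LDOPA = 2,
                                          HOM_VEH = 2, HOM_LDOPA = 2),
                          growth_30min = c(WT_VEH = 1, WT_LDOPA = 1,
                                           HOM_VEH = 1, HOM_LDOPA = 1),
                          between_subject_cv = 0, growth_sd = 0, seed = 4)
  cohort <- simulate_cohort(design, base = waveform_params(noise_sd_uV = 0))
  subj1 <- which(cohort$truth$subject == cohort$truth$subject[1])
  ref <- cohort$waveforms[[subj1[1]]]$samples_uV
  for (k in subj1[-1])
    expect_identical(cohort$waveforms[[k]]$samples_uV, ref)
})

test_that("repeated-measures structure: within-subject coherence exceeds between", {
  design <- cohort_design(n_per_group = c(WT_VEH = 50, WT_LDOPA = 50,
                                          HOM_VEH = 50, HOM_LDOPA = 50),
                          growth_30min = c(WT_VEH = 1, WT_LDOPA = 1,
                                           HOM_VEH = 1, HOM_LDOPA = 1),
                          growth_sd = 0, between_subject_cv = 0.2, seed = 6)
  m <- simulate_measure_cohort(design)
  m <- m[m$measure == "rm_p3_uV" & m$genotype == "WT", ]
  wide <- stats::reshape(m[, c("subject", "time_min", "value")],
                         idvar = "subject", timevar = "time_min",
                         direction = "wide")
  r <- stats::cor(wide$value.0, wide$value.30)
  expect_gt(r, 0.9)  # scaler dominates: strong within-subject correlation
})

test_that("OCT cohort applies offsets and thinning as designed", {
  # deterministic construction: no variability at all
  L <- default_oct_layers()
  L$sd_um[] <- 0
  d0 <- oct_cohort_design(layers = L, noise_sd_um = 0, seed = 1)
  tab <- simulate_oct_cohort(d0)
  onl <- tab[tab$measure == "ONL", ]
  d_onl <- mean(onl$value[onl$genotype == "HOM" & onl$time_min == 0]) -
    mean(onl$value[onl$genotype == "WT" & onl$time_min == 0])
  expect_equal(d_onl, L$hom_offset_um[L$layer == "ONL"])
  # zero-effect design: every record equals its baseline mean
  L2 <- L; L2$hom_offset_um[] <- 0; L2$time_thinning_um[] <- 0
  tab2 <- simulate_oct_cohort(oct_cohort_design(layers = L2, noise_sd_um = 0,
                                                seed = 1))
  for (lay in L2$layer)
    expect_true(all(tab2$value[tab2$measure == lay] ==
                      L2$baseline_mean_um[L2$layer == lay]))
  # TRT is the exact sum of component layers plus the remainder
  tab3 <- simulate_oct_cohort(oct_cohort_design(seed = 12))
  byrec <- split(tab3, paste(tab3$subject, tab3$time_min))
  for (rec in byrec[1:10])
    expect_equal(rec$value[rec$measure == "TRT"],
                 sum(rec$value[rec$measure != "TRT"]) + 55)
})

test_that("default OCT design thins the OPL over the session in every group", {
  tab <- simulate_oct_cohort(oct_cohort_design(seed = 1))
  opl <- tab[tab$measure == "OPL", ]
  m <- tapply(opl$value, list(opl$group, opl$time_min), mean)
  expect_true(all(m[, "30"] < m[, "0"]))
})

test_that("invalid cohort designs are rejected", {
  expect_error(cohort_design(n_per_group = c(WT_VEH = 1, WT_LDOPA = 11,
                                             HOM_VEH = 13, HOM_LDOPA = 11)),
               "n >= 2")
  expect_error(cohort_design(timepoints_min = c(5, 10)))
  expect_error(cohort_design(n_per_group = c(WT_VEH = 5)), "must name")
  expect_error(simulate_oct_cohort(oct_cohort_design(),
                                   n_per_group = c(WT_VEH = 0, WT_LDOPA = 1,
                                                   HOM_VEH = 1, HOM_LDOPA = 1)),
               "empty group")
})
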