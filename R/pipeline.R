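# End-to-end pipeline: simulate (or load) a cohort, decompose every
# record, run the longitudinal statistics on raw and baseline-normalised
# measures, and repeat the statistical layer on the OCT thickness table.

#' Run the full screening analysis pipeline
#'
#' Stages: (1) simulate the ERG cohort (or reuse supplied waveforms);
#' (2) decompose every record into RmP3 and P2 peak; (3) ROUT outlier
#' removal per group x time x measure; (4) repeated-measures ANOVA and
#' Sidak post hocs on raw and baseline-normalised measures, including
#' the treatment x time analysis within the HOM genotype; (5) the same
#' statistical layer on the OCT thickness table; (6) write all tables
#' and a run log to `out_dir`.
#'
#' @param out_dir Output directory for the artifact bundle; NULL keeps
#'   everything in memory.
#' @param seed Integer seed driving both generators.
#' @param design A [cohort_design()]; its seed is overridden by `seed`.
#' @param oct_design An [oct_cohort_design()]; seed overridden by
#'   `seed + 1`.
#' @param base [waveform_params()] for the WT baseline.
#' @param acq [acquisition_spec()].
#' @param q_outlier ROUT FDR level.
#' @param write_waveforms If TRUE, also write the waveform directory
#'   container (large; off by default).
#' @return Invisibly, a list with every intermediate table and fit.
#' @export
full_run <- function(out_dir = NULL, seed = 1,
                     design = cohort_design(),
                     oct_design = oct_cohort_design(),
                     base = waveform_params(),
                     acq = acquisition_spec(),
                     q_outlier = 0.01,
                     write_waveforms = FALSE) {
  design$seed <- seed
  oct_design$seed <- seed + 1
  t_start <- Sys.time()

  cohort <- simulate_cohort(design, base = base, acq = acq)
  dec <- decompose_cohort(cohort$waveforms)

  measures <- rbind(
    data.frame(subject = dec$subject, genotype = dec$genotype,
               treatment = dec$treatment, time_min = dec$time_min,
               measure = "rm_p3_uV", value = dec$rm_p3_uV,
               stringsAsFactors = FALSE),
    data.frame(subject = dec$subject, genotype = dec$genotype,
               treatment = dec$treatment, time_min = dec$time_min,
               measure = "p2_peak_uV", value = dec$p2_peak_uV,
               stringsAsFactors = FALSE))
  measures$group <- paste(measures$genotype, measures$treatment, sep = "_")
  cleaned <- remove_outliers(measures, Q = q_outlier)
  norm <- normalize_to_baseline(cleaned$table)

  analyses <- list()
  for (msr in unique(measures$measure)) {
    raw_m <- cleaned$table[cleaned$table$measure == msr, ]
    norm_m <- norm[norm$measure == msr, ]
    hom_norm <- norm_m[norm_m$genotype == "HOM", ]
    analyses[[msr]] <- list(
      raw_anova = mixed_anova(raw_m, between = "group"),
      norm_anova = mixed_anova(norm_m, between = "group"),
      hom_treatment_anova = mixed_anova(hom_norm, between = "treatment"),
      posthoc = posthoc_by_time(mixed_anova(norm_m, between = "group"),
                                contrasts = list(c("WT_LDOPA", "WT_VEH"),
                                                 c("HOM_LDOPA", "HOM_VEH"))),
      raw_summary = summarize_groups(raw_m),
      norm_summary = summarize_groups(norm_m))
  }

  oct <- simulate_oct_cohort(oct_design)
  oct_norm <- normalize_to_baseline(oct)
  oct_analyses <- list()
  for (lay in unique(oct$measure)) {
    raw_l <- oct[oct$measure == lay, ]
    norm_l <- oct_norm[oct_norm$measure == lay, ]
    oct_analyses[[lay]] <- list(
      raw_anova = mixed_anova(raw_l, between = c("genotype", "treatment")),
      norm_anova = mixed_anova(norm_l, between = c("genotype", "treatment")),
      raw_summary = summarize_groups(raw_l),
      norm_summary = summarize_groups(norm_l))
  }

  result <- list(design = design, oct_design = oct_design, seed = seed,
                 truth = cohort$truth, decomposition = dec,
                 measures = measures, outliers = cleaned$removed,
                 normalized = norm, analyses = analyses,
                 oct_table = oct, oct_normalized = oct_norm,
                 oct_analyses = oct_analyses)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (write_waveforms)
      write_waveform_dir(cohort$waveforms, file.path(out_dir, "waveforms"))
    utils::write.csv(cohort$truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(dec, file.path(out_dir, "decomposition.csv"),
                     row.names = FALSE)
    write_measure_table(measures, file.path(out_dir, "measures_raw.csv"))
    write_measure_table(norm, file.path(out_dir, "measures_normalized.csv"))
    write_measure_table(oct, file.path(out_dir, "oct_measures.csv"))
    if (nrow(cleaned$removed))
      write_measure_table(cleaned$removed, file.path(out_dir, "outliers_removed.csv"))
    anova_rows <- list()
    for (msr in names(analyses))
      for (an in c("raw_anova", "norm_anova", "hom_treatment_anova")) {
        tb <- analyses[[msr]][[an]]$table
        tb$measure <- msr; tb$analysis <- an
        anova_rows[[paste(msr, an)]] <- tb
      }
    for (lay in names(oct_analyses))
      for (an in c("raw_anova", "norm_anova")) {
        tb <- oct_analyses[[lay]][[an]]$table
        tb$measure <- lay; tb$analysis <- an
        anova_rows[[paste(lay, an)]] <- tb
      }
    utils::write.csv(do.call(rbind, anova_rows),
                     file.path(out_dir, "anova_effects.csv"), row.names = FALSE)
    ph <- do.call(rbind, lapply(names(analyses), function(msr) {
      p <- analyses[[msr]]$posthoc; p$measure <- msr; p
    }))
    utils::write.csv(ph, file.path(out_dir, "posthoc.csv"), row.names = FALSE)
    log <- c(sprintf("ergoct full_run"),
             sprintf("seed: %d", seed),
             sprintf("package version: %s",
                     as.character(utils::packageVersion("ergoct"))),
             sprintf("R version: %s", R.version.string),
             sprintf("n per group (ERG): %s",
                     paste(names(design$n_per_group), design$n_per_group,
                           sep = "=", collapse = ", ")),
             sprintf("timepoints (min): %s",
                     paste(design$timepoints_min, collapse = ", ")),
             sprintf("ROUT Q: %g; outliers removed: %d", q_outlier,
                     nrow(cleaned$removed)),
             sprintf("started: %s", format(t_start)),
             sprintf("finished: %s", format(Sys.time())))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}

#' Plot group mean +/- SEM trajectories
#'
#' @param summary A summary table from [summarize_groups()].
#' @param main Plot title.
#' @param ylab Y-axis label.
#' @return Invisibly, NULL. Draws on the active graphics device.
#' @export
plot_group_trajectories <- function(summary, main = "", ylab = "value") {
  stopifnot(all(c("group", "time_min", "mean", "sem") %in% names(summary)))
  groups <- unique(summary$group)
  cols <- stats::setNames(grDevices::hcl.colors(max(length(groups), 3), "Dark 3"),
                          groups[seq_along(groups)])[seq_along(groups)]
  rng <- range(summary$mean + summary$sem, summary$mean - summary$sem,
               na.rm = TRUE)
  graphics::plot(NA, xlim = range(summary$time_min), ylim = rng,
                 xlab = "time after treatment (min)", ylab = ylab, main = main)
  for (g in groups) {
    s <- summary[summary$group == g, ]
    s <- s[order(s$time_min), ]
    graphics::lines(s$time_min, s$mean, col = cols[[g]], lwd = 2)
    graphics::points(s$time_min, s$mean, col = cols[[g]], pch = 16)
    graphics::arrows(s$time_min, s$mean - s$sem, s$time_min, s$mean + s$sem,
                     angle = 90, code = 3, length = 0.03, col = cols[[g]])
  }
  graphics::legend("topleft", legend = groups, col = cols, lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(NULL)
}
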