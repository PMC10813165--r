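# Synthetic OCT layer-thickness cohort: per-layer outer-ring means with
# genotype-specific outer-retinal thinning and a global thinning drift
# across the imaging session (the anaesthesia-related effect the
# longitudinal analysis must separate from drug effects).

#' Design of a synthetic OCT thickness cohort
#'
#' @param layers data.frame with one row per segmented layer: columns
#'   `layer` (RNFL, GCIPL, INL, OPL, ONL), `baseline_mean_um`,
#'   `sd_um` (between-subject SD), `hom_offset_um` (added for HOM
#'   animals; negative for the outer layers), `time_thinning_um`
#'   (added at the follow-up timepoint). Total retinal thickness (TRT)
#'   is derived as the sum of the component layers plus `remainder_um`.
#' @param remainder_um Constant thickness of retina not covered by the
#'   segmented component layers (photoreceptor inner/outer segments,
#'   RPE), included in TRT.
#' @param noise_sd_um Within-subject measurement SD per layer per visit
#'   (sector means from registered follow-up scans are highly
#'   repeatable, so this is well below the between-subject SD).
#' @param timepoints_min Imaging timepoints (default baseline and 30 min).
#' @param seed Integer seed.
#' @return An object of class `oct_cohort_design`.
#' @export
oct_cohort_design <- function(layers = default_oct_layers(),
                              remainder_um = 55, noise_sd_um = 0.6,
                              timepoints_min = c(0, 30), seed = 1) {
  need <- c("layer", "baseline_mean_um", "sd_um", "hom_offset_um",
            "time_thinning_um")
  stopifnot(is.data.frame(layers), all(need %in% names(layers)),
            all(layers$baseline_mean_um > 0), all(layers$sd_um >= 0),
            remainder_um >= 0, noise_sd_um >= 0,
            length(timepoints_min) == 2, timepoints_min[1] == 0)
  structure(list(layers = layers, remainder_um = remainder_um,
                 noise_sd_um = noise_sd_um, timepoints_min = timepoints_min,
                 seed = seed),
            class = "oct_cohort_design")
}

#' Default mouse retinal layer parameters
#'
#' Outer-ring means typical of the adult mouse retina, with HOM-specific
#' thinning confined to the outer plexiform and outer nuclear layers and
#' a small global thinning at the follow-up scan.
#' @return data.frame of per-layer generator parameters.
#' @export
default_oct_layers <- function() {
  data.frame(layer = c("RNFL", "GCIPL", "INL", "OPL", "ONL"),
             baseline_mean_um = c(14, 62, 28, 17, 58),
             sd_um = c(1.2, 2.5, 1.8, 1.2, 2.5),
             hom_offset_um = c(0, 0, 0, -1.5, -4),
             time_thinning_um = c(-0.5, -1.5, -0.7, -0.5, -1.2),
             stringsAsFactors = FALSE)
}

#' Simulate an OCT thickness cohort
#'
#' One record per subject x timepoint x layer. HOM animals receive the
#' per-layer `hom_offset_um`; all animals receive `time_thinning_um` at
#' the follow-up timepoint. TRT is the exact sum of the component layers
#' plus the remainder term in every record.
#'
#' @param design An [oct_cohort_design()].
#' @param n_per_group Named integer vector over
#'   `WT_VEH, WT_LDOPA, HOM_VEH, HOM_LDOPA`.
#' @return A measure table data.frame: subject, group, genotype,
#'   treatment, time_min, measure (layer name incl. TRT), value (um).
#' @export
simulate_oct_cohort <- function(design,
                                n_per_group = c(WT_VEH = 13, WT_LDOPA = 14,
                                                HOM_VEH = 16, HOM_LDOPA = 18)) {
  stopifnot(inherits(design, "oct_cohort_design"))
  groups <- c("WT_VEH", "WT_LDOPA", "HOM_VEH", "HOM_LDOPA")
  if (!all(groups %in% names(n_per_group)))
    stop("n_per_group must name all of: ", paste(groups, collapse = ", "))
  if (any(n_per_group[groups] < 1)) stop("empty group")
  L <- design$layers
  with_seed(design$seed, {
    rows <- list()
    for (g in groups) {
      geno <- sub("_.*", "", g)
      trt <- sub(".*_", "", g)
      for (i in seq_len(n_per_group[[g]])) {
        sid <- sprintf("%s_oct%02d", g, i)
        mu <- L$baseline_mean_um + if (geno == "HOM") L$hom_offset_um else 0
        base_i <- stats::rnorm(nrow(L), mu, L$sd_um)
        for (tp in design$timepoints_min) {
          v <- base_i + (tp > 0) * L$time_thinning_um +
            stats::rnorm(nrow(L), 0, design$noise_sd_um)
          if (any(v <= 0))
            stop("negative layer thickness generated; design parameters inconsistent")
          trt_total <- sum(v) + design$remainder_um
          rows[[length(rows) + 1L]] <-
            data.frame(subject = sid, group = g, genotype = geno,
                       treatment = trt, time_min = tp,
                       measure = c(L$layer, "TRT"),
                       value = c(v, trt_total),
                       stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
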