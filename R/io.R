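# Readers/writers: waveform container (directory of two-column delimited
# text files plus a manifest), measure tables, thickness maps and run
# configuration. All writers are deterministic (stable row order, fixed
# float formatting) so repeated runs are diffable.

GENOTYPES <- c("WT", "HOM")
TREATMENTS <- c("VEH", "LDOPA")

fmt_num <- function(x) trimws(formatC(x, format = "g", digits = 6))

#' Write a cohort of waveforms to a directory container
#'
#' One delimited text file per record (columns `time_s`, `voltage_uV`)
#' plus a `manifest.csv` describing every record.
#'
#' @param waveforms List of [erg_waveform()] objects with subject,
#'   genotype, treatment, time_min, eye metadata.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_waveform_dir <- function(waveforms, dir) {
  stopifnot(is.list(waveforms), length(waveforms) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(waveforms), function(i) {
    w <- waveforms[[i]]
    stopifnot(inherits(w, "erg_waveform"))
    file <- sprintf("rec_%04d.csv", i)
    t <- erg_times(w)
    df <- data.frame(time_s = fmt_num(t), voltage_uV = fmt_num(w$samples_uV))
    utils::write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
    data.frame(file = file,
               subject = w$meta$subject %||% NA_character_,
               genotype = w$meta$genotype %||% NA_character_,
               treatment = w$meta$treatment %||% NA_character_,
               time_min = w$meta$time_min %||% NA_real_,
               eye = w$meta$eye %||% "OD",
               flash_log = w$flash_energy_log,
               fs_hz = w$fs_hz, t0_s = w$t0_s,
               n_samples = length(w$samples_uV),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

validate_manifest <- function(manifest, dir) {
  need <- c("file", "subject", "genotype", "treatment", "time_min", "eye",
            "flash_log", "fs_hz")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    if (!file.exists(file.path(dir, r$file)))
      stop(sprintf("manifest row %d: file '%s' does not exist", i, r$file))
    if (!r$genotype %in% GENOTYPES)
      stop(sprintf("manifest row %d: unknown genotype token '%s'", i, r$genotype))
    if (!r$treatment %in% TREATMENTS)
      stop(sprintf("manifest row %d: unknown treatment token '%s'", i, r$treatment))
    if (!is.finite(r$time_min) || !is.finite(r$fs_hz) || r$fs_hz <= 0)
      stop(sprintf("manifest row %d: invalid time_min or fs_hz", i))
  }
  key <- paste(manifest$subject, manifest$time_min, manifest$eye)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(sprintf("manifest row %d: duplicate (subject, time_min, eye)", i))
  }
  invisible(manifest)
}

#' Read one waveform record
#'
#' @param path Path to a two-column (`time_s`, `voltage_uV`) delimited
#'   text file.
#' @param manifest_row One-row data.frame from the manifest carrying the
#'   record metadata; sampling rate and length are cross-checked against
#'   the file.
#' @return An [erg_waveform()].
#' @export
read_waveform <- function(path, manifest_row) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "voltage_uV") %in% names(df)))
    stop(sprintf("'%s': expected columns time_s, voltage_uV", path))
  t <- as.numeric(df$time_s); v <- as.numeric(df$voltage_uV)
  if (any(!is.finite(t)) || any(!is.finite(v)))
    stop(sprintf("'%s': non-numeric sample values", path))
  fs_obs <- 1 / stats::median(diff(t))
  if (abs(fs_obs - manifest_row$fs_hz) / manifest_row$fs_hz > 1e-3)
    stop(sprintf("'%s': sampling rate %.6g does not match manifest fs_hz %.6g",
                 path, fs_obs, manifest_row$fs_hz))
  if (!is.null(manifest_row$n_samples) && is.finite(manifest_row$n_samples) &&
      length(v) != manifest_row$n_samples)
    stop(sprintf("'%s': %d samples but manifest says %d", path, length(v),
                 manifest_row$n_samples))
  erg_waveform(v, fs_hz = manifest_row$fs_hz, t0_s = t[1],
               flash_energy_log = manifest_row$flash_log,
               meta = list(subject = manifest_row$subject,
                           genotype = manifest_row$genotype,
                           treatment = manifest_row$treatment,
                           time_min = manifest_row$time_min,
                           eye = manifest_row$eye))
}

#' Read a waveform directory container
#'
#' @param dir Directory holding `manifest.csv` and the per-record files.
#' @return List of [erg_waveform()] objects.
#' @export
read_waveform_dir <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  validate_manifest(manifest, dir)
  lapply(seq_len(nrow(manifest)), function(i)
    read_waveform(file.path(dir, manifest$file[i]), manifest[i, ]))
}

#' Write a measure table as schema-stable CSV
#'
#' Rows are sorted by (measure, subject, time_min) and floats rendered
#' with six significant digits so output is diffable across runs.
#'
#' @param tab Measure table (subject, genotype, treatment, time_min,
#'   measure, value).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_measure_table <- function(tab, path) {
  need <- c("subject", "genotype", "treatment", "time_min", "measure", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("measure table missing column(s): ", paste(miss, collapse = ", "))
  tab <- tab[order(tab$measure, tab$subject, tab$time_min), need]
  tab$value <- fmt_num(tab$value)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a measure table CSV
#'
#' Numeric parsing is locale-independent ('.' decimal separator,
#' exponent notation accepted); genotype/treatment tokens are checked
#' against the fixed vocabularies.
#'
#' @param path CSV path.
#' @return Measure table data.frame with a derived `group` column.
#' @export
read_measure_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(value = "character"))
  need <- c("subject", "genotype", "treatment", "time_min", "measure", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("measure table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!tab$genotype %in% GENOTYPES)
  if (length(bad)) stop(sprintf("row %d: unknown genotype token '%s'",
                                bad[1], tab$genotype[bad[1]]))
  bad <- which(!tab$treatment %in% TREATMENTS)
  if (length(bad)) stop(sprintf("row %d: unknown treatment token '%s'",
                                bad[1], tab$treatment[bad[1]]))
  v <- suppressWarnings(as.numeric(tab$value))
  if (any(is.na(v))) stop(sprintf("row %d: non-numeric value '%s'",
                                  which(is.na(v))[1], tab$value[which(is.na(v))[1]]))
  tab$value <- v
  tab$time_min <- as.numeric(tab$time_min)
  tab$group <- paste(tab$genotype, tab$treatment, sep = "_")
  tab
}

#' Write a thickness map with a small text header
#'
#' @param m A [thickness_map()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_thickness_map <- function(m, path) {
  stopifnot(inherits(m, "thickness_map"))
  hdr <- c(sprintf("# layer: %s", m$layer),
           sprintf("# eye: %s", m$eye),
           sprintf("# pitch_mm: %s %s", fmt_num(m$pitch_mm[1]), fmt_num(m$pitch_mm[2])),
           sprintf("# centre_px: %s %s", fmt_num(m$centre_px[1]), fmt_num(m$centre_px[2])))
  body <- apply(m$grid, 1, function(r) paste(fmt_num(r), collapse = ","))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a thickness map written by [write_thickness_map()]
#'
#' @param path Input path.
#' @return A [thickness_map()].
#' @export
read_thickness_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "", grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  pitch <- as.numeric(strsplit(trimws(get("pitch_mm")), "\\s+")[[1]])
  centre <- as.numeric(strsplit(trimws(get("centre_px")), "\\s+")[[1]])
  body <- lines[!grepl("^#", lines)]
  grid <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(l, ",")[[1]])))
  thickness_map(grid, pitch_mm = pitch, centre_px = centre,
                layer = get("layer"), eye = get("eye"))
}

#' Read a run configuration file
#'
#' YAML key-value configuration mirroring the cohort-design fields; the
#' `seed` key is mandatory.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config missing required key: seed")
  cfg
}
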