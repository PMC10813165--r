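# Longitudinal statistical layer: baseline normalisation, ROUT robust
# outlier detection, two-way repeated-measures ANOVA with separate error
# strata, Sidak-adjusted post hoc contrasts at specific times, and
# group mean +/- SEM summaries.

#' Normalise a longitudinal measure table to baseline
#'
#' Expresses every value as a percentage of the same subject's baseline
#' (t = 0) value of the same measure: `100 * value(t) / value(0)`.
#' Baseline rows become exactly 100. Subjects with a missing or zero
#' baseline are excluded with a warning.
#'
#' @param tab data.frame with columns `subject`, `time_min`, `value` and
#'   optionally `measure` (normalisation is per subject per measure).
#' @return The table with `value` replaced by the normalised percentage.
#' @examples
#' tab <- data.frame(subject = "a", time_min = c(0, 30), value = c(200, 250))
#' normalize_to_baseline(tab)$value
#' @export
normalize_to_baseline <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("subject", "time_min", "value") %in% names(tab)))
  if (!"measure" %in% names(tab)) {
    tab$measure <- "value"
    drop_measure <- TRUE
  } else drop_measure <- FALSE
  key <- interaction(tab$subject, tab$measure, drop = TRUE)
  keep <- rep(TRUE, nrow(tab))
  out_value <- tab$value
  for (k in levels(key)) {
    idx <- which(key == k)
    b <- tab$value[idx][tab$time_min[idx] == 0]
    if (length(b) != 1 || !is.finite(b) || b == 0) {
      warning(sprintf("subject '%s' (measure '%s'): missing or zero baseline; excluded",
                      tab$subject[idx[1]], tab$measure[idx[1]]))
      keep[idx] <- FALSE
    } else {
      # ratio first so baseline rows are exactly 100 in floating point
      out_value[idx] <- 100 * (tab$value[idx] / b)
    }
  }
  tab$value <- out_value
  tab <- tab[keep, , drop = FALSE]
  if (drop_measure) tab$measure <- NULL
  rownames(tab) <- NULL
  tab
}

#' ROUT robust outlier detection (constant model)
#'
#' Identifies outliers by the robust-fit + false-discovery-rate rule,
#' reduced to a location model: the robust centre is the median, the
#' robust scale (RSDR) is the 68.27th percentile of the absolute
#' residuals with the small-sample correction `N/(N - K)` (K = 1
#' parameter), each point receives a two-sided t p-value from
#' `|residual| / RSDR` (df = N - K), and points are flagged by a
#' Benjamini-Hochberg step-up at level `Q`.
#'
#' @param values Numeric vector, length >= 3.
#' @param Q Maximum desired false-discovery rate (default 0.01).
#' @return An object of class `rout_report`: `flagged` (indices into
#'   `values`), `Q`, `centre`, `rsdr`, `p` (per-point p-values).
#' @examples
#' rout_outliers(c(1, 2, 3, 4, 1000))$flagged
#' @export
rout_outliers <- function(values, Q = 0.01) {
  stopifnot(is.numeric(values), Q > 0, Q < 1)
  n <- length(values)
  if (n < 3) stop("ROUT needs at least 3 values")
  if (any(!is.finite(values))) stop("values must be finite")
  res <- values - stats::median(values)
  if (all(res == 0))
    return(structure(list(flagged = integer(0), Q = Q,
                          centre = stats::median(values), rsdr = 0,
                          p = rep(1, n)),
                     class = "rout_report"))
  rsdr <- stats::quantile(abs(res), 0.6827, names = FALSE) * n / (n - 1)
  if (rsdr == 0) {
    # majority of points identical: any deviating point is infinitely extreme
    flagged <- which(res != 0)
    p <- ifelse(res == 0, 1, 0)
  } else {
    tstat <- abs(res) / rsdr
    p <- 2 * stats::pt(tstat, df = n - 1, lower.tail = FALSE)
    ord <- order(p)
    thresh <- Q * seq_len(n) / n
    below <- p[ord] <= thresh
    k <- if (any(below)) max(which(below)) else 0L
    flagged <- if (k > 0) sort(ord[seq_len(k)]) else integer(0)
  }
  structure(list(flagged = flagged, Q = Q, centre = stats::median(values),
                 rsdr = rsdr, p = p),
            class = "rout_report")
}

#' @export
print.rout_report <- function(x, ...) {
  cat(sprintf("<rout_report> Q = %g, centre = %.4g, RSDR = %.4g, %d flagged\n",
              x$Q, x$centre, x$rsdr, length(x$flagged)))
  invisible(x)
}

#' Remove ROUT outliers from a measure table
#'
#' Applies [rout_outliers()] within each group x timepoint x measure
#' cell and drops the flagged rows.
#'
#' @param tab Measure table with columns `group` (or `genotype` +
#'   `treatment`), `time_min`, `measure`, `value`.
#' @param Q FDR level.
#' @return List with `table` (cleaned) and `removed` (flagged rows).
#' @export
remove_outliers <- function(tab, Q = 0.01) {
  stopifnot(is.data.frame(tab), all(c("time_min", "value") %in% names(tab)))
  if (!"group" %in% names(tab))
    tab$group <- paste(tab$genotype, tab$treatment, sep = "_")
  if (!"measure" %in% names(tab)) tab$measure <- "value"
  key <- interaction(tab$group, tab$time_min, tab$measure, drop = TRUE)
  drop <- logical(nrow(tab))
  for (k in levels(key)) {
    idx <- which(key == k)
    if (length(idx) >= 3) {
      rep <- rout_outliers(tab$value[idx], Q = Q)
      drop[idx[rep$flagged]] <- TRUE
    }
  }
  list(table = tab[!drop, , drop = FALSE], removed = tab[drop, , drop = FALSE])
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to [0, 1]. Identity at m = 1,
#' monotone increasing in both `p` and `m`.
#'
#' @param p Raw p-value(s) in [0, 1].
#' @param m Number of comparisons in the family, >= 1.
#' @return Adjusted p-value(s).
#' @examples
#' sidak_adjust(0.05, 2)
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1), is.numeric(m), m >= 1)
  pmin(pmax(1 - (1 - p)^m, 0), 1)
}

#' Two-way repeated-measures (mixed) ANOVA
#'
#' Classical two-stratum sum-of-squares decomposition for a design with
#' one between-subjects factor and one within-subjects (time) factor,
#' every retained subject observed at every timepoint. The between
#' effect is tested against subjects-within-groups MS; the time and
#' group x time interaction effects are tested against the
#' subject x time residual MS. Because every subject is observed at
#' every timepoint the decomposition is exactly orthogonal even with
#' unequal group sizes. Subjects missing any timepoint are listwise
#' deleted with a warning.
#'
#' @param tab data.frame in long format.
#' @param dv Name of the response column (default "value").
#' @param between Character vector of between-subject factor column(s);
#'   multiple columns are collapsed into their crossing.
#' @param subject Name of the subject id column.
#' @param within Name of the within-subject (time) column.
#' @return An object of class `erg_anova`: `table` (effect, df, SS, MS,
#'   F, p for between, time, interaction, subjects, residual), cell
#'   statistics and error-stratum MS for post hoc use.
#' @examples
#' tab <- simulate_null_measures(n_per_group = 5, seed = 2)
#' mixed_anova(tab, between = "group")
#' @export
mixed_anova <- function(tab, dv = "value", between = "group",
                        subject = "subject", within = "time_min") {
  stopifnot(is.data.frame(tab),
            all(c(dv, between, subject, within) %in% names(tab)))
  g <- if (length(between) > 1)
    interaction(tab[between], drop = TRUE, sep = "_") else factor(tab[[between]])
  s <- factor(tab[[subject]])
  tm <- factor(tab[[within]])
  y <- tab[[dv]]
  if (any(!is.finite(y))) {
    keep <- is.finite(y)
    tab <- tab[keep, , drop = FALSE]
    g <- droplevels(g[keep]); s <- droplevels(s[keep]); tm <- droplevels(tm[keep])
    y <- y[keep]
  }
  if (nlevels(g) < 2) stop("between factor needs at least 2 levels")
  if (nlevels(tm) < 2) stop("within factor needs at least 2 levels")
  if (any(table(s, tm) > 1)) stop("duplicate subject x time observations")

  n_t <- nlevels(tm)
  cnt <- table(s)
  incomplete <- names(cnt)[cnt < n_t]
  if (length(incomplete)) {
    warning(sprintf("%d subject(s) missing timepoints; listwise deleted: %s",
                    length(incomplete), paste(incomplete, collapse = ", ")))
    keep <- !(as.character(s) %in% incomplete)
    g <- droplevels(g[keep]); s <- droplevels(s[keep])
    tm <- droplevels(tm[keep]); y <- y[keep]
  }
  subj_group <- tapply(as.integer(g), s, function(v) v[1])
  n_g <- table(factor(levels(g)[subj_group], levels = levels(g)))
  if (any(n_g < 2)) stop("every group needs at least 2 complete subjects")
  n_s <- nlevels(s)
  N <- length(y)

  grand <- mean(y)
  m_subj <- tapply(y, s, mean)
  m_grp <- tapply(y, g, mean)
  m_time <- tapply(y, tm, mean)
  m_cell <- tapply(y, list(g, tm), mean)

  ss_total <- sum((y - grand)^2)
  ss_bs <- n_t * sum((m_subj - grand)^2)              # between-subjects stratum
  ss_group <- n_t * sum(as.numeric(n_g) * (m_grp - grand)^2)
  ss_subj <- ss_bs - ss_group                          # subjects within groups
  ss_within <- ss_total - ss_bs
  ss_time <- n_s * sum((m_time - grand)^2)
  dev_cell <- sweep(sweep(m_cell, 1, m_grp), 2, m_time) + grand
  ss_int <- sum(as.numeric(n_g) * rowSums(dev_cell^2))
  ss_res <- ss_within - ss_time - ss_int

  df_group <- nlevels(g) - 1
  df_subj <- n_s - nlevels(g)
  df_time <- n_t - 1
  df_int <- df_group * df_time
  df_res <- df_subj * df_time

  # numerical guards: orthogonality can leave tiny negative residual SS
  tol <- 1e-8 * max(1, ss_total)
  if (ss_res < -tol || ss_subj < -tol) stop("internal error: negative SS")
  ss_res <- max(ss_res, 0); ss_subj <- max(ss_subj, 0)
  stopifnot(abs(ss_group + ss_subj + ss_time + ss_int + ss_res - ss_total) <= 1e-6 * max(1, ss_total),
            df_group + df_subj + df_time + df_int + df_res == N - 1)

  ms <- c(ss_group, ss_subj, ss_time, ss_int, ss_res) /
    c(df_group, df_subj, df_time, df_int, df_res)
  # a zero numerator is a zero F even when the error MS is also zero
  # (e.g. exactly parallel profiles with no residual noise)
  fdiv <- function(num, den) if (num == 0) 0 else num / den
  f_group <- fdiv(ms[1], ms[2])
  f_time <- fdiv(ms[3], ms[5])
  f_int <- fdiv(ms[4], ms[5])
  p_group <- stats::pf(f_group, df_group, df_subj, lower.tail = FALSE)
  p_time <- stats::pf(f_time, df_time, df_res, lower.tail = FALSE)
  p_int <- stats::pf(f_int, df_int, df_res, lower.tail = FALSE)

  table <- data.frame(
    effect = c("between", "subjects_within_groups", "time", "interaction", "residual"),
    df = c(df_group, df_subj, df_time, df_int, df_res),
    SS = c(ss_group, ss_subj, ss_time, ss_int, ss_res),
    MS = ms[c(1, 2, 3, 5, 5)] * NA, # filled below to keep order explicit
    F = c(f_group, NA, f_time, f_int, NA),
    p = c(p_group, NA, p_time, p_int, NA),
    stringsAsFactors = FALSE)
  table$MS <- table$SS / table$df

  structure(list(table = table, dv = dv, between = between,
                 levels = levels(g), times = levels(tm),
                 n_per_group = as.numeric(n_g), n_subjects = n_s,
                 n_times = n_t, cell_means = m_cell,
                 ms_subj = ms[2], df_subj = df_subj,
                 ms_res = ms[5], df_res = df_res,
                 grand_mean = grand),
            class = "erg_anova")
}

#' @export
print.erg_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA: %s ~ %s x %s\n", x$dv,
              paste(x$between, collapse = ":"), "time"))
  tb <- x$table
  tb$SS <- signif(tb$SS, 6); tb$MS <- signif(tb$MS, 6)
  tb$F <- signif(tb$F, 5); tb$p <- signif(tb$p, 4)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Pairwise group contrasts at each timepoint with Sidak correction
#'
#' Compares between-subject groups at each level of the within factor
#' using the pooled error appropriate to a mixed design,
#' `(MS_subjects + (T - 1) MS_residual) / T`, with Satterthwaite degrees
#' of freedom, then applies the Sidak adjustment with `m` equal to the
#' family size (all requested contrast x time combinations by default).
#'
#' @param fit An `erg_anova` from [mixed_anova()].
#' @param contrasts List of length-2 character vectors naming group
#'   levels to compare; NULL means all pairwise contrasts.
#' @param m Family size for the Sidak adjustment; default is the number
#'   of rows returned.
#' @return data.frame: contrast, time, estimate, se, df, t, raw_p,
#'   sidak_p.
#' @export
posthoc_by_time <- function(fit, contrasts = NULL, m = NULL) {
  stopifnot(inherits(fit, "erg_anova"))
  lev <- fit$levels
  if (is.null(contrasts)) {
    pairs <- utils::combn(lev, 2, simplify = FALSE)
  } else {
    pairs <- contrasts
    for (pr in pairs)
      if (!all(pr %in% lev))
        stop("undefined contrast label(s): ", paste(setdiff(pr, lev), collapse = ", "))
  }
  T_ <- fit$n_times
  ms_comb <- (fit$ms_subj + (T_ - 1) * fit$ms_res) / T_
  # Satterthwaite df of the combined mean square
  a <- fit$ms_subj / T_
  b <- (T_ - 1) * fit$ms_res / T_
  df_comb <- (a + b)^2 / (a^2 / fit$df_subj + if (b > 0) b^2 / fit$df_res else 0)
  n_by <- stats::setNames(fit$n_per_group, lev)
  rows <- list()
  for (pr in pairs) {
    i1 <- match(pr[1], lev); i2 <- match(pr[2], lev)
    se <- sqrt(ms_comb * (1 / n_by[[pr[1]]] + 1 / n_by[[pr[2]]]))
    for (j in seq_along(fit$times)) {
      est <- fit$cell_means[i1, j] - fit$cell_means[i2, j]
      tstat <- est / se
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = paste(pr[1], "-", pr[2]), time = fit$times[j],
        estimate = est, se = se, df = df_comb, t = tstat,
        raw_p = 2 * stats::pt(abs(tstat), df_comb, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(m)) m <- nrow(out)
  out$sidak_p <- sidak_adjust(out$raw_p, m)
  out
}

#' Group mean and SEM per timepoint
#'
#' @param tab Measure table.
#' @param dv Response column.
#' @param groups Grouping column(s) (default `group`).
#' @param within Time column.
#' @return data.frame with n, mean, sd, sem per cell; cells with a
#'   single subject carry `sem = NA` and `flag = "single_subject"`.
#' @export
summarize_groups <- function(tab, dv = "value", groups = "group",
                             within = "time_min") {
  stopifnot(is.data.frame(tab), all(c(dv, groups, within) %in% names(tab)))
  key <- interaction(c(tab[groups], tab[within]), drop = TRUE, sep = "\r")
  parts <- do.call(rbind, strsplit(as.character(levels(key)), "\r", fixed = TRUE))
  out <- data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- c(groups, within)
  out$n <- as.integer(tapply(tab[[dv]], key, length))
  out$mean <- as.numeric(tapply(tab[[dv]], key, mean))
  out$sd <- as.numeric(tapply(tab[[dv]], key, stats::sd))
  out$sem <- out$sd / sqrt(out$n)
  out$flag <- ifelse(out$n < 2, "single_subject", "")
  out$sem[out$n < 2] <- NA_real_
  numeric_within <- suppressWarnings(as.numeric(out[[within]]))
  if (!any(is.na(numeric_within))) out[[within]] <- numeric_within
  out <- out[do.call(order, out[c(groups, within)]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
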