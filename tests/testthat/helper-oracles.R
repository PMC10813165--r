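# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Brute-force per-pixel ETDRS quadrant means: double loop, no vectorised
# sharing with the implementation.
brute_force_quadrants <- function(m, ring = c(1, 3, 6)) {
  g <- m$grid
  sums <- counts <- stats::setNames(numeric(4),
                                    c("superior", "inferior", "nasal", "temporal"))
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(ncol(g))) {
      x <- (j - m$centre_px[2]) * m$pitch_mm[1]
      y <- (m$centre_px[1] - i) * m$pitch_mm[2]
      r <- sqrt(x^2 + y^2)
      if (r >= ring[2] / 2 && r < ring[3] / 2 && !is.na(g[i, j])) {
        a <- atan2(y, x) * 180 / pi
        q <- if (a >= 45 && a < 135) "superior"
        else if (a >= -135 && a < -45) "inferior"
        else if (a >= -45 && a < 45) {
          if (m$eye == "OD") "temporal" else "nasal"
        } else {
          if (m$eye == "OD") "nasal" else "temporal"
        }
        sums[q] <- sums[q] + g[i, j]
        counts[q] <- counts[q] + 1
      }
    }
  }
  list(means = sums / counts, counts = counts)
}

# Exhaustive coarse grid search for the P3 least-squares problem, on the
# exact objective the fit minimised (baseline-referenced samples over the
# fit window).
p3_grid_oracle_sse <- function(w, fit,
                               rm_grid = seq(50, 1200, by = 25),
                               s_grid = exp(seq(log(20), log(5000), length.out = 18)),
                               td_grid = seq(0.001, 0.012, by = 0.0005)) {
  t <- erg_times(w)
  y <- w$samples_uV - fit$baseline_uV
  win <- t >= fit$fit_window_s[1] & t <= fit$fit_window_s[2]
  tw <- t[win]; yw <- y[win]
  E <- 10^fit$flash_energy_log
  best <- Inf
  for (S in s_grid) for (td in td_grid) {
    d <- tw - td
    b <- ifelse(d > 0, 1 - exp(-E * S * d^2), 0)
    sse <- colSums((yw + outer(b, rm_grid))^2)
    best <- min(best, min(sse))
  }
  best
}

# The printed 8-value toy table: two groups of two subjects, two
# timepoints, parallel profiles.
toy_anova_table <- function() {
  data.frame(
    subject = rep(c("A", "B", "C", "D"), each = 2),
    group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    time_min = rep(c(0, 30), 4),
    value = c(10, 12, 14, 16, 20, 22, 24, 26))
}

# Measured amplitude of a steady sinusoid after filtering (grid-aligned
# frequency, interior samples to avoid any edge effects).
sine_gain <- function(filter_fun, freq_hz, fs = 4000,
                      n = if ((freq_hz * 4096 / fs) %% 1 == 0) 4096 else 4000) {
  stopifnot((freq_hz * n / fs) %% 1 == 0)  # exact DFT bin
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * freq_hz * t)
  y <- filter_fun(x)
  max(abs(y)) / max(abs(x))
}
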