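test_that("a uniform map yields the same mean in every quadrant", {
  m <- thickness_map(matrix(220, 81, 81), pitch_mm = 0.1)
  s <- etdrs_quadrant_means(m)
  expect_equal(unname(s$quadrant_means_um), rep(220, 4))
  expect_equal(s$combined_mean_um, 220)
  expect_equal(unname(s$coverage), rep(1, 4))
  expect_false(s$low_coverage)
})

test_that("quadrant labels follow the 45-degree diagonals and eye side", {
  # value 10 strictly above the horizontal midline, 20 below
  g <- matrix(20, 81, 81)
  g[1:40, ] <- 10            # rows above the centre row = superior half
  m <- thickness_map(g, pitch_mm = 0.1)
  s <- etdrs_quadrant_means(m)
  expect_equal(unname(s$quadrant_means_um["superior"]), 10)
  expect_equal(unname(s$quadrant_means_um["inferior"]), 20)
  # left/right split: value 5 on the left half, 25 on the right
  g2 <- matrix(25, 81, 81)
  g2[, 1:40] <- 5
  od <- etdrs_quadrant_means(thickness_map(g2, pitch_mm = 0.1, eye = "OD"))
  os <- etdrs_quadrant_means(thickness_map(g2, pitch_mm = 0.1, eye = "OS"))
  expect_equal(unname(od$quadrant_means_um["temporal"]), 25)
  expect_equal(unname(od$quadrant_means_um["nasal"]), 5)
  expect_equal(unname(os$quadrant_means_um["nasal"]), 25)
  expect_equal(unname(os$quadrant_means_um["temporal"]), 5)
})

test_that("quadrant means equal the brute-force per-pixel oracle", {
  for (s in 1:5) {
    m <- simulate_thickness_map(seed = s)
    got <- etdrs_quadrant_means(m)
    oracle <- brute_force_quadrants(m)
    expect_equal(got$quadrant_means_um, oracle$means, tolerance = 1e-12)
    expect_equal(got$n_pixels, oracle$counts)
    # combined mean is the pixel-count-weighted quadrant mean
    expect_equal(got$combined_mean_um,
                 sum(oracle$means * oracle$counts) / sum(oracle$counts),
                 tolerance = 1e-12)
  }
})

test_that("missing pixels are excluded and tracked by coverage", {
  m <- simulate_thickness_map(seed = 7)
  m$grid[1:40, 41:81] <- NA   # knock out most of the superior-right area
  got <- etdrs_quadrant_means(m)
  oracle <- brute_force_quadrants(m)
  expect_equal(got$quadrant_means_um, oracle$means, tolerance = 1e-12)
  expect_lt(got$coverage[["superior"]], 1)
  expect_true(got$low_coverage)
})

test_that("rotating the map permutes quadrant means and preserves the combined mean", {
  m <- simulate_thickness_map(seed = 9)   # odd size: exact centre pixel
  s0 <- etdrs_quadrant_means(m)
  rot <- m
  rot$grid <- t(m$grid)[ncol(m$grid):1, ]   # rigid 90-degree rotation
  s1 <- etdrs_quadrant_means(rot)
  expect_equal(sort(unname(s1$quadrant_means_um)),
               sort(unname(s0$quadrant_means_um)), tolerance = 1e-12)
  expect_equal(s1$combined_mean_um, s0$combined_mean_um, tolerance = 1e-12)
})

test_that("scaling pitch and ring diameters together changes nothing", {
  m <- simulate_thickness_map(seed = 10)
  s0 <- etdrs_quadrant_means(m, ring_mm = c(1, 3, 6))
  k <- 0.37
  ms <- m; ms$pitch_mm <- m$pitch_mm * k
  s1 <- etdrs_quadrant_means(ms, ring_mm = c(1, 3, 6) * k)
  expect_equal(s1$quadrant_means_um, s0$quadrant_means_um)
  expect_equal(s1$n_pixels, s0$n_pixels)
})

test_that("a ring outside the map is rejected", {
  m <- thickness_map(matrix(200, 11, 11), pitch_mm = 0.01)  # 0.11 mm map
  expect_error(etdrs_quadrant_means(m), "does not intersect")
})

test_that("oct_measure_table assembles rows and rejects duplicates", {
  maps <- lapply(1:4, function(i) simulate_thickness_map(seed = i, layer = "ONL"))
  meta <- data.frame(subject = c("m1", "m1", "m2", "m2"),
                     genotype = c("WT", "WT", "HOM", "HOM"),
                     treatment = "VEH", time_min = c(0, 30, 0, 30))
  tab <- oct_measure_table(maps, meta)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$measure, rep("ONL", 4))
  expect_equal(tab$value[1],
               etdrs_quadrant_means(maps[[1]])$combined_mean_um)
  meta_bad <- meta; meta_bad$time_min <- 0
  expect_error(oct_measure_table(maps, meta_bad), "duplicate")
  # pre-sectored route
  meta$layer <- "ONL"
  tab2 <- oct_measure_table(metadata = meta, values_um = c(60, 58, 55, 54))
  expect_equal(tab2$value, c(60, 58, 55, 54))
  expect_error(oct_measure_table(metadata = meta[0, ], values_um = numeric(0)))
})
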