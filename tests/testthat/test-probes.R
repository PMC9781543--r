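test_that("SRS site counts are unbiased for the contour area", {
  rect <- rbind(c(0, 0), c(4000, 0), c(4000, 2000), c(0, 2000))
  # expected sites = area / grid cell = 2
  n <- vapply(1:1000, function(s) {
    nrow(place_srs_grid(rect, c(2000, 2000), seed = s))
  }, numeric(1))
  expect_lt(abs(mean(n) - 2) / 2, 0.05)

  # determinism and degenerate input
  expect_identical(place_srs_grid(rect, c(500, 500), seed = 3),
                   place_srs_grid(rect, c(500, 500), seed = 3))
  expect_equal(nrow(place_srs_grid(rect[1:2, ], c(500, 500), seed = 1)), 0)

  # a polygon smaller than one grid cell holds at most one site
  small <- rbind(c(0, 0), c(300, 0), c(300, 200), c(0, 200))
  counts <- vapply(1:200, function(s) {
    nrow(place_srs_grid(small, c(2000, 2000), seed = s))
  }, numeric(1))
  expect_true(all(counts <= 1))
})

test_that("the counting frame is half-open on all three axes", {
  frame <- c(100, 100); zw <- c(1, 19)
  # exclusion boundaries: left/bottom edges and the top of the z window
  on_exclusion <- rbind(c(0, 50, 10), c(50, 0, 10), c(100, 50, 10),
                        c(50, 100, 10), c(50, 50, 19), c(50, 50, 0.5))
  expect_equal(count_in_frame(on_exclusion[1:2, , drop = FALSE], c(0, 0), frame, zw), 2)
  expect_equal(count_in_frame(on_exclusion[3:6, , drop = FALSE], c(0, 0), frame, zw), 0)
  # interior point counts
  expect_equal(count_in_frame(rbind(c(50, 50, 10)), c(0, 0), frame, zw), 1)
})

test_that("tiling a section with frames is an exact census", {
  set.seed(41)
  pts <- data.frame(x_um = runif(1e4, 0, 1000), y_um = runif(1e4, 0, 1000),
                    z_um = runif(1e4, 0, 20))
  total <- 0
  for (x0 in seq(0, 900, by = 100)) {
    for (y0 in seq(0, 900, by = 100)) {
      q <- count_in_frame(pts, c(x0, y0), c(100, 100), c(0, 20))
      # direct enumeration oracle for this tile
      expect_equal(q, sum(pts$x_um >= x0 & pts$x_um < x0 + 100 &
                            pts$y_um >= y0 & pts$y_um < y0 + 100))
      total <- total + q
    }
  }
  expect_equal(total, 1e4)
})

test_that("Cavalieri point counts are unbiased and converge to the shoelace area", {
  sq <- rbind(c(0, 0), c(2000, 0), c(2000, 2000), c(0, 2000))
  p <- vapply(1:1000, function(s) {
    point_count_section(sq, 1000, seed = s)
  }, numeric(1))
  expect_lt(abs(mean(p) - 4) / 4, 0.05)

  # irregular polygon, fine grid: P x spacing^2 within 0.5% of shoelace area
  set.seed(12)
  th <- sort(runif(12, 0, 2 * pi))
  poly <- cbind(3000 * cos(th) * runif(12, 0.6, 1), 2200 * sin(th) * runif(12, 0.6, 1))
  spacing <- (max(poly[, 1]) - min(poly[, 1])) / 100
  p1 <- point_count_section(poly, spacing, seed = 5)
  expect_lt(abs(p1 * spacing^2 - polygon_area(poly)) / polygon_area(poly), 0.005)

  expect_equal(point_count_section(poly[1:2, ], 100, seed = 1), 0)
})

test_that("sphere-surface crossing counts match the quadratic-root oracle", {
  r <- 18; ctr <- c(0, 0, 10); slab <- c(1, 19)
  # diameter chord through the center, surface fully inside the slab: 2
  expect_equal(intersect_fiber_sphere(c(-30, 0, 10), c(30, 0, 10), ctr, 9, slab), 2L)
  # segment entirely inside the sphere: 0
  expect_equal(intersect_fiber_sphere(c(-3, 0, 10), c(3, 0, 10), ctr, r, slab), 0L)
  # tangent line: 0
  expect_equal(intersect_fiber_sphere(c(-30, 18, 10), c(30, 18, 10), ctr, r, NULL), 0L)

  # Monte-Carlo agreement with an independent per-segment oracle
  set.seed(77)
  n <- 1e4
  p1 <- cbind(runif(n, -40, 40), runif(n, -40, 40), runif(n, -20, 40))
  p2 <- p1 + cbind(rnorm(n, 0, 25), rnorm(n, 0, 25), rnorm(n, 0, 25))
  fast <- intersect_fiber_sphere(p1, p2, ctr, r, slab)
  slow <- vapply(seq_len(n), function(i) {
    oracle_sphere_crossings(p1[i, ], p2[i, ], ctr, r, slab)
  }, integer(1))
  expect_identical(fast, as.integer(slow))
  expect_gt(sum(fast), 0)
})

test_that("a design with all sampling fractions 1 returns the exact census", {
  reg <- sphere_region(300)
  pts <- simulate_neuron_field(reg, 2e5, seed = 14)
  st <- section_stack(reg, points = pts, cut_thickness_um = 50)
  cnt <- run_probe(st, census_design(), probe = "fractionator", seed = 1)
  expect_equal(sum(cnt$tally), nrow(pts))
  # and the fractionator estimate is then the count itself
  est <- optical_fractionator(cnt, census_design())
  expect_equal(est$value, nrow(pts))
})

test_that("probe tallying equals per-site counting frames over the grid translates", {
  reg <- sphere_region(300)
  pts <- simulate_neuron_field(reg, 1e5, seed = 21)
  des <- sampling_design(2, cut_thickness_um = 50, mounted_thickness_um = 20,
                         grid_um = c(200, 200), frame_um = c(120, 120))
  st <- section_stack(reg, points = pts, cut_thickness_um = 50,
                      shrinkage = shrinkage_model(1, 0.4, 0))
  cnt <- run_probe(st, des, probe = "fractionator", seed = 8, section_offset = 0)
  # recompute one sampled section by looping counting frames explicitly
  s <- cnt$section_index[3]
  p <- st$points[st$points$section_index == s, ]
  # the grid offset used for section s is reproducible from the seed
  set.seed(8)
  offs <- lapply(seq_along(cnt$section_index), function(i) runif(2, 0, 200))
  off <- offs[[3]]
  q <- 0
  for (gx in seq(off[1] - 400, 300, by = 200)) {
    for (gy in seq(off[2] - 400, 300, by = 200)) {
      q <- q + count_in_frame(p, c(gx, gy), c(120, 120), c(1, 19))
    }
  }
  expect_equal(cnt$tally[3], q)
})

test_that("the optical fractionator is unbiased for a known Poisson population", {
  reg <- sphere_region(400)
  density <- 2e4
  n_true <- density * um3_to_mm3(reg$true_volume_um3)
  des <- sampling_design(2, cut_thickness_um = 50, mounted_thickness_um = 20,
                         grid_um = c(200, 200), frame_um = c(100, 100))
  shr <- shrinkage_model(1, 0.4, 0)
  est <- vapply(1:200, function(s) {
    pts <- simulate_neuron_field(reg, density, seed = s)
    st <- section_stack(reg, points = pts, cut_thickness_um = 50, shrinkage = shr)
    optical_fractionator(
      run_probe(st, des, probe = "fractionator", seed = s + 4000), des
    )$value
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - n_true), 3 * se)
  expect_lt(abs(mean(est) - n_true) / n_true, 0.01)
})

test_that("probe runners validate their inputs", {
  reg <- sphere_region(300)
  st <- section_stack(reg, cut_thickness_um = 50)
  expect_error(run_probe(st, ic_design(), probe = "fractionator", seed = 1),
               class = "stereofract_error_bad_design")  # mounted 20 vs stack 50
})
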