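test_that("Gundersen-Jensen CE reproduces the hand-computed cases", {
  # A = 400, B = 300, C = 200 -> sqrt(200/240)/40
  expect_equal(gundersen_ce(c(10, 10, 10, 10)), sqrt(200 / 240) / 40)
  expect_equal(round(gundersen_ce(c(10, 10, 10, 10)), 4), 0.0228)
  # single section: sqrt(3/240), independent of the count
  expect_equal(gundersen_ce(17), sqrt(3 / 240))
  expect_equal(gundersen_ce(400), sqrt(3 / 240))
  # nugget variant: sqrt(80/240 + 40)/40
  expect_equal(gundersen_ce(c(10, 10, 10, 10), nugget = TRUE),
               sqrt(80 / 240 + 40) / 40)
  expect_equal(round(gundersen_ce(c(10, 10, 10, 10), nugget = TRUE), 4), 0.1588)
  # m = 0 uses divisor 12
  expect_equal(gundersen_ce(c(10, 10, 10, 10), smoothness_m = 0),
               sqrt(200 / 12) / 40)
  expect_error(gundersen_ce(c(0, 0, 0)), class = "stereofract_error_zero_total")
  expect_error(gundersen_ce(numeric(0)), class = "stereofract_error_bad_counts")
})

test_that("Cavalieri arithmetic matches the worked example", {
  # d = 1500 um, a(p) = 4e6 um^2, sum P = 227 -> 1362 mm^3
  counts <- c(20, 35, 42, 45, 40, 30, 15)  # sums to 227
  expect_equal(sum(counts), 227)
  est <- cavalieri_volume(counts, 1500, 4e6)
  expect_equal(um3_to_mm3(est$value), 1362)
  expect_equal(prod(est$components), est$value)

  # d = 1000 um, a(p) = 1e6 um^2, one point -> 1 mm^3
  expect_equal(um3_to_mm3(cavalieri_volume(1, 1000, 1e6)$value), 1)

  z <- cavalieri_volume(c(0, 0), 1000, 1e6)
  expect_equal(z$value, 0)
  expect_true(is.na(z$ce))
  expect_error(cavalieri_volume(numeric(0), 1000, 1e6),
               class = "stereofract_error_bad_counts")
})

test_that("fractionator scaling reproduces the dolphin IC worked example", {
  des <- ic_design()
  # 1/ssf = 30, 1/asf = 2000^2/150^2, 1/tsf = 20/18
  expect_equal(1 / des$ssf, 30)
  expect_equal(1 / des$asf, 2000^2 / 150^2)
  expect_equal(1 / des$tsf, 20 / 18)
  est <- optical_fractionator(rep(818 / 14, 14), des)
  expect_equal(est$value, 818 * 30 * (2000^2 / 150^2) * (20 / 18))
  expect_equal(round(est$value / 1e6, 2), 4.85)
  expect_equal(prod(est$components), est$value)

  z <- optical_fractionator(rep(0, 5), des)
  expect_equal(z$value, 0)
  expect_true(is.na(z$ce))
})

test_that("Spaceballs closed-form density and length follow from the zone area", {
  des <- sampling_design(30, mounted_thickness_um = 50, grid_um = c(2000, 2000))
  # r = 18, h = 18: S = 2 pi 18 18 = 2035.75; one site, I = 2
  S <- 2 * pi * 18 * 18
  est <- spaceballs_length(2, des, n_sites = 1, reference_volume_um3 = 1e9)
  lv_um2 <- est$value / 1e9
  expect_equal(lv_um2, 4 / S)
  expect_equal(round(lv_um2_to_m_per_mm3(lv_um2), 3), 1.965)
  expect_equal(prod(est$components), est$value)

  # expected crossings per site at the dolphin CN length density: Lv S / 2
  expect_equal(round((1.69 / 1e3) * S / 2, 2), 1.72)

  expect_equal(spaceballs_length(0, des, n_sites = 10, reference_volume_um3 = 1e9)$value, 0)
  expect_error(spaceballs_length(2, des, n_sites = 0, reference_volume_um3 = 1e9),
               class = "stereofract_error_bad_design")
})

test_that("Spaceballs recovers an isotropic length density within 2%", {
  reg <- sphere_region(600)
  lv <- 4  # m/mm^3
  des <- sampling_design(2, cut_thickness_um = 50, mounted_thickness_um = 50,
                         grid_um = c(300, 300))
  v_ref <- reg$true_volume_um3
  # fibers generated in a 40 um dilated clip region: the structure sits in
  # continuous fiber-bearing tissue, so boundary spheres see a stationary field
  est <- vapply(1:50, function(s) {
    fib <- simulate_fiber_field(reg, lv, 100, seed = s, dilate_um = 40)
    st <- section_stack(reg, fibers = fib, cut_thickness_um = 50)
    cnt <- run_probe(st, des, probe = "spaceballs", seed = s + 9000)
    spaceballs_length(cnt, des, reference_volume_um3 = v_ref)$value
  }, numeric(1))
  truth <- (lv / 1e3) * v_ref
  expect_lt(abs(mean(est) - truth) / truth, 0.02)
})

test_that("fibers aligned with the cutting axis bias the Spaceballs estimate", {
  # vertical lines only cross the spherical zone over a thin annulus, so
  # the isotropic estimator must understate a fully z-aligned field
  reg <- sphere_region(600)
  lv_um2 <- 4 / 1e3
  set.seed(33)
  # vertical chords through uniform (x, y): length density Lv needs
  # n = Lv * pi R^2 / (mean chord length) ... simpler: fix n and measure truth
  n <- 3000
  xy <- matrix(runif(2 * n, -600, 600), ncol = 2)
  keep <- rowSums(xy^2) < 600^2
  xy <- xy[keep, ]
  half <- sqrt(600^2 - rowSums(xy^2))
  fib <- data.frame(
    x1_um = xy[, 1], y1_um = xy[, 2], z1_um = -half,
    x2_um = xy[, 1], y2_um = xy[, 2], z2_um = half,
    length_um = 2 * half
  )
  truth <- sum(fib$length_um)
  des <- sampling_design(2, cut_thickness_um = 50, mounted_thickness_um = 50,
                         grid_um = c(300, 300))
  st <- section_stack(reg, fibers = fib, cut_thickness_um = 50)
  est <- mean(vapply(1:20, function(s) {
    cnt <- run_probe(st, des, probe = "spaceballs", seed = s)
    spaceballs_length(cnt, des, reference_volume_um3 = reg$true_volume_um3)$value
  }, numeric(1)))
  bias <- est / truth - 1
  expect_lt(bias, -0.05)  # documented anisotropy bias, about -50% here
})
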