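test_that("Poisson fields have the requested intensity and are seed-deterministic", {
  reg <- sphere_region((3 / (4 * pi) * 1e9)^(1 / 3))  # exactly 1 mm^3

  expect_equal(nrow(simulate_neuron_field(reg, 0, seed = 1)), 0)
  expect_error(simulate_neuron_field(reg, -1, seed = 1),
               class = "stereofract_error_bad_density")

  # mean count over 100 seeds within 3 * sqrt(lambda V / 100) of lambda V
  lambda_v <- 500
  counts <- vapply(1:100, function(s) {
    nrow(simulate_neuron_field(reg, lambda_v, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - lambda_v), 3 * sqrt(lambda_v / 100))

  expect_identical(simulate_neuron_field(reg, 1000, seed = 7),
                   simulate_neuron_field(reg, 1000, seed = 7))
})

test_that("compartment labels follow the Bernoulli mixture", {
  reg <- sphere_region((3 / (4 * pi) * 1e9)^(1 / 3))
  probs <- c(nuclear = 0.71, cytoplasmic = 0.009, both = 0.14, none = 0.141)
  pts <- simulate_neuron_field(reg, 1.2e5, probs, seed = 3)
  n <- nrow(pts)
  expect_gt(n, 1e5)
  frac <- mean(pts$compartment == "nuclear")
  expect_lt(abs(frac - 0.71), 3 * sqrt(0.71 * 0.29 / n))

  expect_error(
    simulate_neuron_field(reg, 10, c(nuclear = 0.5, none = 0.6), seed = 1),
    class = "stereofract_error_bad_probs"
  )
  expect_error(
    simulate_neuron_field(reg, 10, c(nucleolar = 1), seed = 1),
    class = "stereofract_error_bad_enum"
  )
})

test_that("glial fields are cytoplasmic-only at the requested density", {
  reg <- sphere_region((3 / (2 * pi) * 1e9)^(1 / 3))  # 2 mm^3
  # astrocyte density reported for the dolphin central nucleus
  lambda_v <- 526510 * 2
  counts <- vapply(1:3, function(s) {
    g <- simulate_glia_field(reg, 526510, "astrocyte", seed = s)
    expect_true(all(g$compartment == "cytoplasmic"))
    expect_true(all(g$cell_class == "astrocyte"))
    nrow(g)
  }, numeric(1))
  expect_lt(abs(mean(counts) - lambda_v), 3 * sqrt(lambda_v / 3))
  expect_equal(nrow(simulate_glia_field(reg, 0, "microglia", seed = 1)), 0)
})

test_that("fiber fields are isotropic with the requested length density", {
  reg <- sphere_region((3 / (4 * pi) * 1e8)^(1 / 3) * 10)  # 100 mm^3 sphere
  expect_equal(nrow(simulate_fiber_field(reg, 0, 100, seed = 1)), 0)
  expect_error(simulate_fiber_field(reg, -1, 100, seed = 1),
               class = "stereofract_error_bad_density")
  expect_error(simulate_fiber_field(reg, 1, 0, seed = 1),
               class = "stereofract_error_bad_length")

  fib <- simulate_fiber_field(reg, 1.69, segment_length_um = 500, seed = 11)
  # total in-region length ~ 169 m within 2%
  expect_lt(abs(um_to_m(sum(fib$length_um)) - 169) / 169, 0.02)

  # isotropy: |cos theta| of the orientation vs z averages 0.5, and
  # cos theta is uniform on [-1, 1] (Kolmogorov-Smirnov at alpha 0.01)
  dz <- (fib$z2_um - fib$z1_um)
  dl <- sqrt((fib$x2_um - fib$x1_um)^2 + (fib$y2_um - fib$y1_um)^2 + dz^2)
  u <- (dz / dl)[seq_len(min(2e4, nrow(fib)))]
  expect_lt(abs(mean(abs(u)) - 0.5), 3 * sqrt(1 / 12) / sqrt(length(u)))
  # clipped boundary segments keep their original orientation, so the full
  # set is KS-testable
  expect_gt(stats::ks.test(u, "punif", -1, 1)$p.value, 0.01)

  expect_identical(simulate_fiber_field(reg, 0.1, 200, seed = 5),
                   simulate_fiber_field(reg, 0.1, 200, seed = 5))
})

test_that("z-window fiber generation marginalises the full-region process", {
  reg <- sphere_region(600)
  full <- simulate_fiber_field(reg, 3, 100, seed = 2)
  # expected in-window length density matches the full process
  win <- c(-100, 100)
  sub <- simulate_fiber_field(reg, 3, 100, seed = 2, z_window = win)
  len_in_window <- function(f) {
    # crude: midpoints z inside window
    zm <- (f$z1_um + f$z2_um) / 2
    sum(f$length_um[zm >= win[1] & zm < win[2]])
  }
  # both draws estimate the same expected quantity; agree within 3 x a
  # generous Poisson-scale tolerance
  lf <- len_in_window(full); ls <- len_in_window(sub)
  expect_lt(abs(lf - ls) / max(lf, ls), 0.10)
})
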