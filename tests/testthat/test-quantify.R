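test_that("densities and totals satisfy the identity density x volume = total", {
  expect_equal(number_density(0, 10), 0)
  # dolphin CN: 2299.47 m over the 1362 mm^3 Cavalieri volume -> 1.69 m/mm^3
  expect_equal(round_half_up(number_density(2299.47, 1362), 2), 1.69)
  # VCN: 316,380 neurons over 129 mm^3 -> 2452.6 per mm^3
  expect_equal(round_half_up(number_density(316380, 129), 1), 2452.6)
  expect_error(number_density(1, 0), class = "stereofract_error_bad_volume")

  for (tot in c(10, 4.85e6, 0.3)) {
    for (v in c(0.5, 129, 1362)) {
      expect_equal(number_density(tot, v) * v, tot)
    }
  }
  rep_ <- subnucleus_report("CN", total = 4.85e6, volume_mm3 = 1362)
  expect_equal(rep_$density_per_mm3 * rep_$volume_mm3, rep_$total)
})

test_that("probe totals combine into mean and sample SD", {
  out <- combine_probe_totals(c(5, 5, 5))
  expect_equal(out$mean, 5)
  expect_equal(out$sd, 0)
  expect_error(combine_probe_totals(numeric(0)), class = "stereofract_error_bad_counts")

  # three independent synthetic fractionator runs agree with the truth
  reg <- sphere_region(400)
  des <- sampling_design(2, cut_thickness_um = 50, mounted_thickness_um = 20,
                         grid_um = c(200, 200), frame_um = c(100, 100))
  shr <- shrinkage_model(1, 0.4, 0)
  n_true <- 2e4 * um3_to_mm3(reg$true_volume_um3)
  ests <- lapply(1:3, function(s) {
    pts <- simulate_neuron_field(reg, 2e4, seed = s + 100)
    st <- section_stack(reg, points = pts, cut_thickness_um = 50, shrinkage = shr)
    optical_fractionator(run_probe(st, des, probe = "fractionator", seed = s), des)
  })
  out <- combine_probe_totals(ests)
  expect_lt(abs(out$mean - n_true), 2 * out$sd / sqrt(out$n) + 0.05 * n_true)
})

test_that("immunoreactivity profiles are empirical fractions summing to one", {
  expect_equal(ir_profile(rep("nuclear", 10))$fractions,
               c(nuclear = 1, cytoplasmic = 0, both = 0, none = 0))
  # counts 23 / 0 / 14 / 63 -> fractions 0.23, 0, 0.14, 0.63
  labels <- rep(c("nuclear", "both", "none"), c(23, 14, 63))
  pr <- ir_profile(labels)
  expect_equal(unname(pr$fractions),  c(0.23, 0, 0.14, 0.63))
  expect_equal(sum(pr$fractions), 1)
  expect_equal(pr$n_counted, 100)
  expect_error(ir_profile(character(0)), class = "stereofract_error_bad_counts")
  expect_error(ir_profile("nucleolar"), class = "stereofract_error_bad_enum")

  # Bernoulli labels at the CN amyloid-beta mix recover 71% nuclear
  reg <- sphere_region(500)
  pts <- simulate_neuron_field(
    reg, 2e5, c(nuclear = 0.71, cytoplasmic = 0.009, both = 0.14, none = 0.141),
    seed = 19
  )
  pr <- ir_profile(pts)
  expect_lt(abs(pr$fractions[["nuclear"]] - 0.71),
            3 * sqrt(0.71 * 0.29 / pr$n_counted))
})

test_that("weighted and mean percentages reproduce the printed summaries", {
  # fibronectin: 37% of 4.85 M CN neurons, 30% of 1.28 M EC neurons -> 36%
  expect_equal(weighted_fraction(c(37, 30), c(4.85e6, 1.28e6)), 36)
  expect_equal(weighted_fraction(c(37, 30), c(4.85e6, 1.28e6), round = FALSE),
               (37 * 4.85 + 30 * 1.28) / 6.13)
  expect_equal(weighted_fraction(c(42, 42), c(1, 99)), 42)
  expect_error(weighted_fraction(c(1, 2), 1), class = "stereofract_error_bad_counts")

  # TDP-43 combined percentages: means of the three subnuclei
  expect_equal(mean_fraction(c(67, 53, 55)), 58)
  expect_equal(mean_fraction(c(17, 26, 19)), 21)
  expect_equal(mean_fraction(c(8, 8, 8)), 8)
  expect_error(mean_fraction(numeric(0)), class = "stereofract_error_bad_counts")

  # equal weights reduce the weighted form to the unweighted mean
  set.seed(2)
  for (i in 1:20) {
    f <- runif(4, 0, 100)
    expect_equal(weighted_fraction(f, rep(3, 4), round = FALSE),
                 mean_fraction(f, round = FALSE))
    w <- runif(4, 0.1, 10)
    expect_equal(weighted_fraction(f, w, round = FALSE), sum(f * w) / sum(w))
  }
})

test_that("shrinkage ratios reproduce the Cavalieri/MRI percentages", {
  expect_equal(shrinkage_ratio(1362, 1775), 77)
  expect_equal(shrinkage_ratio(129, 435), 30)
  expect_equal(shrinkage_ratio(285, 378), 75)
  expect_equal(shrinkage_ratio(5, 5), 100)
  expect_error(shrinkage_ratio(0, 1), class = "stereofract_error_bad_volume")
})

test_that("comparison tables report pairwise percentage ratios", {
  a <- subnucleus_report("VCN-dolphin", 316.38e3, 129, processing = "DPX")
  b <- subnucleus_report("VCN-human", 91.47e3, 45, processing = "celloidin")
  tab <- comparison_table(list(a, b))
  hb <- tab[tab$a == "VCN-human" & tab$b == "VCN-dolphin", ]
  expect_equal(round_half_up(hb$total_ratio_pct, 1), 28.9)
  expect_true(hb$processing_differs)

  same <- comparison_table(list(a, a))
  expect_true(all(same$total_ratio_pct == 100 & same$volume_ratio_pct == 100))
  expect_false(any(same$processing_differs))

  # ratio columns equal brute-force division for random pairs
  set.seed(5)
  for (i in 1:10) {
    t1 <- runif(1, 1e3, 1e6); t2 <- runif(1, 1e3, 1e6)
    v1 <- runif(1, 10, 2000); v2 <- runif(1, 10, 2000)
    tab <- comparison_table(list(subnucleus_report("a", t1, v1),
                                 subnucleus_report("b", t2, v2)))
    ab <- tab[tab$a == "a", ]
    expect_equal(ab$total_ratio_pct, 100 * t1 / t2)
    expect_equal(ab$density_ratio_pct, 100 * (t1 / v1) / (t2 / v2))
  }
})

test_that("reports keep source discrepancies as metadata", {
  rep_ <- subnucleus_report(
    "VCN", 316.38e3, 129, reference_volume_mm3 = 435,
    notes = "total also reported as 3.16 million; kept the density-consistent value"
  )
  expect_match(rep_$notes, "3.16 million")
  expect_equal(round_half_up(rep_$shrinkage_percent), 30)
})
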