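# Length-to-trait conversions and the feasibility window.

test_that("body depth reproduces hand-evaluated values of the power law", {
  cf <- trait_coefficients()
  # frozen from scalar evaluation of exp(a + b*ln(L)) with the printed
  # coefficients (see helper oracle)
  expect_equal(unname(prey_body_depth(10, "cryptobenthic", cf)),
               2.2584720413, tolerance = 1e-9)
  expect_equal(unname(prey_body_depth(5, "cryptobenthic", cf)),
               1.09835700228, tolerance = 1e-9)
  expect_equal(unname(prey_body_depth(1, "social", cf)), exp(-0.9),
               tolerance = 1e-12)
  expect_equal(unname(prey_body_depth(1, "cryptobenthic", cf)), exp(-1.58),
               tolerance = 1e-12)
  # vectorised over lengths and groups, against the scalar oracle
  L <- c(1.5, 3, 7, 12, 25, 48)
  for (g in prey_groups()) {
    expect_equal(unname(prey_body_depth(L, g, cf)),
                 vapply(L, oracle_depth, numeric(1), group = g),
                 tolerance = 1e-12)
  }
})

test_that("gape reproduces hand-evaluated values of the linear relationship", {
  cf <- trait_coefficients()
  expect_equal(unname(predator_gape(10, "grabber", cf)), 1.74,
               tolerance = 1e-12)
  expect_equal(unname(predator_gape(10, "engulfer", cf)), 2.63,
               tolerance = 1e-12)
  # intercept limit as L -> 0+
  expect_equal(unname(predator_gape(1e-9, "engulfer", cf)), 0.93,
               tolerance = 1e-6)
  L <- c(2, 5.5, 14, 33)
  for (g in predator_groups()) {
    expect_equal(unname(predator_gape(L, g, cf)),
                 vapply(L, oracle_gape, numeric(1), group = g),
                 tolerance = 1e-12)
  }
})

test_that("relative prey size and feasibility honour the closed window", {
  cf <- trait_coefficients()
  expect_equal(relative_prey_size(1.09835700228, 1.74), 0.631239656484,
               tolerance = 1e-9)
  expect_equal(relative_prey_size(2.5, 2.5), 1.0)
  g <- 3.2
  expect_equal(relative_prey_size(0.14 * g, g), 0.14, tolerance = 1e-12)
  # closed interval: both endpoints feasible, just outside is not
  expect_true(is_feasible(0.14, cf))
  expect_true(is_feasible(0.7, cf))
  expect_false(is_feasible(0.71, cf))
  expect_false(is_feasible(1.0, cf))
  expect_false(is_feasible(0.05, cf))
  expect_equal(is_feasible(c(0.14, 0.5, 0.7, 0.7000001), cf),
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("domain errors are raised on invalid lengths, groups and ratios", {
  expect_error(prey_body_depth(-1, "social"), "positive")
  expect_error(prey_body_depth(0, "cryptobenthic"), "positive")
  expect_error(prey_body_depth(5, "pelagic"), "unknown prey")
  expect_error(predator_gape(-2, "grabber"), "positive")
  expect_error(predator_gape(5, "biter"), "unknown predator")
  expect_error(relative_prey_size(1, 0), "gape")
  expect_error(is_feasible(-0.2), "positive")
  expect_error(trait_coefficients(ratio_min = 0.8, ratio_max = 0.7))
  expect_error(trait_coefficients(depth_b = c(cryptobenthic = -1,
                                              epibenthic = 0.74,
                                              social = 0.95)), "slope")
})

test_that("depth is monotone in length and invertible to 1e-9", {
  cf <- trait_coefficients()
  L <- seq(0.5, 60, length.out = 200)
  for (g in prey_groups()) {
    d <- prey_body_depth(L, g, cf)
    expect_true(all(diff(d) > 0))
    expect_equal(unname(prey_length_from_depth(d, g, cf)), L,
                 tolerance = 1e-9)
  }
})

test_that("depth curves order by group with the known epibenthic crossing", {
  cf <- trait_coefficients()
  L <- seq(2, 50, by = 0.5)
  d_c <- prey_body_depth(L, "cryptobenthic", cf)
  d_e <- prey_body_depth(L, "epibenthic", cf)
  d_s <- prey_body_depth(L, "social", cf)
  # social fishes are the deepest-bodied throughout this range
  expect_true(all(d_s > d_e))
  expect_true(all(d_s > d_c))
  # epibenthic exceed cryptobenthic only below the coefficient-implied
  # crossing at exp((a_e - a_c)/(b_c - b_e)) = exp(0.8/0.3) ~ 14.39 cm
  crossing <- exp((cf$depth_a[["epibenthic"]] - cf$depth_a[["cryptobenthic"]]) /
                  (cf$depth_b[["cryptobenthic"]] - cf$depth_b[["epibenthic"]]))
  expect_equal(crossing, 14.39192, tolerance = 1e-6)
  expect_true(all(d_e[L < crossing] > d_c[L < crossing]))
  expect_true(all(d_e[L > crossing] < d_c[L > crossing]))
})

test_that("engulfer gape exceeds grabber gape at every length", {
  cf <- trait_coefficients()
  L <- seq(0.5, 80, length.out = 300)
  expect_true(all(predator_gape(L, "engulfer", cf) >
                  predator_gape(L, "grabber", cf)))
})

test_that("closed-form feasible prey window agrees with a brute-force scan", {
  cf <- trait_coefficients()
  grid <- seq(0.001, 80, by = 0.001)
  cases <- expand.grid(pred_tl = c(4, 12, 30),
                       pred_group = predator_groups(),
                       prey_group = prey_groups(),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    w <- feasible_prey_lengths(cases$pred_tl[k], cases$pred_group[k],
                               cases$prey_group[k], cf)
    gape <- oracle_gape(cases$pred_tl[k], cases$pred_group[k])
    ratio <- vapply(grid, oracle_depth, numeric(1),
                    group = cases$prey_group[k]) / gape
    inside <- grid[ratio >= 0.14 & ratio <= 0.7]
    # scan endpoints bracket the closed-form ones to scan resolution
    expect_lt(abs(min(inside) - w[["min"]]), 0.0011)
    expect_lt(abs(max(inside) - w[["max"]]), 0.0011)
    # the window is contiguous: inside lengths form one run
    expect_true(all(diff(which(ratio >= 0.14 & ratio <= 0.7)) == 1L))
  }
})

test_that("coefficients round-trip through the JSON config", {
  cf <- trait_coefficients(ratio_min = 0.1, ratio_max = 0.6)
  path <- withr::local_tempfile(fileext = ".json")
  write_trait_coefficients(cf, path)
  cf2 <- read_trait_coefficients(path)
  expect_equal(cf2$depth_a, cf$depth_a)
  expect_equal(cf2$gape_a, cf$gape_a)
  expect_equal(cf2$ratio_min, 0.1)
  expect_equal(cf2$ratio_max, 0.6)
})
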