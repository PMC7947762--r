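test_that("illumination-event filtering removes flagged and spiking frames", {
  tc <- time_course(0:9, rep(0.1, 10))
  expect_equal(filter_illumination_events(tc)$a672, tc$a672)

  # one broadband spike above the default 0.1 AU threshold
  a <- rep(0.1, 10); a[5] <- 0.6
  spiky <- time_course(0:9, a)
  kept <- filter_illumination_events(spiky)
  expect_length(kept$a672, 9)
  expect_equal(kept$time_s, (0:9)[-5])

  # masked frames in a 1 s / 11 s cycle are exactly the ones removed
  tc2 <- sim_photoconversion(1, cfg = sim_config(1, noise_sd = 0))
  kept2 <- filter_illumination_events(tc2)
  expect_identical(kept2$time_s, tc2$time_s[!tc2$illuminated])

  all_lit <- time_course(0:4, rep(1, 5), illuminated = rep(TRUE, 5))
  expect_error(filter_illumination_events(all_lit), "all frames")
})

test_that("initial rate finds the linear prefix", {
  # exact line: slope recovered exactly with R^2 = 1
  t <- seq(0, 300, by = 10)
  tc <- time_course(t, 0.06995 * t / 60)
  r <- initial_rate(tc)
  expect_equal(r$slope_au_per_min, 0.06995, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  expect_false(r$fallback)

  # flat trace: slope 0
  flat <- time_course(t, rep(0.2, length(t)))
  expect_equal(initial_rate(flat)$slope_au_per_min, 0)

  # linear-then-saturating generator trace: prefix slope within 2%
  tcs <- sim_photoconversion(1, n_cycles = 120, max_conversion = 0.5,
                             cfg = sim_config(2, noise_sd = 0))
  tcs <- filter_illumination_events(tcs)
  rs <- initial_rate(tcs)
  expect_lt(abs(rs$slope_au_per_min - 0.06995) / 0.06995, 0.02)

  # hopelessly nonlinear (pure quadratic): falls back with a warning
  wob <- time_course(t, (t / 100)^2)
  expect_warning(rw <- initial_rate(wob), "acceptably linear")
  expect_true(rw$fallback)
})

test_that("specific activity follows Beer-Lambert and unit arithmetic", {
  sa <- specific_activity(0.06995, enzyme_mg = 0.01)
  expect_equal(sa$product_rate_uM_per_min, 1.000, tolerance = 1e-9)
  expect_equal(sa$specific_u_per_mg, 0.100, tolerance = 1e-9)
  expect_equal(specific_activity(0, enzyme_mg = 1)$specific_u_per_mg, 0)
  # linear in slope, inverse-linear in mass
  expect_equal(specific_activity(0.14, enzyme_mg = 1)$specific_u_per_mg,
               2 * specific_activity(0.07, enzyme_mg = 1)$specific_u_per_mg)
  expect_equal(specific_activity(0.07, enzyme_mg = 2)$specific_u_per_mg,
               specific_activity(0.07, enzyme_mg = 1)$specific_u_per_mg / 2)
  expect_error(specific_activity(0.1, enzyme_mg = 0), "> 0")
})

test_that("optimum and 80% range use the piecewise-linear interpolant", {
  p <- optimum_and_range(c(7, 8, 9), c(0.6, 1.0, 0.6))
  expect_equal(p$optimum, 8.0)
  expect_equal(p$range_width, 1.0)   # crossings at 7.5 and 8.5
  expect_false(p$truncated)

  # all equal: full span, flagged flat and truncated
  flat <- optimum_and_range(c(5, 6, 7, 8), rep(0.4, 4))
  expect_equal(flat$range_width, 3)
  expect_true(flat$flat)
  expect_true(flat$truncated)

  # monotone profile: optimum at the boundary, truncated
  mono <- optimum_and_range(c(10, 20, 30), c(0.1, 0.5, 0.9))
  expect_equal(mono$optimum, 30)
  expect_true(mono$truncated)

  # tie at the maximum resolves to the midpoint of the tied set
  tie <- optimum_and_range(c(1, 2, 3, 4), c(0.2, 1, 1, 0.2))
  expect_equal(tie$optimum, 2.5)

  # invariance under positive rescaling
  p2 <- optimum_and_range(c(7, 8, 9), 50 * c(0.6, 1.0, 0.6))
  expect_equal(p2$optimum, p$optimum)
  expect_equal(p2$range_width, p$range_width)

  expect_error(optimum_and_range(c(7, 8), c(1, 2)), "at least 3")
  expect_error(optimum_and_range(c(7, 8, 9), c(1, NA, 2)), "non-finite")
})

test_that("substrate preference applies the 1.5-fold rule with one-decimal rounding", {
  eb <- mv_dv_preference(0.22, 0.65)
  expect_equal(eb$fold, 3.0)
  expect_equal(eb$preferred, "DV")
  te <- mv_dv_preference(0.54, 0.61)
  expect_equal(te$fold, 1.1)
  expect_equal(te$preferred, "none")
  eq <- mv_dv_preference(0.4, 0.4)
  expect_equal(eq$fold, 1.0)
  expect_equal(eq$preferred, "none")
  mv <- mv_dv_preference(0.32, 0.16)
  expect_equal(mv$preferred, "MV")
  expect_error(mv_dv_preference(0, 1), "> 0")
})

test_that("whole-cell BChl index normalizes to OD660", {
  wl <- seq(300, 900, by = 2)
  v <- 0.5 * exp(-0.002 * (wl - 300)) + 0.25 * exp(-0.5 * ((wl - 860) / 15)^2)
  od660 <- stats::approx(wl, v, 660)$y
  od860 <- stats::approx(wl, v, 860)$y
  res <- bchl_index(spectrum(wl, v, kind = "whole_cell"))
  expect_equal(res$od860_over_od660, od860 / od660, tolerance = 1e-12)
  expect_equal(stats::approx(res$spectrum$wavelength, res$spectrum$value,
                             660)$y, 1, tolerance = 1e-12)
  # OD660 = 1 leaves the spectrum unchanged
  unit <- bchl_index(spectrum(wl, v / od660, kind = "whole_cell"))
  expect_equal(unit$spectrum$value, v / od660, tolerance = 1e-12)
  expect_error(bchl_index(spectrum(seq(700, 900, 2),
                                   rep(1, 101), kind = "whole_cell")),
               "cover")
})
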