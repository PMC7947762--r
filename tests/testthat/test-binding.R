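test_that("scatter baseline follows a * lambda^-n + y0", {
  expect_equal(scatter_baseline(c(400, 630, 900), a = 0, y0 = 0.1),
               rep(0.1, 3))
  expect_equal(scatter_baseline(500, a = 1), 4.0e-6)
  expect_equal(scatter_baseline(630, a = 1e4), 1e4 / 630^2)
  expect_equal(scatter_baseline(630, a = 1e4), 0.02520, tolerance = 1e-3)
  expect_error(scatter_baseline(-1, a = 1), "> 0")
})

test_that("bound_fraction reproduces limits and the frozen quadratic value", {
  # A = 0 returns s0 exactly
  expect_equal(bound_fraction(0, kd = 3, pigment_conc = 2, s0 = 0.12,
                              smax = 0.9), 0.12)
  # stoichiometric limit Kd -> 0
  expect_equal(bound_fraction(5, kd = 0, pigment_conc = 2), 1.0)
  expect_equal(bound_fraction(1, kd = 0, pigment_conc = 2), 0.5)
  # frozen from the equilibrium root-finder oracle
  expect_equal(bound_fraction(40, kd = 40, pigment_conc = 2), 0.4937510,
               tolerance = 1e-6)
  expect_error(bound_fraction(1, kd = 1, pigment_conc = 0), "> 0")
  expect_error(bound_fraction(-1, kd = 1, pigment_conc = 2), ">= 0")
})

test_that("bound_fraction agrees with the mass-action oracle over wide ranges", {
  kds <- 10^seq(-2, 3, length.out = 6)
  as <- c(0, 10^seq(-2, 3, length.out = 8))
  bs <- 10^seq(-2, 2, length.out = 5)
  for (kd in kds) for (b in bs) {
    expect_equal(bound_fraction(as, kd = kd, pigment_conc = b),
                 oracle_bound_fraction(as, b, kd), tolerance = 1e-9)
  }
})

test_that("bound_fraction is monotone in protein and in Kd", {
  a <- seq(0, 300, by = 3)
  for (kd in c(0.5, 7, 105)) {
    expect_true(all(diff(bound_fraction(a, kd = kd, pigment_conc = 2)) >= 0))
  }
  for (ai in c(1, 20, 150)) {
    kds <- seq(0.1, 200, length.out = 50)
    v <- vapply(kds, function(k) bound_fraction(ai, kd = k, pigment_conc = 2),
                numeric(1))
    expect_true(all(diff(v) <= 0))
  }
})

test_that("unmixing recovers constructed mixtures and scatter", {
  wl <- seq(620, 720, by = 1)
  free <- spectrum(wl, 2 * 0.03 * exp(-0.5 * ((wl - 630) / 9)^2))
  bound <- spectrum(wl, 2 * 0.03 * exp(-0.5 * ((wl - 638) / 9)^2))
  # identities
  u1 <- unmix_spectrum(free, free, bound)
  expect_equal(u1$x_free, 1, tolerance = 1e-8)
  expect_equal(u1$x_bound, 0, tolerance = 1e-8)
  u2 <- unmix_spectrum(bound, free, bound)
  expect_equal(u2$x_bound, 1, tolerance = 1e-8)
  # constructed mixture with scatter
  mix <- spectrum(wl, 0.3 * free$value + 0.7 * bound$value + 1e4 * wl^-2)
  u3 <- unmix_spectrum(mix, free, bound)
  expect_equal(u3$x_free, 0.3, tolerance = 1e-6)
  expect_equal(u3$x_bound, 0.7, tolerance = 1e-6)
  expect_equal(u3$scatter$a, 1e4, tolerance = 1e-3)
  expect_lt(u3$residual_rms, 1e-10)
  # collinearity warning flag
  near <- spectrum(wl, 2 * 0.03 * exp(-0.5 * ((wl - 630.2) / 9)^2))
  expect_true(unmix_spectrum(mix, free, near)$collinear)
  expect_false(u3$collinear)
})

test_that("global K_d fit recovers truth on noiseless series", {
  for (kd in c(2, 105)) {
    ser <- sim_titration(kd, cfg = sim_config(seed = 21, noise_sd = 0))
    fit <- fit_kd(ser)
    expect_lt(abs(fit$kd_hat - kd) / kd, 0.01)
    expect_true(fit$converged)
    # final mole fractions span [0, 1] within tolerance
    expect_gt(min(fit$x_bound), -1e-6)
    expect_lt(max(fit$x_bound), 1 + 1e-6)
    expect_gt(min(fit$x_free), -1e-6)
    expect_lt(max(fit$x_free), 1 + 1e-6)
  }
})

test_that("iterative refinement strips a contaminated bound reference", {
  ser <- sim_titration(40, cfg = sim_config(seed = 22, noise_sd = 0))
  tr <- attr(ser, "truth")
  contaminated <- spectrum(tr$bound_spectrum$wavelength,
                           0.8 * tr$bound_spectrum$value +
                             0.2 * tr$free_spectrum$value)
  fit <- fit_kd(ser, free_ref = tr$free_spectrum, bound_ref = contaminated)
  expect_lt(abs(fit$kd_hat - 40) / 40, 0.02)
  expect_equal(fit$contamination_hat, 0.20, tolerance = 0.03)
  # refined bound spectrum matches the true species spectrum
  expect_lt(max(abs(fit$bound_spectrum$value - tr$bound_spectrum$value)),
            5e-4)
})

test_that("degenerate titrations are rejected", {
  ser <- sim_titration(40, protein_concs = c(0, 5, 40),
                       cfg = sim_config(23, noise_sd = 0))
  expect_error(fit_kd(ser), "at least 4")
  # no curvature: concentrations far below Kd leave the profile flat
  flat <- sim_titration(5000, protein_concs = c(0, 0.5, 1, 1.5, 2),
                        cfg = sim_config(24, noise_sd = 0))
  expect_error(fit_kd(flat), "identifiable")
})

test_that("K_d recovery stays accurate at instrument-level noise", {
  errs <- vapply(1:10, function(s) {
    ser <- sim_titration(40, cfg = sim_config(seed = 30 + s,
                                              noise_sd = 0.002))
    abs(fit_kd(ser)$kd_hat - 40) / 40
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})
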