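test_that("generators are deterministic under a fixed seed", {
  a <- sim_titration(40, cfg = sim_config(seed = 42))
  b <- sim_titration(40, cfg = sim_config(seed = 42))
  expect_identical(a$spectra[[5]]$value, b$spectra[[5]]$value)
  ta <- sim_photoconversion(1, cfg = sim_config(seed = 42))
  tb <- sim_photoconversion(1, cfg = sim_config(seed = 42))
  expect_identical(ta$a672, tb$a672)
  expect_false(identical(
    sim_titration(40, cfg = sim_config(seed = 1))$spectra[[5]]$value,
    sim_titration(40, cfg = sim_config(seed = 2))$spectra[[5]]$value))
})

test_that("generators restore the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(sim_titration(40, cfg = sim_config(seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("titration generator honours the binding ground truth", {
  cfg <- sim_config(seed = 3, noise_sd = 0)
  ser <- sim_titration(40, protein_concs = c(0, 5, 40, 200), y0 = 0,
                       scatter_a = 0, cfg = cfg)
  tr <- attr(ser, "truth")
  # zero protein: pure free spectrum, bound fraction 0
  expect_equal(tr$bound_fraction[1], 0)
  expect_equal(ser$spectra[[1]]$value, tr$free_spectrum$value,
               tolerance = 1e-12)
  # mass-action value at Kd = 40, B = 2, A = 40 (frozen from the
  # equilibrium root-finder oracle)
  expect_equal(tr$bound_fraction[3], 0.4937510, tolerance = 1e-6)
  expect_equal(tr$bound_fraction[3], oracle_bound_fraction(40, 2, 40),
               tolerance = 1e-9)
  # stoichiometric limit: tiny Kd, protein >> pigment
  ser2 <- sim_titration(1e-9, protein_concs = c(0, 200), cfg = cfg)
  expect_equal(attr(ser2, "truth")$bound_fraction[2], 1, tolerance = 1e-9)
  expect_error(sim_titration(40, protein_concs = c(0, -5)), ">= 0")
  expect_error(sim_titration(-1), "> 0")
})

test_that("photoconversion generator follows Beer-Lambert arithmetic", {
  cfg <- sim_config(seed = 4, noise_sd = 0)
  # rate zero: flat in the dark frames
  tc0 <- sim_photoconversion(0, cfg = cfg)
  expect_equal(diff(range(tc0$a672[!tc0$illuminated])), 0)
  # 1 uM/min at eps 69,950: after 60 s of cumulative light, dA = 0.06995
  # (compared between clean dark frames, before and after)
  tc <- sim_photoconversion(1, pulse_s = 1, dark_s = 11, n_cycles = 80,
                            max_conversion = 1, cfg = cfg)
  i0 <- which(!tc$illuminated)[1]
  i60 <- which(tc$light_s == tc$light_s[i0] + 60 & !tc$illuminated)[1]
  expect_equal(tc$a672[i60] - tc$a672[i0], 0.06995, tolerance = 1e-9)
  # weak-activity protocol: 6 s light per 18 s cycle
  tcw <- sim_photoconversion(1, pulse_s = 6, dark_s = 12, n_cycles = 5,
                             cfg = cfg)
  per_cycle <- tcw$light_s[tcw$time_s == 18] - tcw$light_s[tcw$time_s == 0]
  expect_equal(per_cycle, 6)
  # illuminated frames carry the artifact
  expect_true(all(tc0$a672[tc0$illuminated] > 0.4))
})

test_that("DSF generator places the inflection at tm", {
  tr <- sim_dsf(46.3, cfg = sim_config(seed = 5, noise_sd = 0))
  d <- diff(tr$ratio) / diff(tr$temp_c)
  mid <- (tr$temp_c[-1] + tr$temp_c[-length(tr$temp_c)]) / 2
  expect_lt(abs(mid[which.max(d)] - 46.3), 0.3)
  # equal baselines degenerate to a flat curve
  flat <- sim_dsf(50, baselines = c(1, 1), cfg = sim_config(5, noise_sd = 0))
  expect_equal(diff(range(flat$ratio)), 0)
  expect_error(sim_dsf(90), "inside")
})

test_that("marker generator patterns satisfy or violate the AAPB rule by class", {
  all_aapb <- sim_marker_table(40, class_mix = c(1, 0, 0),
                               cfg = sim_config(6))
  expect_true(all(call_aapb(all_aapb)$is_aapb))
  all_oxy <- sim_marker_table(40, class_mix = c(0, 1, 0),
                              cfg = sim_config(6))
  expect_false(any(call_aapb(all_oxy)$is_aapb))
  mixed <- sim_marker_table(100, class_mix = c(0.5, 0.25, 0.25),
                            cfg = sim_config(7))
  expect_equal(call_aapb(mixed)$is_aapb, attr(mixed, "truth") == "aapb")
})

test_that("tree-set generator hits the requested clade frequency exactly", {
  taxa <- sprintf("t%02d", 1:10)
  clade <- taxa[1:3]
  full <- sim_tree_set(taxa, clade, 1, 20, cfg = sim_config(8))
  expect_true(all(vapply(full, is_clade_monophyletic, logical(1),
                         taxa = clade)))
  half <- sim_tree_set(taxa, clade, 0.5, 10, cfg = sim_config(9))
  hits <- vapply(half, is_clade_monophyletic, logical(1), taxa = clade)
  expect_equal(sum(hits), 5)
  expect_equal(hits, attr(half, "truth"))
  expect_error(sim_tree_set(taxa, taxa[1], 0.5, 10), "at least 2")
})

test_that("noiseless generator output lets estimators recover truth", {
  cfg0 <- function(s) sim_config(seed = s, noise_sd = 0)
  f <- fit_kd(sim_titration(7, cfg = cfg0(10)))
  expect_equal(f$kd_hat, 7, tolerance = 1e-4)
  tm <- melting_temperature(sim_dsf(54.4, cfg = cfg0(11)))
  expect_equal(tm$tm, 54.4, tolerance = 0.05)
  tc <- filter_illumination_events(sim_photoconversion(0.5, cfg = cfg0(12)))
  expect_equal(initial_rate(tc)$slope_au_per_min, 0.5 * 69950 * 1e-6,
               tolerance = 1e-6)
})
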