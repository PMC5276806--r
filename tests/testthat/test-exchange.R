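test_that("growth-integrated cell volume follows the trapezoid arithmetic", {
  g <- growth_curve(c(0, 24), c(3, 3), medium_volume_ml = 3)
  expect_equal(integrated_cell_volume(g), 0.024)
  expect_equal(integrated_cell_volume(g, 5, 5), 0)
  # linear growth from 2 to 4 uL integrates like constant 3 uL
  g_lin <- growth_curve(c(0, 24), c(2, 4), medium_volume_ml = 3)
  expect_equal(integrated_cell_volume(g_lin), 0.024)
  expect_error(integrated_cell_volume(g, 10, 5), "t1")
  expect_error(integrated_cell_volume(g, -5, 24), "span")
})

test_that("net exchange converts medium concentration change to per-cell-volume flux", {
  g <- growth_curve(c(0, 24), c(0.375, 0.375), medium_volume_ml = 3) # 9 uL*hr
  conc <- data.frame(time_hr = c(0, 24), c_total = c(105, 81))       # -24 uM
  expect_equal(net_exchange(conc, g), -8)
  expect_equal(net_exchange(data.frame(time_hr = c(0, 24), c_total = c(105, 105)), g), 0)
  # doubling medium volume at fixed concentrations and pcv doubles |e|
  g2 <- growth_curve(c(0, 24), c(0.375, 0.375), medium_volume_ml = 6)
  expect_equal(net_exchange(conc, g2), -16)
})

test_that("deconvolution solves the hand-solved 2x2 balance systems", {
  # e = 0, dC12/T' = 2, a = 1, b = 0.5 -> r = u = 4
  expect_equal(deconvolve_fluxes(0, 2e3 * 0.01, 0.01, a = 1, b = 0.5),
               c(r = 4, u = 4))
  # a = 1, b = 0, dC_total/T' = -1, dC12/T' = 3 -> r = 3, u = 4
  expect_equal(deconvolve_fluxes(-1e3 * 0.01, 3e3 * 0.01, 0.01, a = 1, b = 0),
               c(r = 3, u = 4))
  # x = b (pure uptake leaves medium composition unchanged) -> r = 0, u = -e
  ru <- deconvolve_fluxes(-10, -10 * 0.3, 0.005, a = 0.8, b = 0.3)
  expect_equal(unname(ru["r"]), 0)
  expect_equal(unname(ru["u"]), 10 * 1e-3 / 0.005)
  expect_error(deconvolve_fluxes(1, 1, 0.01, a = 0.5, b = 0.5), "singular")
  expect_error(deconvolve_fluxes(1, 1, 0.01, a = 1.2, b = 0), "\\[0, 1\\]")
})

test_that("r - u = e exactly for every scanned intracellular fraction", {
  cfg <- scenario("MDA468_normoxia", noise_cv = 0)
  ex <- estimate_exchange(simulate_medium_acetate(cfg)$concentrations,
                          simulate_growth(cfg))
  e <- net_exchange(simulate_medium_acetate(cfg)$concentrations,
                    simulate_growth(cfg))
  expect_equal(ex$scan$r - ex$scan$u, rep(e, nrow(ex$scan)), tolerance = 1e-12)
  expect_equal(ex$e_median, e, tolerance = 1e-12)
  # e is independent of the a-grid
  ex2 <- estimate_exchange(simulate_medium_acetate(cfg)$concentrations,
                           simulate_growth(cfg), a_grid = c(0.5, 0.7, 0.9))
  expect_equal(ex2$e_median, ex$e_median)
})

test_that("|r(a)| is non-increasing in a - b at fixed measurements", {
  ru <- t(vapply(seq(0.4, 1, by = 0.05), function(a)
    deconvolve_fluxes(-5, 8, 0.01, a, b = 0.3), numeric(2)))
  expect_true(all(diff(abs(ru[, 1])) <= 1e-9))
})

test_that("simulator round trip recovers the true fluxes at zero noise", {
  cfg <- scenario(doubling_time = 30, pcv0 = 0.2, u = 4, r = 4, a = 0.9,
                  noise_cv = 0, medium_times = seq(0, 12, by = 3),
                  growth_times = seq(0, 12, by = 1))
  med <- simulate_medium_acetate(cfg)
  g <- simulate_growth(cfg)
  ex <- estimate_exchange(med$concentrations, g,
                          a_grid = sort(c(0.9, seq(0.2, 1, length.out = 100))))
  # true a on the grid: scanned (r, u) interval contains the truth
  expect_lte(min(ex$scan$r), 4)
  expect_gte(max(ex$scan$r), 4)
  # at the true a the fluxes are recovered within 1%
  at_true <- ex$scan[which.min(abs(ex$scan$a - 0.9)), ]
  expect_equal(at_true$r, 4, tolerance = 0.01)
  expect_equal(at_true$u, 4, tolerance = 0.01)
})

test_that("a pure-uptake series yields a zero release lower bound", {
  cfg <- scenario(doubling_time = 48, pcv0 = 0.33, u = 6, r = 0, a = 0.9,
                  noise_cv = 0)
  med <- simulate_medium_acetate(cfg)
  ex <- estimate_exchange(med$concentrations, simulate_growth(cfg))
  expect_equal(ex$r_q05, 0, tolerance = 1e-6)
  expect_equal(ex$u_q05, -ex$e_median, tolerance = 1e-6)
  # medium 12C fraction is constant under pure uptake
  frac <- med$concentrations$c12 / med$concentrations$c_total
  expect_equal(max(frac) - min(frac), 0, tolerance = 1e-9)
})

test_that("fluxes are invariant when all volumes scale together", {
  cfg1 <- scenario("BT474_lowserum", noise_cv = 0)
  cfg2 <- scenario("BT474_lowserum", noise_cv = 0,
                   pcv0 = cfg1$pcv0 * 10, medium_volume = cfg1$medium_volume * 10)
  e1 <- net_exchange(simulate_medium_acetate(cfg1)$concentrations,
                     simulate_growth(cfg1))
  e2 <- net_exchange(simulate_medium_acetate(cfg2)$concentrations,
                     simulate_growth(cfg2))
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("bootstrap over wells is seeded and reproducible", {
  cfg <- scenario("MDA468_normoxia", noise_cv = 0.05)
  med <- simulate_medium_acetate(cfg, seed = 7)
  c_is <- effective_is_concentration(cfg$is_volume_ml, cfg$is_conc_um,
                                     cfg$sample_volume_ml)
  q <- quantify_acetate(med$sim, c_is)
  g <- simulate_growth(cfg)
  ex1 <- estimate_exchange(q, g, n_boot = 50, seed = 11)
  ex2 <- estimate_exchange(q, g, n_boot = 50, seed = 11)
  expect_identical(summary(ex1), summary(ex2))
  expect_equal(ex1$n_boot, 50L)
  expect_equal(ex1$n_wells, 3L)
})

test_that("release/consumption ratio follows the endpoint arithmetic", {
  conc <- data.frame(time_hr = c(0, 48), c12 = c(15, 45), c13 = c(90, 60))
  expect_equal(release_uptake_ratio(conc), 1)
  conc0 <- data.frame(time_hr = c(0, 48), c12 = c(15, 15), c13 = c(90, 60))
  expect_equal(release_uptake_ratio(conc0), 0)
  expect_error(release_uptake_ratio(
    data.frame(time_hr = c(0, 48), c12 = c(15, 45), c13 = c(90, 95))),
    "undefined")
})

test_that("high acetate capture lowers the release/consumption ratio", {
  low_capture <- scenario(u = 3.5, r = 3.5, a = 0.95, noise_cv = 0)
  high_capture <- scenario(u = 8, r = 0.5, a = 0.95, noise_cv = 0)
  r_low <- release_uptake_ratio(simulate_medium_acetate(low_capture)$concentrations)
  r_high <- release_uptake_ratio(simulate_medium_acetate(high_capture)$concentrations)
  expect_lt(r_high, r_low)
})
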