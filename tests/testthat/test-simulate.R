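test_that("growth follows the exponential closed form", {
  cfg <- scenario(doubling_time = 30, pcv0 = 1.5)
  g <- simulate_growth(cfg, times = seq(0, 60, by = 1))
  expect_equal(g$pcv_ul[g$times == 0], 1.5)
  expect_equal(g$pcv_ul[g$times == 30], 3.0)
  # integral over one doubling time: pcv0 * td / ln 2
  T_int <- integrated_cell_volume(g, 0, 30)
  expect_equal(T_int, 1.5 * 30 / log(2) / cfg$medium_volume * 1e-3,
               tolerance = 1e-4)
})

test_that("medium dynamics honor degenerate flux configurations", {
  still <- scenario(u = 0, r = 0, noise_cv = 0)
  conc <- simulate_medium_acetate(still)$concentrations
  expect_equal(conc$c_total, rep(105, nrow(conc)))
  expect_equal(conc$c12, rep(15, nrow(conc)))
})

test_that("medium mass balance matches the flux-times-growth integral", {
  cfg <- scenario("BT474_lowserum", noise_cv = 0)
  conc <- simulate_medium_acetate(cfg)$concentrations
  g <- simulate_growth(cfg, times = seq(0, 48, by = 0.5))
  T_int <- integrated_cell_volume(g)
  expected_drop <- (cfg$r - cfg$u) * T_int * 1e3 # uM
  expect_equal(conc$c_total[nrow(conc)] - conc$c_total[1], expected_drop,
               tolerance = 1e-3)
})

test_that("hypoxic cells consume nearly all labeled acetate by 72 hr", {
  cfg <- scenario("MDA468_hypoxia", noise_cv = 0)
  conc <- simulate_medium_acetate(cfg)$concentrations
  expect_lt(conc$c13[conc$time_hr == 72], 10)
  expect_gt(conc$c13[conc$time_hr == 0] , 89)
})

test_that("palmitate MID simulation respects its degenerate cases", {
  cfg0 <- scenario(D_acetate = 0, noise_cv = 0)
  tab <- simulate_palmitate_mids(cfg0, times = c(0, 48))
  m0 <- mids_from_table(tab)
  # with no enrichment the raw pattern is pure natural abundance at all t
  expect_equal(m0[[1]]$fractions, m0[[2]]$fractions, tolerance = 1e-12)
  cfg_static <- scenario(g_turnover_k = 0, D_acetate = 0.3, noise_cv = 0)
  tab2 <- simulate_palmitate_mids(cfg_static, times = c(0, 24, 48))
  m2 <- mids_from_table(tab2)
  expect_equal(m2[[1]]$fractions, m2[[3]]$fractions, tolerance = 1e-12)
})

test_that("correction plus ISA fit recovers the simulated enrichment", {
  cfg <- scenario("MDA468_hypoxia", noise_cv = 0)
  tab <- simulate_palmitate_mids(cfg, times = 120)
  fit <- fit_isa(na_correct(mids_from_table(tab)[[1]], cfg$fame_formula))
  expect_equal(fit$D, 0.30, tolerance = 0.005)
  expect_equal(fit$g, 1, tolerance = 0.01)
})

test_that("a fixed seed reproduces the bundle bit-for-bit", {
  b1 <- simulate_scenario(scenario("MDA468_normoxia"), seed = 42)
  b2 <- simulate_scenario(scenario("MDA468_normoxia"), seed = 42)
  expect_identical(b1$medium$sim, b2$medium$sim)
  expect_identical(b1$palmitate, b2$palmitate)
  expect_identical(b1$histone, b2$histone)
  b3 <- simulate_scenario(scenario("MDA468_normoxia"), seed = 43)
  expect_false(identical(b3$medium$sim, b1$medium$sim))
})

test_that("scenario validation rejects inconsistent configurations", {
  expect_error(scenario("no_such_preset"), "unknown preset")
  expect_error(scenario(u = -1), "not TRUE")
  expect_error(scenario(a = 1.5), "not TRUE")
  expect_error(scenario(nonsense_field = 1), "unknown scenario field")
})
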