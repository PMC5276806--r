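test_that("the binomial forward model reproduces hand-computed isotopomers", {
  expect_equal(unname(forward_palmitate_mid(0, 0.7)$fractions),
               c(1, numeric(16)))
  expect_equal(unname(forward_palmitate_mid(1, 1)$fractions),
               c(numeric(16), 1))
  m <- forward_palmitate_mid(0.5, 1)
  expect_equal(unname(m$fractions[["M+8"]]), choose(8, 4) / 2^8)
  # odd shifts are structurally zero; output is a valid MID for all (D, g)
  set.seed(5)
  for (i in 1:25) {
    mm <- forward_palmitate_mid(runif(1), runif(1))
    expect_equal(sum(mm$fractions), 1, tolerance = 1e-12)
    expect_true(all(mm$fractions >= 0))
    expect_equal(sum(mm$fractions[seq(2, 17, by = 2)]), 0)
  }
})

test_that("fit recovers (D, g) on a lattice away from the degenerate manifold", {
  for (D in seq(0.05, 0.95, by = 0.15)) {
    for (g in c(0.25, 0.6, 1)) {
      fit <- fit_isa(forward_palmitate_mid(D, g))
      expect_equal(fit$D, D, tolerance = 0.005, label = sprintf("D (true %g, %g)", D, g))
      expect_equal(fit$g, g, tolerance = 0.005, label = sprintf("g (true %g, %g)", D, g))
    }
  }
})

test_that("noiseless hypoxic-level enrichment is recovered exactly", {
  fit <- fit_isa(forward_palmitate_mid(0.30, 1.0))
  expect_equal(fit$D, 0.30, tolerance = 0.005)
  fit2 <- fit_isa(forward_palmitate_mid(0.5, 0.5))
  expect_equal(unname(coef(fit2)), c(0.5, 0.5), tolerance = 0.005)
})

test_that("an all-M+0 input returns (0, 0) by the tie-break rule", {
  fit <- fit_isa(mid(c(1, numeric(16))))
  expect_equal(unname(coef(fit)), c(0, 0))
  expect_equal(fit$ssr, 0)
})

test_that("returned optimum beats every node of an exhaustive coarse grid", {
  obs <- mid(0.6 * forward_palmitate_mid(0.42, 0.83)$fractions +
               0.4 * forward_palmitate_mid(0.15, 0.4)$fractions)
  fit <- fit_isa(obs, grid_resolution = 0.05, refine = FALSE)
  o <- obs$fractions[seq(1, 17, by = 2)]
  for (D in seq(0, 1, by = 0.05))
    for (g in seq(0, 1, by = 0.05)) {
      node <- acetrace:::.isa_ssr(c(D, g), o, 8)
      expect_gte(node + 1e-12, fit$ssr)
    }
})

test_that("appreciable odd-shift mass is diagnosed, not fitted", {
  f <- forward_palmitate_mid(0.3, 0.9)$fractions
  f[2] <- 0.05 # inject M+1 mass
  expect_warning(fit <- fit_isa(mid(f)), "odd-shift")
  expect_equal(fit$D, 0.3, tolerance = 0.01)
})

test_that("recovered D is unbiased under 2% multiplicative noise", {
  truth <- forward_palmitate_mid(0.30, 0.8)$fractions
  s <- sqrt(log(1 + 0.02^2))
  D_hat <- vapply(1:200, function(i) {
    set.seed(2000 + i)
    noisy <- truth * rlnorm(17, -s^2 / 2, s)
    fit_isa(mid(noisy))$D
  }, numeric(1))
  expect_lt(abs(mean(D_hat) - 0.30), 0.01)
})

test_that("tracer contributions map D to percent and flag inconsistency", {
  tc <- tracer_contributions(c(acetate = 0.30, glucose = 0, glutamine = 0))
  expect_equal(tc$percent[tc$tracer == "acetate"], 30)
  expect_equal(tc$percent[tc$tracer == "other"], 70)
  tc0 <- tracer_contributions(c(acetate = 0, glucose = 0))
  expect_equal(tc0$percent[tc0$tracer == "other"], 100)
  expect_warning(tracer_contributions(c(a = 0.4, b = 0.35, c = 0.3)),
                 "inconsistent")
})
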