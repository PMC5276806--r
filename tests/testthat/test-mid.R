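test_that("MID construction enforces the type invariants", {
  m <- mid(c(2, 1, 1), analyte = "acetate")
  expect_s3_class(m, "mid")
  expect_equal(sum(m$fractions), 1, tolerance = 1e-12)
  expect_equal(m$n_carbons, 2L)
  expect_error(mid(c(1, 0), n_carbons = 2), "n_carbons")
  expect_error(mid(c(-0.2, 1.2)), "non-negative")
  expect_error(mid(c(0, 0)), "sum to zero")
})

test_that("correction matrix is the identity when no natural enrichment exists", {
  M <- correction_matrix("C2H3O2", 2, isotopes = pure_isotopes)
  expect_equal(unname(M), diag(3))
})

test_that("correction matrix columns match brute-force isotope enumeration", {
  iso <- acetrace:::.acetrace_isotopes
  for (case in list(list(f = "C2H3O2", n = 2),
                    list(f = "C3H5O2", n = 2),
                    list(f = "C2H6S", n = 1))) {
    counts <- parse_formula(case$f)
    M <- correction_matrix(case$f, case$n)
    for (j in 0:case$n) {
      expect_equal(unname(M[, j + 1]),
                   bf_correction_column(counts, case$n, j, iso),
                   tolerance = 1e-12,
                   label = sprintf("%s column %d", case$f, j))
    }
  }
})

test_that("correction matrix is a lower-triangular sub-probability matrix", {
  M <- correction_matrix("C17H34O2", 16)
  expect_true(all(M >= 0 & M <= 1))
  expect_true(all(colSums(M) <= 1 + 1e-12))
  expect_true(all(M[upper.tri(M)] == 0))
  expect_error(correction_matrix("C2H4O", 3), "carbon count")
  expect_error(correction_matrix(c(C = -1, H = 2), 0), "negative")
})

test_that("na_correct inverts forward convolution on random MIDs", {
  M <- correction_matrix("C17H34O2", 16)
  set.seed(41)
  for (i in 1:20) {
    truth <- random_mid(16, "palmitate")
    raw <- mid(as.vector(M %*% truth$fractions), analyte = "palmitate")
    rec <- na_correct(raw, "C17H34O2")
    expect_equal(rec$fractions, truth$fractions, tolerance = 1e-8)
    # forward-convolving the corrected MID reproduces the raw one
    back <- as.vector(M %*% rec$fractions)
    expect_equal(back / sum(back), unname(raw$fractions), tolerance = 1e-8)
  }
})

test_that("an unlabeled analyte corrects to pure M+0", {
  M <- correction_matrix("C2H3O2", 2)
  raw <- mid(as.vector(M %*% c(1, 0, 0)))
  corr <- na_correct(raw, "C2H3O2")
  expect_equal(unname(corr$fractions), c(1, 0, 0), tolerance = 1e-10)
})

test_that("ill-conditioned corrections fail explicitly and clipping is reported", {
  raw <- mid(c(0.9, 0.05, 0.05))
  expect_error(na_correct(raw, "C2H3O2", cond_max = 1), "ill-conditioned")
  # raw mass moved below what natural abundance alone can explain
  distorted <- mid(c(0.999, 0.0, 0.02), normalize = TRUE)
  expect_warning(na_correct(distorted, "C17H34O2", cond_max = 1e12),
                 "clipped")
})

test_that("fractional labeling summaries follow hand arithmetic", {
  expect_equal(fraction_labeled(mid(c(1, 0, 0))), 0)
  expect_equal(fraction_labeled(mid(c(0, 0, 1))), 1)
  m <- mid(c(0.5, 0.25, 0.25))
  expect_equal(fraction_labeled(m), 0.5)
  expect_equal(mean_enrichment(m), 0.375)
  # invariant under renormalization of the input
  m2 <- mid(c(2, 1, 1))
  expect_equal(fraction_labeled(m2), fraction_labeled(m))
  expect_equal(mean_enrichment(m2), mean_enrichment(m))
})

test_that("formula parsing handles counts, implicit 1s and bad input", {
  expect_equal(parse_formula("C17H34O2"), c(C = 17, H = 34, O = 2))
  expect_equal(parse_formula("CH4")[["H"]], 4)
  expect_equal(parse_formula("CH4")[["C"]], 1)
  expect_error(parse_formula("C2Xx3"), "unknown element")
})
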