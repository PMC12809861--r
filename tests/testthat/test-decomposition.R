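test_that("rph decomposition follows the product rule and is additive", {
  # worked identities: printed-table inputs reproduce printed outputs at 2 dp
  d1 <- decompose_rph(rg = 0.42, rc = 0, re = 0.21,
                      h2_x = 0.30, c2_x = 0.22, e2_x = 0.48,
                      h2_d = 0.90, c2_d = 0, e2_d = 0.10)
  expect_equal(d1$rph_a, 0.42 * sqrt(0.30 * 0.90), tolerance = 1e-12)
  expect_equal(twinace:::round_half_away(d1$rph_a), 0.22)
  d2 <- decompose_rph(rg = -0.20, rc = 0, re = 0.02,
                      h2_x = 0.67, c2_x = 0.09, e2_x = 0.24,
                      h2_d = 0.85, c2_d = 0, e2_d = 0.15)
  expect_equal(twinace:::round_half_away(d2$rph_a), -0.15)
  # additivity and zero-factor cases
  set.seed(1)
  for (i in 1:25) {
    v <- abs(rnorm(3)); v <- v / sum(v)
    w <- abs(rnorm(3)); w <- w / sum(w)
    rg <- runif(1, -1, 1); rc <- runif(1, -1, 1); re <- runif(1, -1, 1)
    dd <- decompose_rph(rg, rc, re, v[1], v[2], v[3], w[1], w[2], w[3])
    expect_equal(dd$rph, dd$rph_a + dd$rph_c + dd$rph_e, tolerance = 1e-10)
    expect_lte(abs(dd$rph_a), sqrt(v[1] * w[1]) + 1e-12)
    expect_lte(abs(dd$rph), 1 + 1e-9)
  }
  expect_equal(decompose_rph(0, 0.5, 0.5, 0.3, 0.3, 0.4,
                             0.5, 0.2, 0.3)$rph_a, 0)
  expect_identical(decompose_rph(0.5, 0.9, 0.5, 0.3, 0.3, 0.4,
                                 0.9, 0, 0.1)$rph_c, 0)
  expect_error(decompose_rph(0, 0, 0, -0.1, 0.5, 0.6, 0.9, 0, 0.1),
               "non-negative")
})

test_that("genetic sharing is the squared genetic correlation in percent", {
  expect_identical(genetic_sharing(0.36), 13)
  expect_identical(genetic_sharing(0), 0)
  expect_identical(genetic_sharing(1), 100)
  expect_identical(genetic_sharing(0.24), 6)
  expect_identical(genetic_sharing(0.42), 18)
  expect_equal(genetic_sharing(0.36, rounded = FALSE), 12.96)
  expect_error(genetic_sharing(1.2), "\\[-1, 1\\]")
})

test_that("criteria engine gates, combines and reports indeterminacy", {
  # all four pass
  r <- endophenotype_criteria(c(-0.30, -0.17), 0.72, c(0.49, 0.79),
                              c(-0.37, -0.17), c(-0.28, -0.13))
  expect_true(r$is_endophenotype)
  # c1 gate short-circuits the genetic stage
  g <- endophenotype_criteria(c(-0.05, 0.15), 0.80, c(0.5, 0.9),
                              c(0.2, 0.9), c(0.1, 0.3))
  expect_false(g$is_endophenotype)
  expect_true(g$gated)
  expect_true(is.na(g$c2_heritability))
  # significant h2 below the 10% floor fails criterion 2
  f <- endophenotype_criteria(c(0.06, 0.21), 0.09, c(0.01, 0.44),
                              c(0.53, 1), c(0.07, 0.23))
  expect_false(f$c2_heritability)
  expect_false(f$is_endophenotype)
  # non-significant h2 fails criterion 2 even when large
  f2 <- endophenotype_criteria(c(0.06, 0.21), 0.40, c(0, 0.6),
                               c(0.53, 1), c(0.07, 0.23))
  expect_false(f2$c2_heritability)
  # missing CI -> indeterminate criterion, not an endophenotype
  m <- endophenotype_criteria(c(0.06, 0.21), 0.40, c(0.2, 0.6),
                              NULL, c(0.07, 0.23))
  expect_true(is.na(m$c3_rg))
  expect_false(m$is_endophenotype)
})

test_that("criteria evaluation is deterministic on the reference fixture", {
  fx <- criteria_fixture()
  for (i in seq_len(nrow(fx))) {
    r <- fx[i, ]
    got <- endophenotype_criteria(
      c(r$c1_lo, r$c1_hi), r$h2,
      if (is.na(r$h2_lo)) NULL else c(r$h2_lo, r$h2_hi),
      if (is.na(r$rg_lo)) NULL else c(r$rg_lo, r$rg_hi),
      if (is.na(r$ra_lo)) NULL else c(r$ra_lo, r$ra_hi))
    expect_identical(got$is_endophenotype, r$expect_endo,
                     label = paste(r$measure, r$phenotype))
    expect_identical(got$gated, r$expect_stage == "gate",
                     label = paste(r$measure, r$phenotype, "gate"))
  }
})
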