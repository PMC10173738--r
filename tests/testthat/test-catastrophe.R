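test_that("gamma catastrophe density matches the exponential limit and an independent oracle", {
  m1 <- catastrophe_model(1, 35, tau0 = 20)
  expect_equal(catastrophe_density(0, m1), 1 / 35)
  m2 <- catastrophe_model(2, 10, tau0 = 5)
  expect_equal(catastrophe_density(10, m2), oracle_gamma_pdf(10, 2, 10),
               tolerance = 1e-8)
  m3 <- catastrophe_model(3.6, 35)
  expect_equal(catastrophe_density(60, m3), oracle_gamma_pdf(60, 3.6, 35),
               tolerance = 1e-8)
  # normalization over the effective support
  for (m in list(m1, m2, m3)) {
    z <- integrate(function(t) catastrophe_density(t, m), 0,
                   50 * m$step_parameter * m$timescale, rel.tol = 1e-9)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
  expect_error(catastrophe_density(-1, m1), "non-negative")
  expect_error(catastrophe_density(NaN, m1), "finite")
})

test_that("window truncation renormalizes the density on the window", {
  m <- catastrophe_model(3.6, 35)
  t <- c(0, 20, 50, 100, 250, 500)
  expect_equal(catastrophe_density_truncated(t, m, 0, Inf),
               catastrophe_density(t, m))
  # renormalization oracle: quadrature of the untruncated pdf over the window
  mass <- integrate(function(u) catastrophe_density(u, m), 40, 300,
                    rel.tol = 1e-10)$value
  inside <- c(40, 60, 120, 299)
  expect_equal(catastrophe_density_truncated(inside, m, 40, 300),
               catastrophe_density(inside, m) / mass, tolerance = 1e-7)
  expect_equal(catastrophe_density_truncated(c(10, 350), m, 40, 300), c(0, 0))
  z <- integrate(function(u) catastrophe_density_truncated(u, m, 40, 300),
                 40, 300, rel.tol = 1e-9)$value
  expect_equal(z, 1, tolerance = 1e-6)
  expect_error(catastrophe_density_truncated(1, m, 5000, 6000), "degenerate")
})

test_that("inverse hazard is memoryless at N = 1, diverges at age 0 for N > 1, and matches quadrature", {
  m1 <- catastrophe_model(1, 35, tau0 = 20)
  expect_equal(inverse_hazard(c(0, 10, 100, 5000), m1), rep(35, 4))
  m2 <- catastrophe_model(2, 10, tau0 = 5)
  expect_identical(inverse_hazard(0, m2), Inf)
  m3 <- catastrophe_model(3.6, 35)
  expect_equal(inverse_hazard(100, m3), oracle_inverse_hazard(100, 3.6, 35),
               tolerance = 1e-6)
  # log-space evaluation stays finite far in the tail
  far <- inverse_hazard(5000, m3)
  expect_true(is.finite(far) && far > 0)
})

test_that("per-step catastrophe probability has the closed form and is monotone", {
  m <- catastrophe_model(1, 35, tau0 = 20)
  expect_equal(catastrophe_probability(50, 0.1, m), 1 - exp(-0.1 / 35))
  expect_lt(catastrophe_probability(50, 1e-9, m), 1e-9)
  m3 <- catastrophe_model(3.6, 35)
  dts <- c(0.01, 0.1, 1, 10)
  expect_true(all(diff(catastrophe_probability(80, dts, m3)) > 0))
  lf <- c(1, 1.5, 2, 5)
  p <- vapply(lf, function(l) catastrophe_probability(80, 0.1, m3, l),
              numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("force rescaling interpolates between the free and stalled catastrophe times", {
  m <- catastrophe_model(3.6, 35, tau0 = 25)
  expect_equal(rescale_catastrophe_time(125, m, 1), 125)
  expect_equal(rescale_catastrophe_time(125, m, 0.5), 75)
  expect_equal(rescale_catastrophe_time(125, m, 1e-12), 25, tolerance = 1e-9)
  expect_warning(out <- rescale_catastrophe_time(10, m, 0.5), "clamped")
  expect_equal(out, 25)
  taus <- seq(26, 500, by = 7)
  for (v in c(0.1, 0.34, 0.9)) {
    r <- rescale_catastrophe_time(taus, m, v)
    expect_true(all(r >= m$tau0 - 1e-12) && all(r <= taus + 1e-12))
  }
})

test_that("single-filament stepping grows, catastrophizes and rescues as specified", {
  kin <- kinetic_params()
  mt <- microtubule_state(length = 1, drawn_tau = 100)
  out <- step_microtubule(mt, 0.1, in_contact = FALSE, kin)
  expect_equal(out$length, 1 + 0.05 * 0.1)
  expect_equal(out$cat_clock, 0.1)
  # contact advances the clock faster than real time
  out2 <- step_microtubule(mt, 0.1, in_contact = TRUE, kin)
  expect_equal(out2$length, 1 + 0.017 * 0.1)
  expect_gt(out2$cat_clock, 0.1)
  # catastrophe at the drawn time
  mt$cat_clock <- 99.95
  out3 <- step_microtubule(mt, 0.1, in_contact = FALSE, kin)
  expect_identical(out3$phase, "shrinking")
  # instantaneous rescue at zero length
  set.seed(1)
  sh <- microtubule_state(length = 0.01, phase = "shrinking", drawn_tau = 100)
  out4 <- step_microtubule(sh, 0.1, in_contact = FALSE, kin)
  expect_identical(out4$phase, "growing")
  expect_identical(out4$length, 0)
  expect_identical(out4$cat_clock, 0)
  expect_true(is.na(out4$buckling_ref_length))
  expect_false(identical(out4$drawn_tau, sh$drawn_tau))
})

test_that("hazard-driven catastrophe ages match direct gamma sampling (KS < 0.01)", {
  set.seed(4)
  ages <- mtcentering:::.catastrophe_age_sample(1e5, 0.05, 3.6, 35, 25, 1,
                                                FALSE, 1L)
  ks <- suppressWarnings(stats::ks.test(ages, pgamma, shape = 3.6,
                                        scale = 35))
  expect_lt(unname(ks$statistic), 0.01)
  # exponential limit: N = 1 ages are exponential(T)
  set.seed(5)
  ages1 <- mtcentering:::.catastrophe_age_sample(5e4, 0.05, 1, 35, 0.1,
                                                 1, FALSE, 1L)
  ks1 <- suppressWarnings(stats::ks.test(ages1, stats::pexp, rate = 1 / 35))
  expect_lt(unname(ks1$statistic), 0.01)
})

test_that("permanent-contact ensemble reproduces the rescaled mean catastrophe time", {
  set.seed(6)
  ages <- mtcentering:::.catastrophe_age_sample(1e4, 0.05, 3.6, 35, 25, 0.5,
                                                TRUE, 0L)
  predicted <- 25 + (3.6 * 35 - 25) * 0.5
  sem <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - predicted), 2 * sem + 0.05) # 0.05 s step rounding
})
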