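test_that("gamma log-likelihood has the exponential closed form and is additive", {
  d1 <- catastrophe_dataset(50, window = c(1, 1000))
  expect_equal(gamma_log_likelihood(d1, 1, 35), -log(35) - 50 / 35)
  set.seed(20)
  t <- rgamma(200, 3.6, scale = 35)
  d <- catastrophe_dataset(t)
  dd <- catastrophe_dataset(c(t, t), window = d$window)
  expect_equal(gamma_log_likelihood(dd, 3.6, 35),
               2 * gamma_log_likelihood(d, 3.6, 35))
  # likelihood dominance at the sample-matched parameters
  set.seed(21)
  big <- catastrophe_dataset(rgamma(1e4, 3.6, scale = 35))
  ll0 <- gamma_log_likelihood(big, 3.6, 35)
  expect_gt(ll0, gamma_log_likelihood(big, 4.5, 35))
  expect_gt(ll0, gamma_log_likelihood(big, 3.6, 45))
})

test_that("gamma MLE recovers generating parameters and is scale equivariant", {
  d <- gen_catastrophe_times(shape = 3.6, scale = 35, window = c(1e-4, 1e6),
                             n = 1e4, seed = 22)
  f <- mle_fit(d)
  expect_lt(abs(f$shape - 3.6) / 3.6, 0.05)
  expect_lt(abs(f$scale - 35) / 35, 0.05)
  # cross-check against an established fitter on the same data
  if (requireNamespace("fitdistrplus", quietly = TRUE)) {
    ref <- fitdistrplus::fitdist(d$times, "gamma")
    expect_equal(f$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
    expect_equal(f$scale, 1 / unname(ref$estimate["rate"]), tolerance = 1e-3)
  }
  # scale equivariance
  d2 <- catastrophe_dataset(d$times * 3, window = d$window * 3)
  f2 <- mle_fit(d2)
  expect_equal(f2$shape, f$shape, tolerance = 1e-4)
  expect_equal(f2$scale, 3 * f$scale, tolerance = 1e-4)
  # exponential data recover shape ~ 1
  dexp_ <- catastrophe_dataset(with(list(), {set.seed(23); rexp(5e3, 1 / 40)}))
  fe <- mle_fit(dexp_)
  expect_lt(abs(fe$shape - 1), 0.1)
})

test_that("informative prior hits the target max/min ratio and normalizes", {
  ll <- mal3_anchor_loglik(n = 200, seed = 1)
  prior <- build_informative_prior(ll, target_ratio = 10)
  expect_equal(max(prior) / min(prior), 10, tolerance = 0.01)
  expect_equal(sum(prior), 1, tolerance = 1e-9)
  # near-flat target puts almost all weight on the uniform component
  p2 <- build_informative_prior(ll, target_ratio = 1.001)
  expect_equal(max(p2) / min(p2), 1.001, tolerance = 1e-4)
  expect_lt(attr(p2, "weight"), attr(prior, "weight"))
  # a flat surface cannot reach any ratio above 1
  flat <- matrix(0, 5, 5)
  expect_error(build_informative_prior(flat, 10), "unreachable")
})

test_that("grid posterior normalizes, matches the grid MLE under a flat prior, and concentrates", {
  d <- gen_catastrophe_times(n = 500, seed = 24)
  pg <- grid_posterior(d)
  expect_equal(sum(pg$posterior), 1, tolerance = 1e-9)
  ij <- which(pg$log_likelihood == max(pg$log_likelihood), arr.ind = TRUE)[1, ]
  expect_equal(unname(pg$mode["shape"]), pg$shape_grid[ij[1]])
  expect_equal(unname(pg$mode["scale"]), pg$scale_grid[ij[2]])
  # posterior mass concentrates with sample size
  sizes <- c(100, 1000, 10000)
  areas <- vapply(sizes, function(n) {
    credible_region_size(grid_posterior(gen_catastrophe_times(n = n,
                                                              seed = 25)))
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("posterior mode recovers the generating parameters within one grid cell", {
  d <- gen_catastrophe_times(shape = 3.6, scale = 35, window = c(10, 400),
                             n = 1e4, seed = 1)
  pg <- grid_posterior(d, truncated = TRUE)
  expect_lte(abs(pg$mode["shape"] - 3.6), 0.05 + 1e-9)
  expect_lte(abs(pg$mode["scale"] - 35), 1 + 1e-9)
})

test_that("exponential catastrophe data put the posterior mode at the N = 1 grid edge", {
  set.seed(26)
  t <- rexp(500, 1 / 80)
  d <- catastrophe_dataset(t)
  pg <- grid_posterior(d)
  expect_equal(unname(pg$mode["shape"]), 1)
})

test_that("the informative prior pulls small samples toward the anchor and washes out with data", {
  prior <- build_informative_prior(mal3_anchor_loglik(n = 200, seed = 1))
  anchor_mode <- c(3.6, 35)
  d10 <- gen_catastrophe_times(shape = 6, scale = 20, window = c(10, 400),
                               n = 10, seed = 27)
  m_flat <- grid_posterior(d10)$mode
  m_info <- grid_posterior(d10, prior = prior)$mode
  dist <- function(m) sqrt(((m["shape"] - anchor_mode[1]) / 0.05)^2 +
                             ((m["scale"] - anchor_mode[2]) / 1)^2)
  expect_lt(dist(m_info), dist(m_flat))
  dbig <- gen_catastrophe_times(shape = 6, scale = 20, window = c(10, 400),
                                n = 1e4, seed = 28)
  mb_flat <- grid_posterior(dbig)$mode
  mb_info <- grid_posterior(dbig, prior = prior)$mode
  expect_lte(abs(mb_flat["shape"] - mb_info["shape"]), 0.05 + 1e-9)
  expect_lte(abs(mb_flat["scale"] - mb_info["scale"]), 1 + 1e-9)
})

test_that("truncated fit check separates the generating model from a shifted one", {
  d <- gen_catastrophe_times(n = 300, seed = 29)
  ok <- truncated_fit_check(d, 3.6, 35, n_boot = 199, seed = 30)
  expect_lt(ok$ks, 0.1)
  expect_gt(ok$p_value, 0.05)
  shifted <- catastrophe_dataset(d$times + 3 * 35,
                                 window = d$window + 3 * 35)
  bad <- truncated_fit_check(shifted, 3.6, 35, n_boot = 199, seed = 30)
  expect_gt(bad$ks, ok$ks)
  expect_lt(bad$p_value, 0.01)
})

test_that("the parametric bootstrap p value is calibrated under the null", {
  set.seed(31)
  rejections <- 0L
  nrep <- 100
  for (i in seq_len(nrep)) {
    d <- gen_catastrophe_times(n = 100, seed = 4000 + i)
    fc <- truncated_fit_check(d, 3.6, 35, n_boot = 99, seed = 5000 + i)
    if (fc$p_value <= 0.05) rejections <- rejections + 1L
  }
  expect_lt(abs(rejections / nrep - 0.05), 0.031)
})
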