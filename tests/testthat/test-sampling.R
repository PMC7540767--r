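n_check <- 2e5  # large enough for tight moment checks, fast enough for CI

fam_draws <- list(
  uncorrelated = function(n, seed) sample_uncorrelated(n, seed = seed),
  correlated_product = function(n, seed) {
    sample_correlated_product(n, seed = seed)
  },
  steepness_scaled = function(n, seed) {
    sample_steepness_scaled(n, slope_target = 0.005, seed = seed)
  },
  truncated_bvn = function(n, seed) {
    sample_truncated_bvn(n, rho = 0.7, seed = seed)
  }
)

test_that("every family respects bounds, normalization and reproducibility", {
  for (nm in names(fam_draws)) {
    s <- fam_draws[[nm]](n_check, seed = 101)
    expect_true(all(s$gamma >= 0 & s$gamma <= 1), info = nm)
    expect_true(all(s$omega >= 1e-4 - 1e-12 & s$omega <= 1), info = nm)
    # marginal expectations shared across families: <gamma> = 0.5 and
    # <log10 omega> = -2, checked within 4 standard errors
    se_g <- sd(s$gamma) / sqrt(n_check)
    se_w <- sd(log10(s$omega)) / sqrt(n_check)
    expect_lt(abs(mean(s$gamma) - 0.5), 4 * se_g, label = nm)
    expect_lt(abs(mean(log10(s$omega)) + 2), 4 * se_w, label = nm)
    # identical seed, identical draws; the caller's RNG state is restored
    expect_identical(s, fam_draws[[nm]](n_check, seed = 101))
    expect_identical(nrow(fam_draws[[nm]](0, seed = 1)), 0L)
  }
})

test_that("uncorrelated draws are uncorrelated, correlated families are not", {
  s0 <- sample_uncorrelated(n_check, seed = 7)
  expect_lt(abs(cor(s0$gamma, log10(s0$omega))), 0.01)
  # at the shallow default steepness the correlation is small but must be
  # decisively positive (its magnitude is ~steepness, se ~ 1/sqrt(n))
  s1 <- sample_correlated_product(n_check, seed = 7)
  expect_gt(cor(s1$gamma, log10(s1$omega)), 4 / sqrt(n_check))
  s1b <- sample_correlated_product(n_check, steepness = 0.5, seed = 7)
  expect_gt(cor(s1b$gamma, log10(s1b$omega)), 0.3)
  s2 <- sample_truncated_bvn(n_check, rho = 0.7, seed = 7)
  expect_gt(cor(s2$gamma, log10(s2$omega)), 0.4)
})

test_that("fit_slope recovers exact lines and flags degeneracy", {
  w <- 10^seq(-4, 0, length.out = 20)
  s <- strain_params(0.1 * log10(w) + 0.9, w)
  expect_equal(unname(fit_slope(s)), c(0.1, 0.9), tolerance = 1e-12)
  flat <- strain_params(rep(0.4, 10), 10^seq(-3, -1, length.out = 10))
  expect_equal(unname(fit_slope(flat)[1]), 0, tolerance = 1e-12)
  expect_error(fit_slope(strain_params(c(0.2, 0.8), c(0.01, 0.01))),
               "identical")
  # independence implies zero slope
  s0 <- sample_uncorrelated(n_check, seed = 12)
  a <- fit_slope(s0)[["a"]]
  se <- sd(s0$gamma) / (sd(log10(s0$omega)) * sqrt(n_check))
  expect_lt(abs(a), 4 * se)
})

test_that("correlated product realises the configured slope", {
  for (k in c(0.2, 0.8)) {
    s <- sample_correlated_product(n_check, steepness = k, seed = 3)
    expect_equal(fit_slope(s)[["a"]], k / 4, tolerance = 0.05)
  }
  # the shallow default slope is resolved against its standard error
  s <- sample_correlated_product(n_check, seed = 3)
  se <- sd(s$gamma) / (sd(log10(s$omega)) * sqrt(n_check))
  expect_lt(abs(fit_slope(s)[["a"]] - default_steepness() / 4), 4 * se)
  expect_error(sample_correlated_product(10, steepness = 1.2), "steepness")
})

test_that("steepness scaling hits the slope target and preserves the mean", {
  # identity scaling reproduces the unscaled family draw for draw
  s_id <- sample_steepness_scaled(5000, slope_target = 0.05,
                                  steepness = 0.2, seed = 5)
  s_cp <- sample_correlated_product(5000, steepness = 0.2, seed = 5)
  expect_equal(s_id$gamma, s_cp$gamma, tolerance = 1e-12)
  expect_equal(s_id$omega, s_cp$omega, tolerance = 1e-12)
  # shallower trade-offs: slope matches the target, gamma contracts to 1/2
  for (tgt in c(0.1, 0.02)) {
    s <- sample_steepness_scaled(n_check, slope_target = tgt,
                                 steepness = 0.8, seed = 5)
    expect_equal(fit_slope(s)[["a"]], tgt, tolerance = 0.05)
    expect_equal(mean(s$gamma), 0.5, tolerance = 0.01)
  }
  s0 <- sample_steepness_scaled(1000, slope_target = 0, seed = 5)
  expect_true(all(abs(s0$gamma - 0.5) < 1e-12))
  expect_error(sample_steepness_scaled(10, slope_target = 1,
                                       steepness = 0.2), "slope_target")
})

test_that("degenerate truncated normal lies exactly on the diagonal", {
  s <- sample_truncated_bvn(5000, rho = 1, seed = 9)
  expect_equal(s$gamma, 0.5 + (log10(s$omega) + 2) / 4, tolerance = 1e-12)
  s0 <- sample_truncated_bvn(n_check, rho = 0, seed = 9)
  expect_lt(abs(cor(s0$gamma, log10(s0$omega))), 0.01)
  expect_error(sample_truncated_bvn(10, rho = 1.5), "rho")
})

test_that("sampler closures draw from the ambient RNG stream", {
  draw <- make_sampler("correlated_product")
  set.seed(42)
  a <- draw(5)
  set.seed(42)
  b <- draw(5)
  expect_identical(a, b)
  expect_error(make_sampler("truncated_bvn"), "rho")
  expect_error(make_sampler("steepness_scaled"), "slope_target")
})
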