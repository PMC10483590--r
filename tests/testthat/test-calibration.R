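test_that("reference intensities cover all four modes", {
  expect_equal(reference_intensity(c(4, 6), mode = "inclusive_mean"), 5)
  expect_equal(reference_intensity(c(4, 6), member = 1, mode = "exclusive_mean"), 6)
  expect_equal(reference_intensity(c(4, 6), mode = "max"), 6)
  expect_true(is.na(reference_intensity(5, mode = "exclusive_mean")))
  expect_equal(reference_intensity(c(4, 6), mode = "weighted_mean", sigmas = c(1, 2)),
               (4 / 1 + 6 / 4) / (1 + 1 / 4))
})

test_that("normalized deviations: pair signature, singleton zero, plain arithmetic", {
  gs <- make_groups(list(c(4, 6)))
  sig <- model1_assign(gs, build_esu_lookup(make_groups(list(c(4, 6)),
                                                        d_star = list(0.3))))
  d <- normalized_deviations(gs, sigma = sig)
  expect_equal(sort(d), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  g1 <- make_groups(list(42))
  expect_equal(as.numeric(normalized_deviations(g1)), 0)
  expect_false(attr(normalized_deviations(g1), "usable"))

  g3 <- make_groups(list(c(2, 4, 9)))
  d3 <- normalized_deviations(g3, sigma = rep(1, 3))
  expect_equal(sort(d3), c(-3, -1, 4))

  expect_error(normalized_deviations(gs, sigma = c(0, 1)), "positive")
})

test_that("theoretical quantiles are antisymmetric inverse-normal plotting positions", {
  expect_equal(theoretical_quantiles(1), 0)
  expect_equal(theoretical_quantiles(3), c(qnorm(1 / 6), 0, qnorm(5 / 6)),
               tolerance = 1e-12)
  expect_equal(round(theoretical_quantiles(3), 5), c(-0.96742, 0, 0.96742))
  for (n in c(2, 7, 100)) {
    q <- theoretical_quantiles(n)
    expect_true(all(diff(q) > 0))
    expect_equal(q + rev(q), rep(0, n), tolerance = 1e-12)
  }
  q2 <- theoretical_quantiles(4, rule = "expected")
  expect_equal(q2, qnorm((1:4) / 5), tolerance = 1e-12)
  expect_error(theoretical_quantiles(0), ">= 1")
})

test_that("Tukey fences match a brute-force oracle and respect the pair rule", {
  fl <- tukey_outliers(c(1:9, 100))
  expect_equal(which(fl), 10L)
  expect_false(any(tukey_outliers(c(1:9, 100), k = 1e6)))
  expect_warning(f3 <- tukey_outliers(c(1, 2, 3)), "fewer")
  expect_false(any(f3))

  set.seed(17)
  for (i in 1:30) {
    x <- c(rnorm(sample(6:60, 1)), rnorm(2, 0, 12))
    k <- runif(1, 0.5, 3)
    qs <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    oracle <- x < qs[1] - k * diff(qs) | x > qs[2] + k * diff(qs)
    expect_equal(tukey_outliers(x, k), oracle)
    # affine invariance
    a <- runif(1, 0.1, 5); b <- rnorm(1, 0, 10)
    expect_equal(tukey_outliers(a * x + b, k), oracle)
  }

  # one member of a two-equivalent group flagged drags its partner
  deltas <- c(-5, 0.1, 0.2, -0.1, 0.3, 0)
  gid <- c(1L, 1L, 2L, 2L, 3L, 3L)
  fl2 <- tukey_outliers(deltas, 1.5, gid)
  expect_true(all(fl2[gid == 1L]))
  expect_false(any(fl2[gid != 1L]))
})

test_that("supercycle minimization never worsens the misfit from its start", {
  sim <- simulate_reflections(synthetic_spec(n_groups = 400, seed = 5))
  g <- group_equivalents(sim$measurements, identity_sym())
  far <- error_model_params(4, 0, 0)
  f1 <- fit_error_model(g, "inclusive_mean",
                        calibration_config(init = far, max_supercycles = 1))
  f12 <- fit_error_model(g, "inclusive_mean",
                         calibration_config(init = far, max_supercycles = 12))
  expect_lte(f12$D, f1$D + 1e-9)
  expect_equal(f12$D, sum((f12$deltas_sorted - f12$quantiles)^2), tolerance = 1e-9)
  expect_true(!is.unsorted(f12$deltas_sorted))
})

test_that("the fit recovers moderate generating parameters", {
  tp <- error_model_params(1.3, 10, 0.05)
  sim <- simulate_reflections(synthetic_spec(n_groups = 2000, true_params = tp,
                                             seed = 21))
  g <- group_equivalents(sim$measurements, identity_sym())
  f <- fit_error_model(g, "inclusive_mean")
  expect_lt(abs(f$params$s_fac - 1.3) / 1.3, 0.1)
  expect_lt(abs(f$params$s_b - 10), 0.05 * 1000)
  expect_lt(f$params$s_add, 0.1)
})

test_that("calibration is a fixed point of another fit/reject round", {
  sim <- simulate_reflections(synthetic_spec(n_groups = 800, seed = 6,
                                             outlier_fraction = 0.03))
  g <- group_equivalents(sim$measurements, identity_sym())
  fit <- esu_calibrate(g, model = 2)
  expect_true(fit$converged)
  again <- esu_calibrate(g, model = 2,
                         config = calibration_config(init = fit$params))
  expect_equal(sum(again$outlier_flags), sum(fit$outlier_flags),
               tolerance = 0.01 * max(1, sum(fit$outlier_flags)))
  expect_equal(coef(again), coef(fit), tolerance = 0.05)
})

test_that("calibration object methods expose the fit coherently", {
  sim <- simulate_reflections(synthetic_spec(n_groups = 400, seed = 9))
  g <- group_equivalents(sim$measurements, identity_sym())
  fit <- esu_calibrate(g, model = 3)
  expect_s3_class(fit, "esu_calibration")
  expect_named(coef(fit), c("s_fac", "s_B", "s_add"))
  expect_output(print(fit), "model 3")
  expect_output(print(summary(fit)), "unique reflections")
  expect_length(residuals(fit), fit$n_used)
  pr <- predict(fit)
  expect_length(pr, nrow(g$measurements))
  expect_true(all(pr > 0))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
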