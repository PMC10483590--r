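test_that("sample standard deviation uses Bessel's correction", {
  expect_equal(sample_std(c(4, 6)), sqrt(2), tolerance = 1e-12)
  expect_equal(sample_std(c(5, 5, 5)), 0)
  expect_equal(sample_std(1:4), 1.29099, tolerance = 1e-5)
  expect_error(sample_std(7), "two")
  # brute-force two-pass oracle
  set.seed(3)
  for (i in 1:25) {
    x <- rnorm(sample(2:40, 1), sd = runif(1, 0.1, 50))
    oracle <- sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1))
    expect_equal(sample_std(x), oracle, tolerance = 1e-12)
  }
})

test_that("lookup table bins by intensity decile and 0.2/A resolution shells", {
  # 20 pairs with constant scatter -> every populated cell equals that e.s.u.
  set.seed(5)
  base <- seq(10, 2000, length.out = 20)
  gs <- make_groups(lapply(base, function(b) c(b - 1.5, b + 1.5)),
                    d_star = as.list(runif(20, 0.1, 1.5)))
  tab <- build_esu_lookup(gs)
  expect_s3_class(tab, "esu_lookup")
  expect_equal(tab$n_reflections, 20L)
  vals <- tab$cell[!is.na(tab$cell)]
  expect_equal(vals, rep(sample_std(c(-1.5, 1.5)), length(vals)), tolerance = 1e-12)
  # a cell with a single member reports that member's e.s.u.
  g1 <- make_groups(list(c(4, 6), c(96, 104)), d_star = list(0.1, 1.3))
  t1 <- build_esu_lookup(g1)
  expect_true(any(abs(t1$cell - sample_std(c(96, 104))) < 1e-12, na.rm = TRUE))
  # all-singleton input is not usable
  expect_error(build_esu_lookup(make_groups(list(5, 7))), "n = 1")
})

test_that("model 1 assigns group sample deviations and lookup values for singles", {
  gs <- make_groups(list(c(4, 6), c(100, 104), 55),
                    d_star = list(0.3, 0.35, 0.32))
  sig <- model1_assign(gs)
  m <- gs$measurements
  pair1 <- which(gs$groups$n[m$group] == 2L & m$intensity %in% c(4, 6))
  expect_equal(sig[pair1], rep(sqrt(2), 2), tolerance = 1e-12)
  # the n=1 reflection at intensity 55 sits above the midpoint between the
  # two pair means (53.5), so it draws from the (100,104) decile's cell
  single <- which(gs$groups$n[m$group] == 1L)
  expect_equal(sig[single], sample_std(c(100, 104)), tolerance = 1e-12)
})

test_that("model 1 falls back to the nearest populated resolution bin", {
  # two pairs in the same intensity range but distant resolution shells,
  # plus a single at an empty shell in between
  gs <- make_groups(list(c(9, 11), c(8.5, 11.5), 10),
                    d_star = list(0.1, 1.5, 0.75))
  tab <- build_esu_lookup(gs)
  sig <- model1_assign(gs, tab)
  single <- which(gs$groups$n[gs$measurements$group] == 1L)
  # nearest populated shell (either side) supplies the value
  expect_true(sig[single] %in% c(sample_std(c(9, 11)), sample_std(c(8.5, 11.5))))
})

test_that("three-parameter correction evaluates and clamps negative references", {
  expect_equal(corrected_sigma(2, 10, error_model_params(1, 0, 0)), 2)
  expect_equal(corrected_sigma(0, 4, error_model_params(2, 1, 0.5)), 5.65685,
               tolerance = 1e-5)
  expect_equal(corrected_sigma(1, 6, error_model_params(1, 1, 0)), sqrt(7),
               tolerance = 1e-12)
  # negative reference: linear term clamps to zero, quadratic survives
  expect_equal(corrected_sigma(1, -10, error_model_params(1, 5, 0.2)),
               sqrt(1 + 4), tolerance = 1e-12)
  expect_error(error_model_params(0, 0, 0), "positive")
  expect_error(error_model_params(1, -1, 0), "non-negative")
  # monotone nondecreasing in each parameter and in sigma
  set.seed(8)
  for (i in 1:20) {
    s <- runif(1, 0, 5); I <- runif(1, 0, 500)
    p <- runif(3, c(0.2, 0, 0), c(3, 20, 0.3))
    base <- corrected_sigma(s, I, error_model_params(p[1], p[2], p[3]))
    expect_gte(corrected_sigma(s, I, error_model_params(p[1] * 1.1, p[2], p[3])), base)
    expect_gte(corrected_sigma(s, I, error_model_params(p[1], p[2] + 1, p[3])), base)
    expect_gte(corrected_sigma(s, I, error_model_params(p[1], p[2], p[3] + 0.05)), base)
    expect_gte(corrected_sigma(s * 1.1, I, error_model_params(p[1], p[2], p[3])), base)
  }
})

test_that("apply_error_model honours the model contracts", {
  gs <- make_groups(list(c(4, 6), c(7, 7)), sigmas = list(c(1, 1), c(2, 2)))
  # model 0: identity
  g0 <- apply_error_model(gs, 0)
  expect_equal(g0$measurements$sigma_adj, gs$measurements$sigma)
  # identical member intensities: models 2 and 3 agree
  p <- error_model_params(1.3, 2, 0.1)
  g2 <- apply_error_model(gs, 2, p)
  g3 <- apply_error_model(gs, 3, p)
  eq <- gs$measurements$intensity == 7
  expect_equal(g2$measurements$sigma_adj[eq], g3$measurements$sigma_adj[eq])
  # worked pair: sigma=1, p=(1,1,0): mean ref sqrt(6), max ref sqrt(7)
  p110 <- error_model_params(1, 1, 0)
  s2 <- apply_error_model(gs, 2, p110)$measurements$sigma_adj
  s3 <- apply_error_model(gs, 3, p110)$measurements$sigma_adj
  pair <- gs$measurements$intensity %in% c(4, 6)
  expect_equal(s2[pair], rep(sqrt(6), 2), tolerance = 1e-12)
  expect_equal(s3[pair], rep(sqrt(7), 2), tolerance = 1e-12)
  # intensities never modified; params mandatory for 2/3
  expect_equal(g2$measurements$intensity, gs$measurements$intensity)
  expect_error(apply_error_model(gs, 2), "require")
  # model 3 e.s.u. >= model 2 e.s.u. whenever intensities are non-negative
  set.seed(13)
  for (i in 1:10) {
    gr <- make_groups(list(abs(rnorm(4, 100, 40)), abs(rnorm(3, 20, 10))))
    pp <- error_model_params(runif(1, 0.5, 2), runif(1, 0, 5), runif(1, 0, 0.2))
    a2 <- apply_error_model(gr, 2, pp)$measurements$sigma_adj
    a3 <- apply_error_model(gr, 3, pp)$measurements$sigma_adj
    expect_true(all(a3 >= a2 - 1e-12))
  }
})
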