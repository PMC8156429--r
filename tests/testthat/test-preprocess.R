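test_that("MSC reference is the per-band training mean", {
  s <- runif(20, 0.2, 0.8)
  expect_equal(msc_fit(matrix(s, 1))$reference_spectrum, s)
  expect_equal(msc_fit(rbind(s, 3 * s))$reference_spectrum, 2 * s)
  set.seed(2)
  S <- matrix(runif(50 * 24), 50, 24)
  oracle <- vapply(seq_len(24), function(j) sum(S[, j]) / 50, numeric(1))
  expect_equal(msc_fit(S)$reference_spectrum, oracle, tolerance = 1e-12)
  expect_error(msc_fit(S[0, , drop = FALSE]), ">= 1")
})

test_that("MSC correction removes affine scatter exactly", {
  set.seed(3)
  ref <- msc_fit(matrix(runif(4 * 40, 0.2, 0.8), 4, 40))
  r <- ref$reference_spectrum
  expect_equal(msc_apply(r, ref), r, tolerance = 1e-12)
  expect_equal(msc_apply(2 * r + 3, ref), r, tolerance = 1e-10)
  # post-correction OLS against the reference has slope 1, intercept 0
  s <- 1.4 * r + 0.2 + rnorm(40, 0, 0.05)
  corr <- msc_apply(s, ref)
  fit <- coef(lm(corr ~ r))
  rc <- r - mean(r)
  slope_oracle <- sum(rc * (corr - mean(corr))) / sum(rc^2)
  expect_equal(unname(fit[2]), 1, tolerance = 1e-10)
  expect_equal(unname(fit[1]), 0, tolerance = 1e-10)
  expect_equal(slope_oracle, 1, tolerance = 1e-10)
})

test_that("MSC is idempotent and rejects degenerate spectra", {
  set.seed(5)
  ref <- msc_fit(matrix(runif(6 * 30, 0.2, 0.8), 6, 30))
  s <- runif(30)
  once <- msc_apply(s, ref)
  expect_equal(msc_apply(once, ref), once, tolerance = 1e-10)
  flat <- rep(0.5, 30)   # zero slope against any non-constant reference
  expect_error(msc_apply(flat, ref), "degenerate-spectrum")
})

test_that("min-max normalization maps to [0,1] and is affine-invariant", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(6)
  s <- rnorm(50)
  n1 <- minmax_normalize(s)
  expect_equal(min(n1), 0)
  expect_equal(max(n1), 1)
  expect_equal(minmax_normalize(3.2 * s + 7), n1, tolerance = 1e-12)
  expect_true(all(diff(order(s)) == diff(order(n1))))  # order-preserving
  expect_error(minmax_normalize(rep(1, 10)), "degenerate-range")
})

test_that("Savitzky-Golay reproduces polynomials and matches the oracle", {
  cfg1 <- preprocess_config("SG", 15, 2, 1)
  cfg0 <- preprocess_config("SG", 15, 2, 0)
  # constant -> zero derivative everywhere (edges included)
  expect_equal(savitzky_golay(rep(4.2, 60), cfg1), rep(0, 60))
  # quadratic s(i) = i^2 -> derivative 2i, exact at every band because the
  # local quadratic model is exact even on truncated edge windows
  i <- 0:59
  expect_equal(savitzky_golay(i^2, cfg1), 2 * i, tolerance = 1e-8)
  # smoothing reproduces any quadratic exactly
  q <- 3 + 0.5 * i - 0.02 * i^2
  expect_equal(savitzky_golay(q, cfg0), q, tolerance = 1e-8)
  # random spectra vs per-band brute-force local fits
  set.seed(7)
  S <- matrix(rnorm(20 * 80), 20, 80)
  for (cfg in list(cfg0, cfg1)) {
    expect_lt(max(abs(savitzky_golay(S, cfg) -
                      sg_brute_force(S, 15, 2, cfg$sg_deriv))), 1e-8)
  }
})

test_that("Savitzky-Golay is linear and validates its config", {
  cfg <- preprocess_config("SG", 11, 2, 1)
  set.seed(8)
  s1 <- rnorm(40); s2 <- rnorm(40)
  expect_equal(savitzky_golay(2 * s1 - 3 * s2, cfg),
               2 * savitzky_golay(s1, cfg) - 3 * savitzky_golay(s2, cfg),
               tolerance = 1e-10)
  expect_error(savitzky_golay(rnorm(9), preprocess_config("SG", 15, 2, 1)),
               "exceeds")
  expect_error(preprocess_config("SG", 14, 2, 1), "odd")
  expect_error(preprocess_config("SG", 3, 3, 1), "odd and greater")
  expect_error(preprocess_config("SG", 15, 0, 1), "exceed")
})

test_that("Savitzky-Golay agrees with signal::sgolayfilt on interior bands", {
  set.seed(30)
  s <- rnorm(80)
  for (m in 0:1) {
    mine <- savitzky_golay(s, preprocess_config("SG", 15, 2, m))
    ref <- signal::sgolayfilt(s, p = 2, n = 15, m = m)
    # edge conventions differ by design; interior bands must agree
    expect_lt(max(abs(mine[8:73] - ref[8:73])), 1e-12)
  }
})

test_that("apply_preprocessing dispatches one method with provenance", {
  ds <- tiny_dataset(n = 6, B = 40)
  norm <- apply_preprocessing(ds, preprocess_config("NORM"))
  expect_equal(unname(apply(norm$spectra, 1, min)), rep(0, 6))
  expect_equal(unname(apply(norm$spectra, 1, max)), rep(1, 6))
  expect_identical(norm$references, ds$references)
  expect_equal(norm$preprocessing$method, "NORM")

  sg <- apply_preprocessing(ds, preprocess_config("SG"))
  expect_equal(dim(sg$spectra), dim(ds$spectra))

  cfg <- preprocess_config("MSC")
  expect_error(apply_preprocessing(ds, cfg), "state error")
  fitted <- fit_preprocessing(ds, cfg)
  msc <- apply_preprocessing(ds, cfg, fitted)
  expect_equal(msc$preprocessing$fitted_state$reference_spectrum,
               colMeans(ds$spectra))
})

test_that("MSC fit on train transfers to held-out spectra", {
  set.seed(10)
  base <- runif(50, 0.3, 0.7)
  train <- t(replicate(30, exp(rnorm(1, 0, 0.1)) * base + rnorm(1, 0, 0.02)))
  held <- t(replicate(10, exp(rnorm(1, 0, 0.1)) * base + rnorm(1, 0, 0.02)))
  ref <- msc_fit(train)
  corr <- msc_apply(held, ref)
  r <- ref$reference_spectrum
  slopes <- apply(corr, 1, function(s) coef(lm(s ~ r))[2])
  expect_equal(unname(slopes), rep(1, 10), tolerance = 1e-8)
})
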