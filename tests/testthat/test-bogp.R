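test_that("unit-cube encoding maps bounds to 0/1 and round-trips", {
  sp <- hyperparam_space()
  lo <- decode_hp(rep(0, nrow(sp)))
  expect_equal(encode_hp(lo)[["filters1"]], 0)
  expect_equal(lo$filters1, 5L)
  hi <- decode_hp(rep(1, nrow(sp)))
  expect_equal(unname(encode_hp(hi)), rep(1, nrow(sp)))
  set.seed(19)
  int_dims <- sp$name[sp$integer]
  for (i in 1:100) {
    hp <- decode_hp(runif(nrow(sp)))
    back <- decode_hp(encode_hp(hp))
    expect_identical(back[int_dims], hp[int_dims])
    expect_equal(unclass(back), unclass(hp), tolerance = 1e-12)
  }
  bad <- small_hp()
  bad$filters1 <- 300L   # outside the space, bypassing the constructor
  expect_error(encode_hp(bad), "outside the search space")
})

test_that("noiseless GP posterior interpolates its observations", {
  set.seed(20)
  X <- matrix(runif(16), 8, 2)
  y <- sin(3 * X[, 1]) + X[, 2]^2
  gp <- gp_fit(X, y, noise = 1e-8)
  p <- gp_predict(gp, X)
  expect_lt(max(abs(p$mean - y)), 1e-6)
  # variance at observed points below variance far away
  far <- matrix(rep(0.987, 2), 1)
  expect_lt(max(p$sd), gp_predict(gp, far)$sd + 1e-12)
  expect_error(gp_fit(X[1, , drop = FALSE], y[1]), "at least 2")
  expect_error(gp_fit(X[c(1, 1), ], y[c(1, 1)]), "conditioning error")
})

test_that("GP recovers a 1-d sine from 12 points", {
  set.seed(21)
  X <- matrix(seq(0, 1, length.out = 12), ncol = 1)
  f <- function(x) sin(2 * pi * x)
  gp <- gp_fit(X, f(X[, 1]), noise = 1e-8)
  grid <- matrix(seq(0, 1, length.out = 200), ncol = 1)
  pred <- gp_predict(gp, grid)
  err <- sqrt(mean((pred$mean - f(grid[, 1]))^2))
  expect_lt(err, sd(f(grid[, 1])))   # far below the prior-std baseline
  expect_lt(err, 0.05)
})

test_that("expected improvement matches its closed-form limits and MC", {
  set.seed(22)
  X <- matrix(runif(10), 5, 2)
  y <- X[, 1] + X[, 2]
  gp <- gp_fit(X, y, noise = 1e-8)
  best <- min(y)
  # at an observed non-best point EI is ~0
  worst <- which.max(y)
  expect_lt(expected_improvement(gp, X[worst, ], best), 1e-6)
  expect_true(all(expected_improvement(gp, matrix(runif(40), 20, 2), best)
                  >= 0))
  # deterministic limit: sd -> 0, mu = best - xi - delta -> EI = delta
  expect_equal(ei_moments(mu = 1 - 0.01 - 0.3, sd = 0, best_so_far = 1,
                          xi = 0.01), 0.3)
  expect_error(ei_moments(0, -1, 0), "invariant violation")
  # Monte-Carlo oracle: E[max(f* - xi - Y, 0)], Y ~ N(mu, sd^2)
  mu <- 0.5; sdv <- 0.3; bst <- 0.4; xi <- 0.01
  set.seed(1)
  draws <- pmax(bst - xi - rnorm(1e6, mu, sdv), 0)
  expect_lt(abs(ei_moments(mu, sdv, bst, xi) - mean(draws)),
            3 * sd(draws) / sqrt(1e6))
})

test_that("proposals maximize EI over random references deterministically", {
  set.seed(23)
  sp <- hyperparam_space()[1:2, ]
  X <- matrix(c(0.2, 0.8, 0.5, 0.4, 0.9, 0.1), 3, 2)
  y <- c(0.5, 0.2, 0.9)
  gp <- gp_fit(X, y)
  set.seed(7)
  prop <- propose_next(gp, sp, best_so_far = min(y), evaluated = X)
  refs <- matrix(runif(2000), 1000, 2)
  expect_gte(prop$ei + 1e-12,
             max(expected_improvement(gp, refs, min(y))))
  # proposal avoids already-evaluated points
  expect_false(any(apply(X, 1, function(u)
    isTRUE(all.equal(unname(encode_hp(prop$hp, sp)), u)))))
  set.seed(7)
  prop2 <- propose_next(gp, sp, best_so_far = min(y), evaluated = X)
  expect_identical(prop$u, prop2$u)
})

test_that("the optimizer traces, improves monotonically and handles failures", {
  sp <- hyperparam_space()[1:2, ]
  obj <- function(hp) {
    u <- encode_hp(hp, sp)
    (u[1] - 0.3)^2 + (u[2] - 0.7)^2
  }
  res <- bogp_optimize(obj, sp, n_random = 5, n_gp_iter = 5, seed = 33,
                       n_candidates = 500)
  expect_lte(nrow(res$trace), 10)
  expect_equal(res$best_objective, min(res$trace$objective))
  expect_identical(res$trace$phase, rep(c("random", "gp"), c(5, 5)))
  run_min <- cummin(res$trace$objective)
  expect_true(all(diff(run_min) <= 0))
  # deterministic trace under the same seed
  res2 <- bogp_optimize(obj, sp, n_random = 5, n_gp_iter = 5, seed = 33,
                        n_candidates = 500)
  expect_identical(res$trace, res2$trace)
  # failures get a penalty and stay out of the incumbent
  flaky <- function(hp) {
    u <- encode_hp(hp, sp)
    if (u[1] > 0.5) stop("boom") else u[1]
  }
  resf <- bogp_optimize(flaky, sp, n_random = 6, n_gp_iter = 2, seed = 2,
                        n_candidates = 200)
  expect_true(any(resf$trace$failed))
  expect_false(resf$trace$failed[which.min(resf$trace$objective)])
  always_fail <- function(hp) stop("nope")
  expect_error(bogp_optimize(always_fail, sp, n_random = 3, n_gp_iter = 0,
                             seed = 1), "optimization error")
})
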