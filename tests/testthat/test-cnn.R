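test_that("hyperparameter ranges are validated", {
  expect_s3_class(small_hp(), "hyperparams")
  expect_error(small_hp(kernel1 = 200L), "validation error")
  expect_error(small_hp(filters1 = 2L), "validation error")
  expect_error(small_hp(lr = 0.2), "validation error")
  expect_error(small_hp(dropout1 = 0.05), "validation error")
})

test_that("pooling shape law holds: flatten = floor(floor(B/2)/5) * filters2", {
  expect_equal(1040 %/% 2, 520)
  expect_equal(520 %/% 5, 104)
  expect_equal(flatten_length(1040, 60), 6240)
  set.seed(12)
  sp <- hyperparam_space()
  for (i in 1:50) {
    hp <- decode_hp(runif(nrow(sp)))
    B <- sample(10:1200, 1)
    m <- build_model(hp, B, seed = 1)
    expect_equal(ncol(m$params$W3), ((B %/% 2) %/% 5) * hp$filters2)
  }
})

test_that("parameter counts match the layer-by-layer closed form", {
  # hand-computed oracle for a minimal configuration
  hp <- hyperparams(filters1 = 5, kernel1 = 3, filters2 = 5, kernel2 = 3,
                    neurons = 4, dropout1 = 0.1, dropout2 = 0.1,
                    lr = 0.02, batch_size = 8)
  m <- build_model(hp, 10, seed = 1)
  flat <- 1 * 5                      # floor(floor(10/2)/5) = 1 position
  oracle <- (3 * 1 * 5 + 5) + 4 * 5 +       # conv1 + bn1
            (3 * 5 * 5 + 5) + 4 * 5 +       # conv2 + bn2
            (flat * 4 + 4) + (4 + 1)        # dense + output
  expect_equal(count_parameters(m), oracle)
  # counting the actual weight arrays agrees (bn running stats included)
  actual <- sum(vapply(m$params, length, numeric(1)))
  expect_equal(actual, oracle)
  # adding neurons changes the count by flatten_len + 1 + 1 per neuron
  m2 <- build_model(hyperparams(filters1 = 5, kernel1 = 3, filters2 = 5,
                                kernel2 = 3, neurons = 5, dropout1 = 0.1,
                                dropout2 = 0.1, lr = 0.02, batch_size = 8),
                    10, seed = 1)
  expect_equal(count_parameters(m2) - count_parameters(m), flat + 1 + 1)
  # identical hyperparameters give identical counts
  expect_equal(count_parameters(build_model(hp, 10, seed = 9)),
               count_parameters(m))
})

test_that("a small network memorizes an 8-sample set", {
  set.seed(42)
  B <- 64
  X <- matrix(runif(8 * B), 8, B)
  y <- rowSums(X[, 1:5]) * 3 + 10
  m <- build_model(small_hp(lr = 0.06), B, seed = 1)
  m <- train(m, list(x = X, y = y), list(x = X, y = y),
             train_config(4000, 3999, seed = 2))
  expect_lt(min(m$history$train_mse), 1e-2 * m$history$train_mse[1])
  # predictions on the memorized inputs are close to the targets
  expect_lt(rmse(predict(m, X), y), 0.35 * sd(y))
  # duplicated inputs give duplicated outputs
  p <- predict(m, X[c(1, 1, 2), ])
  expect_identical(p[1], p[2])
  # wrong band count is a shape error
  expect_error(predict(m, X[, 1:32]), "shape error")
})

test_that("early stopping halts and reports the validation minimum", {
  set.seed(14)
  B <- 32
  X <- matrix(runif(40 * B), 40, B)
  y <- rowMeans(X) * 10
  Xv <- matrix(runif(12 * B), 12, B)
  yv <- rowMeans(Xv) * 10
  m <- build_model(small_hp(batch_size = 16L), B, seed = 3)
  m <- train(m, list(x = X, y = y), list(x = Xv, y = yv),
             train_config(400, 5, seed = 3))
  expect_lt(m$stopped_epoch, 400)              # patience triggered
  expect_equal(m$best_epoch, which.min(m$history$val_mse))
  expect_equal(nrow(m$history), m$stopped_epoch)
})

test_that("training is reproducible under a fixed seed", {
  set.seed(15)
  B <- 32
  X <- matrix(runif(24 * B), 24, B); y <- rowMeans(X) * 10
  run <- function() {
    m <- build_model(small_hp(), B, seed = 5)
    train(m, list(x = X, y = y), list(x = X, y = y),
          train_config(20, 19, seed = 8))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("pretrained initialization preserves predictions exactly", {
  set.seed(16)
  B <- 32
  X <- matrix(runif(30 * B), 30, B); y <- rowMeans(X) * 10
  src <- train(build_model(small_hp(), B, seed = 2),
               list(x = X, y = y), list(x = X, y = y),
               train_config(30, 29, seed = 2))
  fresh <- build_model(small_hp(), B, seed = 99)
  copied <- init_from_pretrained(fresh, src)
  Xnew <- matrix(runif(20 * B), 20, B)
  expect_identical(predict(copied, Xnew), predict(src, Xnew))
  # zero-epoch fine-tune leaves the model unchanged
  ft0 <- fine_tune(copied, list(x = X, y = y), list(x = X, y = y),
                   train_config(0, 0, seed = 1))
  expect_identical(ft0$params, copied$params)
  # architecture mismatch is an incompatibility error
  other <- build_model(small_hp(filters2 = 16L), B, seed = 1)
  expect_error(init_from_pretrained(other, src), "incompatibility")
})

test_that("fine-tuning on a shifted distribution lowers its validation MSE", {
  set.seed(17)
  B <- 32
  X <- matrix(runif(60 * B), 60, B); y <- rowMeans(X) * 10
  src <- train(build_model(small_hp(batch_size = 16L), B, seed = 2),
               list(x = X, y = y), list(x = X, y = y),
               train_config(80, 79, seed = 2))
  # shifted task: same spectra family, offset targets
  Xn <- matrix(runif(40 * B), 40, B); yn <- rowMeans(Xn) * 10 + 4
  before <- mean((predict(src, Xn) - yn)^2)
  ft <- fine_tune(init_from_pretrained(build_model(small_hp(batch_size = 16L),
                                                   B, seed = 3), src),
                  list(x = Xn[1:30, ], y = yn[1:30]),
                  list(x = Xn[31:40, ], y = yn[31:40]),
                  train_config(60, 59, seed = 3))
  after <- mean((predict(ft, Xn[31:40, ]) - yn[31:40])^2)
  expect_lt(after, before)
})

test_that("model artifacts round-trip through disk", {
  set.seed(18)
  ds <- tiny_dataset(n = 12, B = 32)
  cfg <- preprocess_config("SG", 11, 2, 1)
  prepped <- apply_preprocessing(ds, cfg)
  m <- build_model(small_hp(), 32, seed = 4)
  m <- train(m, prepped, prepped, train_config(10, 9, seed = 4))
  stem <- file.path(tempdir(), "model-rt")
  save_model(m, stem)
  m2 <- load_model(stem)
  X <- matrix(runif(5 * 32), 5, 32)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_equal(m2$preprocessing$config$sg_window, 11L)
})
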