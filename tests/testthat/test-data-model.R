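test_that("reflectance calibration satisfies the white/dark identities", {
  B <- 12; P <- 4
  DI <- matrix(10, P, B); SI <- matrix(100, P, B)
  expect_equal(compute_reflectance(raw_frames(SI, DI, SI))$reflectance,
               matrix(1, P, B))
  expect_equal(compute_reflectance(raw_frames(DI, DI, SI))$reflectance,
               matrix(0, P, B))
  GI <- matrix(55, P, B)
  expect_equal(compute_reflectance(raw_frames(GI, DI, SI))$reflectance,
               matrix(0.5, P, B))
})

test_that("calibration is invariant under common affine frame rescaling", {
  set.seed(4)
  P <- 6; B <- 20
  DI <- matrix(runif(P * B, 5, 15), P, B)
  SI <- DI + matrix(runif(P * B, 50, 100), P, B)
  GI <- DI + matrix(runif(P * B, 0, 1), P, B) * (SI - DI)
  r0 <- compute_reflectance(raw_frames(GI, DI, SI))$reflectance
  a <- 2.7; cc <- 13
  r1 <- compute_reflectance(raw_frames(a * GI + cc, a * DI + cc,
                                       a * SI + cc))$reflectance
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("near-zero white dynamic flags bands invalid without clipping", {
  P <- 3; B <- 10
  DI <- matrix(0, P, B)
  SI <- matrix(100, P, B)
  SI[, 4] <- 1e-9   # collapses SI - DI on band 4
  GI <- matrix(50, P, B)
  out <- compute_reflectance(raw_frames(GI, DI, SI))
  expect_false(out$valid_bands[4])
  expect_true(all(out$valid_bands[-4]))
  expect_true(all(is.na(out$reflectance[, 4])))
  expect_true(all(is.finite(out$reflectance[, -4])))
  # specular values > 1 are preserved on valid bands
  GI2 <- matrix(150, P, B)
  out2 <- compute_reflectance(raw_frames(GI2, DI, matrix(100, P, B)))
  expect_true(all(out2$reflectance > 1))
})

test_that("calibration input errors are reported", {
  expect_error(raw_frames(matrix(1, 2, 3), matrix(0, 2, 3), matrix(2, 3, 2)),
               "input error")
  # white never exceeding dark
  DI <- matrix(5, 2, 4)
  expect_error(compute_reflectance(raw_frames(DI, DI, DI)),
               "calibration error")
  # every band invalid: one scan position with collapsed white dynamic
  SI <- matrix(100, 2, 4); SI[1, ] <- 5
  expect_error(compute_reflectance(raw_frames(DI, DI, SI)),
               "all bands invalid")
})

test_that("mean-spectrum extraction equals the brute-force masked mean", {
  # uniform cube
  cube <- matrix(0.7, 8, 5)
  expect_equal(extract_mean_spectrum(cube, 0.5), rep(0.7, 5))
  # two-region cube
  cube2 <- rbind(matrix(0.9, 3, 5), matrix(0.1, 5, 5))
  expect_equal(extract_mean_spectrum(cube2, 0.5), rep(0.9, 5))
  # random cube vs direct loop
  set.seed(9)
  cube3 <- matrix(runif(20 * 6), 20, 6)
  thr <- 0.5
  keep <- which(rowMeans(cube3) > thr)
  oracle <- colSums(cube3[keep, , drop = FALSE]) / length(keep)
  expect_equal(extract_mean_spectrum(cube3, thr), oracle, tolerance = 1e-12)
  expect_error(extract_mean_spectrum(cube3, 10), "empty-mask")
})

test_that("dataset construction enforces id alignment and integrity", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "spec_dataset")
  expect_identical(ds$metadata$sample_id, rownames(ds$spectra))
  # permuted metadata is realigned to the spectra order
  md <- ds$metadata[rev(seq_len(5)), ]
  ds2 <- spec_dataset(ds$spectra, md, ds$references)
  expect_identical(ds2$metadata$sample_id, rownames(ds$spectra))
  # missing reference row is an integrity error
  expect_error(spec_dataset(ds$spectra, ds$metadata, ds$references[-2, ]),
               "integrity error")
  # duplicated ids are integrity errors
  md_dup <- rbind(ds$metadata, ds$metadata[1, ])
  expect_error(spec_dataset(ds$spectra, md_dup, ds$references),
               "integrity error")
  # reference value ranges
  bad <- ds$references; bad$sugar[1] <- -1
  expect_error(spec_dataset(ds$spectra, ds$metadata, bad), "sugar")
})

test_that("inventory counts conserve totals and group sums", {
  ds <- tiny_dataset(n = 7)
  ds$metadata$variety <- c("A", "A", "B", "B", "B", "A", "B")
  ds$metadata$vintage <- c(2016L, 2017L, 2016L, 2016L, 2017L, 2016L, 2017L)
  inv <- summarize_inventory(spec_dataset(ds$spectra, ds$metadata,
                                          ds$references))
  expect_equal(inv$n_total, 7)
  expect_equal(sum(inv$groups$n), inv$n_total)
  merged <- merge(stats::aggregate(n ~ variety, inv$groups, sum),
                  inv$variety_totals, by = "variety")
  expect_equal(merged$n.x, merged$n.y)
  # empty dataset gives an empty summary
  empty <- subset_dataset(ds, character(0))
  inv0 <- summarize_inventory(empty)
  expect_equal(inv0$n_total, 0L)
  expect_equal(nrow(inv0$groups), 0L)
})

test_that("subset and bind preserve alignment", {
  ds <- tiny_dataset(n = 6)
  a <- subset_dataset(ds, c("s02", "s05"))
  expect_equal(n_samples(a), 2)
  expect_equal(a$references$sample_id, c("s02", "s05"))
  b <- subset_dataset(ds, c("s01", "s03"))
  ab <- bind_datasets(a, b)
  expect_equal(n_samples(ab), 4)
  expect_error(subset_dataset(ds, "nope"), "unknown sample ids")
})
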