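test_that("percentile bins partition 1..100 into five equal strata", {
  bins <- compute_percentile_bins(1:100)
  expect_equal(as.vector(table(bins$assignment)), rep(20L, 5))
  expect_equal(bins$cut_values, quantile(1:100, c(.2, .4, .6, .8), type = 7,
                                         names = FALSE))
})

test_that("degenerate all-identical values collapse into bin 1", {
  bins <- compute_percentile_bins(rep(3.3, 12))
  expect_true(all(bins$assignment == 1L))
  expect_true(all(bins$cut_values == 3.3))
  expect_error(compute_percentile_bins(1:4), "group-too-small")
})

test_that("random values bin identically to the sort-and-slice oracle", {
  set.seed(11)
  v <- runif(1000)
  bins <- compute_percentile_bins(v)
  occ <- unname(table(bins$assignment))
  expect_true(all(abs(occ - 200) <= 1))   # rank-rounding only
  # oracle: cut sorted values into 5 consecutive slices; with distinct
  # values, membership must agree with the interval assignment
  cuts <- quantile(v, c(.2, .4, .6, .8), type = 7, names = FALSE)
  oracle <- 1L + vapply(v, function(x) sum(cuts < x), integer(1))
  expect_identical(bins$assignment, oracle)
})

test_that("stratified partition is disjoint, exhaustive and deterministic", {
  ds <- generate_dataset(three_vintage_config(n_per = 120L, B = 16L))$dataset
  sp <- stratified_partition(ds, "sugar", seed = 11)
  all_ids <- rownames(ds$spectra)
  got <- c(sp$train_ids, sp$val_ids, sp$test_ids)
  expect_equal(sort(got), sort(all_ids))
  expect_equal(length(got), length(unique(got)))
  sp2 <- stratified_partition(ds, "sugar", seed = 11)
  expect_identical(sp[c("train_ids", "val_ids", "test_ids")],
                   sp2[c("train_ids", "val_ids", "test_ids")])
  sp3 <- stratified_partition(ds, "sugar", seed = 12)
  expect_false(identical(sort(sp$test_ids), sort(sp3$test_ids)))
  expect_equal(length(sp3$test_ids), length(sp$test_ids))
})

test_that("per-cell test and val counts follow the rounding rule", {
  ds <- generate_dataset(three_vintage_config(n_per = 120L, B = 16L))$dataset
  sp <- stratified_partition(ds, "sugar", seed = 11)
  md <- ds$metadata
  y <- target_values(ds, "sugar")
  role <- setNames(rep("train", nrow(md)), md$sample_id)
  role[sp$val_ids] <- "val"; role[sp$test_ids] <- "test"
  for (v in unique(md$vintage)) {
    ids_v <- md$sample_id[md$vintage == v]
    bins <- compute_percentile_bins(y[ids_v], ids = ids_v)
    for (b in unique(bins$assignment)) {
      cell <- names(bins$assignment)[bins$assignment == b]
      n <- length(cell)
      want <- if (n >= 3) max(1, floor(0.1 * n + 0.5)) else 0
      expect_equal(sum(role[cell] == "test"), want)
      expect_equal(sum(role[cell] == "val"), want)
    }
  }
})

test_that("invalid fractions and too-small groups are rejected", {
  ds <- tiny_dataset(n = 12)
  expect_error(stratified_partition(ds, "sugar",
                                    fractions = c(test = 0.5, val = 0.5)),
               "config error")
  ds4 <- tiny_dataset(n = 4)
  expect_error(stratified_partition(ds4, "sugar"), "group-too-small")
})

test_that("repeated splits are valid, distinct and seeded predictably", {
  ds <- generate_dataset(three_vintage_config(n_per = 60L, B = 16L,
                                              seed = 23L))$dataset
  reps <- repeated_splits(ds, "sugar", n_repeats = 10, base_seed = 5)
  expect_length(reps, 10)
  all_ids <- sort(rownames(ds$spectra))
  tests <- lapply(reps, function(sp) sort(sp$test_ids))
  for (sp in reps)
    expect_equal(sort(c(sp$train_ids, sp$val_ids, sp$test_ids)), all_ids)
  expect_equal(length(unique(tests)), 10)   # all memberships differ
  single <- repeated_splits(ds, "sugar", n_repeats = 1, base_seed = 5)
  direct <- stratified_partition(ds, "sugar", seed = 5)
  expect_identical(single[[1]]$test_ids, direct$test_ids)
})

test_that("stratified splits balance the target better than naive splits", {
  ds <- generate_dataset(three_vintage_config(n_per = 120L, B = 16L))$dataset
  y <- target_values(ds, "sugar")
  set.seed(31)
  wins <- 0L
  for (s in 1:10) {
    sp <- stratified_partition(ds, "sugar", seed = s)
    d_strat <- abs(mean(y[sp$train_ids]) - mean(y[sp$test_ids]))
    nt <- length(sp$test_ids)
    d_naive <- replicate(50, {
      te <- sample(names(y), nt)
      abs(mean(y[setdiff(names(y), te)]) - mean(y[te]))
    })
    wins <- wins + (d_strat <= quantile(d_naive, 0.9))
  }
  expect_gte(wins, 9L)
})
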