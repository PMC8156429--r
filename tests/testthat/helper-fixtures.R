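# Shared fixtures, built in code at test time.

# tiny raw dataset: n samples on B bands with plausible references
tiny_dataset <- function(n = 5, B = 16, seed = 1) {
  set.seed(seed)
  spectra <- matrix(runif(n * B, 0.2, 0.8), n, B)
  ids <- sprintf("s%02d", seq_len(n))
  rownames(spectra) <- ids
  spec_dataset(
    spectra,
    metadata = data.frame(sample_id = ids, variety = "SVA",
                          vintage = 2017L, berries_per_sample = 6L),
    references = data.frame(sample_id = ids,
                            sugar = runif(n, 10, 25),
                            ph = runif(n, 3, 4)))
}

# three-vintage synthetic config at a chosen scale
three_vintage_config <- function(n_per = 120L, B = 32L, seed = 13L, ...) {
  g <- data.frame(variety = "SVA", vintage = 2016:2018, n = n_per,
                  sugar_mean = c(17.5, 19, 20.5), sugar_sd = 3.5,
                  ph_mean = c(3.5, 3.6, 3.7), ph_sd = 0.3)
  synthetic_config(n_bands = B, groups = g, seed = seed, ...)
}

# dataset expanded from the bundled field-campaign inventory counts
inventory_dataset <- function() {
  counts <- read.csv(system.file("extdata", "campaign_inventory.csv",
                                 package = "vitispec"))
  n <- sum(counts$n)
  ids <- sprintf("inv%04d", seq_len(n))
  spectra <- matrix(0.5, n, 8)
  rownames(spectra) <- ids
  spec_dataset(
    spectra,
    metadata = data.frame(sample_id = ids,
                          variety = rep(counts$variety, counts$n),
                          vintage = rep(counts$vintage, counts$n),
                          berries_per_sample = 6L),
    references = data.frame(sample_id = ids, sugar = 15, ph = 3.5))
}

# small, fast-training hyperparameters used across CNN tests
small_hp <- function(...) {
  args <- list(filters1 = 8L, kernel1 = 7L, filters2 = 8L, kernel2 = 5L,
               neurons = 16L, dropout1 = 0.1, dropout2 = 0.1, lr = 0.05,
               batch_size = 8L)
  override <- list(...)
  args[names(override)] <- override
  do.call(hyperparams, args)
}

# independent per-band local polynomial fit (direct normal equations),
# used as the Savitzky-Golay oracle
sg_brute_force <- function(S, window, polyorder, deriv) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  B <- ncol(S)
  h <- (window - 1) %/% 2
  out <- matrix(0, nrow(S), B)
  for (i in seq_len(B)) {
    lo <- max(1, i - h); hi <- min(B, i + h)
    off <- (lo:hi) - i
    X <- outer(off, 0:polyorder, "^")
    coefs <- solve(crossprod(X), t(X) %*% t(S[, lo:hi, drop = FALSE]))
    out[, i] <- coefs[deriv + 1, ] * factorial(deriv)
  }
  out
}
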