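# Synthetic reflectance datasets with known ground truth. The generator
# emulates the statistical structure of berry-level reflectance campaigns:
# per-sample mean spectra whose absorption-band amplitudes depend linearly
# on sugar and pH, corrupted by per-sample multiplicative scatter and
# additive offset (berry size/curvature effects), band noise, and
# vintage/variety-level distribution shifts, with reference values carrying
# their own measurement noise.

default_groups <- function() {
  va <- data.frame(variety = "SVA", vintage = c(2012:2014, 2016:2018),
                   n = 50L, stringsAsFactors = FALSE)
  vb <- data.frame(variety = "SVB", vintage = c(2013, 2014, 2016, 2017),
                   n = 20L, stringsAsFactors = FALSE)
  vc <- data.frame(variety = "SVC", vintage = c(2013, 2014, 2016, 2017),
                   n = 20L, stringsAsFactors = FALSE)
  g <- rbind(va, vb, vc)
  veff <- c(SVA = 0, SVB = -1.5, SVC = 1.5)
  peff <- c(SVA = 0, SVB = -0.12, SVC = 0.12)
  g$sugar_mean <- 19 + (g$vintage - 2015) * 0.6 + veff[g$variety]
  g$sugar_sd <- 3.5
  g$ph_mean <- 3.6 + (g$vintage - 2015) * 0.04 + peff[g$variety]
  g$ph_sd <- 0.3
  rownames(g) <- NULL
  g
}

default_peaks <- function() {
  # 8 Gaussian absorption bands: three sugar-linked, two pH-linked, three
  # inert; amplitudes a_k = alpha_k + beta_k * sugar + gamma_k * pH
  list(centers_frac = c(0.08, 0.20, 0.32, 0.44, 0.56, 0.68, 0.80, 0.92),
       widths_frac = rep(0.03, 8),
       alpha = c(0.16, -0.04, 0.08, 0.02, 0.06, 0.22, 0.12, 0.05),
       beta = c(-0.0050, 0, 0, 0.0040, 0, 0, -0.0030, 0),
       gamma = c(0, 0.050, 0, 0, 0, -0.040, 0, 0))
}

#' Synthetic dataset configuration
#'
#' Defines the study conditions the generator emulates: group design
#' (varieties x vintages with per-group sample counts and target
#' distributions), the absorption-peak library and its coefficient map, the
#' scatter/offset/noise model, and target-side measurement noise. Defaults
#' mirror a multi-vintage campaign (one variety with six vintages, two with
#' four) at desk scale, with sugar truncated to [5.5, 30.3] degrees Brix
#' and pH to [2.6, 5.0].
#'
#' @param n_bands spectral bands (default 1040).
#' @param groups data.frame with columns `variety`, `vintage`, `n`,
#'   `sugar_mean`, `sugar_sd`, `ph_mean`, `ph_sd`.
#' @param sugar_range,ph_range hard truncation bounds for emitted targets.
#' @param peaks peak library list (`centers_frac`, `widths_frac`, `alpha`,
#'   `beta`, `gamma`).
#' @param scatter_sdlog SD of log multiplicative scatter factor (log-normal
#'   around 1); 0 disables scatter.
#' @param offset_sd SD of the additive offset (reflectance units).
#' @param noise_sd per-band additive noise SD.
#' @param sugar_sigma_y,ph_sigma_y measurement noise SD of the reference
#'   values (°Brix / pH units).
#' @param baseline_shift amplitude of a smooth additive baseline drift
#'   (models instrument/season drift between vintages).
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_bands = 1040L, groups = default_groups(),
                             sugar_range = c(5.5, 30.3),
                             ph_range = c(2.6, 5.0),
                             peaks = default_peaks(),
                             scatter_sdlog = 0.1, offset_sd = 0.02,
                             noise_sd = 0.005,
                             sugar_sigma_y = 0.5, ph_sigma_y = 0.05,
                             baseline_shift = 0, seed = 1L) {
  stopifnot(n_bands >= 8, all(groups$n >= 1),
            sugar_range[1] < sugar_range[2], ph_range[1] < ph_range[2],
            scatter_sdlog >= 0, offset_sd >= 0, noise_sd >= 0,
            sugar_sigma_y >= 0, ph_sigma_y >= 0)
  k <- length(peaks$centers_frac)
  stopifnot(length(peaks$widths_frac) == k, length(peaks$alpha) == k,
            length(peaks$beta) == k, length(peaks$gamma) == k)
  structure(list(n_bands = as.integer(n_bands), groups = groups,
                 sugar_range = sugar_range, ph_range = ph_range,
                 peaks = peaks, scatter_sdlog = scatter_sdlog,
                 offset_sd = offset_sd, noise_sd = noise_sd,
                 sugar_sigma_y = sugar_sigma_y, ph_sigma_y = ph_sigma_y,
                 baseline_shift = baseline_shift, seed = as.integer(seed)),
            class = "synthetic_config")
}

# inverse-CDF truncated normal (one RNG draw per sample, so the stream
# stays aligned regardless of the bounds)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  stats::qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

synthetic_baseline <- function(cfg) {
  t <- seq(0, 1, length.out = cfg$n_bands)
  0.5 + 0.1 * sin(2 * pi * (1.3 * t + 0.2)) +
    cfg$baseline_shift * sin(2 * pi * (0.9 * t) + 1.0)
}

peak_basis <- function(cfg) {
  t <- seq(0, 1, length.out = cfg$n_bands)
  k <- length(cfg$peaks$centers_frac)
  G <- matrix(0, k, cfg$n_bands)
  for (i in seq_len(k))
    G[i, ] <- exp(-(t - cfg$peaks$centers_frac[i])^2 /
                    (2 * cfg$peaks$widths_frac[i]^2))
  G
}

#' Generate a synthetic reflectance dataset with ground truth
#'
#' For sample i with true targets (sugar_i, pH_i):
#' `spectrum_i = m_i * (baseline + sum_k a_k(sugar_i, pH_i) * G_k) + c_i +
#' noise`, with `a_k = alpha_k + beta_k * sugar + gamma_k * pH`, `m_i`
#' log-normal scatter, `c_i` normal offset, Gaussian band noise. Reference
#' values are the true targets plus measurement noise, clamped to the
#' configured truncation ranges.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `dataset` (a [spec_dataset()]) and `truth` (per-sample
#'   true targets/scatter, the noiseless spectra, the peak library and the
#'   baseline).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  local_seed(cfg$seed)
  base <- synthetic_baseline(cfg)
  G <- peak_basis(cfg)
  gs <- cfg$groups
  n_tot <- sum(gs$n)
  B <- cfg$n_bands

  ids <- character(n_tot)
  variety <- character(n_tot)
  vintage <- integer(n_tot)
  sugar_true <- ph_true <- m <- cc <- numeric(n_tot)
  spectra <- noiseless <- matrix(0, n_tot, B)
  pos <- 0L
  for (g in seq_len(nrow(gs))) {
    n <- gs$n[g]
    idx <- pos + seq_len(n)
    ids[idx] <- sprintf("%s_%d_%03d", gs$variety[g], gs$vintage[g],
                        seq_len(n))
    variety[idx] <- gs$variety[g]
    vintage[idx] <- gs$vintage[g]
    sugar_true[idx] <- rtruncnorm(n, gs$sugar_mean[g], gs$sugar_sd[g],
                                  cfg$sugar_range[1], cfg$sugar_range[2])
    ph_true[idx] <- rtruncnorm(n, gs$ph_mean[g], gs$ph_sd[g],
                               cfg$ph_range[1], cfg$ph_range[2])
    m[idx] <- exp(rnorm(n, 0, cfg$scatter_sdlog))
    cc[idx] <- rnorm(n, 0, cfg$offset_sd)
    amp <- cbind(1, sugar_true[idx], ph_true[idx]) %*%
      rbind(cfg$peaks$alpha, cfg$peaks$beta, cfg$peaks$gamma)  # n x k
    clean <- sweep(amp %*% G, 2L, base, "+")
    noiseless[idx, ] <- clean
    eps <- if (cfg$noise_sd > 0) matrix(rnorm(n * B, 0, cfg$noise_sd), n, B)
           else 0
    spectra[idx, ] <- pmax(clean * m[idx] + cc[idx] + eps, 1e-6)
    pos <- pos + n
  }
  clamp <- function(x, r) pmin(pmax(x, r[1]), r[2])
  sugar_ref <- clamp(sugar_true + rnorm(n_tot, 0, cfg$sugar_sigma_y),
                     cfg$sugar_range)
  ph_ref <- clamp(ph_true + rnorm(n_tot, 0, cfg$ph_sigma_y), cfg$ph_range)
  rownames(spectra) <- rownames(noiseless) <- ids
  ds <- spec_dataset(
    spectra,
    metadata = data.frame(sample_id = ids, variety = variety,
                          vintage = vintage, berries_per_sample = 6L,
                          stringsAsFactors = FALSE),
    references = data.frame(sample_id = ids, sugar = sugar_ref, ph = ph_ref,
                            stringsAsFactors = FALSE),
    grid = wavelength_grid(B))
  truth <- list(table = data.frame(sample_id = ids, sugar_true = sugar_true,
                                   ph_true = ph_true, m = m, c = cc,
                                   stringsAsFactors = FALSE),
                noiseless = noiseless, peaks = cfg$peaks, baseline = base)
  list(dataset = ds, truth = truth)
}

#' Synthesize raw frames with a planted reflectance field
#'
#' Builds dark (`DI`) and white (`SI`) reference frames with a smooth
#' spectral lamp profile and emits `GI = DI + R * (SI - DI)`, so that
#' reflectance calibration recovers the planted field `R` exactly (up to
#' floating point).
#'
#' @param cfg a [synthetic_config()] (band count and seed are used).
#' @param n_positions scan positions (>= 1).
#' @param reflectance optional planted field (positions x bands, or a single
#'   value recycled); default: uniform random in (0.05, 0.95).
#' @return list with `frames` (a [raw_frames()]) and `reflectance` (the
#'   planted field).
#' @export
generate_raw_frames <- function(cfg, n_positions = 16L, reflectance = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"), n_positions >= 1)
  local_seed(cfg$seed)
  B <- cfg$n_bands
  t <- seq(0, 1, length.out = B)
  dark <- 96 + 8 * sin(3 * t)
  lamp <- 1500 * (0.55 + 0.45 * sin(pi * t)) + 50
  DI <- matrix(rep(dark, each = n_positions), n_positions, B) +
    matrix(rnorm(n_positions * B, 0, 0.1), n_positions, B)
  SI <- DI + matrix(rep(lamp, each = n_positions), n_positions, B)
  R <- if (is.null(reflectance))
    matrix(runif(n_positions * B, 0.05, 0.95), n_positions, B)
  else if (length(reflectance) == 1L)
    matrix(reflectance, n_positions, B)
  else as.matrix(reflectance)
  stopifnot(identical(dim(R), dim(DI)))
  GI <- DI + R * (SI - DI)
  list(frames = raw_frames(GI, DI, SI), reflectance = R)
}

#' Source / shifted-new-vintage dataset pair for transfer experiments
#'
#' Splits the configured groups of one variety into source vintages (all but
#' the newest) and a new vintage whose target means are shifted and whose
#' baseline drifts, emulating vintage-to-vintage climate and instrument
#' drift. Ground truth is retained for both.
#'
#' @param cfg a [synthetic_config()]; the variety with the most vintages is
#'   used and must have >= 3 (>= 2 source vintages plus the new one).
#' @param sugar_shift added to the new vintage's sugar mean (°Brix).
#' @param ph_shift added to the new vintage's pH mean.
#' @param baseline_drift baseline drift amplitude of the new vintage
#'   (reflectance units).
#' @return list with `source` and `new`, each a `list(dataset, truth)` as
#'   returned by [generate_dataset()].
#' @export
make_transfer_fixture <- function(cfg, sugar_shift = 2, ph_shift = 0.1,
                                  baseline_drift = 0.03) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gs <- cfg$groups
  counts <- table(gs$variety)
  v <- names(counts)[which.max(counts)]
  gv <- gs[gs$variety == v, , drop = FALSE]
  if (nrow(gv) < 3L)
    stop("need >= 2 source vintages plus a new vintage for ", v)
  newest <- max(gv$vintage)
  src_cfg <- cfg
  src_cfg$groups <- gv[gv$vintage != newest, , drop = FALSE]
  new_cfg <- cfg
  ng <- gv[gv$vintage == newest, , drop = FALSE]
  ng$sugar_mean <- ng$sugar_mean + sugar_shift
  ng$ph_mean <- ng$ph_mean + ph_shift
  new_cfg$groups <- ng
  new_cfg$baseline_shift <- cfg$baseline_shift + baseline_drift
  new_cfg$seed <- cfg$seed + 1000L
  list(source = generate_dataset(src_cfg), new = generate_dataset(new_cfg))
}
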