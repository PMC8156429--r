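# Core dataset containers: wavelength grid, raw line-scan frames, and the
# id-aligned (spectra, metadata, references) triple used by every stage.

#' Wavelength grid of a spectra matrix
#'
#' Describes the spectral axis: `n_bands` contiguous bands indexed
#' `0..n_bands - 1`, optionally carrying physical wavelengths in nm. All
#' algorithms in the package operate on band index; wavelengths are metadata.
#'
#' @param n_bands number of spectral bands (>= 8). Default 1040, the band
#'   count of the line-scan spectrograph setup the package targets.
#' @param wavelengths optional numeric vector of length `n_bands`, strictly
#'   increasing physical wavelengths (nm).
#' @return an object of class `wavelength_grid`.
#' @export
wavelength_grid <- function(n_bands = 1040, wavelengths = NULL) {
  n_bands <- as.integer(n_bands)
  if (length(n_bands) != 1L || is.na(n_bands) || n_bands < 8L)
    stop("n_bands must be a single integer >= 8")
  if (!is.null(wavelengths)) {
    if (length(wavelengths) != n_bands)
      stop("wavelengths must have length n_bands")
    if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
      stop("wavelengths must be finite and strictly increasing")
  }
  structure(
    list(n_bands = n_bands, band_index = seq_len(n_bands) - 1L,
         wavelengths = wavelengths),
    class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat("<wavelength_grid> ", x$n_bands, " bands",
      if (!is.null(x$wavelengths))
        sprintf(", %.1f-%.1f nm", min(x$wavelengths), max(x$wavelengths)),
      "\n", sep = "")
  invisible(x)
}

#' Raw line-scan frame triple for reflectance calibration
#'
#' Holds the three positions-by-bands intensity frames needed to calibrate
#' reflectance: `GI` (light reflected by the sample), `DI` (dark current,
#' shutter closed) and `SI` (white reference target).
#'
#' @param GI,DI,SI numeric matrices of identical dimension
#'   (positions x bands).
#' @return an object of class `raw_frames`.
#' @seealso [compute_reflectance()]
#' @export
raw_frames <- function(GI, DI, SI) {
  GI <- as.matrix(GI); DI <- as.matrix(DI); SI <- as.matrix(SI)
  if (!identical(dim(GI), dim(DI)) || !identical(dim(GI), dim(SI)))
    stop("input error: GI, DI, SI must have identical dimensions")
  if (any(!is.finite(GI)) || any(!is.finite(DI)) || any(!is.finite(SI)))
    stop("input error: frames must be finite")
  structure(list(GI = GI, DI = DI, SI = SI), class = "raw_frames")
}

#' Calibrate reflectance from raw frames
#'
#' Converts raw intensities to reflectance band-wise and position-wise:
#' \deqn{R(x, \lambda) = \frac{GI(x,\lambda) - DI(x,\lambda)}
#'                            {SI(x,\lambda) - DI(x,\lambda)}}
#' Bands where the white dynamic `SI - DI` falls at or below a small epsilon
#' (a fraction `eps_frac` of the overall white dynamic range) anywhere along
#' the scan are flagged invalid rather than clipped; reflectance values above
#' 1 (specular highlights) are legal and preserved.
#'
#' @param frames a [raw_frames()] object.
#' @param eps_frac validity threshold as a fraction of `max(SI - DI)`.
#' @return list with `reflectance` (positions x bands matrix, finite on valid
#'   bands) and `valid_bands` (logical vector, length = bands).
#' @export
compute_reflectance <- function(frames, eps_frac = 1e-6) {
  stopifnot(inherits(frames, "raw_frames"))
  denom <- frames$SI - frames$DI
  dyn <- max(denom)
  if (dyn <= 0) stop("calibration error: white reference never exceeds dark")
  eps <- eps_frac * dyn
  valid <- apply(denom, 2L, function(col) all(col > eps))
  if (!any(valid)) stop("calibration error: all bands invalid (SI - DI <= eps)")
  refl <- (frames$GI - frames$DI) / denom
  refl[, !valid] <- NA_real_
  list(reflectance = refl, valid_bands = valid)
}

#' Mean spectrum of the above-threshold region of a cube
#'
#' Minimal mask-and-average hook standing in for berry segmentation: positions
#' whose broadband mean intensity exceeds `threshold` are averaged into a
#' single spectrum.
#'
#' @param cube positions x bands numeric matrix.
#' @param threshold intensity threshold on the per-position broadband mean.
#' @return numeric vector of length `ncol(cube)`.
#' @export
extract_mean_spectrum <- function(cube, threshold) {
  cube <- as.matrix(cube)
  keep <- rowMeans(cube) > threshold
  if (!any(keep)) stop("empty-mask error: no position exceeds the threshold")
  colMeans(cube[keep, , drop = FALSE])
}

#' Assemble an id-aligned spectra dataset
#'
#' The central container: a samples-by-bands spectra matrix plus sample
#' metadata (variety, vintage, berries per sample) and the reference table of
#' wet-chemistry values (sugar in degrees Brix, pH), all aligned by
#' `sample_id`. Metadata and reference rows are re-ordered to the spectra row
#' order on construction; missing or duplicated ids are integrity errors.
#'
#' @param spectra numeric matrix, one spectrum per row; rownames are sample
#'   ids (or supply ids via `metadata$sample_id` in matching order).
#' @param metadata data.frame with columns `sample_id`, `variety`, `vintage`,
#'   `berries_per_sample`.
#' @param references data.frame with columns `sample_id`, `sugar`, `ph`.
#' @param grid a [wavelength_grid()]; defaults to one matching `ncol(spectra)`.
#' @param preprocessing optional provenance record (set by
#'   [apply_preprocessing()]); raw datasets (NULL provenance) must be
#'   non-negative.
#' @return an object of class `spec_dataset`.
#' @export
spec_dataset <- function(spectra, metadata, references, grid = NULL,
                         preprocessing = NULL) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  if (is.null(rownames(spectra))) {
    if (nrow(spectra) != nrow(metadata))
      stop("integrity error: spectra rows and metadata rows differ in count")
    rownames(spectra) <- as.character(metadata$sample_id)
  }
  ids <- rownames(spectra)
  if (anyDuplicated(ids))
    stop("integrity error: duplicated sample_id in spectra")
  if (nrow(spectra) > 0 && any(!is.finite(spectra)))
    stop("integrity error: spectra contain non-finite values")
  if (is.null(preprocessing) && nrow(spectra) > 0 && any(spectra < 0))
    stop("integrity error: raw reflectance must be non-negative")

  metadata <- as.data.frame(metadata)
  references <- as.data.frame(references)
  req_meta <- c("sample_id", "variety", "vintage", "berries_per_sample")
  if (!all(req_meta %in% names(metadata)))
    stop("metadata must have columns: ", paste(req_meta, collapse = ", "))
  if (!all(c("sample_id", "sugar", "ph") %in% names(references)))
    stop("references must have columns: sample_id, sugar, ph")
  metadata$sample_id <- as.character(metadata$sample_id)
  references$sample_id <- as.character(references$sample_id)
  if (anyDuplicated(metadata$sample_id) || anyDuplicated(references$sample_id))
    stop("integrity error: duplicated sample_id")
  miss_m <- setdiff(ids, metadata$sample_id)
  miss_r <- setdiff(ids, references$sample_id)
  if (length(miss_m) || length(miss_r))
    stop("integrity error: spectra ids without metadata/reference rows: ",
         paste(head(c(miss_m, miss_r), 5), collapse = ", "))
  metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  references <- references[match(ids, references$sample_id), , drop = FALSE]
  rownames(metadata) <- rownames(references) <- NULL
  if (nrow(references) > 0) {
    if (any(!is.finite(references$sugar)) || any(references$sugar <= 0))
      stop("integrity error: sugar must be finite and > 0")
    if (any(references$ph <= 0) || any(references$ph >= 14))
      stop("integrity error: pH must lie in (0, 14)")
  }
  if (is.null(grid)) grid <- wavelength_grid(ncol(spectra))
  stopifnot(inherits(grid, "wavelength_grid"))
  if (grid$n_bands != ncol(spectra))
    stop("grid n_bands does not match ncol(spectra)")

  structure(
    list(spectra = spectra, metadata = metadata, references = references,
         grid = grid, preprocessing = preprocessing),
    class = "spec_dataset")
}

#' @export
print.spec_dataset <- function(x, ...) {
  cat("<spec_dataset> ", nrow(x$spectra), " samples x ", x$grid$n_bands,
      " bands\n", sep = "")
  if (nrow(x$metadata) > 0) {
    tab <- table(x$metadata$variety, x$metadata$vintage)
    print(tab)
  }
  if (!is.null(x$preprocessing))
    cat("preprocessing:", x$preprocessing$method, "\n")
  invisible(x)
}

#' @export
dim.spec_dataset <- function(x) dim(x$spectra)

#' Number of samples in a dataset
#' @param dataset a `spec_dataset`.
#' @return integer sample count.
#' @export
n_samples <- function(dataset) nrow(dataset$spectra)

#' Subset a dataset by sample ids
#'
#' @param dataset a `spec_dataset`.
#' @param ids character vector of sample ids (must all be present).
#' @return a `spec_dataset` restricted to `ids`, in the given order.
#' @export
subset_dataset <- function(dataset, ids) {
  stopifnot(inherits(dataset, "spec_dataset"))
  ids <- as.character(ids)
  missing <- setdiff(ids, rownames(dataset$spectra))
  if (length(missing))
    stop("unknown sample ids: ", paste(head(missing, 5), collapse = ", "))
  idx <- match(ids, dataset$metadata$sample_id)
  spec_dataset(dataset$spectra[ids, , drop = FALSE],
               dataset$metadata[idx, , drop = FALSE],
               dataset$references[idx, , drop = FALSE],
               grid = dataset$grid,
               preprocessing = dataset$preprocessing)
}

#' Bind two datasets with disjoint sample ids
#' @param a,b `spec_dataset` objects on the same grid with identical
#'   preprocessing provenance.
#' @return combined `spec_dataset`.
#' @export
bind_datasets <- function(a, b) {
  stopifnot(inherits(a, "spec_dataset"), inherits(b, "spec_dataset"))
  if (a$grid$n_bands != b$grid$n_bands)
    stop("band counts differ")
  spec_dataset(rbind(a$spectra, b$spectra),
               rbind(a$metadata, b$metadata),
               rbind(a$references, b$references),
               grid = a$grid, preprocessing = a$preprocessing)
}

#' Extract target values from the reference table
#' @param dataset a `spec_dataset`.
#' @param target `"sugar"` or `"ph"`.
#' @return numeric vector named by sample id.
#' @export
target_values <- function(dataset, target = c("sugar", "ph")) {
  target <- match.arg(target)
  stats::setNames(dataset$references[[target]], dataset$references$sample_id)
}

#' Per-variety / per-vintage sample inventory
#'
#' Counts samples grouped by (variety, vintage), with per-variety totals and
#' the grand total, in the shape of a field campaign inventory table.
#'
#' @param dataset a `spec_dataset`.
#' @return list with `groups` (variety, vintage, n), `variety_totals`
#'   (variety, n) and `n_total`.
#' @export
summarize_inventory <- function(dataset) {
  stopifnot(inherits(dataset, "spec_dataset"))
  md <- dataset$metadata
  if (nrow(md) == 0L) {
    return(list(groups = data.frame(variety = character(), vintage = integer(),
                                    n = integer()),
                variety_totals = data.frame(variety = character(),
                                            n = integer()),
                n_total = 0L))
  }
  agg <- stats::aggregate(list(n = md$sample_id),
                          by = list(variety = md$variety, vintage = md$vintage),
                          FUN = length)
  agg <- agg[order(agg$variety, agg$vintage), , drop = FALSE]
  rownames(agg) <- NULL
  tot <- stats::aggregate(list(n = agg$n), by = list(variety = agg$variety),
                          FUN = sum)
  list(groups = agg, variety_totals = tot, n_total = sum(agg$n))
}

# Restore the RNG state on exit so seeded helpers do not disturb the caller's
# random stream.
local_seed <- function(seed, envir = parent.frame()) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", globalenv())
  expr <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}
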