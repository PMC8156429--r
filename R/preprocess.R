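# Spectral preprocessing: multiplicative scatter correction (MSC), min-max
# normalization, and Savitzky-Golay smoothing / differentiation, with a
# leakage-safe fit/apply separation (MSC reference is fit on training data
# only and frozen).

#' Preprocessing configuration
#'
#' Exactly one method is applied per experiment. The Savitzky-Golay variant
#' fits a local least-squares polynomial of order `sg_polyorder` in a moving
#' window of `sg_window` points and returns either the smoothed value
#' (`sg_deriv = 0`) or the first derivative with respect to band index
#' (`sg_deriv = 1`, the default used for modelling).
#'
#' @param method `"MSC"`, `"NORM"` or `"SG"`.
#' @param sg_window odd window size (> `sg_polyorder`); default 15.
#' @param sg_polyorder local polynomial order; default 2.
#' @param sg_deriv derivative order, 0 or 1; default 1.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(method = c("SG", "MSC", "NORM"),
                              sg_window = 15L, sg_polyorder = 2L,
                              sg_deriv = 1L) {
  method <- match.arg(method)
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  sg_deriv <- as.integer(sg_deriv)
  if (sg_window %% 2L != 1L || sg_window <= sg_polyorder)
    stop("sg_window must be odd and greater than sg_polyorder")
  if (!sg_deriv %in% c(0L, 1L)) stop("sg_deriv must be 0 or 1")
  if (sg_deriv > sg_polyorder) stop("sg_deriv must not exceed sg_polyorder")
  structure(list(method = method, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, sg_deriv = sg_deriv),
            class = "preprocess_config")
}

#' Fit the MSC reference spectrum
#'
#' The reference is the per-band arithmetic mean of the training spectra.
#'
#' @param training_spectra numeric matrix (samples x bands) or a
#'   `spec_dataset`.
#' @param provenance label recording which split the reference was averaged
#'   from.
#' @return an object of class `msc_reference`.
#' @export
msc_fit <- function(training_spectra, provenance = "train") {
  if (inherits(training_spectra, "spec_dataset"))
    training_spectra <- training_spectra$spectra
  training_spectra <- as.matrix(training_spectra)
  if (nrow(training_spectra) < 1L) stop("msc_fit needs >= 1 training spectrum")
  ref <- colMeans(training_spectra)
  if (any(!is.finite(ref))) stop("non-finite reference spectrum")
  structure(list(reference_spectrum = as.numeric(ref),
                 provenance = provenance),
            class = "msc_reference")
}

#' Apply multiplicative scatter correction
#'
#' Each spectrum `s` is regressed on the reference by ordinary least squares,
#' `s ~ intercept + slope * ref`, and corrected as
#' `(s - intercept) / slope`, removing per-sample multiplicative scatter and
#' additive offset.
#'
#' @param spectra numeric vector (one spectrum) or matrix (samples x bands).
#' @param ref an [msc_fit()] reference.
#' @return corrected spectrum/spectra, same shape as the input.
#' @export
msc_apply <- function(spectra, ref) {
  stopifnot(inherits(ref, "msc_reference"))
  r <- ref$reference_spectrum
  one <- is.null(dim(spectra))
  S <- if (one) matrix(spectra, nrow = 1) else as.matrix(spectra)
  if (ncol(S) != length(r)) stop("band count does not match the reference")
  rc <- r - mean(r)
  denom <- sum(rc * rc)
  if (denom <= 0) stop("degenerate reference spectrum (constant)")
  slope <- as.numeric(S %*% rc - rowSums(S) * mean(rc)) / denom
  if (any(abs(slope) <= 1e-8))
    stop("degenerate-spectrum error: near-zero slope against the reference")
  intercept <- rowMeans(S) - slope * mean(r)
  out <- sweep(sweep(S, 1L, intercept, "-"), 1L, slope, "/")
  if (one) as.numeric(out) else out
}

#' Min-max normalize spectra to [0, 1]
#'
#' Per spectrum: subtract the minimum and divide by the range, so the
#' smallest intensity maps to 0 and the largest to 1.
#'
#' @param spectra numeric vector or matrix (samples x bands).
#' @return normalized spectrum/spectra, same shape.
#' @export
minmax_normalize <- function(spectra) {
  one <- is.null(dim(spectra))
  S <- if (one) matrix(spectra, nrow = 1) else as.matrix(spectra)
  lo <- apply(S, 1L, min)
  hi <- apply(S, 1L, max)
  if (any(hi - lo <= 0))
    stop("degenerate-range error: constant spectrum has no range")
  out <- sweep(sweep(S, 1L, lo, "-"), 1L, hi - lo, "/")
  if (one) as.numeric(out) else out
}

# Per-output-band coefficient rows of the Savitzky-Golay projection. Interior
# bands share one symmetric-window row; the first/last (w-1)/2 bands use
# truncated asymmetric windows (fit on the available points), keeping the
# output length equal to the input length.
sg_coefficients <- function(n_bands, config) {
  w <- config$sg_window; p <- config$sg_polyorder; d <- config$sg_deriv
  if (n_bands < w) stop("sg window exceeds the number of bands")
  h <- (w - 1L) %/% 2L
  row_for <- function(offsets) {
    X <- outer(offsets, 0:p, "^")
    # value (or derivative) at offset 0 of the local LS polynomial:
    # coefficient of x^d times d!
    M <- solve(crossprod(X), t(X))
    M[d + 1L, ] * factorial(d)
  }
  interior <- row_for(-h:h)
  edges_lo <- lapply(seq_len(h), function(i) row_for(seq_len(i + h) - i))
  list(interior = interior, edges_lo = edges_lo, h = h)
}

#' Savitzky-Golay filter (smoothing or first derivative)
#'
#' At each band the value (or first derivative with respect to band index) of
#' the local least-squares polynomial over the moving window is returned. At
#' the first and last `(sg_window - 1)/2` bands the window is truncated to
#' the available points (asymmetric fit), so the output length equals the
#' input length.
#'
#' @param spectra numeric vector or matrix (samples x bands).
#' @param config a [preprocess_config()] (its `sg_*` fields are used).
#' @return filtered spectrum/spectra, same shape.
#' @export
savitzky_golay <- function(spectra, config = preprocess_config("SG")) {
  stopifnot(inherits(config, "preprocess_config"))
  one <- is.null(dim(spectra))
  S <- if (one) matrix(spectra, nrow = 1) else as.matrix(spectra)
  B <- ncol(S)
  co <- sg_coefficients(B, config)
  h <- co$h
  out <- matrix(0, nrow(S), B)
  # interior bands: vectorized sliding dot product over window offsets
  n_int <- B - 2L * h
  for (j in seq_len(2L * h + 1L)) {
    cols <- seq.int(j, length.out = n_int)
    out[, (h + 1L):(B - h)] <- out[, (h + 1L):(B - h), drop = FALSE] +
      co$interior[j] * S[, cols, drop = FALSE]
  }
  # truncated edge windows
  for (i in seq_len(h)) {
    wlo <- co$edges_lo[[i]]                 # window 1..(i+h), centred at i
    out[, i] <- S[, seq_len(i + h), drop = FALSE] %*% wlo
    # mirror for the right edge: band B+1-i, window (B-i-h+1)..B.
    # With offsets negated the derivative picks up a sign flip.
    whi <- rev(wlo) * (-1)^config$sg_deriv
    out[, B + 1L - i] <- S[, (B - i - h + 1L):B, drop = FALSE] %*% whi
  }
  dimnames(out) <- dimnames(S)
  if (one) as.numeric(out) else out
}

#' Fit the state a preprocessing method needs from training data
#'
#' MSC needs a reference spectrum averaged from the training split; NORM and
#' SG are stateless.
#'
#' @param train_dataset a `spec_dataset` (training split only).
#' @param config a [preprocess_config()].
#' @return an `msc_reference` for MSC, otherwise `NULL`.
#' @export
fit_preprocessing <- function(train_dataset, config) {
  stopifnot(inherits(config, "preprocess_config"))
  if (config$method == "MSC") msc_fit(train_dataset) else NULL
}

#' Apply a preprocessing method to a dataset
#'
#' Replaces the spectra, leaves metadata and references untouched, and
#' records provenance (method, config and — for MSC — the fitted reference)
#' on the returned dataset so that downstream prediction can reproduce the
#' transform exactly.
#'
#' @param dataset a `spec_dataset`.
#' @param config a [preprocess_config()].
#' @param fitted_state for MSC, the [fit_preprocessing()] result (an
#'   `msc_reference` fit on training data only); ignored otherwise.
#' @return a `spec_dataset` with transformed spectra and a `preprocessing`
#'   provenance record.
#' @export
apply_preprocessing <- function(dataset, config, fitted_state = NULL) {
  stopifnot(inherits(dataset, "spec_dataset"),
            inherits(config, "preprocess_config"))
  S <- dataset$spectra
  out <- switch(config$method,
    MSC = {
      if (!inherits(fitted_state, "msc_reference"))
        stop("state error: MSC requires a fitted msc_reference")
      msc_apply(S, fitted_state)
    },
    NORM = minmax_normalize(S),
    SG = savitzky_golay(S, config))
  prov <- list(method = config$method, config = config,
               fitted_state = if (config$method == "MSC") fitted_state)
  spec_dataset(out, dataset$metadata, dataset$references,
               grid = dataset$grid, preprocessing = prov)
}
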