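# File I/O: CSV table triple and RDS container for datasets, ENVI raster
# cubes for raw frames, CSV split manifests.

#' Save a dataset to disk
#'
#' Two on-disk representations are supported. `"csv"` writes a sibling table
#' triple keyed by `sample_id` (`<stem>_spectra.csv` with header
#' `sample_id, band_0..band_{B-1}`, `<stem>_metadata.csv`,
#' `<stem>_references.csv`, plus `<stem>_wavelengths.csv` when the grid
#' carries physical wavelengths), UTF-8 with `.` decimal, values at 12
#' significant digits. `"rds"` writes a single binary container preserving
#' the object bit-wise.
#'
#' @param dataset a [spec_dataset()].
#' @param path file path: the stem for `"csv"`, the file name for `"rds"`.
#' @param format `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path, format = c("csv", "rds")) {
  stopifnot(inherits(dataset, "spec_dataset"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(dataset, path)
    return(invisible(path))
  }
  spec <- dataset$spectra
  df <- data.frame(sample_id = rownames(spec),
                   signif(spec, 12), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("sample_id", paste0("band_", seq_len(ncol(spec)) - 1L))
  write.csv(df, paste0(path, "_spectra.csv"), row.names = FALSE,
            fileEncoding = "UTF-8")
  write.csv(dataset$metadata, paste0(path, "_metadata.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(dataset$references, paste0(path, "_references.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(dataset$grid$wavelengths))
    write.csv(data.frame(band_index = dataset$grid$band_index,
                         wavelength = dataset$grid$wavelengths),
              paste0(path, "_wavelengths.csv"), row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a dataset from disk
#'
#' Counterpart of [save_dataset()]. Id alignment, duplicate detection and
#' reference completeness are enforced on load (integrity errors).
#'
#' @param path file path: the stem for `"csv"`, the file name for `"rds"`.
#' @param format `"csv"` or `"rds"`.
#' @return a [spec_dataset()].
#' @export
load_dataset <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    if (!file.exists(path)) stop("file not found: ", path)
    ds <- readRDS(path)
    stopifnot(inherits(ds, "spec_dataset"))
    return(ds)
  }
  spath <- paste0(path, "_spectra.csv")
  if (!file.exists(spath)) stop("file not found: ", spath)
  sp <- read.csv(spath, check.names = FALSE, stringsAsFactors = FALSE)
  spectra <- as.matrix(sp[, -1, drop = FALSE])
  dimnames(spectra) <- list(as.character(sp$sample_id), NULL)
  metadata <- read.csv(paste0(path, "_metadata.csv"),
                       stringsAsFactors = FALSE)
  references <- read.csv(paste0(path, "_references.csv"),
                         stringsAsFactors = FALSE)
  wpath <- paste0(path, "_wavelengths.csv")
  grid <- if (file.exists(wpath)) {
    w <- read.csv(wpath)
    wavelength_grid(ncol(spectra), wavelengths = w$wavelength)
  } else wavelength_grid(ncol(spectra))
  preprocessing <- if (any(spectra < 0)) list(method = "unknown") else NULL
  spec_dataset(spectra, metadata, references, grid = grid,
               preprocessing = preprocessing)
}

#' Write a split manifest
#'
#' Persists a [stratified_partition()] result as a two-column CSV
#' (`sample_id`, `role` in train/val/test).
#'
#' @param split a `dataset_split`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  df <- data.frame(
    sample_id = c(split$train_ids, split$val_ids, split$test_ids),
    role = rep(c("train", "val", "test"),
               c(length(split$train_ids), length(split$val_ids),
                 length(split$test_ids))),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a split manifest written by [write_split_manifest()]
#' @param path CSV path.
#' @return a `dataset_split` (id lists only).
#' @export
read_split_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(list(train_ids = df$sample_id[df$role == "train"],
                 val_ids = df$sample_id[df$role == "val"],
                 test_ids = df$sample_id[df$role == "test"],
                 fractions = NULL, seed = NA_integer_,
                 stratify_on = NA_character_, grouping = NA_character_),
            class = "dataset_split")
}

# --- ENVI raster I/O (minimal) ----------------------------------------------
# Header-file key = value parser plus raw binary read/write for the BSQ/BIL/
# BIP interleaves and IEEE float/double types, enough to move line-scan
# frame stacks in and out of the calibration step.

.envi_types <- c("4" = "float", "5" = "double")
.envi_sizes <- c("4" = 4L, "5" = 8L)

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) next
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- tolower(trimws(parts[1]))
    val <- trimws(paste(parts[-1], collapse = "="))
    kv[[key]] <- val
  }
  kv
}

#' Read an ENVI raster cube
#'
#' Reads a flat-binary ENVI raster (`.hdr` sidecar plus data file) into a
#' `lines x samples x bands` array. Supports interleaves `bsq`, `bil`, `bip`,
#' IEEE `float`/`double` data types (ENVI codes 4 and 5), both byte orders
#' and a header offset.
#'
#' @param hdr_path path to the `.hdr` header; the data file is `hdr_path`
#'   without its extension (or with `.dat`/`.img` appended).
#' @return numeric array `c(lines, samples, bands)`.
#' @export
read_envi_cube <- function(hdr_path) {
  kv <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  if (!all(need %in% names(kv)))
    stop("ENVI header missing fields: ",
         paste(setdiff(need, names(kv)), collapse = ", "))
  ns <- as.integer(kv[["samples"]]); nl <- as.integer(kv[["lines"]])
  nb <- as.integer(kv[["bands"]])
  dt <- kv[["data type"]]
  if (!dt %in% names(.envi_types)) stop("unsupported ENVI data type: ", dt)
  interleave <- tolower(kv[["interleave"]])
  offset <- as.integer(kv[["header offset"]] %||% "0")
  endian <- if ((kv[["byte order"]] %||% "0") == "1") "big" else "little"
  base <- sub("\\.hdr$", "", hdr_path, ignore.case = TRUE)
  data_path <- c(base, paste0(base, ".dat"), paste0(base, ".img"))
  data_path <- data_path[file.exists(data_path)][1]
  if (is.na(data_path)) stop("ENVI data file not found for ", hdr_path)
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  n <- ns * nl * nb
  vals <- readBin(con, "numeric", n = n, size = .envi_sizes[[dt]],
                  endian = endian)
  if (length(vals) != n) stop("ENVI data file truncated")
  cube <- array(NA_real_, c(nl, ns, nb))
  if (interleave == "bsq") {            # band-sequential: (sample, line, band)
    cube <- aperm(array(vals, c(ns, nl, nb)), c(2, 1, 3))
  } else if (interleave == "bil") {     # (sample, band, line)
    cube <- aperm(array(vals, c(ns, nb, nl)), c(3, 1, 2))
  } else if (interleave == "bip") {     # (band, sample, line)
    cube <- aperm(array(vals, c(nb, ns, nl)), c(3, 2, 1))
  } else stop("unsupported interleave: ", interleave)
  cube
}

#' Write an ENVI raster cube
#'
#' @param cube numeric array `c(lines, samples, bands)`.
#' @param base_path output path without extension; writes `<base>.dat` and
#'   `<base>.hdr`.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @return `base_path`, invisibly.
#' @export
write_envi_cube <- function(cube, base_path, interleave = c("bsq", "bil", "bip")) {
  interleave <- match.arg(interleave)
  stopifnot(is.array(cube), length(dim(cube)) == 3L)
  d <- dim(cube)  # lines, samples, bands
  perm <- switch(interleave,
                 bsq = c(2, 1, 3), bil = c(2, 3, 1), bip = c(3, 2, 1))
  vals <- as.numeric(aperm(cube, perm))
  con <- file(paste0(base_path, ".dat"), "wb")
  writeBin(vals, con, size = 8L, endian = "little")
  close(con)
  hdr <- c("ENVI",
           paste("samples =", d[2]), paste("lines =", d[1]),
           paste("bands =", d[3]), "header offset = 0",
           "data type = 5", paste("interleave =", interleave),
           "byte order = 0")
  writeLines(hdr, paste0(base_path, ".hdr"))
  invisible(base_path)
}

#' Read a raw frame triple from ENVI cubes
#'
#' Loads GI/DI/SI cubes and flattens `lines x samples` to the positions axis.
#'
#' @param gi_hdr,di_hdr,si_hdr paths to the three `.hdr` files.
#' @return a [raw_frames()] object (positions x bands).
#' @export
frames_from_envi <- function(gi_hdr, di_hdr, si_hdr) {
  flatten <- function(cube) {
    d <- dim(cube)
    matrix(cube, nrow = d[1] * d[2], ncol = d[3])
  }
  raw_frames(flatten(read_envi_cube(gi_hdr)),
             flatten(read_envi_cube(di_hdr)),
             flatten(read_envi_cube(si_hdr)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
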