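# Raster I/O. Quantized interferograms go through tiff::writeTIFF as
# 16-bit integer TIFF. Floating-point maps (fields, phase, OPD) need IEEE
# float sample format, which tiff::writeTIFF does not produce, so a
# compact single-strip uncompressed float32 writer lives here; reading
# always goes through tiff::readTIFF, which handles both.

tiff_ifd_entry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3) { # SHORT: value left-justified in the 4-byte slot
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write matrices as a 32-bit floating-point TIFF
#'
#' Single- or multi-page, uncompressed, little-endian, IEEE float
#' samples. Values round-trip exactly at float32 precision through
#' [read_float_tiff()]. The file is written atomically (temp file +
#' rename).
#'
#' @param x A numeric matrix or list of equally-sized matrices (pages).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(x, path) {
  pages <- if (is.matrix(x)) list(x) else x
  stopifnot(length(pages) >= 1, all(vapply(pages, is.matrix, logical(1))))
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  if (!all(vapply(pages, function(p) nrow(p) == nr && ncol(p) == nc,
                  logical(1)))) {
    abort_dimension("all TIFF pages must share one size")
  }
  npix <- nr * nc
  n_pages <- length(pages)
  data_bytes <- 4 * npix
  data_offsets <- 8 + (seq_len(n_pages) - 1) * data_bytes
  ifd_size <- 2 + 10 * 12 + 4
  ifd_offsets <- 8 + n_pages * data_bytes + (seq_len(n_pages) - 1) * ifd_size

  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tif")
  con <- file(tmp, "wb")
  done <- FALSE
  on.exit({
    if (!done) try(close(con), silent = TRUE)
    if (file.exists(tmp)) unlink(tmp)
  }, add = TRUE)
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offsets[1]), con, size = 4, endian = "little")
  for (p in pages) { # scanlines are matrix rows
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
  }
  for (i in seq_len(n_pages)) {
    writeBin(10L, con, size = 2, endian = "little")
    tiff_ifd_entry(con, 256, 4, 1, nc)            # ImageWidth
    tiff_ifd_entry(con, 257, 4, 1, nr)            # ImageLength
    tiff_ifd_entry(con, 258, 3, 1, 32)            # BitsPerSample
    tiff_ifd_entry(con, 259, 3, 1, 1)             # no compression
    tiff_ifd_entry(con, 262, 3, 1, 1)             # BlackIsZero
    tiff_ifd_entry(con, 273, 4, 1, data_offsets[i])
    tiff_ifd_entry(con, 277, 3, 1, 1)             # SamplesPerPixel
    tiff_ifd_entry(con, 278, 4, 1, nr)            # RowsPerStrip
    tiff_ifd_entry(con, 279, 4, 1, data_bytes)
    tiff_ifd_entry(con, 339, 3, 1, 3)             # SampleFormat: IEEE float
    nxt <- if (i < n_pages) ifd_offsets[i + 1] else 0
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  close(con)
  done <- TRUE
  if (!file.rename(tmp, path)) abort_config(sprintf("cannot write %s", path))
  invisible(path)
}

#' Read a floating-point TIFF written by [write_float_tiff()]
#'
#' @param path File path.
#' @param all If `TRUE`, return all pages as a list; otherwise the first
#'   page as a matrix.
#' @return Matrix or list of matrices.
#' @export
read_float_tiff <- function(path, all = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (all) pages else pages[[1]]
}

#' Write a quantized interferogram as 16-bit TIFF
#'
#' @param intensity Matrix of integer counts.
#' @param path Output path.
#' @param bit_depth Bit depth of the counts (scaled to the 16-bit range).
#' @return `path`, invisibly.
#' @export
write_u16_tiff <- function(intensity, path, bit_depth = 14) {
  tiff::writeTIFF(intensity / (2^bit_depth - 1), path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}

# Plain-text sidecar (YAML) next to a raster file.
sidecar_path <- function(path) paste0(path, ".meta.yaml")

write_sidecar <- function(path, meta) {
  yaml::write_yaml(meta, sidecar_path(path), precision = 15)
  invisible(sidecar_path(path))
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    abort_config(sprintf("missing sidecar metadata file: %s", sc))
  }
  yaml::read_yaml(sc)
}

#' Export a complex field as paired float TIFFs
#'
#' Writes `<stem>_real.tif` and `<stem>_imag.tif` plus a sidecar with
#' wavelength and pixel pitch.
#'
#' @param field A [complex_field()].
#' @param stem Output path stem (no extension).
#' @return Character vector of the two raster paths, invisibly.
#' @export
write_field <- function(field, stem) {
  stopifnot(inherits(field, "complex_field"))
  paths <- paste0(stem, c("_real.tif", "_imag.tif"))
  write_float_tiff(Re(field$amplitude), paths[1])
  write_float_tiff(Im(field$amplitude), paths[2])
  write_sidecar(paths[1], list(wavelength_um = field$wavelength,
                               pixel_pitch_um = field$pixel_pitch))
  invisible(paths)
}

#' Read a complex field written by [write_field()]
#' @param stem Path stem used at write time.
#' @return A [complex_field()].
#' @export
read_field <- function(stem) {
  meta <- read_sidecar(paste0(stem, "_real.tif"))
  re <- read_float_tiff(paste0(stem, "_real.tif"))
  im <- read_float_tiff(paste0(stem, "_imag.tif"))
  complex_field(re + 1i * im, meta$wavelength_um, meta$pixel_pitch_um)
}

# Run manifest: config hash, seed, timings, file inventory. Written
# atomically at the end of a run.
write_manifest <- function(out_dir, config, seed, timings, files) {
  files <- files[file.exists(file.path(out_dir, files))]
  manifest <- list(
    software = paste0("anlcsim ", as.character(utils::packageVersion("anlcsim"))),
    config_hash = unname(tools::md5sum(write_temp_yaml(config))),
    seed = seed,
    timings_s = timings,
    files = lapply(files, function(f) {
      list(name = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  path <- file.path(out_dir, "manifest.yaml")
  tmp <- tempfile(tmpdir = out_dir, fileext = ".yaml")
  yaml::write_yaml(manifest, tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_temp_yaml <- function(x) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(x, f)
  f
}
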