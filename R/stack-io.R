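#' Read a multi-page grayscale TIFF z-stack
#'
#' Pixel data are decoded with \pkg{tiff}. Voxel spacing is recovered, in order
#' of preference, from (1) `spacing_override`, (2) a `spacing_nm=` entry in the
#' ImageDescription tag (written by [write_stack()]), or (3) ImageJ-style
#' calibration (XResolution for x/y plus `spacing=`/`unit=` in the
#' description). Spacing is never assumed: a stack with no calibration and no
#' override is an error, because every downstream measurement is physical.
#'
#' @param path TIFF file path.
#' @param spacing_override optional length-3 numeric, nm per voxel (x, y, z);
#'   takes precedence over file metadata.
#' @return a [voxel_grid()]; integer for 8/16-bit files, double for float.
#' @export
read_stack <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF stack: ", path)
  # as.is=TRUE yields raw integers for 8/16-bit files but is rejected for
  # float pages, which are returned unscaled by a plain read
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e) tiff::readTIFF(path, all = TRUE, info = TRUE)
  )
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) > 2L) {
    stop("multi-channel TIFF not supported; expected single-channel grayscale")
  }
  info <- attributes(pages[[1]])
  nyx <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), nyx), logical(1)))) {
    stop("TIFF pages differ in size")
  }
  nx <- nyx[2]; ny <- nyx[1]; nz <- length(pages)
  is_int <- all(vapply(pages, is.integer, logical(1)))
  data <- array(if (is_int) NA_integer_ else NA_real_, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) data[, , k] <- t(pages[[k]])

  meta <- parse_stack_metadata(info)
  spacing <- spacing_override %||% meta$spacing
  if (is.null(spacing)) {
    stop(
      "missing spacing: no voxel-spacing metadata in '", basename(path),
      "' and no spacing_override given"
    )
  }
  voxel_grid(data, spacing, origin = meta$origin %||% c(0, 0, 0))
}

#' Write a voxel grid as a multi-page grayscale TIFF
#'
#' Writes a baseline (uncompressed, little-endian) TIFF with ImageJ-compatible
#' calibration: XResolution/YResolution in pixels per micron plus `spacing=`
#' and `unit=micron` in the ImageDescription, together with an exact
#' `spacing_nm=` record so that [read_stack()] round-trips spacing bit-exactly.
#' Integer grids are stored losslessly at 8 or 16 bits, double grids as 32-bit
#' IEEE floats.
#'
#' @param grid a [voxel_grid()].
#' @param path output file path.
#' @param bits bits per sample for integer data (8 or 16; default 16).
#'   Ignored for double data, which is always written as 32-bit float.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path, bits = 16L) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  if (is.integer(grid$data)) {
    bits <- as.integer(bits)
    if (!bits %in% c(8L, 16L)) stop("integer stacks support 8 or 16 bits per sample")
    rng <- range(grid$data)
    if (any(is.na(rng)) || rng[1] < 0 || rng[2] > 2^bits - 1) {
      stop("integer data out of range for ", bits, "-bit storage")
    }
    fmt <- 1L
  } else {
    bits <- 32L
    fmt <- 3L
    if (any(!is.finite(grid$data))) stop("float stacks must be finite")
  }
  desc <- stack_description(grid, d[3])
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  write_baseline_tiff(con, grid$data, bits, fmt, desc, spacing_um(grid))
  invisible(path)
}

stack_description <- function(grid, nz) {
  num17 <- function(x) paste(format(x, digits = 17, trim = TRUE), collapse = " ")
  paste0(
    "ImageJ=1.53t\nimages=", nz, "\nslices=", nz,
    "\nunit=micron\nspacing=", format(grid$spacing[3] / 1000, digits = 17),
    "\nloop=false\n",
    "spacing_nm=", num17(grid$spacing), "\n",
    "origin_um=", num17(grid$origin), "\n"
  )
}

parse_stack_metadata <- function(info) {
  desc <- info$description %||% ""
  grab <- function(key) {
    m <- regmatches(desc, regexec(paste0(key, "=([^\n]*)"), desc))[[1]]
    if (length(m) < 2) return(NULL)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(m[2]), "[ ,]+")[[1]]))
    if (any(is.na(vals))) NULL else vals
  }
  spacing <- grab("spacing_nm")
  origin <- grab("origin_um")
  if (is.null(spacing)) {
    # ImageJ-style calibration: resolution in pixels per unit, z spacing in unit
    unit_m <- regmatches(desc, regexec("unit=([^\n]*)", desc))[[1]]
    unit <- if (length(unit_m) >= 2) trimws(unit_m[2]) else NA_character_
    to_nm <- switch(unit,
      "micron" = 1e3, "um" = 1e3, "µm" = 1e3,
      "mm" = 1e6, "nm" = 1, NA_real_
    )
    xres <- info$x.resolution %||% NA_real_
    yres <- info$y.resolution %||% xres
    sz <- grab("spacing")
    if (!is.na(to_nm) && isTRUE(xres > 0) && !is.null(sz)) {
      spacing <- c(1 / xres * to_nm, 1 / yres * to_nm, sz[1] * to_nm)
    }
  }
  list(spacing = spacing, origin = origin)
}

# --- minimal baseline TIFF writer -----------------------------------------
# The installed TIFF binding cannot write tags, so calibration is emitted by
# this small writer: header, per-page pixel strips, shared out-of-line values
# (description, resolution rationals), then one IFD per page.

write_baseline_tiff <- function(con, data, bits, sample_format, desc, sp_um) {
  d <- dim(data); nx <- d[1]; ny <- d[2]; nz <- d[3]
  bpp <- bits / 8L
  strip_bytes <- nx * ny * bpp
  pad <- function(n) n + (n %% 2L)

  pos <- 8L
  strip_off <- integer(nz)
  for (k in seq_len(nz)) { strip_off[k] <- pos; pos <- pos + pad(strip_bytes) }
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  desc_off <- pos; pos <- pos + pad(length(desc_raw))
  xres_off <- pos; pos <- pos + 8L
  yres_off <- pos; pos <- pos + 8L
  n_entries <- c(14L, rep(13L, max(nz - 1L, 0L)))  # description on page 1 only
  ifd_off <- integer(nz)
  for (k in seq_len(nz)) { ifd_off[k] <- pos; pos <- pos + 2L + 12L * n_entries[k] + 4L }

  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  # header
  writeBin(charToRaw("II"), con); w16(42L); w32(ifd_off[1])

  # pixel strips (row-major, x fastest: as.vector of [, , k] is already so)
  for (k in seq_len(nz)) {
    v <- as.vector(data[, , k])
    if (sample_format == 3L) {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else if (bits == 8L) {
      writeBin(as.raw(v), con)
    } else {
      lo <- as.raw(v %% 256L); hi <- as.raw(v %/% 256L)
      writeBin(as.vector(rbind(lo, hi)), con)
    }
    if (strip_bytes %% 2L) writeBin(as.raw(0L), con)
  }

  writeBin(desc_raw, con)
  if (length(desc_raw) %% 2L) writeBin(as.raw(0L), con)

  # resolution: pixels per micron as an exact-ish rational
  res_rational <- function(s_um) {
    den <- round(s_um * 1e6); num <- 1e6
    while (den > 2^31 - 1) { den <- round(den / 10); num <- num / 10 }
    c(num, den)
  }
  w32(res_rational(sp_um[1])); w32(res_rational(sp_um[2]))

  entry <- function(tag, type, count, value, raw_offset = FALSE) {
    w16(tag); w16(type); w32(count)
    if (type == 3L && !raw_offset) { w16(value); w16(0L) } else w32(value)
  }
  for (k in seq_len(nz)) {
    w16(n_entries[k])
    entry(256L, 4L, 1L, nx)                 # ImageWidth
    entry(257L, 4L, 1L, ny)                 # ImageLength
    entry(258L, 3L, 1L, bits)               # BitsPerSample
    entry(259L, 3L, 1L, 1L)                 # Compression: none
    entry(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
    if (k == 1L) entry(270L, 2L, length(desc_raw), desc_off)
    entry(273L, 4L, 1L, strip_off[k])       # StripOffsets
    entry(277L, 3L, 1L, 1L)                 # SamplesPerPixel
    entry(278L, 4L, 1L, ny)                 # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)        # StripByteCounts
    entry(282L, 5L, 1L, xres_off)           # XResolution
    entry(283L, 5L, 1L, yres_off)           # YResolution
    entry(296L, 3L, 1L, 1L)                 # ResolutionUnit: none (unit in desc)
    entry(339L, 3L, 1L, sample_format)      # SampleFormat
    w32(if (k < nz) ifd_off[k + 1L] else 0L)
  }
  invisible(NULL)
}
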