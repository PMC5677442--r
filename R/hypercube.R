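# Hyperspectral cube container, ENVI-style I/O, ROI handling, band
# pre-cleaning and reflectance recovery.

#' Hyperspectral cube
#'
#' Container for a rows x cols x bands raster of radiance or reflectance with
#' its wavelength axis. This is the raster substrate every pipeline stage
#' operates on: VNIR cubes (385-1000 nm) from a pushbroom UAV sensor, or
#' synthetic scenes from [generate_scene()].
#'
#' @param data 3-D numeric array, rows x cols x bands, finite and >= 0.
#' @param wavelengths_nm Strictly increasing numeric vector, one value per band.
#' @param quantity `"radiance"` (sensor-measured energy) or `"reflectance"`
#'   (illumination-normalised surface property in `[0, ceiling]`).
#' @param gsd_cm_per_px Optional ground sample distance in cm/pixel.
#' @return An object of class `hypercube`.
#' @seealso [read_cube()], [to_reflectance()], [crop_roi()]
#' @export
hypercube <- function(data, wavelengths_nm, quantity = c("radiance", "reflectance"),
                      gsd_cm_per_px = NULL) {
  quantity <- match.arg(quantity)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_ms("cube data must be a 3-D array (rows x cols x bands)", "data_error")
  }
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != dim(data)[3]) {
    abort_ms(sprintf("wavelength count (%d) does not match band count (%d)",
                     length(wavelengths_nm), dim(data)[3]), "format_error")
  }
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0)) {
    abort_ms("wavelengths must be strictly increasing", "format_error")
  }
  if (!all(is.finite(data)) || any(data < 0)) {
    abort_ms("cube values must be finite and non-negative", "data_error")
  }
  if (!is.null(gsd_cm_per_px)) {
    stopifnot(is.numeric(gsd_cm_per_px), length(gsd_cm_per_px) == 1L, gsd_cm_per_px > 0)
  }
  structure(list(data = data, wavelengths_nm = wavelengths_nm,
                 quantity = quantity, gsd_cm_per_px = gsd_cm_per_px),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s%s\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$quantity,
              if (is.null(x$gsd_cm_per_px)) "" else
                sprintf(", GSD %.2f cm/px", x$gsd_cm_per_px)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

# ---- ENVI-style header + raw binary cube ------------------------------------

envi_dtype <- function(code) {
  switch(as.character(code),
    "1"  = list(what = "integer", size = 1L, signed = FALSE),
    "2"  = list(what = "integer", size = 2L, signed = TRUE),
    "3"  = list(what = "integer", size = 4L, signed = TRUE),
    "4"  = list(what = "numeric", size = 4L, signed = TRUE),
    "5"  = list(what = "numeric", size = 8L, signed = TRUE),
    "12" = list(what = "integer", size = 2L, signed = FALSE),
    abort_ms(sprintf("unsupported ENVI data type code: %s", code), "format_error")
  )
}

parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  # join { ... } blocks spanning several lines, then split into key = value
  merged <- character(0); buf <- NULL
  for (ln in lines) {
    if (!is.null(buf)) {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) { merged <- c(merged, buf); buf <- NULL }
    } else if (grepl("\\{", ln) && !grepl("\\}", ln)) {
      buf <- ln
    } else {
      merged <- c(merged, ln)
    }
  }
  if (!is.null(buf)) abort_ms("unterminated '{' block in ENVI header", "format_error")
  kv <- merged[grepl("=", merged)]
  keys <- tolower(trimws(sub("=.*$", "", kv)))
  vals <- trimws(sub("^[^=]*=", "", kv))
  names(vals) <- keys
  vals
}

hdr_field <- function(hdr, key) {
  if (!key %in% names(hdr)) {
    abort_ms(sprintf("ENVI header is missing required field '%s'", key), "format_error")
  }
  hdr[[key]]
}

hdr_int <- function(hdr, key) {
  v <- suppressWarnings(as.integer(hdr_field(hdr, key)))
  if (is.na(v)) abort_ms(sprintf("ENVI header field '%s' is not an integer", key), "format_error")
  v
}

#' Read and write ENVI-style hyperspectral cubes
#'
#' The on-disk format is an ASCII `key = value` header (`.hdr`) next to a raw
#' binary payload, the dialect exported by Headwall pushbroom sensors.
#' Required header fields: `samples`, `lines`, `bands`, `interleave`
#' (`bil`, `bip` or `bsq`), `data type` and `wavelength`. `read_cube`
#' returns the payload bit-exactly; `write_cube` defaults to 8-byte IEEE
#' floats (data type 5) so that a write/read round trip is the identity.
#'
#' @param header_path Path to the `.hdr` file. The payload is looked up by
#'   stripping the `.hdr` extension (or adding `.img`).
#' @return `read_cube`: a [hypercube] (quantity defaults to radiance).
#' @export
read_cube <- function(header_path) {
  if (!file.exists(header_path)) {
    abort_ms(sprintf("header file not found: %s", header_path), "format_error")
  }
  hdr <- parse_envi_header(header_path)
  samples <- hdr_int(hdr, "samples")   # columns
  lines   <- hdr_int(hdr, "lines")     # rows
  bands   <- hdr_int(hdr, "bands")
  interleave <- tolower(hdr_field(hdr, "interleave"))
  if (!interleave %in% c("bil", "bip", "bsq")) {
    abort_ms(sprintf("unsupported interleave '%s' in ENVI header", interleave), "format_error")
  }
  dt <- envi_dtype(hdr_field(hdr, "data type"))
  wl_raw <- hdr_field(hdr, "wavelength")
  wl <- suppressWarnings(as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1]]))
  if (any(is.na(wl))) abort_ms("ENVI header field 'wavelength' is not numeric", "format_error")
  if (length(wl) != bands) {
    abort_ms(sprintf("ENVI header declares %d bands but %d wavelengths", bands, length(wl)),
             "format_error")
  }
  byte_order <- if ("byte order" %in% names(hdr)) hdr_int(hdr, "byte order") else 0L
  endian <- if (byte_order == 0L) "little" else "big"

  bin_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(bin_path)) bin_path <- paste0(bin_path, ".img")
  if (!file.exists(bin_path)) {
    abort_ms(sprintf("binary payload for %s not found", header_path), "format_error")
  }
  n <- samples * lines * bands
  expected_bytes <- n * dt$size
  actual_bytes <- file.info(bin_path)$size
  if (actual_bytes != expected_bytes) {
    abort_ms(sprintf("payload size mismatch: header implies %d bytes, file has %d",
                     expected_bytes, actual_bytes), "size_error")
  }
  con <- file(bin_path, "rb"); on.exit(close(con))
  raw_v <- readBin(con, what = dt$what, n = n, size = dt$size,
                   signed = dt$signed, endian = endian)
  arr <- switch(interleave,
    # BSQ: sample fastest, then line, then band
    bsq = aperm(array(raw_v, dim = c(samples, lines, bands)), c(2, 1, 3)),
    # BIL: sample fastest, then band, then line
    bil = aperm(array(raw_v, dim = c(samples, bands, lines)), c(3, 1, 2)),
    # BIP: band fastest, then sample, then line
    bip = aperm(array(raw_v, dim = c(bands, samples, lines)), c(3, 2, 1))
  )
  hypercube(arr, wl, quantity = "radiance")
}

#' @rdname read_cube
#' @param cube A [hypercube].
#' @param interleave One of `"bil"`, `"bip"`, `"bsq"`.
#' @param data_type ENVI data type code; 5 (float64, the default) is lossless
#'   for R doubles, 4 (float32) halves the file size.
#' @export
write_cube <- function(cube, header_path, interleave = c("bil", "bip", "bsq"),
                       data_type = 5L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  dt <- envi_dtype(data_type)
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {moundscan hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", as.integer(data_type)),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = {%s}", paste(format(cube$wavelengths_nm, trim = TRUE,
                                              digits = 15), collapse = ", "))
  )
  writeLines(hdr, header_path)
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1)))
  )
  bin_path <- sub("\\.hdr$", "", header_path)
  con <- file(bin_path, "wb"); on.exit(close(con))
  if (dt$what == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = dt$size, endian = "little")
  invisible(header_path)
}

# ---- ancillary registers ----------------------------------------------------

#' Read a white-reference illuminant spectrum
#'
#' CSV with columns `wavelength_nm,intensity`: the sensor's response to a
#' white calibration panel, one strictly positive value per band, recorded
#' before the flight. Dividing radiance by this spectrum recovers reflectance.
#'
#' @param path CSV file path.
#' @return A `white_reference` object (list of `wavelengths_nm`, `intensity`).
#' @export
read_white_reference <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(df))) {
    abort_ms("white reference CSV needs columns wavelength_nm,intensity", "format_error")
  }
  white_reference(df$wavelength_nm, df$intensity)
}

#' @rdname read_white_reference
#' @param wavelengths_nm Ascending wavelengths (nm).
#' @param intensity Strictly positive per-band intensity.
#' @export
white_reference <- function(wavelengths_nm, intensity) {
  wavelengths_nm <- as.numeric(wavelengths_nm); intensity <- as.numeric(intensity)
  if (length(wavelengths_nm) != length(intensity)) {
    abort_ms("white reference wavelength/intensity length mismatch", "format_error")
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    abort_ms("white reference wavelengths must be strictly increasing", "format_error")
  }
  if (!all(is.finite(intensity)) || any(intensity <= 0)) {
    abort_ms("white reference intensity must be strictly positive", "data_error")
  }
  structure(list(wavelengths_nm = wavelengths_nm, intensity = intensity),
            class = "white_reference")
}

#' @rdname read_white_reference
#' @param white A `white_reference`.
#' @export
write_white_reference <- function(white, path) {
  utils::write.csv(data.frame(wavelength_nm = white$wavelengths_nm,
                              intensity = white$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Region-of-interest register
#'
#' Rectangular pixel windows cropped out of a flight-line cube, one per
#' surveyed site, optionally tagged with GPS coordinates. Windows use 0-based
#' row/column origins and half-open extents `[row0, row0 + height)`.
#'
#' @param path CSV with columns `roi_id,row0,col0,height,width` and optional
#'   `lat,lon`.
#' @return A `roi_register` (data frame subclass).
#' @export
read_roi_register <- function(path) {
  df <- utils::read.csv(path, colClasses = c(roi_id = "character"))
  need <- c("roi_id", "row0", "col0", "height", "width")
  if (!all(need %in% names(df))) {
    abort_ms(sprintf("ROI register CSV needs columns %s", paste(need, collapse = ",")),
             "format_error")
  }
  if (anyDuplicated(df$roi_id)) abort_ms("duplicate roi_id in register", "format_error")
  structure(df, class = c("roi_register", "data.frame"))
}

#' @rdname read_roi_register
#' @param register A `roi_register`.
#' @export
write_roi_register <- function(register, path) {
  utils::write.csv(as.data.frame(register), path, row.names = FALSE)
  invisible(path)
}

#' Crop a region of interest out of a cube
#'
#' @param cube A [hypercube].
#' @param register A `roi_register` from [read_roi_register()].
#' @param roi_id Identifier of the window to extract.
#' @return The windowed [hypercube]; wavelengths and quantity unchanged.
#' @export
crop_roi <- function(cube, register, roi_id) {
  stopifnot(inherits(cube, "hypercube"))
  i <- match(roi_id, register$roi_id)
  if (is.na(i)) abort_ms(sprintf("roi_id '%s' not present in register", roi_id), "lookup_error")
  r0 <- register$row0[i]; c0 <- register$col0[i]
  h <- register$height[i]; w <- register$width[i]
  d <- dim(cube$data)
  if (r0 < 0 || c0 < 0 || h < 1 || w < 1 || r0 + h > d[1] || c0 + w > d[2]) {
    abort_ms(sprintf("ROI '%s' window [%d,%d) x [%d,%d) exceeds cube extent %d x %d",
                     roi_id, r0, r0 + h, c0, c0 + w, d[1], d[2]), "bounds_error")
  }
  hypercube(cube$data[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), , drop = FALSE],
            cube$wavelengths_nm, quantity = cube$quantity,
            gsd_cm_per_px = cube$gsd_cm_per_px)
}

# ---- band pre-cleaning and reflectance --------------------------------------

#' Pre-clean a cube's bands by grayscale closing
#'
#' One pass of grayscale morphological closing with a 3x3 rectangular
#' structuring element, applied independently to every band. Fills small dark
#' speckle (dead pixels, shot noise) left after radiometric calibration.
#' Closing is extensive (`output >= input` pointwise) and idempotent.
#'
#' @param cube A [hypercube] with at least one band.
#' @return A [hypercube] of identical shape and quantity.
#' @export
preclean_cube <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  out <- cube$data
  for (b in seq_len(dim(out)[3])) out[, , b] <- close3(out[, , b], "box")
  hypercube(out, cube$wavelengths_nm, quantity = cube$quantity,
            gsd_cm_per_px = cube$gsd_cm_per_px)
}

#' Recover reflectance from radiance
#'
#' Divides each pixel spectrum by the white-reference illuminant, band by
#' band, and clips the result at `ceiling`. The white spectrum is linearly
#' interpolated onto the cube's wavelength axis when the two grids differ;
#' extrapolation outside the white reference's support is refused.
#'
#' @param cube A radiance [hypercube].
#' @param white A `white_reference`.
#' @param ceiling Upper clip for recovered reflectance (default 2). Radiance
#'   can exceed the panel signal on specular facets; the clip keeps the
#'   classifier's feature space bounded.
#' @return A reflectance [hypercube].
#' @export
to_reflectance <- function(cube, white, ceiling = 2.0) {
  stopifnot(inherits(cube, "hypercube"), inherits(white, "white_reference"))
  if (cube$quantity != "radiance") {
    abort_ms("to_reflectance expects a radiance cube", "data_error")
  }
  wl <- cube$wavelengths_nm
  if (min(wl) < min(white$wavelengths_nm) - 1e-9 ||
      max(wl) > max(white$wavelengths_nm) + 1e-9) {
    abort_ms("cube wavelengths extend beyond the white reference; extrapolation refused",
             "alignment_error")
  }
  w <- if (length(white$wavelengths_nm) == length(wl) &&
           all(abs(white$wavelengths_nm - wl) < 1e-9)) {
    white$intensity
  } else {
    stats::approx(white$wavelengths_nm, white$intensity, xout = wl)$y
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort_ms("white reference non-positive after resampling", "data_error")
  }
  out <- cube$data
  for (b in seq_along(wl)) out[, , b] <- pmin(out[, , b] / w[b], ceiling)
  hypercube(out, wl, quantity = "reflectance", gsd_cm_per_px = cube$gsd_cm_per_px)
}
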