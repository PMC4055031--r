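# Image and result I/O. PNG and TIFF via the png/tiff packages, NIfTI via
# RNifti; results serialize to JSON with a schema version so downstream
# tooling can detect format changes.

RESULT_SCHEMA_VERSION <- "1.0"

#' Read a 2D grayscale image
#'
#' Supports PNG, TIFF and NIfTI. Multi-channel rasters are converted to
#' grayscale by averaging channels. Integer-typed inputs are normalized to
#' \[0, 1\]; floating-point data pass through unchanged. For 3D NIfTI
#' volumes a `slice_index` (along the last axis) must be given.
#'
#' @param path file path (.png, .tif/.tiff, .nii/.nii.gz).
#' @param slice_index slice to extract from a 3D NIfTI volume.
#' @return numeric matrix.
#' @export
read_image <- function(path, slice_index = NULL) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  flatten <- function(a) {
    if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
    a
  }
  if (ext == "png") {
    img <- flatten(png::readPNG(path)) # already scaled to [0, 1]
  } else if (ext %in% c("tif", "tiff")) {
    img <- flatten(tiff::readTIFF(path)) # integer formats scaled to [0, 1]
  } else if (ext == "nii") {
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    if (length(d) == 3L && d[3] == 1L) {
      vol <- vol[, , 1]
      d <- dim(vol)
    }
    if (length(d) == 3L) {
      if (is.null(slice_index))
        stop("3D NIfTI volume requires `slice_index`: ", path)
      if (slice_index < 1 || slice_index > d[3])
        stop("slice_index out of range for ", path)
      img <- vol[, , slice_index]
    } else if (length(d) == 2L) {
      img <- vol[, ]
    } else stop("unsupported NIfTI dimensionality in ", path)
    img <- matrix(as.numeric(img), nrow(img), ncol(img))
    dt <- attr(RNifti::niftiHeader(path), "datatype")
    if (is.null(dt)) dt <- RNifti::niftiHeader(path)$datatype
    # integer datatypes (NIfTI codes < 16 except 0) get scaled to [0, 1]
    if (!is.null(dt) && dt %in% c(2, 4, 8, 256, 512, 768) && max(img) > 0)
      img <- img / max(img)
  } else {
    stop("unsupported image format: ", path)
  }
  as_image(img)
}

# big-endian 4-byte encoding of a nonnegative number < 2^32
int_to_raw4 <- function(n) {
  as.raw(c(n %/% 16777216, (n %/% 65536) %% 256, (n %/% 256) %% 256, n %% 256))
}

# CRC-32 (IEEE, as required by PNG chunk trailers) of a raw vector
crc32_raw4 <- function(r) {
  hex <- formatC(digest::digest(r, algo = "crc32", serialize = FALSE),
                 width = 8, flag = "0")
  int_to_raw4(strtoi(substr(hex, 1, 4), 16L) * 65536 +
              strtoi(substr(hex, 5, 8), 16L))
}

# Minimal 16-bit grayscale PNG encoder. The png package reads 16-bit PNGs
# but writes only 8 bits per sample, which would quantize phantom images;
# the format itself is simple enough to emit directly: IHDR / IDAT / IEND
# chunks, scanlines with filter byte 0, and the zlib stream that
# memCompress(type = "gzip") produces (it emits zlib framing with the
# Adler-32 trailer, which is exactly what the IDAT chunk holds).
write_png16 <- function(img, path) {
  v <- round(pmin(pmax(img, 0), 1) * 65535)
  h <- nrow(v)
  w <- ncol(v)
  scan <- rbind(matrix(0, 1, h),
                matrix(rbind(as.vector(t(v) %/% 256), as.vector(t(v) %% 256)),
                       2L * w, h))
  raw_data <- as.raw(as.vector(scan))
  zlib <- memCompress(raw_data, "gzip")
  if (zlib[1] != as.raw(0x78))
    stop("unexpected compression framing from memCompress")
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(int_to_raw4(length(data)), body, crc32_raw4(body))
  }
  ihdr <- c(int_to_raw4(w), int_to_raw4(h),
            as.raw(c(16, 0, 0, 0, 0))) # depth 16, grayscale, no interlace
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           chunk("IHDR", ihdr), chunk("IDAT", zlib), chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

#' Write a 2D image to PNG (16-bit) or TIFF (32-bit float)
#'
#' PNG output is clipped to \[0, 1\] and stored with 16 bits per sample;
#' TIFF output stores 32-bit floats losslessly.
#'
#' @param img numeric matrix.
#' @param path destination ending in .png, .tif or .tiff.
#' @export
write_image <- function(img, path) {
  img <- as_image(img)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    write_png16(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 32L)
  } else stop("unsupported output format: ", path)
  invisible(path)
}

#' Serialize an estimate or registration result to JSON
#'
#' Writes a schema-versioned JSON file. For rotation estimates the cost
#' curve is included only when `dump_curve = TRUE`.
#'
#' @param x a `"rotation_estimate"`, `"edgemap_estimate"` or
#'   `"registration_result"`.
#' @param path output path.
#' @param dump_curve include the full cost curve (default FALSE).
#' @export
write_result <- function(x, path, dump_curve = FALSE) {
  out <- list(schema_version = RESULT_SCHEMA_VERSION)
  if (inherits(x, "rotation_estimate")) {
    out <- c(out, list(
      type = "rotation_estimate", angle_deg = x$angle_deg,
      refined_angle_deg = x$refined_angle_deg, J = x$J, K = x$K,
      metric = x$metric, ambiguous_180 = x$ambiguous_180,
      runner_up = x$runner_up))
    if (dump_curve) out$cost_curve <- x$cost_curve
  } else if (inherits(x, "edgemap_estimate")) {
    out <- c(out, list(
      type = "edgemap_estimate", angle_deg = x$angle_deg,
      peak_value = x$peak_value, angular_bins = x$angular_bins))
  } else if (inherits(x, "registration_result")) {
    out <- c(out, list(
      type = "registration_result", params = unclass(x$params),
      ssd_initial = x$ssd_initial, ssd_final = x$ssd_final,
      iterations = x$iterations, converged = x$converged,
      initialized_rotation = x$initialized_rotation))
  } else stop("unsupported result type: ", paste(class(x), collapse = "/"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write result to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}
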