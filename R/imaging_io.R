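# Raster readers/writers. Gray images travel as numeric matrices on the
# 0-255 scale; binary masks are written as 8-bit 0/255 PNGs so a read-back
# followed by thresholding at 128 is an exact round trip.

png_bit_depth <- function(path) {
  # IHDR bit-depth byte: 8-byte signature + 4 length + 4 "IHDR" + 8 (w, h).
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("malformed image: ", path)
  as.integer(hdr[25L])
}

#' Read a grayscale raster
#'
#' Reads a lossless raster (PNG or TIFF) as a gray image on the 0-255 scale.
#' 8-bit input maps identically (a stored 114 reads back as 114); 16-bit
#' input is linearly rescaled from its own min/max onto 0-255; color input is
#' converted by the arithmetic mean of the first three channels (any alpha
#' channel is ignored).
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric matrix of intensities in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("input not found: ", path)
  if (file.size(path) == 0L) stop("malformed image: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("malformed image: unsupported format '", ext, "'")
    ),
    error = function(e) stop("malformed image: ", conditionMessage(e))
  )
  bits <- if (ext == "png") {
    png_bit_depth(path)
  } else {
    b <- attr(tiff::readTIFF(path, info = TRUE), "bits.per.sample")
    if (is.null(b)) 8L else as.integer(b)
  }
  if (length(dim(arr)) == 3L) {
    nch <- min(dim(arr)[3L], 3L) # drop alpha
    arr <- apply(arr[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  if (!is.matrix(arr) || length(arr) == 0L) stop("malformed image: ", path)
  if (bits > 8L) {
    raw <- arr * (2^bits - 1)
    rng <- range(raw)
    if (rng[2] > rng[1]) {
      arr <- 255 * (raw - rng[1]) / (rng[2] - rng[1])
    } else {
      arr <- 255 * arr
    }
  } else {
    arr <- arr * 255
  }
  as_gray_image(arr)
}

#' Write a gray image
#'
#' Quantizes to 8 bits (round + clamp to `[0, 255]`) and writes a PNG or
#' TIFF depending on the file extension.
#'
#' @param image gray image matrix.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  check_writable(path)
  scaled <- round(clamp255(image)) / 255
  write_raster(scaled, path)
  invisible(path)
}

#' Write a binary mask
#'
#' Writes an 8-bit raster with 0 -> 0 and 1 -> 255. `read_mask()` (threshold
#' at 128) reproduces the mask bit-exactly.
#'
#' @param mask binary mask matrix.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  check_writable(path)
  write_raster(mask, path)
  invisible(path)
}

#' Read a binary mask
#'
#' Reads a raster and thresholds at 128: intensities >= 128 become 1.
#'
#' @param path path to a mask raster.
#' @return binary mask matrix.
#' @export
read_mask <- function(path) {
  img <- read_gray_image(path)
  as_binary_mask((img >= 128) * 1)
}

check_writable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output not writable: ", path)
  invisible(TRUE)
}

write_raster <- function(scaled01, path) {
  storage.mode(scaled01) <- "double"
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
      png = png::writePNG(scaled01, path),
      tif = ,
      tiff = tiff::writeTIFF(scaled01, path, bits.per.sample = 8L),
      stop("unsupported output format '", ext, "'")
    )
    TRUE
  }, error = function(e) stop("output not writable: ", conditionMessage(e)))
  invisible(ok)
}
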