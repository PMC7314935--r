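#' Grey image container
#'
#' A `grey_image` holds a single-channel intensity raster together with the
#' acquisition metadata needed by the scratch-assay pipeline: the experimental
#' condition, the replicate id, and the time post-scratch in hours.
#'
#' Pixels are stored as a numeric matrix with `nrow = height` rows and
#' `ncol = width` columns, intensities in `[0, 1]`. Pixel coordinates follow
#' R's 1-based `(row, column)` convention; column indices increase rightward.
#'
#' @param pixels numeric matrix of intensities in `[0, 1]` (rows = height).
#' @param condition free-text condition label.
#' @param replicate positive integer replicate id.
#' @param hour non-negative time post-scratch, hours.
#' @return An object of class `grey_image` with elements `pixels`, `height`,
#'   `width`, `condition`, `replicate`, `hour`.
#' @export
grey_image <- function(pixels, condition = "unknown", replicate = 1L, hour = 0) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("all intensities must be finite and non-negative")
  if (length(replicate) != 1L || is.na(replicate) || replicate < 1)
    stop("'replicate' must be a positive integer")
  if (length(hour) != 1L || is.na(hour) || hour < 0)
    stop("'hour' must be a non-negative number")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         condition = as.character(condition), replicate = as.integer(replicate),
         hour = as.numeric(hour)),
    class = "grey_image")
}

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf("<grey_image> %d x %d px  condition=%s replicate=%d hour=%g\n",
              x$width, x$height, x$condition, x$replicate, x$hour))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Rec. 709 luminance weights for RGB -> grey conversion
.LUMA <- c(0.2126, 0.7152, 0.0722)

#' Load a raster image as a grey image
#'
#' Reads a TIFF or PNG file and normalizes it into a [grey_image]. RGB inputs
#' are collapsed to a single channel with Rec. 709 luminance weights
#' (0.2126 R + 0.7152 G + 0.0722 B); an alpha channel, if present, is ignored.
#' Intensities are rescaled to `[0, 1]` regardless of the stored bit depth.
#'
#' @param path path to a readable TIFF (.tif/.tiff) or PNG (.png) file.
#' @param condition,replicate,hour metadata attached to the returned image.
#' @return A [grey_image].
#' @export
load_image <- function(path, condition = "unknown", replicate = 1L, hour = 0) {
  if (!file.exists(path))
    stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tryCatch(tiff::readTIFF(path),
                            error = function(e) stop("cannot read image file: ", path)),
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop("cannot read image file: ", path)),
    stop("unsupported image format '", ext, "' for: ", path))
  if (length(raw) == 0L)
    stop("zero-sized image: ", path)
  if (length(dim(raw)) == 3L) {
    nch <- dim(raw)[3L]
    if (nch >= 3L) {
      raw <- .LUMA[1] * raw[, , 1] + .LUMA[2] * raw[, , 2] + .LUMA[3] * raw[, , 3]
    } else {
      raw <- raw[, , 1]
    }
  }
  raw <- pmin(pmax(raw, 0), 1)
  grey_image(raw, condition = condition, replicate = replicate, hour = hour)
}

#' Write a grey image to TIFF or PNG
#'
#' Intensities are clamped to `[0, 1]` and written at the requested bit depth.
#' The format is chosen from the file extension.
#'
#' @param image a [grey_image].
#' @param path output path ending in .tif/.tiff or .png.
#' @param bits_per_sample bit depth for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits_per_sample = 16L) {
  stopifnot(inherits(image, "grey_image"))
  px <- pmin(pmax(image$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = bits_per_sample),
    png = png::writePNG(px, path),
    stop("unsupported image format '", ext, "' for: ", path))
  invisible(path)
}

#' Load an experiment manifest
#'
#' The manifest is a CSV file with the header `path,condition,replicate,hour`,
#' one row per image. Relative image paths are resolved against the directory
#' containing the manifest. Each `(condition, replicate, hour)` triple must be
#' unique, and every `(condition, replicate)` series must include an hour-0
#' entry, which anchors the disruption-center alignment.
#'
#' @param path path to the manifest CSV.
#' @return A data frame of class `scratch_manifest` with columns `path`,
#'   `condition`, `replicate`, `hour`, sorted by (condition, replicate, hour).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path))
    stop("cannot read manifest file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("manifest is empty: ", path)
  required <- c("path", "condition", "replicate", "hour")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest missing required column(s): ", paste(missing, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  df$hour <- as.numeric(df$hour)
  if (any(is.na(df$replicate)) || any(df$replicate < 1))
    stop("manifest 'replicate' entries must be positive integers")
  if (any(is.na(df$hour)) || any(df$hour < 0))
    stop("manifest 'hour' entries must be non-negative numbers")
  key <- paste(df$condition, df$replicate, df$hour, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (condition, replicate, hour) in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  series <- split(df$hour, paste(df$condition, df$replicate, sep = "/"))
  no_t0 <- names(series)[!vapply(series, function(h) any(h == 0), logical(1))]
  if (length(no_t0))
    stop("replicate series lacking an hour-0 entry: ",
         paste(no_t0, collapse = ", "))
  # resolve relative paths against the manifest location
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(base, df$path[rel])
  df <- df[order(df$condition, df$replicate, df$hour), required]
  rownames(df) <- NULL
  class(df) <- c("scratch_manifest", "data.frame")
  df
}

#' Write an experiment manifest
#'
#' @param entries data frame with columns `path`, `condition`, `replicate`,
#'   `hour`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  stopifnot(all(c("path", "condition", "replicate", "hour") %in% names(entries)))
  utils::write.csv(entries[, c("path", "condition", "replicate", "hour")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
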