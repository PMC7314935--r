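#' Segmentation parameters
#'
#' Parameters for gradient-magnitude binarization. Cells are textured and
#' edge-rich, so their gradient magnitudes are high; cell-free media is flat
#' and dark in gradient space. Thresholding the gradient map therefore codes
#' cell edges and texture as white; morphological closing and hole filling
#' then turn cell interiors white, and small white specks are removed.
#'
#' @param smoothing_sigma Gaussian pre-smoothing in pixels before the gradient
#'   is taken (0 disables smoothing). Default 1.
#' @param threshold_method `"otsu"` (threshold chosen by Otsu's method on the
#'   gradient-magnitude histogram) or `"fixed"`.
#' @param fixed_threshold gradient-magnitude threshold used when
#'   `threshold_method = "fixed"`; intensities are on `[0, 1]`.
#' @param closing_radius radius in pixels of the disc structuring element used
#'   for morphological closing. Default 5.
#' @param min_object_area white connected components smaller than this area in
#'   pixels are removed. Default 64.
#' @param fill_holes fill black holes enclosed by white regions. Default TRUE.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 1,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0.05,
                                closing_radius = 5L,
                                min_object_area = 64L,
                                fill_holes = TRUE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(smoothing_sigma >= 0, closing_radius >= 0, min_object_area >= 0,
            fixed_threshold >= 0, is.logical(fill_holes))
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 closing_radius = as.integer(closing_radius),
                 min_object_area = as.integer(min_object_area),
                 fill_holes = isTRUE(fill_holes)),
            class = "segmentation_params")
}

#' Binary cell/media mask
#'
#' `TRUE` (white) marks cell pixels, `FALSE` (black) marks media pixels.
#'
#' @param pixels logical matrix.
#' @param condition,replicate,hour metadata carried over from the source image.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, condition = "unknown", replicate = 1L, hour = 0) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("'pixels' must be a logical matrix")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         condition = as.character(condition), replicate = as.integer(replicate),
         hour = as.numeric(hour)),
    class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px  white (cell) fraction %.3f\n",
              x$width, x$height, mean(x$pixels)))
  invisible(x)
}

#' Gradient magnitude of an intensity image
#'
#' Smooths the image with an isotropic Gaussian of standard deviation
#' `smoothing_sigma` and returns the per-pixel Euclidean magnitude of the
#' intensity gradient, computed by central differences (one-sided at image
#' borders). Flat regions map to 0; edges and texture map to high values.
#'
#' @param image a [grey_image] or a numeric matrix.
#' @param smoothing_sigma Gaussian pre-smoothing sigma in pixels; 0 skips
#'   smoothing.
#' @return A numeric matrix of non-negative gradient magnitudes, same
#'   dimensions as the input.
#' @export
gradient_magnitude <- function(image, smoothing_sigma = 1) {
  px <- if (inherits(image, "grey_image")) image$pixels else image
  stopifnot(is.matrix(px), is.numeric(px), smoothing_sigma >= 0)
  if (smoothing_sigma > 0)
    px <- EBImage::gblur(px, sigma = smoothing_sigma, boundary = "replicate")
  nr <- nrow(px); nc <- ncol(px)
  # central differences along rows and columns, one-sided at the borders
  dr <- px
  if (nr >= 3L)
    dr[2:(nr - 1L), ] <- (px[3:nr, ] - px[1:(nr - 2L), ]) / 2
  if (nr >= 2L) {
    dr[1L, ] <- px[2L, ] - px[1L, ]
    dr[nr, ] <- px[nr, ] - px[nr - 1L, ]
  } else dr[] <- 0
  dc <- px
  if (nc >= 3L)
    dc[, 2:(nc - 1L)] <- (px[, 3:nc] - px[, 1:(nc - 2L)]) / 2
  if (nc >= 2L) {
    dc[, 1L] <- px[, 2L] - px[, 1L]
    dc[, nc] <- px[, nc] - px[, nc - 1L]
  } else dc[] <- 0
  sqrt(dr * dr + dc * dc)
}

# closing -> hole fill -> small-object removal, in that order
.clean_mask <- function(bw, params) {
  if (params$closing_radius > 0) {
    size <- 2L * params$closing_radius + 1L
    bw <- EBImage::closing(bw, EBImage::makeBrush(size, shape = "disc")) > 0.5
  }
  if (params$fill_holes)
    bw <- EBImage::fillHull(bw * 1L) > 0.5
  if (params$min_object_area > 0 && any(bw)) {
    lab <- EBImage::bwlabel(bw)
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= params$min_object_area)
    bw <- matrix(lab %in% keep, nrow(bw), ncol(bw))
  }
  bw
}

#' Binarize an image into a cell/media mask
#'
#' Pipeline: gradient magnitude of the smoothed image, threshold (Otsu on the
#' magnitude histogram, or a fixed value), morphological closing with a disc,
#' optional hole filling, and removal of small white components. High-gradient
#' (edge) pixels end up white, so cell borders are coded as cell; closing and
#' hole filling extend white into cell interiors; textureless media stays
#' black.
#'
#' If the gradient-magnitude histogram is degenerate (single-valued, e.g. a
#' perfectly uniform image), the mask is all black and a warning is emitted:
#' a media-only field is a legitimate observation, not an error.
#'
#' @param image a [grey_image].
#' @param params a [segmentation_params] object.
#' @return A [binary_mask] with white = cell, black = media.
#' @export
binarize <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "grey_image"), inherits(params, "segmentation_params"))
  if (image$height < 2L || image$width < 2L)
    stop("image must be at least 2 x 2 pixels to binarize")
  mag <- gradient_magnitude(image, params$smoothing_sigma)
  rng <- range(mag)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    warning("degenerate gradient-magnitude histogram; returning all-black mask")
    bw <- matrix(FALSE, image$height, image$width)
    return(binary_mask(bw, image$condition, image$replicate, image$hour))
  }
  thr <- switch(params$threshold_method,
    otsu  = EBImage::otsu(EBImage::Image(mag), range = c(rng[1], rng[2]),
                          levels = 256L),
    fixed = params$fixed_threshold)
  bw <- mag > thr
  bw <- .clean_mask(bw, params)
  binary_mask(bw, image$condition, image$replicate, image$hour)
}

#' Apply mask cleanup only
#'
#' Runs the post-threshold cleanup stages (closing, hole fill, small-object
#' removal) on an existing mask. Cleanup is idempotent: applying it to an
#' already-cleaned mask changes nothing.
#'
#' @param mask a [binary_mask].
#' @param params a [segmentation_params] object.
#' @return A cleaned [binary_mask].
#' @export
clean_mask <- function(mask, params = segmentation_params()) {
  stopifnot(inherits(mask, "binary_mask"))
  binary_mask(.clean_mask(mask$pixels, params),
              mask$condition, mask$replicate, mask$hour)
}

#' Write a binary mask as a PNG file
#'
#' White (cell) pixels are written as 1, black (media) pixels as 0.
#'
#' @param mask a [binary_mask].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$pixels * 1, path)
  invisible(path)
}

#' Intersection-over-union of two masks
#'
#' @param a,b logical matrices or [binary_mask] objects of equal dimensions.
#' @return IoU in `[0, 1]`; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  pa <- if (inherits(a, "binary_mask")) a$pixels else a
  pb <- if (inherits(b, "binary_mask")) b$pixels else b
  stopifnot(identical(dim(pa), dim(pb)))
  uni <- sum(pa | pb)
  if (uni == 0) return(1)
  sum(pa & pb) / uni
}
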