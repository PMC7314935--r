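#' Rectangular region of interest
#'
#' Half-open in neither sense: the ROI covers rows `top..bottom` and columns
#' `left..right` inclusive, 1-based.
#'
#' @param top,left,bottom,right 1-based pixel indices.
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(top, left, bottom, right) {
  stopifnot(top >= 1, left >= 1, bottom >= top, right >= left)
  structure(list(top = as.integer(top), left = as.integer(left),
                 bottom = as.integer(bottom), right = as.integer(right)),
            class = "rect_roi")
}

#' Spot-detection parameters
#'
#' Multi-scale Laplacian-of-Gaussian (LoG) blob detection, sized by default
#' for bright roundish objects of roughly 5-15 px diameter (e.g. fluorescently
#' labelled cell bodies).
#'
#' @param min_sigma,max_sigma LoG scale range in pixels (defaults 2 and 8).
#' @param n_sigma number of scales, log-spaced between the two.
#' @param detect_threshold minimum scale-normalized LoG response for a
#'   maximum to count as a spot; intensities on `[0, 1]`. Default 0.05.
#' @param min_separation maxima closer than this (pixels) are merged, keeping
#'   the stronger. Default 5.
#' @return A list of class `spot_params`.
#' @export
spot_params <- function(min_sigma = 2, max_sigma = 8, n_sigma = 8L,
                        detect_threshold = 0.05, min_separation = 5) {
  stopifnot(min_sigma > 0, max_sigma >= min_sigma, detect_threshold > 0,
            min_separation >= 0, n_sigma >= 1)
  structure(list(min_sigma = min_sigma, max_sigma = max_sigma,
                 n_sigma = as.integer(n_sigma),
                 detect_threshold = detect_threshold,
                 min_separation = min_separation),
            class = "spot_params")
}

# scale-normalized negative LoG response (positive for bright blobs),
# computed by direct convolution with an analytic LoG kernel
.log_response <- function(px, sigma) {
  half <- max(3L, as.integer(ceiling(3.5 * sigma)))
  x <- (-half):half
  g1 <- exp(-x^2 / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  # separable parts of the LoG: d2/dx2 of the 1-D Gaussian
  d2 <- (x^2 / sigma^4 - 1 / sigma^2) * g1
  # LoG(x,y) = d2(x) g(y) + g(x) d2(y); convolve separably via filter2
  k1 <- outer(d2, g1)
  k2 <- outer(g1, d2)
  resp <- EBImage::filter2(px, k1 + k2, boundary = "replicate")
  -sigma^2 * resp
}

#' Count bright spots in a region of interest
#'
#' Runs multi-scale Laplacian-of-Gaussian blob detection over the image,
#' keeps local maxima of the scale-maximized response above
#' `detect_threshold`, merges maxima closer than `min_separation` (keeping
#' the stronger), and restricts the result to the ROI.
#'
#' @param image a [grey_image] (fluorescence channel) or numeric matrix.
#' @param roi a [rect_roi]; must lie within the image.
#' @param params a [spot_params] object.
#' @return List with `count` and `spots`, a data frame with one row per
#'   detected spot: `row`, `col`, `sigma` (scale of the strongest response)
#'   and `response`.
#' @export
count_spots <- function(image, roi = NULL, params = spot_params()) {
  px <- if (inherits(image, "grey_image")) image$pixels else image
  stopifnot(is.matrix(px), inherits(params, "spot_params"))
  nr <- nrow(px); nc <- ncol(px)
  if (is.null(roi)) roi <- rect_roi(1, 1, nr, nc)
  stopifnot(inherits(roi, "rect_roi"))
  if (roi$bottom > nr || roi$right > nc)
    stop("ROI [", roi$top, ":", roi$bottom, ", ", roi$left, ":", roi$right,
         "] outside image bounds (", nr, " x ", nc, ")")
  sigmas <- if (params$n_sigma == 1L) params$min_sigma else
    exp(seq(log(params$min_sigma), log(params$max_sigma),
            length.out = params$n_sigma))
  best <- matrix(-Inf, nr, nc)
  best_sigma <- matrix(sigmas[1L], nr, nc)
  for (s in sigmas) {
    r <- .log_response(px, s)
    upd <- r > best
    best[upd] <- r[upd]
    best_sigma[upd] <- s
  }
  # 2-D local maxima of the scale-maximized response
  dil <- EBImage::dilate(best, EBImage::makeBrush(3L, "box"))
  peak <- which(best >= dil & best > params$detect_threshold, arr.ind = TRUE)
  if (nrow(peak) == 0L)
    return(list(count = 0L,
                spots = data.frame(row = integer(), col = integer(),
                                   sigma = numeric(), response = numeric())))
  spots <- data.frame(row = peak[, 1L], col = peak[, 2L],
                      sigma = best_sigma[peak],
                      response = best[peak])
  # greedy non-maximum suppression by distance
  spots <- spots[order(-spots$response), , drop = FALSE]
  keep <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (spots$row[keep] - spots$row[i])^2 + (spots$col[keep] - spots$col[i])^2
    if (all(d2 >= params$min_separation^2)) keep[i] <- TRUE
  }
  spots <- spots[keep, , drop = FALSE]
  inside <- spots$row >= roi$top & spots$row <= roi$bottom &
    spots$col >= roi$left & spots$col <= roi$right
  spots <- spots[inside, , drop = FALSE]
  rownames(spots) <- NULL
  list(count = nrow(spots), spots = spots)
}

#' Immunofluorescence area fraction and per-nucleus signal
#'
#' Thresholds a fluorescence image and reports the fraction of pixels above
#' threshold (an abundance proxy for stained extracellular matrix) and the
#' above-threshold pixel count normalized to the number of nuclei in the
#' field. Fold changes between two conditions are the ratio of their
#' per-nucleus signals (see [fold_change]).
#'
#' @param image a [grey_image] (fluorescence channel) or numeric matrix.
#' @param signal_threshold intensity cutoff in `(0, 1)`.
#' @param nuclei_count number of nuclei in the field (>= 1), e.g. from a
#'   counterstain count.
#' @return List with `area_fraction`, `per_nucleus` (above-threshold pixels
#'   per nucleus), and `signal_px`.
#' @export
area_fraction <- function(image, signal_threshold = 0.5, nuclei_count = 1L) {
  px <- if (inherits(image, "grey_image")) image$pixels else image
  stopifnot(is.matrix(px), signal_threshold > 0, signal_threshold < 1)
  if (length(nuclei_count) != 1L || is.na(nuclei_count) || nuclei_count < 1)
    stop("'nuclei_count' must be a positive integer")
  signal <- sum(px > signal_threshold)
  list(area_fraction = signal / length(px),
       per_nucleus = signal / nuclei_count,
       signal_px = signal)
}

#' Fold change between per-nucleus signals
#'
#' @param treated,control outputs of [area_fraction] (or bare per-nucleus
#'   numbers).
#' @return `treated / control` on the per-nucleus scale.
#' @export
fold_change <- function(treated, control) {
  a <- if (is.list(treated)) treated$per_nucleus else treated
  b <- if (is.list(control)) control$per_nucleus else control
  if (b <= 0) stop("control per-nucleus signal must be positive")
  a / b
}
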