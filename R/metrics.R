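#' Disruption (gap) region from the hour-0 profile
#'
#' The initial gap region is the maximal contiguous run of columns whose
#' black fraction is at or above `threshold`, containing the detected
#' disruption center. The default threshold of 0.95 (rather than exactly 1)
#' keeps a few stray white pixels from fragmenting the run on textured
#' backgrounds.
#'
#' @param profile0 hour-0 `column_profile`.
#' @param center 1-based disruption center column (from [find_gap_center]).
#' @param threshold black-fraction cutoff in `(0, 1]` defining "gap" columns.
#' @return An object of class `gap_region`: list with `left` and `right`
#'   (1-based, closed interval `[left, right]`) and `width` in columns.
#' @export
gap_region_from_t0 <- function(profile0, center, threshold = 0.95) {
  stopifnot(inherits(profile0, "column_profile"),
            threshold > 0, threshold <= 1)
  if (!isTRUE(profile0$hour == 0))
    stop("gap region must be derived from an hour-0 profile")
  bf <- profile0$black_fraction
  if (center < 1L || center > length(bf))
    stop("'center' out of bounds")
  if (is.na(bf[center]) || bf[center] < threshold)
    stop("no gap at center: black fraction ", sprintf("%.3f", bf[center]),
         " at column ", center, " is below threshold ", threshold)
  left <- center
  while (left > 1L && !is.na(bf[left - 1L]) && bf[left - 1L] >= threshold)
    left <- left - 1L
  right <- center
  while (right < length(bf) && !is.na(bf[right + 1L]) && bf[right + 1L] >= threshold)
    right <- right + 1L
  structure(list(left = as.integer(left), right = as.integer(right),
                 width = as.integer(right - left + 1L)),
            class = "gap_region")
}

#' @export
print.gap_region <- function(x, ...) {
  cat(sprintf("<gap_region> columns [%d, %d], width %d\n",
              x$left, x$right, x$width))
  invisible(x)
}

#' Gap width at any hour
#'
#' Width in columns of the contiguous run of columns at or above the
#' black-fraction threshold that contains (or, failing that, lies nearest)
#' the anchor column. The anchor is the replicate's own hour-0 disruption
#' center, so the measurement tracks the same scratch as it closes. Returns
#' 0 when no qualifying column remains within `search_halfwidth` of the
#' anchor (the gap has closed).
#'
#' @param profile a `column_profile` at any hour.
#' @param center anchor column (the hour-0 disruption center).
#' @param threshold black-fraction cutoff, as in [gap_region_from_t0].
#' @param search_halfwidth how far from the anchor (columns) to look for a
#'   remaining gap run. Default 100.
#' @return Gap width in columns (0 when fully closed).
#' @export
gap_width <- function(profile, center, threshold = 0.95,
                      search_halfwidth = 100L) {
  stopifnot(inherits(profile, "column_profile"))
  bf <- profile$black_fraction
  if (center < 1L || center > length(bf))
    stop("'center' out of bounds")
  qual <- !is.na(bf) & bf >= threshold
  if (!any(qual)) return(0L)
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # distance from the anchor to each run (0 if the run contains it)
  dist <- pmax(starts[runs] - center, center - ends[runs], 0L)
  nearest <- runs[which.min(dist)]
  if (min(dist) > search_halfwidth) return(0L)
  as.integer(r$lengths[nearest])
}

#' Percent gap closure relative to hour 0
#'
#' `100 * (1 - width_t / width_0)`; 0 at hour 0 by construction, 100 when the
#' gap has fully closed.
#'
#' @param width_t gap width at the later hour, columns.
#' @param width_0 gap width at hour 0, columns (> 0).
#' @return Percent closure.
#' @export
closure_percent <- function(width_t, width_0) {
  if (width_0 <= 0) stop("'width_0' must be positive")
  100 * (1 - width_t / width_0)
}

#' Cell-to-space ratio within the initial gap region
#'
#' White:black pixel ratio of a mask restricted to the columns of the hour-0
#' gap region — the endpoint used to quantify migration into the scratch.
#' The companion `occupied_fraction` (white / (white + black)) is always
#' finite and satisfies
#' `occupied_fraction = ratio / (1 + ratio)` whenever the ratio is finite;
#' the ratio itself is `Inf` when the region contains no black pixel.
#'
#' @param mask a [binary_mask] at any hour.
#' @param region a `gap_region` derived from the same replicate's hour-0
#'   profile.
#' @return List with `cell_to_space_ratio`, `occupied_fraction`,
#'   `white_px`, `black_px`.
#' @export
cell_to_space_ratio <- function(mask, region) {
  stopifnot(inherits(mask, "binary_mask"), inherits(region, "gap_region"))
  if (region$left < 1L || region$right > mask$width || region$left > region$right)
    stop("gap region [", region$left, ", ", region$right,
         "] outside mask bounds (width ", mask$width, ")")
  sub <- mask$pixels[, region$left:region$right, drop = FALSE]
  white <- sum(sub)
  black <- length(sub) - white
  list(cell_to_space_ratio = if (black > 0) white / black else Inf,
       occupied_fraction = white / length(sub),
       white_px = white, black_px = black)
}

#' Gap metrics for one replicate series
#'
#' Convenience wrapper computing, per hour, the gap width, percent closure,
#' and cell-to-space ratio / occupied fraction inside the hour-0 gap region.
#'
#' @param masks list of [binary_mask]es of one replicate, containing hour 0.
#' @param threshold black-fraction cutoff for gap columns.
#' @return A data frame with one row per hour: `condition`, `replicate`,
#'   `hour`, `gap_width_px`, `closure_percent`, `cell_to_space_ratio`,
#'   `occupied_fraction`.
#' @export
gap_metrics <- function(masks, threshold = 0.95) {
  stopifnot(length(masks) >= 1L,
            all(vapply(masks, inherits, logical(1), "binary_mask")))
  hours <- vapply(masks, `[[`, numeric(1), "hour")
  if (!any(hours == 0)) stop("replicate series lacks an hour-0 mask")
  masks <- masks[order(hours)]
  hours <- sort(hours)
  profiles <- lapply(masks, column_profile)
  center <- find_gap_center(profiles[[which(hours == 0)[1L]]])
  region <- gap_region_from_t0(profiles[[which(hours == 0)[1L]]], center,
                               threshold)
  width0 <- region$width
  rows <- lapply(seq_along(masks), function(i) {
    w <- gap_width(profiles[[i]], center, threshold)
    cs <- cell_to_space_ratio(masks[[i]], region)
    data.frame(condition = masks[[i]]$condition,
               replicate = masks[[i]]$replicate,
               hour = hours[i],
               gap_width_px = w,
               closure_percent = closure_percent(w, width0),
               cell_to_space_ratio = cs$cell_to_space_ratio,
               occupied_fraction = cs$occupied_fraction)
  })
  do.call(rbind, rows)
}
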