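#' Column-wise black/white profile of a mask
#'
#' For each of the mask's columns, computes the fraction of black (media)
#' pixels and the black-to-white pixel ratio. The black fraction is the
#' primary statistic: it is bounded in `[0, 1]` and averages cleanly across
#' replicates. The B/W ratio is reported alongside it; columns with zero
#' white pixels (the fully disrupted scratch columns) have an infinite ratio
#' and are flagged rather than averaged.
#'
#' @param mask a [binary_mask] (white = cell, black = media).
#' @return An object of class `column_profile`: list with `black_fraction`
#'   and `bw_ratio` (numeric vectors of length `width`; `bw_ratio` is `Inf`
#'   where a column is all black), `height`, `width`, `hour`, `replicate`,
#'   `condition`, and `center` (`NA` until [find_gap_center] is applied).
#' @export
column_profile <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  white <- colSums(mask$pixels)
  black <- mask$height - white
  structure(
    list(black_fraction = black / mask$height,
         bw_ratio = ifelse(white > 0, black / white, Inf),
         height = mask$height, width = mask$width,
         condition = mask$condition, replicate = mask$replicate,
         hour = mask$hour, center = NA_integer_),
    class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf("<column_profile> %d columns  hour=%g replicate=%d center=%s\n",
              x$width, x$hour, x$replicate,
              if (is.na(x$center)) "unset" else x$center))
  invisible(x)
}

#' Locate the disruption (scratch) center at hour 0
#'
#' The scratch center is defined from the hour-0 profile as the center column
#' of the disruption region. If any columns are entirely black
#' (`black_fraction == 1`), the center is the midpoint of the longest
#' contiguous run of such columns (lower median for even-length runs, ties
#' between equally long runs broken toward the left). If no all-black column
#' exists, the profile is smoothed with a 51-column moving average and the
#' argmax is returned, with a warning that the disruption is only partial.
#'
#' @param profile a `column_profile` taken at hour 0.
#' @return 1-based column index of the disruption center.
#' @export
find_gap_center <- function(profile) {
  stopifnot(inherits(profile, "column_profile"))
  if (!isTRUE(profile$hour == 0))
    stop("gap center must be located on an hour-0 profile (got hour ",
         profile$hour, ")")
  bf <- profile$black_fraction
  if (max(bf) < 0.5)
    stop("no detectable disruption: maximum column black fraction ",
         sprintf("%.3f", max(bf)), " < 0.5")
  solid <- bf >= 1
  if (any(solid)) {
    r <- rle(solid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    return(as.integer(floor((starts[best] + ends[best]) / 2)))
  }
  warning("no all-black column at hour 0; using smoothed argmax of the ",
          "black-fraction profile")
  k <- 51L
  sm <- stats::filter(bf, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- -Inf  # border columns lack a full window
  as.integer(which.max(sm))
}

#' Re-center a column profile onto a common axis
#'
#' Shifts the profile by an integer number of columns so that `center` lands
#' on `target_center` of an axis of `target_width` columns. Source columns
#' shifted outside the axis are dropped; axis columns with no source column
#' are `NA` (missing), never zero-filled. No interpolation is performed.
#'
#' @param profile a `column_profile`.
#' @param center 1-based column index of the disruption center in `profile`
#'   (for hours > 0, the center inherited from the replicate's hour-0 image).
#' @param target_center 1-based target column; defaults to
#'   `floor(target_width / 2) + 1`, the center of the common axis.
#' @param target_width width of the common axis in columns.
#' @return A `column_profile` of width `target_width` with `center` set to
#'   `target_center`; missing columns are `NA` in both vectors.
#' @export
recenter <- function(profile, center, target_width = profile$width,
                     target_center = floor(target_width / 2) + 1L) {
  stopifnot(inherits(profile, "column_profile"))
  if (target_width <= 0)
    stop("'target_width' must be positive")
  if (center < 1L || center > profile$width)
    stop("'center' must lie within the profile (1..", profile$width, ")")
  shift <- as.integer(target_center - center)
  src <- seq_len(target_width) - shift     # source column for each target column
  ok <- src >= 1L & src <= profile$width
  bf <- rep(NA_real_, target_width)
  bw <- rep(NA_real_, target_width)
  bf[ok] <- profile$black_fraction[src[ok]]
  bw[ok] <- profile$bw_ratio[src[ok]]
  structure(
    list(black_fraction = bf, bw_ratio = bw,
         height = profile$height, width = as.integer(target_width),
         condition = profile$condition, replicate = profile$replicate,
         hour = profile$hour, center = as.integer(target_center)),
    class = "column_profile")
}

#' Average re-centered replicate profiles at one time point
#'
#' Per-column mean of the black fraction over the replicates contributing a
#' value at that column, with the per-column standard error and replicate
#' count. Columns where no replicate contributes stay `NA`. All profiles must
#' share the same hour and the same axis width.
#'
#' @param profiles list of re-centered `column_profile`s at a common hour.
#' @return An object of class `aligned_profile`: list with `hour`,
#'   `mean_black_fraction`, `se_black_fraction`, `n_replicates` (vectors of
#'   length `target_width`), `target_width` and `target_center`.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) == 0L)
    stop("'profiles' must contain at least one profile")
  stopifnot(all(vapply(profiles, inherits, logical(1), "column_profile")))
  hours <- unique(vapply(profiles, `[[`, numeric(1), "hour"))
  if (length(hours) != 1L)
    stop("profiles mix hours: ", paste(hours, collapse = ", "))
  widths <- unique(vapply(profiles, `[[`, integer(1), "width"))
  if (length(widths) != 1L)
    stop("profiles are not on a common axis (widths ",
         paste(widths, collapse = ", "), ")")
  m <- do.call(rbind, lapply(profiles, `[[`, "black_fraction"))
  n <- colSums(!is.na(m))
  mean_bf <- ifelse(n > 0, colMeans(m, na.rm = TRUE), NA_real_)
  ss <- colSums(sweep(m, 2, mean_bf)^2, na.rm = TRUE)
  se <- ifelse(n > 1, sqrt(ss / (n - 1)) / sqrt(n), ifelse(n == 1, 0, NA_real_))
  structure(
    list(hour = hours, mean_black_fraction = mean_bf, se_black_fraction = se,
         n_replicates = as.integer(n), target_width = widths,
         target_center = profiles[[1L]]$center),
    class = "aligned_profile")
}

#' @export
print.aligned_profile <- function(x, ...) {
  cat(sprintf(
    "<aligned_profile> hour=%g  %d columns  replicates %d-%d per column\n",
    x$hour, x$target_width, min(x$n_replicates), max(x$n_replicates)))
  invisible(x)
}

#' Tidy data frame of profiles
#'
#' Flattens column profiles and/or aligned profiles into a long data frame
#' suitable for CSV export, with columns `condition`, `hour`, `replicate`
#' (the replicate id, or `"mean"` for aligned averages), `column_index`,
#' `black_fraction`, `bw_ratio` (`NA` for averages), and `n` (1 for a single
#' profile, the contributing replicate count for averages).
#'
#' @param profiles list of `column_profile` and/or `aligned_profile` objects.
#' @param condition condition label used for `aligned_profile` entries.
#' @return A data frame in long format.
#' @export
profiles_to_df <- function(profiles, condition = "unknown") {
  rows <- lapply(profiles, function(p) {
    if (inherits(p, "column_profile")) {
      data.frame(condition = p$condition, hour = p$hour,
                 replicate = as.character(p$replicate),
                 column_index = seq_len(p$width),
                 black_fraction = p$black_fraction,
                 bw_ratio = p$bw_ratio, n = 1L)
    } else if (inherits(p, "aligned_profile")) {
      data.frame(condition = condition, hour = p$hour, replicate = "mean",
                 column_index = seq_len(p$target_width),
                 black_fraction = p$mean_black_fraction,
                 bw_ratio = NA_real_, n = p$n_replicates)
    } else stop("unsupported profile object of class ", class(p)[1L])
  })
  do.call(rbind, rows)
}
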