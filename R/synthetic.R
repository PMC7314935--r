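# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Scratch-assay simulation parameters
#'
#' Describes a synthetic phase-contrast-like time series of a confluent cell
#' monolayer with a straight vertical scratch of known center and width. At
#' hour 0 the gap is cell-free; at later hours cells occupy the gap from its
#' edges inward until the planted fill fraction is reached, emulating
#' migration-driven closure. The defaults mirror a typical acquisition:
#' a 1600 x 1200 px field with a 200-column scratch centered at column 800,
#' imaged at 0, 24 and 48 h with fill fractions 0, 0.5 and 0.9.
#'
#' @param width,height canvas size in pixels (defaults 1600, 1200).
#' @param gap_center planted scratch center column (1-based). Default 800.
#' @param gap_width_0 planted scratch width at hour 0, columns. Default 200.
#' @param fill_fraction named numeric vector mapping hour to the fraction of
#'   the hour-0 gap area occupied by cells; must start at 0 for hour 0 and be
#'   non-decreasing. Default `c("0" = 0, "24" = 0.5, "48" = 0.9)`.
#' @param cell_density cells per 10^4 px^2 of monolayer. Default 8.
#' @param cell_radius_range min/max cell (ellipse) semi-axis, px. Default
#'   `c(8, 16)`.
#' @param texture_contrast standard deviation of the intracellular texture
#'   field, intensity units. Default 0.2.
#' @param noise_sd Gaussian pixel noise standard deviation. Default 0.02.
#' @param background flat media intensity. Default 0.25.
#' @param cell_base mean intensity of the cell sheet. Default 0.5.
#' @param rim_intensity intensity of bright cell rims. Default 0.85.
#' @param seed integer seed; the same parameters and seed give bit-identical
#'   rasters. Per-hour sub-seeds are derived deterministically from it.
#' @return A list of class `scratch_sim_params`.
#' @export
scratch_sim_params <- function(width = 1600L, height = 1200L,
                               gap_center = 800L, gap_width_0 = 200L,
                               fill_fraction = c("0" = 0, "24" = 0.5,
                                                 "48" = 0.9),
                               cell_density = 8,
                               cell_radius_range = c(8, 16),
                               texture_contrast = 0.2,
                               noise_sd = 0.02,
                               background = 0.25, cell_base = 0.5,
                               rim_intensity = 0.85,
                               seed = 1L) {
  stopifnot(width >= 4, height >= 4, gap_width_0 > 0, gap_width_0 < width,
            gap_center >= 1, gap_center <= width,
            cell_density > 0, length(cell_radius_range) == 2L,
            cell_radius_range[1] > 0,
            cell_radius_range[2] >= cell_radius_range[1],
            texture_contrast >= 0, noise_sd >= 0)
  hours <- as.numeric(names(fill_fraction))
  if (any(is.na(hours)) || !any(hours == 0))
    stop("'fill_fraction' must be named by hour and include hour 0")
  ord <- order(hours)
  hours <- hours[ord]; fill_fraction <- as.numeric(fill_fraction[ord])
  if (fill_fraction[hours == 0] != 0)
    stop("fill fraction at hour 0 must be 0 (the scratch is cell-free)")
  if (any(diff(fill_fraction) < 0))
    stop("'fill_fraction' must be non-decreasing in hour")
  if (any(fill_fraction < 0 | fill_fraction > 1))
    stop("'fill_fraction' values must lie in [0, 1]")
  if (2 * cell_radius_range[2] > min(width, height))
    stop("infeasible cell size: cells cannot fit in the canvas")
  n_cells <- cell_density * width * height / 1e4
  if (n_cells > width * height / 4)
    stop("infeasible cell density: cells cannot fit")
  structure(list(width = as.integer(width), height = as.integer(height),
                 gap_center = as.integer(gap_center),
                 gap_width_0 = as.integer(gap_width_0),
                 hours = hours, fill_fraction = fill_fraction,
                 cell_density = cell_density,
                 cell_radius_range = cell_radius_range,
                 texture_contrast = texture_contrast, noise_sd = noise_sd,
                 background = background, cell_base = cell_base,
                 rim_intensity = rim_intensity,
                 seed = as.integer(seed)),
            class = "scratch_sim_params")
}

# gap column extent at hour 0: width w centered (lower-median) on gap_center
.gap_columns <- function(p) {
  left <- p$gap_center - floor((p$gap_width_0 - 1) / 2)
  right <- left + p$gap_width_0 - 1L
  if (left < 1L || right > p$width)
    stop("planted gap extends outside the canvas")
  c(left, right)
}

# columnar cell occupancy at fill fraction f: TRUE for columns holding cells
.cell_columns <- function(p, f) {
  gc <- .gap_columns(p)
  cols <- rep(TRUE, p$width)
  cols[gc[1L]:gc[2L]] <- FALSE
  fill_total <- round(f * p$gap_width_0)
  wl <- floor(fill_total / 2); wr <- fill_total - wl
  if (wl > 0) cols[gc[1L]:(gc[1L] + wl - 1L)] <- TRUE
  if (wr > 0) cols[(gc[2L] - wr + 1L):gc[2L]] <- TRUE
  cols
}

# add bright elliptical rims of randomly placed "cells" wherever allowed
.draw_rims <- function(canvas, allowed, p) {
  h <- nrow(canvas); w <- ncol(canvas)
  n <- max(1L, round(p$cell_density * sum(allowed) / 1e4))
  ok_idx <- which(allowed)
  if (length(ok_idx) == 0L) return(canvas)
  centers <- sample(ok_idx, n, replace = TRUE)
  cr <- ((centers - 1L) %% h) + 1L
  cc <- ((centers - 1L) %/% h) + 1L
  a <- stats::runif(n, p$cell_radius_range[1], p$cell_radius_range[2])
  b <- stats::runif(n, p$cell_radius_range[1], p$cell_radius_range[2])
  th <- stats::runif(n, 0, pi)
  for (i in seq_len(n)) {
    r_ext <- ceiling(max(a[i], b[i])) + 1L
    rr <- max(1L, cr[i] - r_ext):min(h, cr[i] + r_ext)
    cc2 <- max(1L, cc[i] - r_ext):min(w, cc[i] + r_ext)
    dy <- rr - cr[i]; dx <- cc2 - cc[i]
    u <- outer(dy, dx, function(y, x)  x * cos(th[i]) + y * sin(th[i]))
    v <- outer(dy, dx, function(y, x) -x * sin(th[i]) + y * cos(th[i]))
    d <- sqrt((u / a[i])^2 + (v / b[i])^2)
    rim <- abs(d - 1) < 0.12 & allowed[rr, cc2]
    patch <- canvas[rr, cc2]
    patch[rim] <- p$rim_intensity
    canvas[rr, cc2] <- patch
  }
  canvas
}

# render one frame at fill fraction f; returns list(pixels, cell_mask)
.render_frame <- function(p, f) {
  h <- p$height; w <- p$width
  cols <- .cell_columns(p, f)
  cell_mask <- matrix(rep(cols, each = h), h, w)
  canvas <- matrix(p$background, h, w)
  if (any(cols)) {
    tex <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma = 1.5,
                          boundary = "replicate")
    tex <- tex / stats::sd(tex) * p$texture_contrast
    sheet <- p$cell_base + tex
    canvas[cell_mask] <- sheet[cell_mask]
    canvas <- .draw_rims(canvas, cell_mask, p)
  }
  if (p$noise_sd > 0)
    canvas <- canvas + matrix(stats::rnorm(h * w, sd = p$noise_sd), h, w)
  list(pixels = pmin(pmax(canvas, 0), 1), cell_mask = cell_mask)
}

#' Generate a synthetic scratch-assay time series with ground truth
#'
#' Renders one image per hour in `params$hours`. The monolayer is a confluent
#' textured sheet of overlapping elliptical cells with bright rims on a flat
#' darker background; the scratch is a vertical cell-free band of planted
#' center and width. At later hours, cells fill the gap from both edges
#' inward until the planted fill fraction is reached. Ground truth (planted
#' gap geometry, per-pixel cell and gap masks, exact occupied fraction) is
#' emitted alongside every image.
#'
#' @param params a [scratch_sim_params] object.
#' @param condition,replicate metadata stamped on the generated images.
#' @return A list with one element per hour, each a list with `image`
#'   (a [grey_image]) and `truth` (list with `gap_center`, `gap_width`,
#'   `gap_left`, `gap_right`, `hour`, `fill_fraction`,
#'   `occupied_fraction_in_gap` recomputed from the emitted `cell_mask`,
#'   `cell_mask`, and `gap_mask` — the hour-0 gap band).
#' @export
generate_scratch_series <- function(params = scratch_sim_params(),
                                    condition = "synthetic", replicate = 1L) {
  stopifnot(inherits(params, "scratch_sim_params"))
  gc <- .gap_columns(params)
  gap_mask <- matrix(FALSE, params$height, params$width)
  gap_mask[, gc[1L]:gc[2L]] <- TRUE
  out <- vector("list", length(params$hours))
  for (i in seq_along(params$hours)) {
    frame <- .with_seed(params$seed * 1000L + i,
                        .render_frame(params, params$fill_fraction[i]))
    occ <- sum(frame$cell_mask & gap_mask) / sum(gap_mask)
    out[[i]] <- list(
      image = grey_image(frame$pixels, condition = condition,
                         replicate = replicate, hour = params$hours[i]),
      truth = list(gap_center = params$gap_center,
                   gap_width = params$gap_width_0,
                   gap_left = gc[1L], gap_right = gc[2L],
                   hour = params$hours[i],
                   fill_fraction = params$fill_fraction[i],
                   occupied_fraction_in_gap = occ,
                   cell_mask = frame$cell_mask,
                   gap_mask = gap_mask))
  }
  names(out) <- as.character(params$hours)
  out
}

#' Generate a synthetic fluorescence spot image with ground truth
#'
#' Sums isotropic Gaussian bumps on a constant background, adds Gaussian
#' pixel noise, and reports the exact planted centers. When `spot_centers` is
#' `NULL`, `n_spots` centers are drawn uniformly (with a margin of
#' `3 * spot_sigma` from the borders) subject to a minimum pairwise
#' separation.
#'
#' @param width,height canvas size, px.
#' @param n_spots number of spots to plant (ignored when `spot_centers` is
#'   given).
#' @param spot_centers optional 2-column matrix of (row, col) centers.
#' @param spot_sigma Gaussian spot sigma, px. Default 3.
#' @param peak spot peak amplitude above background. Default 0.8.
#' @param background constant background intensity. Default 0.1.
#' @param noise_sd Gaussian noise sd. Default 0.02.
#' @param min_separation minimum pairwise center distance when sampling
#'   centers. Default 30.
#' @param seed integer seed.
#' @param condition,replicate,hour metadata for the returned image.
#' @return List with `image` (a [grey_image]) and `truth` (list with
#'   `spot_centers` matrix and `min_pairwise_distance`).
#' @export
generate_spot_image <- function(width = 800L, height = 600L, n_spots = 25L,
                                spot_centers = NULL, spot_sigma = 3,
                                peak = 0.8, background = 0.1, noise_sd = 0.02,
                                min_separation = 30, seed = 1L,
                                condition = "synthetic", replicate = 1L,
                                hour = 0) {
  stopifnot(width >= 4, height >= 4, peak >= 0, noise_sd >= 0)
  if (spot_sigma <= 0) stop("'spot_sigma' must be positive")
  .with_seed(seed, {
    if (is.null(spot_centers)) {
      margin <- ceiling(3 * spot_sigma)
      centers <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(centers) < n_spots) {
        cand <- c(stats::runif(1, 1 + margin, height - margin),
                  stats::runif(1, 1 + margin, width - margin))
        if (nrow(centers) == 0L ||
            all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >=
                min_separation^2))
          centers <- rbind(centers, cand)
        tries <- tries + 1L
        if (tries > 10000L * max(1L, n_spots))
          stop("cannot place ", n_spots, " spots with separation ",
               min_separation, " in a ", width, " x ", height, " canvas")
      }
      spot_centers <- centers
    } else {
      spot_centers <- as.matrix(spot_centers)
      if (ncol(spot_centers) != 2L)
        stop("'spot_centers' must have two columns (row, col)")
      if (nrow(spot_centers) > 0 &&
          (any(spot_centers[, 1] < 1) || any(spot_centers[, 1] > height) ||
           any(spot_centers[, 2] < 1) || any(spot_centers[, 2] > width)))
        stop("spot centers must lie within the canvas")
    }
    px <- matrix(background, height, width)
    if (nrow(spot_centers) > 0) {
      rows <- seq_len(height); cols <- seq_len(width)
      for (i in seq_len(nrow(spot_centers))) {
        gr <- exp(-(rows - spot_centers[i, 1])^2 / (2 * spot_sigma^2))
        gcv <- exp(-(cols - spot_centers[i, 2])^2 / (2 * spot_sigma^2))
        px <- px + peak * outer(gr, gcv)
      }
    }
    if (noise_sd > 0)
      px <- px + matrix(stats::rnorm(height * width, sd = noise_sd),
                        height, width)
    px <- pmin(pmax(px, 0), 1)
    mind <- if (nrow(spot_centers) >= 2L)
      min(stats::dist(spot_centers)) else Inf
    list(image = grey_image(px, condition = condition, replicate = replicate,
                            hour = hour),
         truth = list(spot_centers = unname(spot_centers),
                      min_pairwise_distance = mind))
  })
}

#' Write a simulated scratch experiment to disk
#'
#' Generates a full multi-condition, multi-replicate scratch time course,
#' writes the images (PNG), a ground-truth table (CSV), and a ready-to-use
#' manifest, so the batch pipeline can be exercised end to end.
#'
#' @param out_dir output directory (created if needed).
#' @param conditions named list mapping condition label to its
#'   `fill_fraction` vector (hour -> fraction); conditions share geometry but
#'   close at their own rates.
#' @param n_replicates replicates per condition.
#' @param base_params a [scratch_sim_params] supplying geometry, texture and
#'   noise; its `fill_fraction` and `seed` are overridden per condition and
#'   replicate. Replicate gap centers are jittered by up to
#'   `center_jitter` columns so that re-centering has real work to do.
#' @param center_jitter maximum absolute replicate-to-replicate shift of the
#'   gap center, columns. Default 40.
#' @param seed master seed.
#' @return Invisibly, a list with `manifest` (path to the manifest CSV) and
#'   `truth` (data frame of planted values per image).
#' @export
simulate_scratch_experiment <- function(out_dir,
                                        conditions = list(
                                          control = c("0" = 0, "24" = 0.25,
                                                      "48" = 0.5),
                                          treated = c("0" = 0, "24" = 0.5,
                                                      "48" = 0.9)),
                                        n_replicates = 3L,
                                        base_params = scratch_sim_params(),
                                        center_jitter = 40L,
                                        seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list(); truths <- list()
  idx <- 0L
  for (ci in seq_along(conditions)) {
    cond <- names(conditions)[ci]
    for (rep_i in seq_len(n_replicates)) {
      idx <- idx + 1L
      sub_seed <- seed * 7919L + idx
      jitter <- .with_seed(sub_seed * 13L,
                           sample(seq(-center_jitter, center_jitter), 1L))
      p <- base_params
      p$fill_fraction <- as.numeric(conditions[[ci]])
      p$hours <- as.numeric(names(conditions[[ci]]))
      p$gap_center <- as.integer(base_params$gap_center + jitter)
      p$seed <- as.integer(sub_seed)
      series <- generate_scratch_series(p, condition = cond,
                                        replicate = rep_i)
      for (fr in series) {
        fname <- sprintf("%s_rep%d_h%03d.png", cond, rep_i, fr$image$hour)
        write_image(fr$image, file.path(out_dir, fname))
        entries[[length(entries) + 1L]] <-
          data.frame(path = fname, condition = cond, replicate = rep_i,
                     hour = fr$image$hour)
        truths[[length(truths) + 1L]] <-
          data.frame(path = fname, condition = cond, replicate = rep_i,
                     hour = fr$image$hour,
                     gap_center = fr$truth$gap_center,
                     gap_width = fr$truth$gap_width,
                     occupied_fraction_in_gap =
                       fr$truth$occupied_fraction_in_gap)
      }
    }
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  write_manifest(do.call(rbind, entries), manifest_path)
  truth_df <- do.call(rbind, truths)
  utils::write.csv(truth_df, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest_path, truth = truth_df))
}
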