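# Brute-force oracles, deliberately naive: every one loops over pixels and
# stays independent of the vectorized implementation paths it checks.

# per-column black/white counts by explicit double loop
brute_column_counts <- function(px) {
  h <- nrow(px); w <- ncol(px)
  black <- integer(w); white <- integer(w)
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (px[i, j]) white[j] <- white[j] + 1L else black[j] <- black[j] + 1L
    }
  }
  list(black = black, white = white)
}

# gradient magnitude by per-pixel finite differences (central in the
# interior, one-sided at borders), no smoothing
brute_gradient_magnitude <- function(px) {
  h <- nrow(px); w <- ncol(px)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      dr <- if (h == 1L) 0 else if (i == 1L) px[2L, j] - px[1L, j]
        else if (i == h) px[h, j] - px[h - 1L, j]
        else (px[i + 1L, j] - px[i - 1L, j]) / 2
      dc <- if (w == 1L) 0 else if (j == 1L) px[i, 2L] - px[i, 1L]
        else if (j == w) px[i, w] - px[i, w - 1L]
        else (px[i, j + 1L] - px[i, j - 1L]) / 2
      out[i, j] <- sqrt(dr^2 + dc^2)
    }
  }
  out
}

# white/black counts in a column range by explicit loop
brute_region_counts <- function(px, left, right) {
  white <- 0L; black <- 0L
  for (j in left:right) {
    for (i in seq_len(nrow(px))) {
      if (px[i, j]) white <- white + 1L else black <- black + 1L
    }
  }
  list(white = white, black = black)
}

# above-threshold pixel count by explicit loop
brute_threshold_count <- function(px, thr) {
  n <- 0L
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px)))
    if (px[i, j] > thr) n <- n + 1L
  n
}

# connected white components (4-connectivity) by flood fill
brute_component_count <- function(px) {
  h <- nrow(px); w <- ncol(px)
  seen <- matrix(FALSE, h, w)
  n <- 0L
  for (i0 in seq_len(h)) for (j0 in seq_len(w)) {
    if (!px[i0, j0] || seen[i0, j0]) next
    n <- n + 1L
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        i <- p[1L] + d[1L]; j <- p[2L] + d[2L]
        if (i >= 1L && i <= h && j >= 1L && j <= w &&
            px[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          stack[[length(stack) + 1L]] <- c(i, j)
        }
      }
    }
  }
  n
}

# small fast simulator geometry shared by unit tests
small_sim_params <- function(seed = 1L, noise_sd = 0.02, ...) {
  scratch_sim_params(width = 400L, height = 300L, gap_center = 200L,
                     gap_width_0 = 80L, cell_radius_range = c(6, 10),
                     noise_sd = noise_sd, seed = seed, ...)
}

random_logical_mask <- function(h, w, p = 0.5) {
  matrix(stats::runif(h * w) < p, h, w)
}
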