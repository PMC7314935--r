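# format numbers to 6 significant digits for byte-stable CSV goldens
.fmt_num <- function(x) {
  if (is.numeric(x)) {
    out <- ifelse(is.na(x), NA_character_,
                  ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"),
                         formatC(signif(x, 6), format = "g", digits = 6)))
    out
  } else x
}

.write_csv6 <- function(df, path) {
  df[] <- lapply(df, .fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every knob of a batch run so that the effective configuration can
#' be serialized next to the outputs and a run can be reproduced exactly.
#'
#' @param manifest path to the manifest CSV (see [load_manifest]).
#' @param out_dir output directory.
#' @param segmentation a [segmentation_params] object.
#' @param gap_threshold black-fraction cutoff defining gap columns.
#' @param target_width common profile axis width in columns; `NULL` uses the
#'   minimum replicate width.
#' @param metric_hour hour at which the cell-to-space endpoint is compared
#'   across conditions. Default 24.
#' @param spots a [spot_params] object (spot pipeline only).
#' @param roi a [rect_roi] applied to every image (spot pipeline only);
#'   `NULL` means whole image.
#' @param alpha significance level for group comparisons. Default 0.05.
#' @param seed integer seed recorded with the run.
#' @param write_plots write per-hour profile plots as PNG. Default FALSE.
#' @return A list of class `run_config`.
#' @export
run_config <- function(manifest, out_dir,
                       segmentation = segmentation_params(),
                       gap_threshold = 0.95, target_width = NULL,
                       metric_hour = 24,
                       spots = spot_params(), roi = NULL,
                       alpha = 0.05, seed = 1L, write_plots = FALSE) {
  stopifnot(inherits(segmentation, "segmentation_params"),
            inherits(spots, "spot_params"),
            gap_threshold > 0, gap_threshold <= 1, alpha > 0, alpha < 1)
  structure(list(manifest = manifest, out_dir = out_dir,
                 segmentation = segmentation, gap_threshold = gap_threshold,
                 target_width = target_width, metric_hour = metric_hour,
                 spots = spots, roi = roi, alpha = alpha,
                 seed = as.integer(seed), write_plots = isTRUE(write_plots)),
            class = "run_config")
}

.config_json <- function(config) {
  ser <- list(manifest = config$manifest, out_dir = config$out_dir,
              segmentation = unclass(config$segmentation),
              gap_threshold = config$gap_threshold,
              target_width = config$target_width,
              metric_hour = config$metric_hour,
              spots = unclass(config$spots),
              roi = if (!is.null(config$roi)) unclass(config$roi),
              alpha = config$alpha, seed = config$seed,
              package_version = as.character(utils::packageVersion("scratchquant")))
  jsonlite::toJSON(ser, auto_unbox = TRUE, null = "null", pretty = TRUE)
}

.plot_aligned <- function(aligned_by_hour, cond, path) {
  grDevices::png(path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  hours <- as.numeric(names(aligned_by_hour))
  cols <- grDevices::hcl.colors(max(3L, length(hours)), "Dark 3")
  w <- aligned_by_hour[[1L]]$target_width
  graphics::plot(NULL, xlim = c(1, w), ylim = c(0, 1),
                 xlab = "column (re-centered axis)",
                 ylab = "black (media) fraction",
                 main = paste0(cond, ": replicate-averaged scratch profiles"))
  for (i in seq_along(aligned_by_hour))
    graphics::lines(seq_len(w), aligned_by_hour[[i]]$mean_black_fraction,
                    col = cols[i], lwd = 2)
  graphics::legend("topright", legend = paste0(hours, " h"),
                   col = cols[seq_along(hours)], lwd = 2, bty = "n")
}

#' Run the full scratch-assay analysis pipeline
#'
#' For every image in the manifest: segment and profile. Per replicate: find
#' the disruption center on the hour-0 profile, re-center every hour onto
#' the common axis, and compute gap metrics anchored to the hour-0 gap
#' region. Per condition and hour: average the re-centered replicate
#' profiles. Finally, compare the occupied-fraction endpoint at
#' `config$metric_hour` across conditions (when at least two conditions with
#' two replicates each are available).
#'
#' Writes `metrics.csv`, `profiles.csv` (re-centered per-replicate and mean
#' profiles in long format), `stats.csv` + `stats.txt`, `run_config.json`,
#' a `run.log`, and optionally per-condition profile plots. Unreadable or
#' failing images are reported with their path and stage and skipped;
#' processing continues.
#'
#' @param config a [run_config].
#' @return Invisibly, a list with `metrics` (data frame), `aligned` (nested
#'   list condition -> hour -> `aligned_profile`), `stats`
#'   (a `group_comparison` or `NULL`), and `failures` (data frame of skipped
#'   images).
#' @export
run_scratch_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("scratchquant %s scratch pipeline",
                         utils::packageVersion("scratchquant")),
                 sprintf("config md5 %s", .config_md5(config)))
  man <- load_manifest(config$manifest)
  failures <- data.frame(path = character(), stage = character(),
                         message = character())
  masks <- list(); keys <- character()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    res <- tryCatch({
      img <- load_image(row$path, condition = row$condition,
                        replicate = row$replicate, hour = row$hour)
      binarize(img, config$segmentation)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(path = row$path, stage = "segment",
                                   message = conditionMessage(res)))
      log_lines <- c(log_lines, sprintf("FAIL segment %s: %s", row$path,
                                        conditionMessage(res)))
      next
    }
    masks[[length(masks) + 1L]] <- res
    keys <- c(keys, paste(row$condition, row$replicate, sep = "/"))
  }
  if (length(masks) == 0L) stop("no image in the manifest could be processed")
  by_rep <- split(masks, keys)
  widths <- vapply(masks, `[[`, integer(1), "width")
  target_width <- if (is.null(config$target_width)) min(widths) else
    as.integer(config$target_width)

  metrics <- list(); recentered <- list()
  for (key in names(by_rep)) {
    series <- by_rep[[key]]
    hours <- vapply(series, `[[`, numeric(1), "hour")
    res <- tryCatch({
      profs <- lapply(series, column_profile)
      center <- find_gap_center(profs[[which(hours == 0)[1L]]])
      met <- gap_metrics(series, threshold = config$gap_threshold)
      rec <- lapply(profs, recenter, center = center,
                    target_width = target_width)
      list(met = met, rec = rec)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(path = key, stage = "profile",
                                   message = conditionMessage(res)))
      log_lines <- c(log_lines, sprintf("FAIL profile %s: %s", key,
                                        conditionMessage(res)))
      next
    }
    metrics[[key]] <- res$met
    recentered[[key]] <- res$rec
  }
  if (length(metrics) == 0L) stop("no replicate series could be profiled")
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  metrics <- metrics[order(metrics$condition, metrics$replicate,
                           metrics$hour), ]

  # per condition x hour replicate averages on the common axis
  flat <- unlist(recentered, recursive = FALSE)
  cond_of <- vapply(flat, `[[`, character(1), "condition")
  hour_of <- vapply(flat, `[[`, numeric(1), "hour")
  aligned <- list(); prof_dfs <- list()
  for (cond in sort(unique(cond_of))) {
    aligned[[cond]] <- list()
    for (h in sort(unique(hour_of[cond_of == cond]))) {
      grp <- flat[cond_of == cond & hour_of == h]
      avg <- average_profiles(grp)
      aligned[[cond]][[as.character(h)]] <- avg
      prof_dfs[[length(prof_dfs) + 1L]] <- profiles_to_df(grp)
      prof_dfs[[length(prof_dfs) + 1L]] <- profiles_to_df(list(avg), cond)
    }
    if (config$write_plots)
      .plot_aligned(aligned[[cond]], cond,
                    file.path(config$out_dir,
                              paste0("profiles_", cond, ".png")))
  }

  # cross-condition comparison of the occupied fraction at metric_hour
  stats_res <- NULL
  endpoint <- metrics[metrics$hour == config$metric_hour, ]
  tab <- data.frame(condition = endpoint$condition,
                    replicate = endpoint$replicate,
                    value = endpoint$occupied_fraction)
  ncond <- length(unique(tab$condition))
  if (ncond >= 2L && all(table(tab$condition) >= 2L)) {
    stats_res <- compare_groups(tab, alpha = config$alpha)
    .write_csv6(stats_res$pairwise, file.path(config$out_dir, "stats.csv"))
    writeLines(format_stats_report(stats_res, summarize_groups(tab)),
               file.path(config$out_dir, "stats.txt"))
  } else {
    log_lines <- c(log_lines,
                   "NOTE fewer than 2 conditions with 2 replicates at the ",
                   "endpoint hour; group comparison skipped")
    if (nrow(tab) > 0)
      .write_csv6(summarize_groups(tab), file.path(config$out_dir, "stats.csv"))
  }

  .write_csv6(metrics, file.path(config$out_dir, "metrics.csv"))
  .write_csv6(do.call(rbind, prof_dfs), file.path(config$out_dir,
                                                  "profiles.csv"))
  writeLines(.config_json(config), file.path(config$out_dir,
                                             "run_config.json"))
  log_lines <- c(log_lines, sprintf("processed %d image(s), %d failure(s)",
                                    length(masks), nrow(failures)))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(metrics = metrics, aligned = aligned, stats = stats_res,
                 failures = failures))
}

.config_md5 <- function(config) {
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(.config_json(config), tf)
  unname(tools::md5sum(tf))
}

#' Run the fluorescence spot-counting pipeline
#'
#' Counts bright spots (e.g. fluorescently labelled neutrophils at a wound
#' site) in every image of a manifest, inside `config$roi` (whole image when
#' `NULL`), summarizes counts per condition as mean +/- SE, and compares
#' conditions at `config$alpha` when at least two conditions with two images
#' each are present (a single condition yields the summary only, with a
#' warning).
#'
#' Writes `spot_counts.csv` (one row per image), `spots.csv` (one row per
#' detected spot), `stats.csv`/`stats.txt`, and `run_config.json`.
#'
#' @param config a [run_config]; `manifest` may list fluorescence images at
#'   any hour (hour-0 rows are not required to be scratch anchors here, but
#'   the manifest contract still applies).
#' @return Invisibly, a list with `counts` (data frame), `summary`,
#'   and `stats` (`NULL` when no comparison was possible).
#' @export
run_spot_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- load_manifest(config$manifest)
  counts <- list(); spot_rows <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    img <- load_image(row$path, condition = row$condition,
                      replicate = row$replicate, hour = row$hour)
    det <- count_spots(img, roi = config$roi, params = config$spots)
    counts[[i]] <- data.frame(path = row$path, condition = row$condition,
                              replicate = row$replicate, hour = row$hour,
                              count = det$count)
    if (det$count > 0)
      spot_rows[[length(spot_rows) + 1L]] <-
        cbind(data.frame(path = row$path, condition = row$condition),
              det$spots)
  }
  counts <- do.call(rbind, counts)
  tab <- data.frame(condition = counts$condition, value = counts$count)
  summ <- summarize_groups(tab)
  stats_res <- NULL
  if (length(unique(tab$condition)) >= 2L && all(table(tab$condition) >= 2L)) {
    stats_res <- compare_groups(tab, alpha = config$alpha)
    writeLines(format_stats_report(stats_res, summ),
               file.path(config$out_dir, "stats.txt"))
    .write_csv6(stats_res$pairwise, file.path(config$out_dir, "stats.csv"))
  } else {
    warning("single condition (or n < 2): summary only, no comparison")
    .write_csv6(summ, file.path(config$out_dir, "stats.csv"))
  }
  .write_csv6(counts, file.path(config$out_dir, "spot_counts.csv"))
  if (length(spot_rows))
    .write_csv6(do.call(rbind, spot_rows), file.path(config$out_dir,
                                                     "spots.csv"))
  writeLines(.config_json(config), file.path(config$out_dir,
                                             "run_config.json"))
  invisible(list(counts = counts, summary = summ, stats = stats_res))
}
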