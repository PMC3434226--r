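## Orchestration: map analysis (baseline -> mask -> SOM -> ratio maps ->
## per-cluster summaries -> statistics) and time-course analysis
## (normalize -> lag/decline -> treated-vs-control comparison), with a
## small run manifest for reproducibility.

#' Pipeline configuration
#'
#' Nested defaults for every stage; any block can be overridden.
#'
#' @param baseline A [baseline_config()].
#' @param mask_window,mask_frac,mask_quantile See [mask_cells()].
#' @param som A [som_config()].
#' @param bands Band registry, see [default_bands()].
#' @param boot_n,boot_seed Bootstrap resamples and seed for cluster
#'   summaries.
#' @param alpha Significance level.
#' @param lag_threshold Mean-normalized intensity threshold for the lag
#'   estimator (default 0.9).
#' @param lag_band Band whose normalized series the lag is read from
#'   (default `"750"`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(baseline = baseline_config(),
                            mask_window = c(1400, 1700), mask_frac = 0.25,
                            mask_quantile = 0.99,
                            som = som_config(),
                            bands = default_bands(),
                            boot_n = 10000, boot_seed = 1,
                            alpha = 0.05,
                            lag_threshold = 0.9, lag_band = "750") {
  structure(list(baseline = baseline, mask_window = mask_window,
                 mask_frac = mask_frac, mask_quantile = mask_quantile,
                 som = som, bands = bands, boot_n = boot_n,
                 boot_seed = boot_seed, alpha = alpha,
                 lag_threshold = lag_threshold, lag_band = lag_band),
            class = "pipeline_config")
}

run_manifest <- function(stage_times, config, seeds, inputs = list()) {
  list(created = format(Sys.time(), tz = "UTC"),
       r_version = as.character(getRversion()),
       package_version = as.character(utils::packageVersion("ramanredox")),
       seeds = seeds, inputs = inputs,
       stage_seconds = stage_times,
       config = utils::capture.output(utils::str(config, give.attr = FALSE)))
}

#' Run the full map analysis
#'
#' Fixed stage order: per-pixel baseline subtraction, cell masking, SOM
#' clustering of the corrected masked spectra, the three analysis ratio
#' maps (I750/I1640, I1125/I1640, I750/I1125), per-cluster bootstrap
#' summaries, and Kruskal-Wallis/Dunn statistics across clusters.
#' Deterministic under a fixed configuration (the SOM and bootstrap seeds
#' live in `config`).
#'
#' @param map A raw [hyperspec_map()], or a path to a long-format map file.
#' @param config A [pipeline_config()].
#' @return List of class `map_analysis`: `corrected`, `mask`, `clusters`
#'   (a [fit_som()] result), `cluster_spectra`, `ratios` (named list of
#'   [ratio_map()]s), `summaries` (named list of per-cluster tables),
#'   `stats` (named list of [stats_report()]s, over clusters with >= 3
#'   valid pixels), `manifest`.
#' @export
run_map_analysis <- function(map, config = pipeline_config()) {
  inputs <- list()
  if (is.character(map)) {
    inputs$path <- map
    inputs$md5 <- unname(tools::md5sum(map))
    map <- read_longform_map(map)
  }
  tm <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  bl <- subtract_baseline_map(map, config$baseline)
  tm["baseline"] <- tic() - t0; t0 <- tic()
  mask <- mask_cells(bl$corrected, window = config$mask_window,
                     frac = config$mask_frac, quantile = config$mask_quantile)
  tm["mask"] <- tic() - t0; t0 <- tic()
  clusters <- fit_som(bl$corrected, mask, config$som)
  tm["som"] <- tic() - t0; t0 <- tic()
  bands <- config$bands
  pairs <- list(r750_1640 = c("750", "1640"),
                r1125_1640 = c("1125", "1640"),
                r750_1125 = c("750", "1125"))
  ratios <- lapply(pairs, function(p)
    ratio_map(bl$corrected, bands[[p[1]]], bands[[p[2]]], mask))
  summaries <- lapply(ratios, function(rm)
    cluster_ratio_summary(rm, clusters, n_boot = config$boot_n,
                          seed = config$boot_seed))
  tm["ratios"] <- tic() - t0; t0 <- tic()
  stats_ <- lapply(ratios, function(rm) {
    groups <- list()
    for (j in seq_len(config$som$n_units)) {
      v <- rm$values[!is.na(clusters$labels) & clusters$labels == j]
      v <- v[!is.na(v)]
      if (length(v) >= 3) groups[[paste0("cluster_", j)]] <- v
    }
    if (length(groups) >= 2) stats_report(groups, alpha = config$alpha)
    else NULL
  })
  tm["stats"] <- tic() - t0
  structure(list(corrected = bl$corrected, mask = mask, clusters = clusters,
                 cluster_spectra = cluster_mean_spectra(bl$corrected, clusters),
                 ratios = ratios, summaries = summaries, stats = stats_,
                 manifest = run_manifest(tm, config,
                                         seeds = c(som = config$som$seed,
                                                   boot = config$boot_seed),
                                         inputs = inputs)),
            class = "map_analysis")
}

#' Match recovered clusters to ground-truth phantom regions
#'
#' For each ground-truth region, the cluster holding the plurality of that
#' region's pixels, with the fraction of the region it captures.
#'
#' @param result A [fit_som()] result.
#' @param truth A `make_cell_phantom()` truth record.
#' @param regions Region names to match (default: the interior regions).
#' @return data.frame `region`, `cluster`, `coverage`.
#' @export
match_clusters_to_regions <- function(result, truth,
                                      regions = c("rod_center", "rod_periphery",
                                                  "round_interior")) {
  regions <- intersect(regions, unique(as.vector(truth$regions)))
  rows <- lapply(regions, function(rg) {
    labs <- result$labels[truth$regions == rg]
    labs <- labs[!is.na(labs)]
    if (!length(labs))
      return(data.frame(region = rg, cluster = NA_integer_, coverage = 0))
    tab <- sort(table(labs), decreasing = TRUE)
    data.frame(region = rg, cluster = as.integer(names(tab)[1]),
               coverage = unname(tab[1]) / length(labs))
  })
  do.call(rbind, rows)
}

#' Lag estimate from a mean normalized series
#'
#' The latest time at which the series is still at or above `threshold`
#' (the decline onset is read as the end of the flat phase).
#'
#' @param times Times, minutes.
#' @param series Mean normalized intensities, same length.
#' @param threshold Default 0.9.
#' @return Scalar lag, minutes.
#' @export
estimate_lag <- function(times, series, threshold = 0.9) {
  ok <- which(series >= threshold)
  if (!length(ok)) return(times[1])
  max(times[ok])
}

#' Run the time-course analysis
#'
#' Per replicate: baseline subtraction, band intensities, normalization to
#' t0. Reports the mean normalized series per band and condition, the lag
#' estimate (threshold crossing on the mean series of `config$lag_band`),
#' end-point fractional declines per band, and a Kruskal-Wallis comparison
#' of treated vs control end-point values per band. A missing control
#' skips the comparison with a warning.
#'
#' @param treated List of [timecourse_record()]s (one per cell).
#' @param control Optional list of control records sharing the same times.
#' @param config A [pipeline_config()].
#' @return List of class `timecourse_analysis`: `times`, `series`
#'   (condition -> time x band matrix of mean normalized intensities),
#'   `lag`, `declines` (condition -> per-band end-point fractional
#'   decline), `comparison` (per-band Kruskal-Wallis on end-point values,
#'   or `NULL`), `manifest`.
#' @export
run_timecourse_analysis <- function(treated, control = NULL,
                                    config = pipeline_config()) {
  if (inherits(treated, "timecourse_record")) treated <- list(treated)
  if (inherits(control, "timecourse_record")) control <- list(control)
  bands <- config$bands[c("750", "1125", "1640")]
  t0 <- proc.time()[["elapsed"]]
  norm_stack <- function(records) {
    mats <- lapply(records, function(rec)
      normalize_timecourse(rec, bands, mode = "to_t0",
                           baseline = config$baseline)$values)
    list(mean = Reduce(`+`, mats) / length(mats),
         end = t(vapply(mats, function(m) m[nrow(m), ], numeric(length(bands)))))
  }
  tr <- norm_stack(treated)
  times <- treated[[1]]$times
  series <- list(treated = tr$mean)
  declines <- list(treated = 1 - tr$mean[nrow(tr$mean), ])
  comparison <- NULL
  if (!is.null(control)) {
    if (!isTRUE(all.equal(control[[1]]$times, times)))
      rr_error("treated and control records must share times", "rr_shape_error")
    ct <- norm_stack(control)
    series$control <- ct$mean
    declines$control <- 1 - ct$mean[nrow(ct$mean), ]
    comparison <- lapply(seq_along(bands), function(j)
      kruskal_wallis(list(treated = tr$end[, j], control = ct$end[, j])))
    names(comparison) <- names(bands)
  } else {
    warning("no control records: treated-vs-control comparison skipped")
  }
  lag <- estimate_lag(times, tr$mean[, config$lag_band],
                      threshold = config$lag_threshold)
  tm <- c(timecourse = proc.time()[["elapsed"]] - t0)
  structure(list(times = times, series = series, lag = lag,
                 declines = declines, comparison = comparison,
                 manifest = run_manifest(tm, config, seeds = c())),
            class = "timecourse_analysis")
}
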