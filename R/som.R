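## Self-organizing-map clustering of masked pixel spectra.
##
## Units live on a 1-D chain (default 6 units). The fit starts from a
## random attribution of pixels to units; prototypes are updated as
## neighborhood-weighted member means with a Gaussian neighborhood whose
## radius decays linearly to zero over the first iterations, after which
## the procedure is plain nearest-prototype reattribution (so the final
## phase is exactly the literal "reattribute until no more than 1% of
## spectra change cluster" rule). Distances are plain Euclidean on
## baseline-corrected spectra restricted to a wavenumber window, with no
## per-spectrum normalization: absolute intensity differences are part of
## the structure (they are what isolates dim cell-boundary pixels).

#' SOM configuration
#'
#' @param n_units Number of units/clusters (default 6).
#' @param converge_frac Convergence rule: stop when at most this fraction
#'   of spectra changes attribution in one iteration (default 0.01).
#' @param max_iter Iteration cap (default 500).
#' @param seed Random seed for the initial attribution.
#' @param radius Initial neighborhood radius on the unit chain (default 2).
#' @param radius_iters Iterations over which the radius decays linearly to
#'   zero (default 10). `radius = 0` makes the whole fit a Lloyd-style
#'   batch k-means with random-partition initialization.
#' @param window Wavenumber window (cm^-1) the clustering operates on
#'   (default `c(600, 1800)`); clipped to the axis.
#' @return A list of class `som_config`.
#' @export
som_config <- function(n_units = 6, converge_frac = 0.01, max_iter = 500,
                       seed = 1, radius = 2, radius_iters = 10,
                       window = c(600, 1800)) {
  if (n_units < 2) rr_error("n_units must be >= 2", "rr_config_error")
  if (converge_frac <= 0 || converge_frac >= 1)
    rr_error("converge_frac must be in (0, 1)", "rr_config_error")
  structure(list(n_units = n_units, converge_frac = converge_frac,
                 max_iter = max_iter, seed = seed, radius = radius,
                 radius_iters = radius_iters, window = window),
            class = "som_config")
}

## squared Euclidean distances pixels x prototypes
sq_dist <- function(X, P) {
  ## |x|^2 - 2 x.p + |p|^2
  d <- outer(rowSums(X^2), rowSums(P^2), "+") - 2 * X %*% t(P)
  pmax(d, 0)
}

#' Fit a self-organizing map to the masked pixels of a map
#'
#' @param map Baseline-corrected [hyperspec_map()].
#' @param mask A [mask_cells()] result or logical matrix; only masked
#'   pixels are clustered.
#' @param config A [som_config()].
#' @return List of class `som_result`:
#'   `labels` (height x width integer matrix, 1..n_units inside the mask,
#'   `NA` outside), `prototypes` (unit x wavenumber matrix on the
#'   clustering window), `window_axis`, `reassign_trace` (per-iteration
#'   reassignment fractions), `converged`, `config`, `mask`.
#' @export
fit_som <- function(map, mask = NULL, config = som_config()) {
  m <- mask_matrix(mask, dim(map$cube)[1:2])
  if (!any(m)) rr_error("mask is empty", "rr_config_error")
  sel <- map$axis >= config$window[1] & map$axis <= config$window[2]
  if (sum(sel) < 2)
    rr_error("clustering window does not overlap the wavenumber axis",
             "rr_config_error")
  X <- map_matrix(map)[as.vector(t(m)), sel, drop = FALSE]
  n <- nrow(X); k <- config$n_units
  if (n < k)
    rr_error(sprintf("only %d masked pixels for %d units", n, k),
             "rr_config_error")
  set.seed(config$seed)
  labels <- sample.int(k, n, replace = TRUE)
  ## prototypes = means of randomly attributed members; empty units get the
  ## spectrum farthest from the global mean
  proto <- matrix(0, k, ncol(X))
  gmean <- colMeans(X)
  far <- order(-rowSums(sweep(X, 2, gmean)^2))
  fi <- 1L
  for (j in seq_len(k)) {
    mem <- labels == j
    if (!any(mem)) {
      labels[far[fi]] <- j
      fi <- fi + 1L
      mem <- labels == j
    }
    proto[j, ] <- colMeans(X[mem, , drop = FALSE])
  }
  trace_ <- numeric(0)
  converged <- FALSE
  units <- seq_len(k)
  for (it in seq_len(config$max_iter)) {
    radius <- if (config$radius_iters > 0)
      max(0, config$radius * (1 - it / config$radius_iters)) else 0
    d <- sq_dist(X, proto)
    new_labels <- max.col(-d, ties.method = "first")  # ties -> lowest index
    frac <- mean(new_labels != labels)
    trace_ <- c(trace_, frac)
    labels <- new_labels
    if (radius > 0) {
      ## batch SOM update: neighborhood-weighted means over the chain
      H <- exp(-outer(units, units, function(a, b) (a - b)^2) / (2 * radius^2))
      W <- H[, labels, drop = FALSE]              # unit x pixel weights
      proto <- (W %*% X) / rowSums(W)
    } else {
      empty <- units[!units %in% labels]
      if (length(empty)) {
        ## reseed emptied units on the worst-fit spectra so prototypes
        ## cannot collapse onto each other
        cur <- d[cbind(seq_len(n), labels)]
        worst <- order(-cur)
        for (e in seq_along(empty)) {
          if (cur[worst[e]] <= 0) break  # perfect fit everywhere: leave empty
          proto[empty[e], ] <- X[worst[e], ]
          labels[worst[e]] <- empty[e]
        }
      }
      for (j in units) {
        mem <- labels == j
        if (any(mem)) proto[j, ] <- colMeans(X[mem, , drop = FALSE])
      }
    }
    if (it > config$radius_iters && frac <= config$converge_frac) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("SOM did not reach the reassignment convergence rule; returning last iterate")
  ## final attribution = plain nearest prototype
  labels <- max.col(-sq_dist(X, proto), ties.method = "first")
  ## scatter back onto the grid in the row-major pixel order of map_matrix()
  lab_full <- rep(NA_integer_, length(m))
  lab_full[as.vector(t(m))] <- labels
  lab_mat <- t(matrix(lab_full, ncol(m), nrow(m)))
  structure(list(labels = lab_mat, prototypes = proto,
                 window_axis = wn_axis(as.numeric(map$axis)[sel]),
                 reassign_trace = trace_, converged = converged,
                 config = config, mask = m),
            class = "som_result")
}

#' Arithmetic mean spectrum of each non-empty cluster
#'
#' Means are computed on the full axis of the supplied (baseline-corrected)
#' map, not just the clustering window.
#'
#' @param map The [hyperspec_map()] that was clustered.
#' @param result A [fit_som()] result for that map.
#' @return Named list of [spectrum()]s, one per non-empty cluster
#'   (`"cluster_1"`, ...); empty clusters are absent.
#' @export
cluster_mean_spectra <- function(map, result) {
  X <- map_matrix(map)
  labs <- as.vector(t(result$labels))
  out <- list()
  for (j in seq_len(result$config$n_units)) {
    mem <- which(!is.na(labs) & labs == j)
    if (!length(mem)) next
    out[[paste0("cluster_", j)]] <-
      spectrum(map$axis, colMeans(X[mem, , drop = FALSE]))
  }
  out
}

#' Per-cluster summary of a ratio map
#'
#' For each cluster: number of valid pixels, mean ratio, and a seeded
#' percentile-bootstrap 95% confidence interval of the mean. Invalid ratio
#' pixels are excluded; clusters with fewer than 3 valid pixels are flagged
#' unreliable.
#'
#' @param rmap A [ratio_map()].
#' @param result A [fit_som()] result sharing the map's shape.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Bootstrap seed.
#' @return data.frame with columns `cluster`, `n`, `mean`, `lo`, `hi`,
#'   `reliable`.
#' @export
cluster_ratio_summary <- function(rmap, result, level = 0.95,
                                  n_boot = 10000, seed = 1) {
  if (!all(dim(rmap$values) == dim(result$labels)))
    rr_error("ratio map and cluster result shapes differ", "rr_shape_error")
  ks <- seq_len(result$config$n_units)
  rows <- lapply(ks, function(j) {
    v <- rmap$values[!is.na(result$labels) & result$labels == j]
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(cluster = j, n = 0L, mean = NA_real_,
                        lo = NA_real_, hi = NA_real_, reliable = FALSE))
    ci <- bootstrap_ci(v, level = level, n_resamples = n_boot,
                       seed = seed + j)
    data.frame(cluster = j, n = length(v), mean = ci$mean,
               lo = ci$lo, hi = ci$hi, reliable = length(v) >= 3)
  })
  do.call(rbind, rows)
}
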