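## Long-format text I/O: the layout most Raman instruments export -- one row
## per (pixel, wavenumber) with columns x, y, wavenumber, intensity.
## Tab- or comma-delimited, auto-detected; decimal point only.

#' Read a hyperspectral map from long-format delimited text
#'
#' Expects columns `x, y, wavenumber, intensity` (header required): one
#' complete spectrum per `(x, y)` pixel, in any row order. `x`/`y` are
#' 0-based grid indices (x = column, y = row, y increasing downward). The
#' axis of the returned map is the sorted unique wavenumber set.
#'
#' @param path File path.
#' @param sep Field separator; `"auto"` (default) lets [data.table::fread()]
#'   detect tab or comma.
#' @param pixel_size Micrometres per pixel recorded on the returned map.
#' @return A [hyperspec_map()].
#' @export
read_longform_map <- function(path, sep = "auto", pixel_size = 1) {
  dt <- data.table::fread(path, sep = sep, header = TRUE)
  need <- c("x", "y", "wavenumber", "intensity")
  if (!all(need %in% names(dt)))
    rr_error(sprintf("expected columns %s in '%s'",
                     paste(need, collapse = ", "), path), "rr_parse_error")
  for (cn in need) {
    v <- dt[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        rr_error(sprintf("non-numeric value in column '%s' at data line %d of '%s'",
                         cn, bad[1], path), "rr_parse_error")
      data.table::set(dt, j = cn, value = vn)
    }
    if (anyNA(dt[[cn]]))
      rr_error(sprintf("missing value in column '%s' at data line %d of '%s'",
                       cn, which(is.na(dt[[cn]]))[1], path), "rr_parse_error")
  }
  x <- NULL; y <- NULL; wavenumber <- NULL  # NSE notes
  dup <- which(duplicated(dt, by = c("x", "y", "wavenumber")))
  if (length(dup))
    rr_error(sprintf("duplicate (x, y, wavenumber) row at data line %d of '%s'",
                     dup[1], path), "rr_parse_error")
  wn <- sort(unique(dt$wavenumber))
  xs <- sort(unique(as.numeric(dt$x))); ys <- sort(unique(as.numeric(dt$y)))
  if (!isTRUE(all.equal(xs, as.numeric(seq_along(xs) - 1))) ||
      !isTRUE(all.equal(ys, as.numeric(seq_along(ys) - 1))))
    rr_error(sprintf("pixel indices must be 0..n-1 with no gaps in '%s'", path),
             "rr_parse_error")
  h <- length(ys); w <- length(xs); p <- length(wn)
  if (nrow(dt) != h * w * p) {
    cnt <- dt[, .N, by = c("x", "y")]
    off <- cnt[cnt$N != p, ]
    rr_error(sprintf("ragged pixel (x=%d, y=%d) has %d of %d wavenumbers in '%s'",
                     as.integer(off$x[1]), as.integer(off$y[1]),
                     as.integer(off$N[1]), p, path), "rr_parse_error")
  }
  data.table::setorder(dt, y, x, wavenumber)
  cube <- aperm(array(dt$intensity, dim = c(p, w, h)), c(3, 2, 1))
  hyperspec_map(wn_axis(wn), cube, pixel_size = pixel_size)
}

#' Write a hyperspectral map as long-format delimited text
#'
#' Rows are ordered by y, then x, then wavenumber, with a header line, so
#' two writes of the same map are byte-identical.
#'
#' @param map A [hyperspec_map()].
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_longform_map <- function(map, path, sep = "\t") {
  d <- dim(map$cube)
  dt <- data.table::data.table(
    x = rep(rep(seq_len(d[2]) - 1L, each = d[3]), times = d[1]),
    y = rep(seq_len(d[1]) - 1L, each = d[2] * d[3]),
    wavenumber = rep(as.numeric(map$axis), times = d[1] * d[2]),
    intensity = as.vector(aperm(map$cube, c(3, 2, 1))))
  data.table::setcolorder(dt, c("x", "y", "wavenumber", "intensity"))
  ok <- tryCatch({
    data.table::fwrite(dt, path, sep = sep, eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    rr_error(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
             "rr_io_error")
  invisible(path)
}

#' Read a single-spot time course
#'
#' Two layouts are accepted: a vector of per-time-point two-column files
#' (`wavenumber, intensity`), or one long file with columns
#' `time, wavenumber, intensity`. All spectra must share one axis. Times are
#' rebased so the first equals 0.
#'
#' @param paths Character vector of file paths (one per time point), or a
#'   single long-format file containing a `time` column.
#' @param times Acquisition times in minutes (per-file layout only). If
#'   `NULL`, inferred as `0, interval, 2*interval, ...`.
#' @param interval Sampling interval in minutes used when `times` is `NULL`.
#' @param condition `"treated"` or `"control"`.
#' @return A [timecourse_record()].
#' @export
read_spectrum_series <- function(paths, times = NULL, interval = 1,
                                 condition = "treated") {
  if (length(paths) == 1L) {
    hdr <- names(data.table::fread(paths, nrows = 0L))
    if ("time" %in% hdr) {
      dt <- data.table::fread(paths)
      tt <- sort(unique(dt$time))
      specs <- lapply(tt, function(t0) {
        sub <- dt[dt$time == t0, ]
        data.table::setorder(sub, wavenumber)
        spectrum(sub$wavenumber, sub$intensity)
      })
      ax <- specs[[1]]$axis
      for (s in specs)
        if (length(s$axis) != length(ax) || any(s$axis != ax))
          rr_error("time points differ in wavenumber axis", "rr_axis_mismatch")
      return(timecourse_record(tt, specs, condition))
    }
  }
  specs <- lapply(paths, function(p) {
    dt <- data.table::fread(p)
    data.table::setorder(dt, wavenumber)
    spectrum(dt$wavenumber, dt$intensity)
  })
  ax <- specs[[1]]$axis
  for (s in specs)
    if (length(s$axis) != length(ax) || any(s$axis != ax))
      rr_error("time points differ in wavenumber axis", "rr_axis_mismatch")
  if (is.null(times)) times <- (seq_along(specs) - 1) * interval
  timecourse_record(times, specs, condition)
}

#' Save or load a map as a single JSON container
#'
#' One self-describing text file holding the axis, the flattened data cube
#' and metadata, for fast reload without re-parsing long-format text.
#'
#' @param map A [hyperspec_map()].
#' @param path File path (`.json`).
#' @return `write_map_container()` returns `path` invisibly;
#'   `read_map_container()` returns a [hyperspec_map()].
#' @export
write_map_container <- function(map, path) {
  d <- dim(map$cube)
  obj <- list(format = "ramanredox-map", version = 1L,
              height = d[1], width = d[2], pixel_size = map$pixel_size,
              axis = as.numeric(map$axis),
              ## row-major pixel order, wavenumber fastest
              cube = as.vector(aperm(map$cube, c(3, 2, 1))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map_container
#' @export
read_map_container <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ramanredox-map"))
    rr_error(sprintf("'%s' is not a ramanredox map container", path),
             "rr_parse_error")
  p <- length(obj$axis)
  cube <- aperm(array(obj$cube, dim = c(p, obj$width, obj$height)), c(3, 2, 1))
  hyperspec_map(wn_axis(obj$axis), cube, pixel_size = obj$pixel_size)
}
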