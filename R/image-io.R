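#' Image stack container
#'
#' A calibrated fluorescence image stack: non-negative intensities indexed
#' `(frame | plane, y, x)` plus physical calibration. Pixel coordinates are
#' 0-based, `(row, column)` order, origin top-left.
#'
#' @param data 3D numeric array `(time | z, y, x)`; finite and >= 0.
#' @param frame_interval Time between frames, s (NA for z-stacks).
#' @param pixel_size Pixel pitch, um.
#' @param z_spacing Plane spacing, um, or NA for time series.
#' @param role One of `"timeseries"`, `"prestack"`, `"poststack"`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, frame_interval = NA_real_, pixel_size,
                        z_spacing = NA_real_,
                        role = c("timeseries", "prestack", "poststack")) {
  role <- match.arg(role)
  if (length(dim(data)) != 3) abort("`data` must be a 3D array (frame, y, x).")
  if (any(!is.finite(data)) || any(data < 0)) {
    abort("Intensities must be finite and >= 0.")
  }
  structure(
    list(
      data = data, frame_interval = frame_interval,
      pixel_size = pixel_size, z_spacing = z_spacing, role = role
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %s: %d frames of %dx%d px (pixel %s um, interval %s s)\n",
    x$role, d[1], d[2], d[3], format(x$pixel_size), format(x$frame_interval)
  ))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack as a multi-page TIFF with a sidecar
#'
#' Intensities are stored as 16-bit unsigned integers (rounded; values must
#' not exceed 65535), one page per frame, with the calibration metadata in a
#' JSON sidecar named `<path>.json`. Integer data round-trip losslessly.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- stack$data
  if (max(d) > 65535) abort("Intensities exceed the 16-bit range (65535).")
  pages <- lapply(seq_len(dim(d)[1]), function(i) round(d[i, , ]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    frame_interval = stack$frame_interval, pixel_size = stack$pixel_size,
    z_spacing = stack$z_spacing, role = stack$role
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' Calibration is taken from the JSON sidecar `<path>.json`; without a
#' sidecar, `frame_interval` and `pixel_size` must be supplied.
#'
#' @param path TIFF path.
#' @param frame_interval,pixel_size,z_spacing,role Calibration overrides;
#'   sidecar values win when present.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, frame_interval = NULL, pixel_size = NULL,
                       z_spacing = NULL, role = NULL) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) abort(paste0("Cannot read TIFF '", path, "': ", conditionMessage(e)))
  )
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) abort("TIFF file contains no pages.")
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1) abort("TIFF pages have inconsistent dimensions.")
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  frame_interval <- meta$frame_interval %||% frame_interval
  pixel_size <- meta$pixel_size %||% pixel_size
  z_spacing <- meta$z_spacing %||% z_spacing
  role <- meta$role %||% role %||% "timeseries"
  if (is.null(pixel_size)) {
    abort(paste0(
      "No calibration found for '", path, "'. Provide a '", sc,
      "' sidecar (frame_interval, pixel_size) or pass the values explicitly."
    ))
  }
  arr <- array(0, dim = c(length(pages), dims[[1]][1], dims[[1]][2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  image_stack(arr,
    frame_interval = frame_interval %||% NA_real_, pixel_size = pixel_size,
    z_spacing = z_spacing %||% NA_real_, role = role
  )
}

#' Write recovery traces to CSV
#'
#' Fixed column order `experiment_id, frame, time_s, raw, normalized, bleach`
#' with deterministic row order (experiment, then frame). Full-precision
#' decimal notation with '.' separator.
#'
#' @param table Data frame with the columns above (`normalized` may be NA).
#' @param path Output CSV path.
#' @export
write_traces <- function(table, path) {
  cols <- c("experiment_id", "frame", "time_s", "raw", "normalized", "bleach")
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0) {
    abort(paste("Trace table lacks columns:", paste(missing, collapse = ", ")))
  }
  out <- dplyr::arrange(as_tibble(table)[cols], .data$experiment_id, .data$frame)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(experiment_id = readr::col_character()))
}
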