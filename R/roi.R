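#' Regions of interest
#'
#' ROI constructors. Coordinates are 0-based pixel units in `(row, column)`
#' order with the origin at the top-left pixel centre; a pixel belongs to a
#' circle when its centre lies within the radius.
#'
#' @param center `c(row, col)`, 0-based pixel coordinates.
#' @param radius Circle radius in pixels (> 0).
#' @param label One of `"frap"`, `"flip"`, `"control"`, `"nucleus"`.
#' @return An object of class `roi`.
#' @export
roi_circle <- function(center, radius, label = "frap") {
  if (radius <= 0) abort("Circle radius must be > 0.")
  new_roi("circle", label, center = as.numeric(center), radius = radius)
}

#' @rdname roi_circle
#' @param origin `c(row, col)` of the top-left corner, 0-based.
#' @param size `c(height, width)` in pixels.
#' @export
roi_rectangle <- function(origin, size, label = "frap") {
  if (any(size <= 0)) abort("Rectangle size must be > 0.")
  new_roi("rectangle", label, origin = as.numeric(origin), size = as.numeric(size))
}

#' @rdname roi_circle
#' @param start,end `c(row, col)` endpoints, 0-based.
#' @export
roi_line <- function(start, end, label = "frap") {
  new_roi("line", label, start = as.numeric(start), end = as.numeric(end))
}

new_roi <- function(shape, label, ...) {
  label <- match.arg(label, c("frap", "flip", "control", "nucleus"))
  structure(list(shape = shape, label = label, ...), class = "roi")
}

#' Pixel membership mask of an ROI
#'
#' @param roi An `roi`.
#' @param dim `c(n_rows, n_cols)` of the target image.
#' @return Logical matrix.
#' @export
roi_mask <- function(roi, dim) {
  ny <- dim[1]
  nx <- dim[2]
  rows <- seq_len(ny) - 1 # 0-based pixel centres
  cols <- seq_len(nx) - 1
  m <- switch(roi$shape,
    circle = outer((rows - roi$center[1])^2, (cols - roi$center[2])^2, `+`) <=
      roi$radius^2,
    rectangle = outer(
      rows >= roi$origin[1] & rows < roi$origin[1] + roi$size[1],
      cols >= roi$origin[2] & cols < roi$origin[2] + roi$size[2],
      `&`
    ),
    line = line_mask(roi, ny, nx),
    abort(paste0("Unknown ROI shape '", roi$shape, "'."))
  )
  if (!any(m)) {
    abort(paste0("ROI '", roi$label, "' selects no pixels."))
  }
  if (roi_out_of_bounds(roi, dim)) {
    abort(paste0("ROI '", roi$label, "' extends outside the image bounds."))
  }
  m
}

line_mask <- function(roi, ny, nx) {
  n_steps <- max(abs(roi$end - roi$start)) + 1
  rr <- round(seq(roi$start[1], roi$end[1], length.out = n_steps))
  cc <- round(seq(roi$start[2], roi$end[2], length.out = n_steps))
  m <- matrix(FALSE, ny, nx)
  ok <- rr >= 0 & rr < ny & cc >= 0 & cc < nx
  m[cbind(rr[ok] + 1, cc[ok] + 1)] <- TRUE
  m
}

roi_out_of_bounds <- function(roi, dim) {
  ny <- dim[1]
  nx <- dim[2]
  switch(roi$shape,
    circle = roi$center[1] - roi$radius < -0.5 ||
      roi$center[1] + roi$radius > ny - 0.5 ||
      roi$center[2] - roi$radius < -0.5 ||
      roi$center[2] + roi$radius > nx - 0.5,
    rectangle = roi$origin[1] < 0 || roi$origin[2] < 0 ||
      roi$origin[1] + roi$size[1] > ny || roi$origin[2] + roi$size[2] > nx,
    line = any(c(roi$start, roi$end) < 0) ||
      roi$start[1] > ny - 1 || roi$end[1] > ny - 1 ||
      roi$start[2] > nx - 1 || roi$end[2] > nx - 1
  )
}

#' Read and write ROI definitions (JSON)
#'
#' The JSON dialect is a list of objects with a `shape`, a `label`, and the
#' shape's geometry in 0-based `(row, col)` pixel coordinates. Overlapping
#' `frap` and `flip` ROIs are physically possible and accepted with a
#' warning.
#'
#' @param path JSON file path.
#' @return A list of `roi` objects.
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rois <- lapply(raw, function(r) {
    switch(r$shape,
      circle = roi_circle(unlist(r$center), r$radius, r$label),
      rectangle = roi_rectangle(unlist(r$origin), unlist(r$size), r$label),
      line = roi_line(unlist(r$start), unlist(r$end), r$label),
      abort(paste0("Unknown ROI shape '", r$shape, "' in ", path))
    )
  })
  warn_roi_overlap(rois)
  rois
}

#' @rdname read_rois
#' @param rois List of `roi` objects.
#' @export
write_rois <- function(rois, path) {
  out <- lapply(rois, function(r) unclass(r))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

warn_roi_overlap <- function(rois) {
  circles <- Filter(function(r) r$shape == "circle" && r$label %in% c("frap", "flip"), rois)
  if (length(circles) < 2) return(invisible(NULL))
  for (i in seq_len(length(circles) - 1)) {
    for (j in seq(i + 1, length(circles))) {
      a <- circles[[i]]
      b <- circles[[j]]
      d <- sqrt(sum((a$center - b$center)^2))
      if (d < a$radius + b$radius) {
        warn(sprintf("ROIs '%s' and '%s' overlap (centres %.1f px apart).",
                     a$label, b$label, d))
      }
    }
  }
  invisible(NULL)
}

#' Convert physical coordinates to an ROI
#'
#' Maps a point in the simulator's micrometre coordinate system (origin at
#' the nucleus centre) to 0-based pixel coordinates of a rendered stack.
#' @param geometry A [nucleus_geometry()].
#' @param imaging An [imaging_config()].
#' @param x,y Physical coordinates, um.
#' @return `c(row, col)` 0-based pixel coordinates.
#' @export
um_to_pixel <- function(geometry, imaging, x, y) {
  grid <- image_grid(geometry, imaging)
  row <- which.min(abs(grid$axis - y)) - 1
  col <- which.min(abs(grid$axis - x)) - 1
  c(row, col)
}
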