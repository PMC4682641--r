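#' Total nuclear fluorescence from a z-stack
#'
#' Background-subtracted sum of all pixels inside the nucleus mask across all
#' planes. The per-plane background is estimated from the pixels outside the
#' mask (median); because the stack integrates over planes, the total is
#' invariant to axial drift of the foci.
#'
#' @param stack An [image_stack()] with role `prestack` or `poststack`.
#' @param nucleus_roi An `roi` labelled `nucleus` covering the nucleus.
#' @param saturation_level,saturation_warn_fraction Warn when more than this
#'   fraction of in-mask pixels sits at or above the saturation level.
#' @return Total fluorescence (numeric scalar).
#' @export
nuclear_total <- function(stack, nucleus_roi,
                          saturation_level = 65535,
                          saturation_warn_fraction = 0.01) {
  stopifnot(inherits(stack, "image_stack"))
  if (!stack$role %in% c("prestack", "poststack")) {
    abort("`nuclear_total()` expects a pre- or post-acquisition z-stack.")
  }
  d <- dim(stack$data)
  mask <- roi_mask(nucleus_roi, d[2:3])
  total <- 0
  n_sat <- 0
  for (p in seq_len(d[1])) {
    plane <- stack$data[p, , ]
    inside <- plane[mask]
    bg <- if (any(!mask)) median(plane[!mask]) else 0
    total <- total + sum(inside - bg)
    n_sat <- n_sat + sum(inside >= saturation_level)
  }
  if (n_sat / (d[1] * sum(mask)) > saturation_warn_fraction) {
    warn("Saturated pixels exceed the configured fraction; totals may be biased.")
  }
  total
}

#' Locus fluorescence from a z-stack
#'
#' Sum of the locus ROI across all planes, with the local background -- the
#' diffuse nucleoplasmic signal -- estimated per plane from an annulus
#' around the ROI and subtracted per pixel. The volume sum makes the
#' recovery fraction robust to the locus drifting out of the single
#' acquisition plane; the annulus removes the shared-pool pedestal so the
#' measurement isolates the focus itself.
#'
#' @inheritParams nuclear_total
#' @param locus_roi A circular `roi` over the locus.
#' @param nucleus_roi Optional nucleus ROI; the background annulus is
#'   restricted to pixels inside it (edge pixels outside the nucleus carry
#'   no pool signal and would bias the background low).
#' @param annulus_factor Outer radius of the background annulus as a
#'   multiple of the ROI radius.
#' @export
locus_total <- function(stack, locus_roi, nucleus_roi = NULL,
                        annulus_factor = 1.8) {
  stopifnot(inherits(stack, "image_stack"))
  if (locus_roi$shape != "circle") abort("Locus ROI must be a circle.")
  d <- dim(stack$data)
  mask <- roi_mask(locus_roi, d[2:3])
  rows <- (seq_len(d[2]) - 1) - locus_roi$center[1]
  cols <- (seq_len(d[3]) - 1) - locus_roi$center[2]
  dist2 <- outer(rows^2, cols^2, `+`)
  ring <- dist2 > locus_roi$radius^2 &
    dist2 <= (annulus_factor * locus_roi$radius)^2
  if (!is.null(nucleus_roi)) ring <- ring & roi_mask(nucleus_roi, d[2:3])
  total <- 0
  for (p in seq_len(d[1])) {
    plane <- stack$data[p, , ]
    bg <- if (any(ring)) median(plane[ring]) else 0
    total <- total + sum(plane[mask] - bg)
  }
  total
}

#' Whole-nucleus-corrected mobile fraction
#'
#' Computes the recovery fraction of a bleached locus, corrected for the
#' fluorescence the bleach destroyed. The locus signal before and after the
#' experiment is measured on the pre- and post-acquisition z-stacks (volume
#' sums, so axial drift cancels); the correction divides by the ratio of
#' whole-nucleus totals after vs before:
#' `F_M = (F_inf / F_initial) / (total_after / total_before)` and
#' `F_I = 1 - F_M`. The uncorrected single-plane ratio (mean of the last
#' plateau frames over the mean of the pre-bleach frames of the planar trace)
#' is reported alongside; it is biased low when the locus drifts out of the
#' focal plane.
#'
#' @param trace A background-subtracted (not normalized) [frap_trace()] with
#'   a known bleach frame.
#' @param pre,post Pre- and post-acquisition z-stacks.
#' @param nucleus_roi ROI covering the nucleus.
#' @param locus_roi ROI covering the bleached locus on the stacks.
#' @param n_plateau Frames defining "end of the time lapse" (same window as
#'   the normalization plateau).
#' @return A one-row tibble of class `mobile_fraction` with `f_initial`,
#'   `f_inf`, `raw_ratio`, `nuclear_total_before`, `nuclear_total_after`,
#'   `correction`, `f_m`, `f_i`, `single_plane_ratio`.
#' @export
corrected_mobile_fraction <- function(trace, pre, post, nucleus_roi,
                                      locus_roi, n_plateau = 15) {
  if (isTRUE(attr(trace, "normalized"))) {
    abort("Use the background-subtracted (not normalized) trace.")
  }
  if (!attr(trace, "background_subtracted")) {
    abort("Subtract the trace background first.")
  }
  idx <- bleach_index(trace)
  if (is.na(idx)) abort("Bleach frame unknown: run `detect_bleach_frame()` first.")

  tot_before <- nuclear_total(pre, nucleus_roi)
  tot_after <- nuclear_total(post, nucleus_roi)
  if (tot_before <= 0 || tot_after <= 0) abort("Nuclear totals must be > 0.")
  correction <- tot_after / tot_before
  if (correction > 1.05) {
    abort("Nuclear total increased by > 5% across the experiment; check the nucleus mask.")
  }

  f_initial <- locus_total(pre, locus_roi, nucleus_roi)
  f_inf <- locus_total(post, locus_roi, nucleus_roi)
  if (f_initial <= 0) abort("Locus signal before bleaching must be > 0.")
  raw_ratio <- f_inf / f_initial

  pre_frames <- trace$intensity[trace$frame < idx]
  plateau <- utils::tail(trace$intensity, n_plateau)
  single_plane_ratio <- mean(plateau) / mean(pre_frames)

  out <- tibble(
    f_initial = f_initial, f_inf = f_inf, raw_ratio = raw_ratio,
    nuclear_total_before = tot_before, nuclear_total_after = tot_after,
    correction = correction,
    f_m = raw_ratio / correction,
    f_i = 1 - raw_ratio / correction,
    single_plane_ratio = single_plane_ratio
  )
  class(out) <- c("mobile_fraction", class(out))
  out
}
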