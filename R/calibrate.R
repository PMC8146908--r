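#' Pixels-per-millimetre calibration ratio
#'
#' The pixel metric is the ratio of a measured pixel distance to the true
#' length of the same distance in millimetres: `pm = pd / td`. The deployed
#' monitor recorded roughly 3.38 px/mm with a tennis ball as reference.
#'
#' @param pd Measured pixel distance (> 0).
#' @param td True distance in mm (> 0).
#' @param source How the measurement was obtained: `"ball"` (Circle Hough
#'   Transform on a reference ball), `"ruler"`, or `"manual"`.
#' @return A `sv_pixel_metric` with fields `pm`, `pd`, `td`, `source`.
#' @examples
#' pixel_metric(169, 50)   # pm = 3.38 px/mm
#' @export
pixel_metric <- function(pd, td, source = c("manual", "ball", "ruler")) {
  if (!is.numeric(pd) || !is.numeric(td) || length(pd) != 1 ||
      length(td) != 1 || is.na(pd) || is.na(td) || pd <= 0 || td <= 0)
    abort("pixel_metric needs pd > 0 and td > 0", class = "sv_domain_error")
  structure(list(pm = pd / td, pd = pd, td = td,
                 source = match.arg(source)),
            class = "sv_pixel_metric")
}

#' @export
print.sv_pixel_metric <- function(x, ...) {
  cat(sprintf("<pixel metric: %.4f px/mm (pd = %.2f px / td = %.2f mm, %s)>\n",
              x$pm, x$pd, x$td, x$source))
  invisible(x)
}

#' Segment the reference ball by its color
#'
#' Thresholds the frame in HSV with the ball's hue range (a tennis ball is
#' a distinct yellow, easy to isolate even in the field) and applies the
#' same morphological opening/closing refinement as the bulb pipeline.
#'
#' @param frame A `sv_frame`.
#' @param ball_range A [hue_range()]; default is saturated yellow
#'   (H 20–40 on the 0–180 scale).
#' @param cfg A [seg_config()] supplying the structuring element.
#' @return Binary integer matrix.
#' @export
segment_reference_ball <- function(frame,
                                   ball_range = hue_range(20, 40, 80, 255, 80, 255),
                                   cfg = seg_config()) {
  stopifnot(inherits(frame, "sv_frame"), inherits(ball_range, "sv_hue_range"))
  hsv <- to_hsv(frame)
  mask <- matrix(as.integer(in_hue_range(hsv, ball_range)),
                 nrow(hsv[, , 1]), ncol(hsv[, , 1]))
  morph_refine(mask, cfg)
}

#' Fit a circle with a Circle Hough Transform
#'
#' Builds an accumulator over the edge pixels of the mask for every integer
#' radius in the window and returns the highest-scoring circle. The score
#' is the fraction of edge pixels voting for the winning center (after 3x3
#' accumulator smoothing), so a clean full circle scores near 1.
#'
#' @param mask Binary matrix (e.g. from [segment_reference_ball()]).
#' @param radius_lo,radius_hi Radius search window in px, `lo < hi`.
#' @param score_floor Minimum accepted score; below it the fit is a
#'   calibration failure.
#' @param n_angles Angular samples per radius.
#' @return A `sv_circle`: `center_row`, `center_col`, `radius_px`,
#'   `diameter_px`, `score`.
#' @export
fit_circle_cht <- function(mask, radius_lo, radius_hi, score_floor = 0.25,
                           n_angles = 96L) {
  stopifnot(is.matrix(mask))
  if (!(radius_lo < radius_hi) || radius_lo <= 0)
    abort("need 0 < radius_lo < radius_hi", class = "sv_config_error")
  edges <- which(boundary_pixels(matrix(as.integer(mask != 0),
                                        nrow(mask), ncol(mask))))
  if (length(edges) == 0)
    abort("calibration failure: empty mask, no edges to fit",
          class = "sv_calibration_error")
  nr <- nrow(mask); nc <- ncol(mask)
  er <- (edges - 1) %% nr + 1
  ec <- (edges - 1) %/% nr + 1
  th <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  best <- list(score = -Inf)
  for (r in seq(ceiling(radius_lo), floor(radius_hi))) {
    off <- unique(cbind(round(r * cos(th)), round(r * sin(th))))
    cr <- rep(er, times = nrow(off)) - rep(off[, 1], each = length(er))
    cc <- rep(ec, times = nrow(off)) - rep(off[, 2], each = length(er))
    ok <- cr >= 1 & cr <= nr & cc >= 1 & cc <= nc
    if (!any(ok)) next
    acc <- matrix(tabulate(cr[ok] + (cc[ok] - 1) * nr, nbins = nr * nc), nr, nc)
    acc <- as.matrix(EBImage::filter2(acc, matrix(1, 3, 3),
                                      boundary = "replicate"))
    sc <- max(acc) / length(edges)
    if (sc > best$score) {
      w <- which.max(acc)
      best <- list(score = sc, radius = r,
                   row = (w - 1) %% nr + 1, col = (w - 1) %/% nr + 1)
    }
  }
  if (!is.finite(best$score) || best$score < score_floor)
    abort(sprintf(
      "calibration failure: no circle with score >= %.2f in radius window [%g, %g]",
      score_floor, radius_lo, radius_hi), class = "sv_calibration_error")
  structure(list(center_row = best$row, center_col = best$col,
                 radius_px = best$radius, diameter_px = 2 * best$radius,
                 score = best$score),
            class = "sv_circle")
}

#' @export
print.sv_circle <- function(x, ...) {
  cat(sprintf("<circle at (%d, %d), diameter %.1f px, score %.2f>\n",
              x$center_row, x$center_col, x$diameter_px, x$score))
  invisible(x)
}

#' Calibrate the pixel metric from reference-ball frames
#'
#' Segments and Hough-fits the ball in every frame and takes the median of
#' the per-frame pixels-per-mm ratios, which is robust to one badly
#' segmented frame — the known failure mode of in-field calibration.
#'
#' @param frames List of `sv_frame`s (at least one).
#' @param ball_range A [hue_range()] for the ball color.
#' @param true_diameter_mm Known ball diameter; default 65.4 mm, the
#'   regulation tennis-ball mid-range.
#' @param radius_window Circle-radius search window in px; default
#'   `c(10, min(H, W)/2)`.
#' @param cfg A [seg_config()] for the ball segmentation.
#' @return A `sv_pixel_metric` with `source = "ball"`.
#' @export
calibrate_from_frames <- function(frames,
                                  ball_range = hue_range(20, 40, 80, 255, 80, 255),
                                  true_diameter_mm = 65.4,
                                  radius_window = NULL,
                                  cfg = seg_config()) {
  if (inherits(frames, "sv_frame")) frames <- list(frames)
  if (length(frames) == 0)
    abort("calibration needs at least one frame", class = "sv_domain_error")
  if (true_diameter_mm <= 0)
    abort("true_diameter_mm must be > 0", class = "sv_domain_error")
  diams <- numeric(0)
  for (f in frames) {
    win <- radius_window %||%
      c(10, floor(min(dim(f$pixels)[1:2]) / 2) - 1)
    fit <- tryCatch({
      mask <- segment_reference_ball(f, ball_range, cfg)
      fit_circle_cht(mask, win[1], win[2])
    }, sv_calibration_error = function(e) {
      warning(sprintf("frame %d: %s", f$frame_id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(fit)) diams <- c(diams, fit$diameter_px)
  }
  if (length(diams) == 0)
    abort("calibration failure: the ball was not found in any frame",
          class = "sv_calibration_error")
  pixel_metric(stats::median(diams), true_diameter_mm, source = "ball")
}
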