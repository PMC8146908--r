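#' Denoise a frame (median then Gaussian blur)
#'
#' Applies a k x k median filter to remove speckle noise, then a k x k
#' Gaussian blur, per channel. The Gaussian standard deviation is tied to
#' the kernel size by the conventional rule
#' `sigma = 0.3 * ((k - 1) / 2 - 1) + 0.8` so results are reproducible
#' across implementations (k = 9 gives sigma = 1.7).
#'
#' @param frame A [new_frame()].
#' @param cfg A [seg_config()]; uses `median_kernel` and `gaussian_kernel`.
#' @return A denoised `sv_frame` of identical dimensions.
#' @export
denoise <- function(frame, cfg = seg_config()) {
  stopifnot(inherits(frame, "sv_frame"), inherits(cfg, "sv_seg_config"))
  d <- dim(frame$pixels)
  for (k in c(cfg$median_kernel, cfg$gaussian_kernel)) {
    if (k > min(d[1], d[2]))
      abort("filter kernel larger than the frame", class = "sv_config_error")
  }
  kern <- gaussian_kernel_2d(cfg$gaussian_kernel)
  out <- frame$pixels
  for (ch in 1:3) {
    x <- frame$pixels[, , ch] / 255
    x <- EBImage::medianFilter(x, (cfg$median_kernel - 1L) %/% 2L)
    x <- EBImage::filter2(x, kern, boundary = "replicate")
    out[, , ch] <- pmin(pmax(as.numeric(x), 0), 1) * 255
  }
  dim(out) <- d
  new_frame(out, timestamp = frame$timestamp, frame_id = frame$frame_id)
}

# k x k separable Gaussian kernel with the size-derived sigma, normalized.
gaussian_kernel_2d <- function(k) {
  sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  r <- (k - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kern <- outer(g, g)
  kern / sum(kern)
}

#' Convert a frame to HSV
#'
#' Hue is returned on the 0–180 scale (degrees halved), saturation and
#' value on 0–255, matching the 8-bit convention of the configured
#' thresholds.
#'
#' @param frame A `sv_frame`.
#' @return An H x W x 3 array with channels H, S, V.
#' @export
to_hsv <- function(frame) {
  stopifnot(inherits(frame, "sv_frame"))
  d <- dim(frame$pixels)
  m <- matrix(aperm(frame$pixels, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  out <- array(0, d)
  out[, , 1] <- matrix(hsv[1, ] * 180, d[1], d[2])
  out[, , 2] <- matrix(hsv[2, ] * 255, d[1], d[2])
  out[, , 3] <- matrix(hsv[3, ] * 255, d[1], d[2])
  out
}

in_hue_range <- function(hsv, r) {
  h <- hsv[, , 1, drop = FALSE]; s <- hsv[, , 2, drop = FALSE]
  v <- hsv[, , 3, drop = FALSE]
  out <- (h >= r$h_lo & h <= r$h_hi & s >= r$s_lo & s <= r$s_hi &
            v >= r$v_lo & v <= r$v_hi)
  matrix(out, dim(hsv)[1], dim(hsv)[2])
}

#' Threshold bulb-skin and specular pixels
#'
#' Foreground is the union of all skin hue ranges and the specular range;
#' each range is an inclusive interval per channel, ANDed across channels
#' and ORed across ranges.
#'
#' @param hsv H x W x 3 HSV array from [to_hsv()].
#' @param cfg A [seg_config()].
#' @return Binary integer matrix (1 = foreground).
#' @export
threshold_onion <- function(hsv, cfg = seg_config()) {
  stopifnot(length(dim(hsv)) == 3, inherits(cfg, "sv_seg_config"))
  fg <- Reduce(`|`, lapply(cfg$skin_ranges, in_hue_range, hsv = hsv))
  fg <- fg | in_hue_range(hsv, cfg$specular_range)
  matrix(as.integer(fg), dim(hsv)[1], dim(hsv)[2])
}

# OpenCV-style elliptical structuring element: inscribed ellipse in a
# size x size box; for even sizes the anchor is the central pixel of the
# bounding box (documented, for reproducibility).
ellipse_kernel <- function(size) {
  c0 <- (size - 1) / 2
  r <- (size - 1) / 2 + 1e-9
  ij <- expand.grid(i = 0:(size - 1), j = 0:(size - 1))
  inside <- ((ij$i - c0) / r)^2 + ((ij$j - c0) / r)^2 <= 1
  matrix(as.integer(inside), size, size)
}

#' Morphological refinement of the thresholded mask
#'
#' Opening (removes noise smaller than the structuring element) followed by
#' closing (fills comparable holes), with a circular structuring element of
#' radius `(morph_kernel - 1) / 2` — the disc inscribed in a
#' `morph_kernel` x `morph_kernel` box. The operations are computed by
#' thresholding exact Euclidean distance transforms, which is equivalent to
#' Minkowski erosion/dilation with that disc but anchor-free: an even
#' element size introduces no half-pixel translation.
#'
#' @param mask Binary matrix.
#' @param cfg A [seg_config()].
#' @return Binary integer matrix.
#' @export
morph_refine <- function(mask, cfg = seg_config()) {
  stopifnot(is.matrix(mask), inherits(cfg, "sv_seg_config"))
  rho <- (cfg$morph_kernel - 1) / 2
  m <- disc_dilate(disc_erode(mask, rho), rho)   # opening
  disc_erode(disc_dilate(m, rho), rho)           # closing
}

# Euclidean-disc erosion: keep pixels whose distance to background > rho.
# Outside the frame counts as foreground, so border-touching regions are
# not eaten from the border side (they are policy-filtered later, not
# destroyed here).
disc_erode <- function(mask, rho) {
  if (!any(mask != 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- distance_map_raw(mask)
  matrix(as.integer(mask != 0 & d > rho), nrow(mask), ncol(mask))
}

# Euclidean-disc dilation: add pixels within rho of the foreground.
disc_dilate <- function(mask, rho) {
  if (all(mask != 0)) return(matrix(1L, nrow(mask), ncol(mask)))
  d <- distance_map_raw(1L - (mask != 0))
  matrix(as.integer(mask != 0 | d <= rho), nrow(mask), ncol(mask))
}

# distmap without the degenerate all-foreground border contract
distance_map_raw <- function(mask) {
  if (!any(mask == 0)) return(matrix(Inf, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)),
                        metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

#' Euclidean distance transform
#'
#' Exact Euclidean distance of every foreground pixel to the nearest
#' background pixel; 0 on background. A mask with no background at all is
#' handled by treating the image border as background.
#'
#' @param mask Binary matrix.
#' @return Numeric matrix of distances.
#' @export
distance_map <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask == 0)) {
    pad <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
    pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
    d <- EBImage::distmap(pad, metric = "euclidean")
    return(matrix(as.numeric(d), nrow(pad), ncol(pad))[2:(nrow(mask) + 1),
                                                       2:(ncol(mask) + 1)])
  }
  d <- EBImage::distmap(mask, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

#' Extract watershed markers from distance-map peaks
#'
#' Local maxima of the distance map restricted to the foreground are the
#' high-confidence bulb cores. Peaks are suppressed so that no two accepted
#' peak components are closer than `cfg$marker_min_distance`, then labelled
#' by 8-connected component analysis.
#'
#' @param dist Distance map from [distance_map()].
#' @param mask Binary matrix of the same shape.
#' @param cfg A [seg_config()].
#' @return A `sv_labels` object: `labels` (integer matrix, 0 = background)
#'   and `region_count`.
#' @export
find_markers <- function(dist, mask, cfg = seg_config()) {
  stopifnot(is.matrix(dist), is.matrix(mask), all(dim(dist) == dim(mask)))
  md <- cfg$marker_min_distance
  if (!any(mask != 0))
    return(new_labels(matrix(0L, nrow(mask), ncol(mask)), 0L))
  brush <- ellipse_kernel(2L * ceiling(md) + 1L)
  maxf <- EBImage::dilate(dist, brush)
  peaks <- mask != 0 & dist > 0 & (dist >= as.numeric(maxf) - 1e-9)
  lab <- cc_label8(matrix(as.integer(peaks), nrow(mask), ncol(mask)))
  k <- max(lab)
  if (k <= 1) return(new_labels(lab, as.integer(k)))
  # greedy suppression of tied-plateau components closer than md,
  # strongest (highest distance value) first
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  height <- vapply(split(dist[idx], comp), max, numeric(1))
  cr <- vapply(split(rows, comp), mean, numeric(1))
  cc <- vapply(split(cols, comp), mean, numeric(1))
  ord <- order(-height, as.integer(names(height)))
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0 ||
        all(sqrt((cr[keep] - cr[i])^2 + (cc[keep] - cc[i])^2) >= md))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  remap <- integer(k)
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  sel <- lab > 0 & remap[pmax(lab, 1L)] > 0
  out[sel] <- remap[lab[sel]]
  new_labels(out, length(keep))
}

new_labels <- function(labels, region_count) {
  structure(list(labels = labels, region_count = as.integer(region_count)),
            class = "sv_labels")
}

#' @export
print.sv_labels <- function(x, ...) {
  cat(sprintf("<sv_labels %d x %d, %d region(s)>\n",
              nrow(x$labels), ncol(x$labels), x$region_count))
  invisible(x)
}

#' Marker-controlled watershed split
#'
#' Floods the negated distance transform of the mask from the given
#' markers (Meyer's algorithm, 8-connectivity), so touching bulbs separate
#' at the ridge between their distance peaks. Pixels where basins meet
#' become boundary (label 0).
#'
#' @param frame The source `sv_frame` (carried for provenance; the flooding
#'   surface is the distance map, not image intensity).
#' @param mask Binary matrix.
#' @param markers `sv_labels` from [find_markers()].
#' @return A `sv_labels` with contiguous labels `1..K`.
#' @export
watershed_split <- function(frame, mask, markers) {
  stopifnot(is.matrix(mask), inherits(markers, "sv_labels"))
  if (markers$region_count == 0)
    return(new_labels(matrix(0L, nrow(mask), ncol(mask)), 0L))
  dist <- distance_map(mask)
  lab <- watershed_flood(-dist, markers$labels,
                         matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  present <- sort(unique(lab[lab > 0]))
  if (length(present) && !identical(present, seq_along(present))) {
    remap <- integer(max(present))
    remap[present] <- seq_along(present)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  new_labels(lab, length(present))
}

#' Measure and filter labelled regions
#'
#' Computes per-region area, contour length, centroid, bounding box and a
#' diameter descriptor (minimum enclosing circle of the contour by default,
#' equivalent-area diameter as the configured alternative), then drops
#' regions failing the area filters or lying within `border_margin` of the
#' frame border.
#'
#' @param labels `sv_labels` from [watershed_split()].
#' @param cfg A [seg_config()].
#' @return A tibble with one row per surviving region: `label`, `area`,
#'   `perimeter`, `centroid_row`, `centroid_col`, `diameter_px`,
#'   `bbox_row0`, `bbox_col0`, `bbox_row1`, `bbox_col1` (half-open).
#' @export
extract_regions <- function(labels, cfg = seg_config()) {
  stopifnot(inherits(labels, "sv_labels"), inherits(cfg, "sv_seg_config"))
  lab <- labels$labels
  empty <- tibble::tibble(
    label = integer(0), area = numeric(0), perimeter = numeric(0),
    centroid_row = numeric(0), centroid_col = numeric(0),
    diameter_px = numeric(0), bbox_row0 = integer(0), bbox_col0 = integer(0),
    bbox_row1 = integer(0), bbox_col1 = integer(0))
  idx <- which(lab > 0)
  if (length(idx) == 0) return(empty)
  v <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  bound <- boundary_pixels(lab)
  g <- split(seq_along(idx), v)
  max_area <- cfg$max_region_area %||% (0.25 * nrow(lab) * ncol(lab))
  res <- lapply(g, function(ii) {
    r <- rows[ii]; co <- cols[ii]
    b <- bound[idx[ii]]
    pts <- cbind(r[b], co[b])
    diam <- if (cfg$diameter == "mec" && nrow(pts) > 0) {
      2 * min_enclosing_circle(pts)$radius
    } else {
      2 * sqrt(length(ii) / pi)
    }
    tibble::tibble(
      label = v[ii[1]], area = length(ii), perimeter = sum(b),
      centroid_row = mean(r), centroid_col = mean(co), diameter_px = diam,
      bbox_row0 = min(r), bbox_col0 = min(co),
      bbox_row1 = max(r) + 1L, bbox_col1 = max(co) + 1L)
  })
  out <- dplyr::bind_rows(res)
  m <- cfg$border_margin
  keep <- out$area >= cfg$min_region_area & out$area <= max_area
  if (m > 0) {
    keep <- keep & out$bbox_row0 > m & out$bbox_col0 > m &
      out$bbox_row1 <= nrow(lab) - m + 1 & out$bbox_col1 <= ncol(lab) - m + 1
  }
  out[keep, , drop = FALSE]
}

# TRUE for pixels whose 4-neighborhood leaves the region (or the frame).
boundary_pixels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  up <- rbind(lab[1, , drop = FALSE] * 0 - 1L, lab[-nr, , drop = FALSE])
  down <- rbind(lab[-1, , drop = FALSE], lab[nr, , drop = FALSE] * 0 - 1L)
  left <- cbind(lab[, 1, drop = FALSE] * 0 - 1L, lab[, -nc, drop = FALSE])
  right <- cbind(lab[, -1, drop = FALSE], lab[, nc, drop = FALSE] * 0 - 1L)
  lab > 0 & (lab != up | lab != down | lab != left | lab != right)
}

#' Run the full segmentation and sizing pipeline on one frame
#'
#' Denoise, HSV threshold, morphological refinement, distance transform,
#' marker extraction, watershed split, region measurement — then, when a
#' pixel metric is available, millimetre conversion and size grading.
#'
#' @param frame A `sv_frame`.
#' @param config A [run_config()] (or a bare [seg_config()], in which case
#'   default size classes and no pixel metric are used).
#' @return A tibble of detected bulbs: region measurements plus
#'   `diameter_mm` and `size_class` (NA, with one warning, when no pixel
#'   metric is configured), and the frame's `frame_id` and `timestamp`.
#' @examples
#' sc <- generate_scene(scene_spec(width = 320, height = 240, n_bulbs = 2,
#'                                 diameter_mm_range = c(28, 38), seed = 4))
#' detect_bulbs(sc$frame, run_config(pixel_metric = pixel_metric(3.38, 1)))
#' @export
detect_bulbs <- function(frame, config = run_config()) {
  if (inherits(config, "sv_seg_config")) config <- run_config(segmentation = config)
  stopifnot(inherits(frame, "sv_frame"), inherits(config, "sv_run_config"))
  cfg <- config$segmentation
  hsv <- to_hsv(denoise(frame, cfg))
  mask <- morph_refine(threshold_onion(hsv, cfg), cfg)
  dist <- distance_map(mask)
  markers <- find_markers(dist, mask, cfg)
  labels <- watershed_split(frame, mask, markers)
  regions <- extract_regions(labels, cfg)
  if (is.null(config$pixel_metric)) {
    warning("no pixel metric configured; reporting pixel-only output",
            call. = FALSE)
    regions$diameter_mm <- NA_real_
    regions$size_class <- factor(NA, levels = config$size_classes$names)
  } else {
    regions$diameter_mm <- px_to_mm(regions$diameter_px, config$pixel_metric)
    regions$size_class <- classify_size(regions$diameter_mm,
                                        config$size_classes)
  }
  regions$frame_id <- frame$frame_id
  regions$timestamp <- frame$timestamp
  regions
}
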