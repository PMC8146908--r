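#' HSV range on the 8-bit OpenCV-style scales
#'
#' Hue lives on the 0–180 scale (degrees halved), saturation and value on
#' 0–255. A pixel is inside the range when every channel lies inside its
#' inclusive interval.
#'
#' @param h_lo,h_hi Hue bounds, 0–180.
#' @param s_lo,s_hi Saturation bounds, 0–255.
#' @param v_lo,v_hi Value bounds, 0–255.
#' @return A `sv_hue_range` list.
#' @examples
#' hue_range(0, 40)                 # red/orange bulb skin
#' hue_range(160, 180)              # wrap-around red skin
#' @export
hue_range <- function(h_lo, h_hi, s_lo = 0, s_hi = 255, v_lo = 0, v_hi = 255) {
  r <- list(h_lo = h_lo, h_hi = h_hi, s_lo = s_lo, s_hi = s_hi,
            v_lo = v_lo, v_hi = v_hi)
  if (any(!vapply(r, is.numeric, logical(1))))
    abort("hue_range bounds must be numeric", class = "sv_config_error")
  if (h_lo > h_hi || s_lo > s_hi || v_lo > v_hi)
    abort("hue_range bounds must satisfy lo <= hi on every channel",
          class = "sv_config_error")
  if (h_lo < 0 || h_hi > 180 || s_lo < 0 || s_hi > 255 || v_lo < 0 || v_hi > 255)
    abort("hue_range bounds outside the 0-180 / 0-255 scales",
          class = "sv_config_error")
  structure(r, class = "sv_hue_range")
}

#' Segmentation configuration
#'
#' Every threshold, kernel and marker parameter of the bulb-segmentation
#' chain. Defaults reproduce the deployed monitor: 9 px median and Gaussian
#' kernels, skin hue in \[0, 40\] and \[160, 180\], a specular range of
#' H in \[0, 60\] with S in \[240, 255\], a 12 px elliptical structuring
#' element, and 8-connectivity throughout.
#'
#' @param median_kernel,gaussian_kernel Odd filter sizes in pixels (>= 3).
#' @param skin_ranges List of [hue_range()]s for bulb skin. The defaults
#'   carry a saturation floor of 40: hue is undefined as saturation
#'   approaches zero (every neutral pixel converts to H = 0), so a literal
#'   hue-only interval would classify the entire gray belt as bulb skin.
#'   Pixels below the floor are treated as achromatic and cannot match a
#'   hue range.
#' @param specular_range One [hue_range()] for specular highlights.
#' @param morph_kernel Side of the elliptical structuring element (px).
#' @param marker_min_distance Minimum separation between accepted distance
#'   peaks (px). The default 20 px is roughly the smallest expected bulb
#'   radius at 3.38 px/mm.
#' @param min_region_area,max_region_area Region area filters in px^2;
#'   `max_region_area = NULL` means a quarter of the frame area.
#' @param border_margin Regions whose bounding box comes within this many
#'   pixels of the frame border are dropped; 0 keeps edge-touching regions.
#' @param diameter Size descriptor: diameter of the minimum enclosing
#'   circle of the region contour (default), or the equivalent-area
#'   diameter.
#' @return A `sv_seg_config` list.
#' @export
seg_config <- function(median_kernel = 9L,
                       gaussian_kernel = 9L,
                       skin_ranges = list(hue_range(0, 40, s_lo = 40),
                                          hue_range(160, 180, s_lo = 40)),
                       specular_range = hue_range(0, 60, 240, 255),
                       morph_kernel = 12L,
                       marker_min_distance = 20,
                       min_region_area = 200,
                       max_region_area = NULL,
                       border_margin = 0,
                       diameter = c("mec", "equivalent_area")) {
  check_kernel <- function(k, what) {
    if (!is.numeric(k) || length(k) != 1 || k < 3 || k %% 2 == 0)
      abort(paste0(what, " must be an odd integer >= 3, got ", k),
            class = "sv_config_error")
  }
  check_kernel(median_kernel, "median_kernel")
  check_kernel(gaussian_kernel, "gaussian_kernel")
  if (inherits(skin_ranges, "sv_hue_range")) skin_ranges <- list(skin_ranges)
  stopifnot(is.list(skin_ranges),
            all(vapply(skin_ranges, inherits, logical(1), "sv_hue_range")),
            inherits(specular_range, "sv_hue_range"))
  if (morph_kernel < 1)
    abort("morph_kernel must be >= 1", class = "sv_config_error")
  if (marker_min_distance < 1)
    abort("marker_min_distance must be >= 1", class = "sv_config_error")
  if (!is.null(max_region_area) && min_region_area >= max_region_area)
    abort("min_region_area must be < max_region_area", class = "sv_config_error")
  structure(list(
    median_kernel = as.integer(median_kernel),
    gaussian_kernel = as.integer(gaussian_kernel),
    skin_ranges = skin_ranges,
    specular_range = specular_range,
    morph_kernel = as.integer(morph_kernel),
    marker_min_distance = marker_min_distance,
    min_region_area = min_region_area,
    max_region_area = max_region_area,
    border_margin = border_margin,
    diameter = match.arg(diameter),
    connectivity = 8L
  ), class = "sv_seg_config")
}

#' Size-class specification
#'
#' Two diameter thresholds cut the millimetre scale into the three market
#' classes. Intervals are half-open: a bulb is small when d < t_small_medium,
#' medium when t_small_medium <= d < t_medium_large, large otherwise, so a
#' boundary diameter always goes to the larger class. Defaults (44 and
#' 54 mm) are the rounded midpoints between the adjacent-class extremes of
#' the hand-calipered grading sample.
#'
#' @param t_small_medium,t_medium_large Thresholds in mm.
#' @param names Class names, smallest first.
#' @param colors Overlay colors per class (blue/green/red convention).
#' @return A `sv_size_classes` list.
#' @export
size_class_spec <- function(t_small_medium = 44,
                            t_medium_large = 54,
                            names = c("small", "medium", "large"),
                            colors = c("blue", "green", "red")) {
  if (!(t_small_medium > 0 && t_small_medium < t_medium_large))
    abort("need 0 < t_small_medium < t_medium_large", class = "sv_config_error")
  stopifnot(length(names) == 3, length(colors) == 3)
  structure(list(t_small_medium = t_small_medium,
                 t_medium_large = t_medium_large,
                 names = as.character(names),
                 colors = as.character(colors)),
            class = "sv_size_classes")
}

#' Run configuration bundling all pipeline parameters
#'
#' @param segmentation A [seg_config()].
#' @param size_classes A [size_class_spec()].
#' @param pixel_metric A [pixel_metric()] or `NULL`. Detection without one
#'   is allowed but yields pixel-only output with a warning.
#' @param frame_interval Seconds between consumed frames (default 2.5 s,
#'   the logging cadence of the deployed monitor).
#' @return A `sv_run_config` list.
#' @export
run_config <- function(segmentation = seg_config(),
                       size_classes = size_class_spec(),
                       pixel_metric = NULL,
                       frame_interval = 2.5) {
  stopifnot(inherits(segmentation, "sv_seg_config"),
            inherits(size_classes, "sv_size_classes"),
            is.null(pixel_metric) || inherits(pixel_metric, "sv_pixel_metric"),
            frame_interval > 0)
  structure(list(segmentation = segmentation, size_classes = size_classes,
                 pixel_metric = pixel_metric, frame_interval = frame_interval),
            class = "sv_run_config")
}

range_to_list <- function(r) unclass(r)
list_to_range <- function(l, default) {
  if (is.null(l)) return(default)
  d <- unclass(default)
  d[names(l)] <- l
  do.call(hue_range, d)
}

#' Write / read a run configuration as YAML
#'
#' Every field is optional in the YAML document; missing fields fall back
#' to the package defaults, so a partial file is a valid configuration.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_config()` returns a `sv_run_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sv_run_config"))
  seg <- config$segmentation
  doc <- list(
    segmentation = list(
      median_kernel = seg$median_kernel,
      gaussian_kernel = seg$gaussian_kernel,
      skin_ranges = lapply(seg$skin_ranges, range_to_list),
      specular_range = range_to_list(seg$specular_range),
      morph_kernel = seg$morph_kernel,
      marker_min_distance = seg$marker_min_distance,
      min_region_area = seg$min_region_area,
      max_region_area = seg$max_region_area,
      border_margin = seg$border_margin,
      diameter = seg$diameter
    ),
    size_classes = unclass(config$size_classes),
    pixel_metric = if (!is.null(config$pixel_metric)) unclass(config$pixel_metric),
    frame_interval = config$frame_interval
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort(paste0("config file not found: ", path), class = "sv_io_error")
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  sd <- doc$segmentation
  def <- seg_config()
  seg <- seg_config(
    median_kernel = sd$median_kernel %||% def$median_kernel,
    gaussian_kernel = sd$gaussian_kernel %||% def$gaussian_kernel,
    skin_ranges = if (is.null(sd$skin_ranges)) def$skin_ranges
                  else lapply(sd$skin_ranges, function(l) do.call(hue_range, l)),
    specular_range = list_to_range(sd$specular_range, def$specular_range),
    morph_kernel = sd$morph_kernel %||% def$morph_kernel,
    marker_min_distance = sd$marker_min_distance %||% def$marker_min_distance,
    min_region_area = sd$min_region_area %||% def$min_region_area,
    max_region_area = sd$max_region_area,
    border_margin = sd$border_margin %||% def$border_margin,
    diameter = sd$diameter %||% def$diameter
  )
  sc <- doc$size_classes
  defc <- size_class_spec()
  classes <- size_class_spec(
    t_small_medium = sc$t_small_medium %||% defc$t_small_medium,
    t_medium_large = sc$t_medium_large %||% defc$t_medium_large,
    names = unlist(sc$names) %||% defc$names,
    colors = unlist(sc$colors) %||% defc$colors
  )
  pmet <- NULL
  if (!is.null(doc$pixel_metric)) {
    p <- doc$pixel_metric
    pmet <- pixel_metric(p$pd, p$td, source = p$source %||% "manual")
  }
  run_config(segmentation = seg, size_classes = classes, pixel_metric = pmet,
             frame_interval = doc$frame_interval %||% 2.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
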