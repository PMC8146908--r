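#' Convert pixel diameters to millimetres
#'
#' Inverse application of the pixel metric: `mm = px / pm`.
#'
#' @param diameter_px Numeric vector of pixel diameters (>= 0).
#' @param pm A [pixel_metric()] or a bare positive number (px/mm).
#' @return Diameters in mm.
#' @examples
#' px_to_mm(148.72, pixel_metric(169, 50))  # 44 mm at 3.38 px/mm
#' @export
px_to_mm <- function(diameter_px, pm) {
  if (inherits(pm, "sv_pixel_metric")) pm <- pm$pm
  if (!is.numeric(pm) || length(pm) != 1 || pm <= 0)
    abort("pm must be a positive pixels-per-mm ratio", class = "sv_domain_error")
  if (any(diameter_px < 0, na.rm = TRUE))
    abort("pixel diameters must be >= 0", class = "sv_domain_error")
  diameter_px / pm
}

#' Assign size classes from millimetre diameters
#'
#' Half-open intervals: small when `d < t_small_medium`, medium when
#' `t_small_medium <= d < t_medium_large`, large otherwise, so every
#' diameter maps to exactly one class and boundary values go to the larger
#' class.
#'
#' @param diameter_mm Numeric vector of diameters (> 0).
#' @param spec A [size_class_spec()].
#' @return Factor with the spec's class names as levels.
#' @examples
#' classify_size(c(37, 47.78, 60.51))
#' @export
classify_size <- function(diameter_mm, spec = size_class_spec()) {
  stopifnot(inherits(spec, "sv_size_classes"))
  if (any(diameter_mm <= 0, na.rm = TRUE))
    abort("diameters must be positive", class = "sv_domain_error")
  i <- 1L + (diameter_mm >= spec$t_small_medium) +
    (diameter_mm >= spec$t_medium_large)
  factor(spec$names[i], levels = spec$names)
}

#' Derive size-class thresholds from labelled diameters
#'
#' For each adjacent class pair the boundary is the midpoint between the
#' maximum diameter of the lower class and the minimum diameter of the
#' upper class. When the classes overlap, the boundary is instead the 1-D
#' cut minimizing the number of misclassified samples under the half-open
#' convention, ties going to the lower cut.
#'
#' @param samples Data frame with columns `diameter` (mm) and `label`
#'   (class names), or two vectors via `diameter` + `label`.
#' @param names The three class names in increasing size order.
#' @return A [size_class_spec()] with the derived thresholds.
#' @examples
#' derive_thresholds(data.frame(
#'   diameter = c(10, 11, 20, 21, 30, 31),
#'   label = rep(c("small", "medium", "large"), each = 2)))
#' @export
derive_thresholds <- function(samples, names = c("small", "medium", "large")) {
  stopifnot(is.data.frame(samples),
            all(c("diameter", "label") %in% colnames(samples)))
  d <- split(samples$diameter, factor(samples$label, levels = names))
  if (any(vapply(d, length, integer(1)) == 0))
    abort("every size class must be represented in the samples",
          class = "sv_domain_error")
  cut_between <- function(lower, upper) {
    lo <- max(lower); hi <- min(upper)
    if (lo < hi) return((lo + hi) / 2)
    # overlap: minimize misclassification; candidates are the sample values
    cand <- sort(unique(c(lower, upper)))
    miscls <- vapply(cand, function(t)
      sum(lower >= t) + sum(upper < t), numeric(1))
    cand[which.min(miscls)] # which.min takes the first (lowest) tie
  }
  size_class_spec(
    t_small_medium = cut_between(d[[1]], d[[2]]),
    t_medium_large = cut_between(d[[2]], d[[3]]),
    names = names
  )
}
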