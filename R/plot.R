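#' Plot a frame with detection circles
#'
#' Renders the frame as a raster with one circle per detected bulb, colored
#' by size class (blue = small, green = medium, red = large by default).
#'
#' @param frame A `sv_frame`.
#' @param bulbs Tibble from [detect_bulbs()] (needs `centroid_row`,
#'   `centroid_col`, `diameter_px`, `size_class`).
#' @param classes A [size_class_spec()] supplying names and colors.
#' @return A ggplot object.
#' @export
plot_detections <- function(frame, bulbs, classes = size_class_spec()) {
  stopifnot(inherits(frame, "sv_frame"))
  H <- dim(frame$pixels)[1]; W <- dim(frame$pixels)[2]
  img <- grDevices::rgb(frame$pixels[, , 1] / 255,
                        frame$pixels[, , 2] / 255,
                        frame$pixels[, , 3] / 255)
  dim(img) <- c(H, W)
  th <- seq(0, 2 * pi, length.out = 73)
  circ <- dplyr::bind_rows(lapply(seq_len(nrow(bulbs)), function(i) {
    tibble::tibble(id = i,
                   x = bulbs$centroid_col[i] + bulbs$diameter_px[i] / 2 * cos(th),
                   y = bulbs$centroid_row[i] + bulbs$diameter_px[i] / 2 * sin(th),
                   size_class = as.character(bulbs$size_class[i]))
  }))
  pal <- stats::setNames(classes$colors, classes$names)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(img, xmin = 0.5, xmax = W + 0.5,
                               ymin = -(H + 0.5), ymax = -0.5) +
    ggplot2::scale_y_continuous(labels = function(b) -b) +
    ggplot2::coord_fixed(xlim = c(0.5, W + 0.5), ylim = c(-(H + 0.5), -0.5),
                         expand = FALSE) +
    ggplot2::labs(x = "column (px)", y = "row (px)", color = "size class") +
    ggplot2::theme_minimal()
  if (nrow(circ) > 0) {
    p <- p + ggplot2::geom_path(
      data = circ,
      ggplot2::aes(x = .data$x, y = -.data$y, group = .data$id,
                   color = .data$size_class),
      linewidth = 0.8) +
      ggplot2::scale_color_manual(values = pal, na.value = "grey70")
  }
  p
}

#' @rdname plot_detections
#' @param object,x A `sv_scene`.
#' @param ... Unused.
#' @export
autoplot.sv_scene <- function(object, classes = size_class_spec(), ...) {
  bulbs <- tibble::tibble(centroid_row = object$truth$row,
                          centroid_col = object$truth$col,
                          diameter_px = object$truth$diameter_px,
                          size_class = object$truth$size_class)
  plot_detections(object$frame, bulbs, classes)
}

#' @export
plot.sv_scene <- function(x, ...) print(autoplot.sv_scene(x, ...))

#' ECDF comparison plot for a size evaluation
#'
#' Predicted vs true diameter ECDFs, faceted by true size class — the
#' curves whose maximum gap is the per-class KS statistic.
#'
#' @param object A `sv_size_eval` from [size_eval()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sv_size_eval <- function(object, ...) {
  d <- object$data
  long <- dplyr::bind_rows(
    tibble::tibble(diameter = d$diameter_pred, which = "predicted",
                   class_true = d$class_true),
    tibble::tibble(diameter = d$diameter_true, which = "true",
                   class_true = d$class_true))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$diameter,
                                     color = .data$which)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$class_true)) +
    ggplot2::labs(x = "diameter (mm)", y = "ECDF", color = NULL) +
    ggplot2::theme_minimal()
}

#' Yield-map plot
#'
#' Tagged frames as points along the track, sized by total bulb count and
#' colored by mean diameter.
#'
#' @param results Tibble from [summarize_frames()] + [tag_frames()].
#' @return A ggplot object.
#' @export
plot_yield_map <- function(results) {
  r <- tibble::as_tibble(results)
  r <- r[!is.na(r$lat) & !is.na(r$lon), , drop = FALSE]
  r$total <- r$n_small + r$n_medium + r$n_large
  ggplot2::ggplot(r, ggplot2::aes(x = .data$lon, y = .data$lat,
                                  size = .data$total,
                                  color = .data$mean_diameter_mm)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_viridis_c(name = "mean diameter (mm)") +
    ggplot2::labs(x = "longitude", y = "latitude", size = "bulbs / frame") +
    ggplot2::theme_minimal()
}

#' Write an annotated overlay PNG
#'
#' Draws class-colored circle boundaries (blue = small, green = medium,
#' red = large) onto the frame and writes it as PNG.
#'
#' @param frame A `sv_frame`.
#' @param bulbs Tibble from [detect_bulbs()].
#' @param path Output PNG path.
#' @param classes A [size_class_spec()].
#' @return `path`, invisibly.
#' @export
write_overlay <- function(frame, bulbs, path, classes = size_class_spec()) {
  stopifnot(inherits(frame, "sv_frame"))
  px <- frame$pixels / 255
  H <- dim(px)[1]; W <- dim(px)[2]
  pal <- stats::setNames(classes$colors, classes$names)
  for (i in seq_len(nrow(bulbs))) {
    col <- pal[as.character(bulbs$size_class[i])]
    if (is.na(col)) col <- "grey70"
    rgbv <- grDevices::col2rgb(col)[, 1] / 255
    r <- bulbs$diameter_px[i] / 2
    th <- seq(0, 2 * pi, length.out = max(32, ceiling(4 * pi * r)))
    for (w in c(-0.5, 0, 0.5)) {
      rr <- round(bulbs$centroid_row[i] + (r + w) * cos(th))
      cc <- round(bulbs$centroid_col[i] + (r + w) * sin(th))
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      lin <- rr[ok] + (cc[ok] - 1) * H
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[lin] <- rgbv[ch]
        px[, , ch] <- plane
      }
    }
  }
  png::writePNG(px, path)
  invisible(path)
}
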