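# Plotting helpers. The evaluation report has an autoplot() method (PR
# curve, see evaluation.R); here annotated scenes get one too.

#' Plot an annotated image
#'
#' Draws the oriented boxes as polygons in image coordinates (y axis
#' reversed so the origin sits at the top-left, as in the pixel frame); when
#' pixels are present they are shown underneath.
#'
#' @param object An [annotated_image()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.annotated_image <- function(object, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(object$pixels)) {
    rast <- grDevices::rgb(
      object$pixels[, , 1] / 255,
      object$pixels[, , 2] / 255,
      object$pixels[, , 3] / 255
    )
    dim(rast) <- dim(object$pixels)[1:2]
    p <- p + ggplot2::annotation_raster(
      rast,
      xmin = 0, xmax = object$width,
      ymin = -object$height, ymax = 0
    )
  }
  if (nrow(object$boxes) > 0) {
    corners <- box_corners(object$boxes)
    p <- p + ggplot2::geom_polygon(
      data = corners,
      ggplot2::aes(x = .data$x, y = -.data$y, group = .data$box),
      fill = NA, colour = "red", linewidth = 0.4
    )
  }
  p +
    ggplot2::coord_fixed(
      xlim = c(0, object$width),
      ylim = c(-object$height, 0), expand = FALSE
    ) +
    ggplot2::scale_y_continuous(labels = function(v) -v) +
    ggplot2::labs(
      x = "x (px)", y = "y (px)",
      title = object$image_id
    ) +
    ggplot2::theme_minimal()
}
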