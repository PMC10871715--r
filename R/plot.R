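#' Plot the attainable-redaction region and its key vectors
#'
#' Draws the region boundary `g = 0` in redaction space, shades the
#' attainable region, and overlays the FOCK vector and the two axis
#' intercepts.
#'
#' @param object A [roar()] fit with `significant = TRUE`.
#' @param n Boundary resolution handed to [roar_boundary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' \donttest{
#' ggplot2::autoplot(roar(70, 30, 50, 50))
#' }
#' @export
autoplot.roar_fit <- function(object, n = 512L, ...) {
  if (!object$significant) {
    stop("nothing to plot: the reported table is not significant",
         call. = FALSE)
  }
  boundary <- roar_boundary(object$surface, n = n)
  vectors <- tibble::tibble(
    xend = c(object$xe, object$xc, 0),
    yend = c(object$ye, 0, object$yc),
    label = c("FOCK", "xc", "yc")
  )
  ggplot2::ggplot(boundary, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(fill = "grey80", alpha = 0.6) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::geom_segment(
      data = vectors,
      ggplot2::aes(x = 0, y = 0, xend = .data$xend, yend = .data$yend,
                   colour = .data$label),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.02, "npc")),
      inherit.aes = FALSE
    ) +
    ggplot2::labs(
      x = "experimental-arm redaction x",
      y = "control-arm redaction y",
      colour = NULL,
      title = "Region of attainable redaction",
      subtitle = sprintf(
        "a=%d b=%d c=%d d=%d, alpha=%s: redactions inside the region nullify significance",
        object$table$a, object$table$b, object$table$c, object$table$d,
        format(object$alpha))
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.roar_fit
#' @param fit A [roar()] fit.
#' @export
plot_roar <- function(fit, n = 512L) {
  autoplot.roar_fit(fit, n = n)
}
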