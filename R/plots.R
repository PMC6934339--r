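#' Plot total surface area against taper
#'
#' @param object A `prep_area_tbl` from [surface_area()].
#' @param ... Unused.
#' @return A ggplot: total area versus nominal taper, one line per wall
#'   height.
#' @method autoplot prep_area_tbl
#' @export
autoplot.prep_area_tbl <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$taper, y = .data$total_area,
      colour = factor(.data$height), group = factor(.data$height)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "axial wall taper (degrees)",
      y = expression("total prepared surface area" ~ (mm^2)),
      colour = "wall height (mm)"
    )
}

#' Plot groove net surface gain against taper
#'
#' @param object A `groove_gain_tbl` from [groove_augmentation()].
#' @param ... Unused.
#' @return A ggplot: net gain versus nominal taper, one line per wall height.
#' @method autoplot groove_gain_tbl
#' @export
autoplot.groove_gain_tbl <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$taper, y = .data$net_gain,
      colour = factor(.data$height), group = factor(.data$height)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "axial wall taper (degrees)",
      y = expression("net surface gain from two grooves" ~ (mm^2)),
      colour = "wall height (mm)"
    )
}

#' Plot model-versus-reference deviations
#'
#' @param object A `replication_tbl` from [replicate_study()].
#' @param ... Unused.
#' @return A ggplot of absolute deviations per quantity, facetted by table.
#' @method autoplot replication_tbl
#' @export
autoplot.replication_tbl <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = factor(.data$height), y = .data$abs_deviation,
      colour = .data$quantity
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~table_id, scales = "free_y") +
    ggplot2::labs(
      x = "wall height (mm)", y = "absolute deviation from reference",
      colour = "quantity"
    )
}

#' Diagram of the rotation arc against the resisting wall
#'
#' Draws the buccolingual section used by the resistance analysis: the
#' tapered resisting wall, the arc traced about the lingual margin axis by
#' the restoration point at the wall base, and the arc's re-entry height
#' `base_length * sin(2 * taper)`.
#'
#' @inheritParams resists
#' @return A ggplot.
#' @examples
#' plot_rotation_arc(12, height = 3, base_length = 8)
#' @export
plot_rotation_arc <- function(taper, height, base_length) {
  stopifnot(length(taper) == 1, length(height) == 1, length(base_length) == 1)
  ystar <- critical_contact_height(taper, base_length)
  phi <- seq(0, asin(pmin(1, min(height * 1.2, base_length) / base_length)),
    length.out = 200
  )
  arc <- tibble::tibble(
    x = base_length * cos(phi),
    y = base_length * sin(phi)
  )
  wall <- tibble::tibble(
    x = c(base_length, base_length - height * tan(deg2rad(taper))),
    y = c(0, height)
  )
  ggplot2::ggplot() +
    ggplot2::geom_path(data = arc, ggplot2::aes(.data$x, .data$y), linetype = 2) +
    ggplot2::geom_line(data = wall, ggplot2::aes(.data$x, .data$y), linewidth = 1) +
    ggplot2::annotate("point", x = 0, y = 0, shape = 4, size = 3) +
    ggplot2::annotate("point",
      x = sqrt(pmax(base_length^2 - ystar^2, 0)), y = ystar, colour = "red"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "buccolingual position (mm, axis at 0)",
      y = "height above margin (mm)",
      title = sprintf(
        "taper %.1f deg, height %g mm, base %g mm: %s",
        taper, height, base_length,
        if (resists(taper, height, base_length)) "resists" else "rotates free"
      )
    )
}
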