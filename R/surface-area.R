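#' Exact surface area of a tapered preparation
#'
#' Computes the prepared surface of the frustum exactly: each axial wall is a
#' planar trapezoid whose parallel edges are the base and top edges of that
#' wall and whose in-plane depth is the slant height `height / cos(taper)`;
#' the occlusal table is the top rectangle. At zero taper this reduces to the
#' rectangular block value `2*W*H + 2*L*H + W*L`.
#'
#' The mesial and distal walls have base edge `bl_length` and top edge
#' `top_bl`; the buccal and lingual walls have base edge `md_width` and top
#' edge `top_md`.
#'
#' @inheritParams set_wall_tapers
#' @return `data` with columns `top_md`, `top_bl`, the per-wall areas
#'   `wall_m`, `wall_d`, `wall_b`, `wall_li`, `occlusal_area` and
#'   `total_area` (all in mm^2) appended. The result carries class
#'   `prep_area_tbl` so that [autoplot()] produces an area-versus-taper plot.
#' @examples
#' prep_grid(height = c(3, 4, 5), taper = 0) |> surface_area()
#' @seealso [mesh_surface_area()] for the triangulation oracle.
#' @export
surface_area <- function(data) {
  out <- top_dimensions(data)
  slant <- function(taper) out$height / cos(deg2rad(taper))
  out <- dplyr::mutate(
    out,
    wall_m = 0.5 * (.data$bl_length + .data$top_bl) * slant(.data$taper_m),
    wall_d = 0.5 * (.data$bl_length + .data$top_bl) * slant(.data$taper_d),
    wall_b = 0.5 * (.data$md_width + .data$top_md) * slant(.data$taper_b),
    wall_li = 0.5 * (.data$md_width + .data$top_md) * slant(.data$taper_li),
    occlusal_area = .data$top_md * .data$top_bl,
    total_area = .data$wall_m + .data$wall_d + .data$wall_b + .data$wall_li +
      .data$occlusal_area
  )
  class(out) <- c("prep_area_tbl", class(out))
  out
}
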