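#' Local radius of a tapered fissure bur
#'
#' Radius of the bur cross-section at a given height above its tip:
#' `tip_radius + height * tan(half_angle)`.
#'
#' @param bur A [fissure_bur()] specification.
#' @param height Height(s) above the bur tip, mm; must be non-negative.
#' @return Numeric vector of radii, mm.
#' @examples
#' groove_profile_radius(fissure_bur(), c(0, 3, 5))
#' @export
groove_profile_radius <- function(bur, height) {
  check_bur(bur)
  if (any(!is.finite(height)) || any(height < 0)) {
    abort("`height` must be non-negative (mm above the bur tip)")
  }
  bur$tip_radius + height * tan(deg2rad(bur$half_angle))
}

#' Distance from the rotation axis to a groove's resisting wall
#'
#' A groove cut at the buccolingual midpoint of a proximal wall places the
#' bur axis `bl_length / 2` from the lingual margin; the groove's lingual
#' wall - the new resisting wall - sits one tip radius closer to the axis:
#' `bl_length / 2 - tip_radius`.
#'
#' @param bl_length Buccolingual base length, mm.
#' @inheritParams groove_profile_radius
#' @return Distance in mm from the lingual rotation axis to the groove's
#'   resisting wall.
#' @examples
#' groove_resisting_wall_distance(8, fissure_bur()) # 3.41 mm
#' @export
groove_resisting_wall_distance <- function(bl_length, bur) {
  check_bur(bur)
  if (any(!is.finite(bl_length)) || any(bl_length <= 0)) {
    abort("`bl_length` must be positive (mm)")
  }
  if (any(bur$tip_radius >= bl_length / 2)) {
    abort("bur tip radius must be smaller than half the buccolingual base")
  }
  bl_length / 2 - bur$tip_radius
}

# One groove on a wall of taper `taper_wall` (degrees), wall height H.
# The bur axis is vertical (along the path of insertion), its tip level with
# the cervical margin, positioned so the bur is embedded to exactly one
# radius at the occlusal edge of the wall.  Going down, the inclined wall
# surface advances towards the bur axis, which therefore lies
# e(h) = (H - h) * tan(taper_wall) inside the tooth at height h: the channel
# deepens towards the margin, and for strongly tapered tall walls the bur is
# fully buried (e >= r) near the base.
#
# Per groove:
#   groove surface  = int_0^H 2*a0(h) * r(h) / cos(phi) dh,
#                     a0 = acos(clamp(-e/r)) in [pi/2, pi]
#   wall strip lost = int_0^H 2*sqrt(max(r^2 - e^2, 0)) / cos(taper) dh
#   occlusal lost   = pi * r(H)^2 / 2   (half-disc; e(H) = 0)
groove_one <- function(height, taper_wall, bur) {
  phi <- deg2rad(bur$half_angle)
  thw <- deg2rad(taper_wall)
  r <- function(h) bur$tip_radius + h * tan(phi)
  e <- function(h) (height - h) * tan(thw)
  arc_integrand <- function(h) {
    2 * acos(pmin(pmax(-e(h) / r(h), -1), 1)) * r(h) / cos(phi)
  }
  strip_integrand <- function(h) {
    2 * sqrt(pmax(r(h)^2 - e(h)^2, 0)) / cos(thw)
  }
  groove <- integrate(arc_integrand, 0, height,
    rel.tol = 1e-10, subdivisions = 400L
  )$value
  strip <- integrate(strip_integrand, 0, height,
    rel.tol = 1e-10, subdivisions = 400L
  )$value
  occ <- pi * r(height)^2 / 2
  c(removed = strip + occ, groove = groove)
}

#' Surface-area augmentation from supplemental axial grooves
#'
#' Models one or two vertical grooves cut with a tapered fissure bur into the
#' mesial (and, for two grooves, distal) axial wall at the buccolingual
#' midpoint. The bur axis follows the path of insertion with its tip at the
#' cervical margin, seated so that the bur is embedded to one full radius at
#' the occlusal edge of the wall; because the wall leans towards the bur, the
#' channel deepens towards the margin, and on tall, strongly tapered walls
#' the bur is fully buried near the base. The groove contributes new conical
#' channel surface while consuming a strip of the axial wall and a half-disc
#' of the occlusal table.
#'
#' @inheritParams set_wall_tapers
#' @param bur A [fissure_bur()] specification.
#' @param n_grooves 1 (mesial wall only) or 2 (mesial and distal).
#' @return `data` with columns `removed_area` (wall + occlusal surface lost,
#'   mm^2, reported positive), `groove_area` (new groove surface, mm^2) and
#'   `net_gain = groove_area - removed_area` appended; class
#'   `groove_gain_tbl` for [autoplot()].
#' @examples
#' premolar_grid() |> groove_augmentation()
#' @export
groove_augmentation <- function(data, bur = fissure_bur(), n_grooves = 2) {
  check_bur(bur)
  if (!n_grooves %in% c(1, 2)) {
    abort("`n_grooves` must be 1 or 2")
  }
  dims <- top_dimensions(data)
  r_top <- groove_profile_radius(bur, dims$height)
  if (any(2 * r_top > dims$top_bl)) {
    abort(paste0(
      "groove too wide: bur diameter at the occlusal (2 * ",
      sprintf("%.3f", max(r_top)), " mm) exceeds the wall's top width"
    ))
  }
  walls <- if (n_grooves == 2) c("taper_m", "taper_d") else "taper_m"
  per_row <- purrr::pmap(
    list(dims$height, dims$taper_m, dims$taper_d),
    function(h, tm, td) {
      tapers <- c(taper_m = tm, taper_d = td)[walls]
      comp <- vapply(tapers, function(tw) groove_one(h, tw, bur), numeric(2))
      c(removed = sum(comp["removed", ]), groove = sum(comp["groove", ]))
    }
  )
  out <- dplyr::mutate(
    data,
    removed_area = purrr::map_dbl(per_row, "removed"),
    groove_area = purrr::map_dbl(per_row, "groove"),
    net_gain = .data$groove_area - .data$removed_area
  )
  class(out) <- c("groove_gain_tbl", class(out))
  out
}
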