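#' Maximal opposing-wall taper that resists rotation
#'
#' When a cemented restoration rotates about an axis along the lingual
#' cervical margin, the point seated at the base of the opposing (buccal)
#' wall, a distance `base_length` from the axis, traces a circular arc. The
#' arc re-enters the plane of a wall tapered at angle `theta` at height
#' `base_length * sin(2 * theta)`; the wall blocks rotation only if it is
#' tall enough to intercept the arc. Solving for the limiting taper gives the
#' half-arcsine rule `theta_max = asin(height / base_length) / 2`. For
#' `height >= base_length` the arc re-entry height never exceeds
#' `base_length <= height`, so every taper below 45 degrees resists and the
#' limit is reported as 45 degrees with `capped = TRUE`.
#'
#' @param height Resisting-wall height(s), mm (>= 0).
#' @param base_length Distance(s) from the rotation axis to the base of the
#'   resisting wall, mm (> 0).
#' @return A tibble with one row per input: `height`, `base_length`,
#'   `theta_max` (degrees), `capped`, and `critical_contact_height` (mm, the
#'   arc re-entry height at `theta_max`; equals `height` when uncapped).
#' @examples
#' max_resistance_angle(c(3, 4, 5), 8) # 11.0, 15.0, 19.3 degrees
#' @export
max_resistance_angle <- function(height, base_length) {
  n <- max(length(height), length(base_length))
  height <- rep_len(height, n)
  base_length <- rep_len(base_length, n)
  if (any(!is.finite(height)) || any(height < 0)) {
    abort("`height` must be non-negative (mm)")
  }
  if (any(!is.finite(base_length)) || any(base_length <= 0)) {
    abort("`base_length` must be positive (mm)")
  }
  capped <- height >= base_length
  ratio <- pmin(height / base_length, 1)
  theta <- rad2deg(asin(ratio)) / 2
  tibble::tibble(
    height = height,
    base_length = base_length,
    theta_max = theta,
    capped = capped,
    critical_contact_height = base_length * sin(2 * deg2rad(theta))
  )
}

#' Arc re-entry height for a given wall taper
#'
#' Height above the margin at which the rotation arc through the resisting
#' wall's base re-crosses the tapered wall plane: `base_length * sin(2 *
#' taper)`. A wall shorter than this lets the restoration rotate free.
#'
#' @param taper Wall taper(s) in degrees, `[0, 45)`.
#' @param base_length Distance(s) from the rotation axis to the wall base, mm.
#' @return Numeric vector of heights, mm.
#' @examples
#' critical_contact_height(15, 8) # 4 mm
#' @export
critical_contact_height <- function(taper, base_length) {
  if (any(!is.finite(taper)) || any(taper < 0) || any(taper >= 45)) {
    abort("`taper` must lie in [0, 45) degrees")
  }
  if (any(!is.finite(base_length)) || any(base_length <= 0)) {
    abort("`base_length` must be positive (mm)")
  }
  base_length * sin(2 * deg2rad(taper))
}

#' Does a wall resist rotation?
#'
#' `TRUE` when the resisting wall intercepts the rotation arc, i.e. when
#' [critical_contact_height()] is strictly below the wall height —
#' equivalently when `taper` is below the half-arcsine limit of
#' [max_resistance_angle()].
#'
#' @inheritParams critical_contact_height
#' @param height Resisting-wall height(s), mm.
#' @return Logical vector.
#' @examples
#' resists(12, height = 3, base_length = 8) # FALSE: exceeds the 11.0 limit
#' resists(19, height = 5, base_length = 8) # TRUE: below 19.3
#' @export
resists <- function(taper, height, base_length) {
  if (any(!is.finite(height)) || any(height < 0)) {
    abort("`height` must be non-negative (mm)")
  }
  critical_contact_height(taper, base_length) < height
}

#' Resistance limit of each preparation in a grid
#'
#' Applies the half-arcsine rule to each row, taking the buccal wall
#' (`taper_b`) as the wall opposing the lingual rotation axis and
#' `bl_length` as the base length.
#'
#' @inheritParams set_wall_tapers
#' @return `data` with `theta_max` (degrees), `capped`,
#'   `critical_contact_height` (mm, at the actual buccal taper) and
#'   `resists` appended.
#' @examples
#' premolar_grid() |> resistance_limit()
#' @export
resistance_limit <- function(data) {
  validate_prep_tbl(data)
  lim <- max_resistance_angle(data$height, data$bl_length)
  dplyr::mutate(
    data,
    theta_max = lim$theta_max,
    capped = lim$capped,
    critical_contact_height =
      critical_contact_height(.data$taper_b, .data$bl_length),
    resists = resists(.data$taper_b, .data$height, .data$bl_length)
  )
}

#' Rotational resistance provided by supplemental grooves
#'
#' A groove cut at the buccolingual midpoint of a proximal wall supplies a
#' new resisting wall whose taper equals the bur's side half-angle and whose
#' base sits [groove_resisting_wall_distance()] from the lingual axis. The
#' half-arcsine rule is re-applied at that shorter base length; with the
#' default 172-style bur on an 8 mm base the groove wall stands 3.41 mm from
#' the axis, and wall heights of 4 mm or more exceed the base so the limit
#' saturates (`capped = TRUE`).
#'
#' @inheritParams set_wall_tapers
#' @param bur A [fissure_bur()].
#' @param groove_wall_taper Taper of the groove's resisting wall, degrees;
#'   defaults to the bur's side half-angle.
#' @return `data` with `groove_base_length` (mm), `groove_theta_max`
#'   (degrees), `groove_capped`, `groove_wall_taper` and `groove_resists`
#'   appended.
#' @examples
#' premolar_grid() |> groove_resistance()
#' @export
groove_resistance <- function(data, bur = fissure_bur(), groove_wall_taper = NULL) {
  validate_prep_tbl(data)
  check_bur(bur)
  groove_wall_taper <- groove_wall_taper %||% bur$half_angle
  base_used <- groove_resisting_wall_distance(data$bl_length, bur)
  lim <- max_resistance_angle(data$height, base_used)
  dplyr::mutate(
    data,
    groove_base_length = base_used,
    groove_theta_max = lim$theta_max,
    groove_capped = lim$capped,
    groove_wall_taper = groove_wall_taper,
    groove_resists = lim$capped |
      resists(groove_wall_taper, .data$height, .data$groove_base_length)
  )
}
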