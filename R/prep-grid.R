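#' Build a grid of simulated crown preparations
#'
#' A preparation is modelled as a rectangular-based frustum: a block of
#' mesiodistal width `md_width` and buccolingual length `bl_length` whose four
#' axial walls (mesial, distal, buccal, lingual) are inclined towards the
#' centre by a per-wall taper angle, leaving a flat occlusal table on top.
#' `prep_grid()` crosses the supplied heights and (uniform) tapers into one
#' row per preparation; [set_wall_tapers()] overrides individual walls.
#'
#' @param height Wall height(s) in mm, measured from the cervical margin to
#'   the occlusal table.
#' @param taper Uniform axial-wall taper angle(s) in degrees, measured from
#'   the long axis (path of insertion). Each value is broadcast to all four
#'   walls. Must lie in `[0, 45)`.
#' @param md_width Mesiodistal base width in mm (default 5, a premolar-sized
#'   form).
#' @param bl_length Buccolingual base length in mm (default 8).
#'
#' @return A tibble with one row per preparation and columns `md_width`,
#'   `bl_length`, `height`, `taper` (the nominal uniform taper, `NA` when
#'   walls differ) and the per-wall angles `taper_m`, `taper_d`, `taper_b`,
#'   `taper_li` (degrees).
#'
#' @examples
#' prep_grid(height = c(3, 4, 5), taper = c(2, 6, 12, 18))
#' @seealso [top_dimensions()], [surface_area()], [premolar_grid()]
#' @export
prep_grid <- function(height, taper, md_width = 5, bl_length = 8) {
  grid <- tidyr::crossing(
    md_width = md_width, bl_length = bl_length,
    height = height, taper = taper
  ) |>
    dplyr::arrange(.data$md_width, .data$bl_length, .data$height, .data$taper) |>
    dplyr::mutate(
      taper_m = .data$taper, taper_d = .data$taper,
      taper_b = .data$taper, taper_li = .data$taper
    )
  validate_prep_tbl(grid)
  grid
}

#' Override per-wall taper angles
#'
#' @param data A preparation tibble from [prep_grid()].
#' @param m,d,b,li Replacement taper angles in degrees for the mesial,
#'   distal, buccal and lingual walls; `NULL` leaves a wall unchanged.
#'   Recycled against the rows of `data`.
#' @return `data` with the requested `taper_*` columns replaced; the nominal
#'   `taper` column becomes `NA` on rows where the four walls now differ.
#' @examples
#' prep_grid(3, 12) |> set_wall_tapers(b = 3)
#' @export
set_wall_tapers <- function(data, m = NULL, d = NULL, b = NULL, li = NULL) {
  if (!is.null(m)) data$taper_m <- m
  if (!is.null(d)) data$taper_d <- d
  if (!is.null(b)) data$taper_b <- b
  if (!is.null(li)) data$taper_li <- li
  uniform <- data$taper_m == data$taper_d &
    data$taper_m == data$taper_b & data$taper_m == data$taper_li
  data$taper <- ifelse(uniform, data$taper_m, NA_real_)
  validate_prep_tbl(data)
  data
}

prep_cols <- c(
  "md_width", "bl_length", "height",
  "taper_m", "taper_d", "taper_b", "taper_li"
)

validate_prep_tbl <- function(data, call = rlang::caller_env()) {
  missing <- setdiff(prep_cols, names(data))
  if (length(missing) > 0) {
    abort(
      paste0(
        "`data` is not a preparation grid; missing column(s): ",
        paste(missing, collapse = ", ")
      ),
      call = call
    )
  }
  dims <- c(data$md_width, data$bl_length, data$height)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    abort("all preparation dimensions must be finite and > 0 mm", call = call)
  }
  tapers <- c(data$taper_m, data$taper_d, data$taper_b, data$taper_li)
  if (any(!is.finite(tapers)) || any(tapers < 0) || any(tapers >= 45)) {
    abort("wall tapers must lie in [0, 45) degrees", call = call)
  }
  invisible(data)
}

#' Occlusal-table dimensions of a tapered preparation
#'
#' Each inclined wall displaces its top edge inwards by
#' `height * tan(taper)`, so the occlusal table measures
#' `md_width - height * (tan(taper_m) + tan(taper_d))` mesiodistally and the
#' analogous reduction buccolingually. A preparation whose walls meet below
#' the nominal height (either top dimension non-positive) is geometrically
#' impossible and rejected.
#'
#' @inheritParams set_wall_tapers
#' @return `data` with columns `top_md` and `top_bl` (mm) appended.
#' @examples
#' prep_grid(3, c(0, 18)) |> top_dimensions()
#' @export
top_dimensions <- function(data) {
  validate_prep_tbl(data)
  out <- dplyr::mutate(
    data,
    top_md = .data$md_width -
      .data$height * (tan(deg2rad(.data$taper_m)) + tan(deg2rad(.data$taper_d))),
    top_bl = .data$bl_length -
      .data$height * (tan(deg2rad(.data$taper_b)) + tan(deg2rad(.data$taper_li)))
  )
  bad <- out$top_md <= 0 | out$top_bl <= 0
  if (any(bad)) {
    abort(paste0(
      "over-truncation: walls meet below the occlusal table in row(s) ",
      paste(head(which(bad), 5), collapse = ", "),
      "; reduce taper or height"
    ))
  }
  out
}

#' Tapered fissure bur geometry
#'
#' Idealises a tapered fissure bur as a cone frustum: a tip circle of radius
#' `tip_radius` widening by `tan(half_angle)` per mm of length. The default is
#' the 172-style bur (0.59 mm tip radius, 3 degree side half-angle, i.e. 6
#' degrees of total taper) used to cut supplemental axial grooves.
#'
#' @param tip_radius Radius of the small tip circle, mm.
#' @param half_angle Side half-angle in degrees (half the total included
#'   taper). Must lie in `[0, 20)`.
#' @param label Free-text identifier.
#' @return An object of class `bur_spec`.
#' @examples
#' fissure_bur()
#' groove_profile_radius(fissure_bur(), height = 3)
#' @export
fissure_bur <- function(tip_radius = 0.59, half_angle = 3, label = "172 tapered fissure") {
  if (!is.numeric(tip_radius) || length(tip_radius) != 1 || !is.finite(tip_radius) ||
      tip_radius <= 0) {
    abort("`tip_radius` must be a single positive length in mm")
  }
  if (!is.numeric(half_angle) || length(half_angle) != 1 || !is.finite(half_angle) ||
      half_angle < 0 || half_angle >= 20) {
    abort("`half_angle` must be a single angle in [0, 20) degrees")
  }
  structure(
    list(tip_radius = tip_radius, half_angle = half_angle, label = label),
    class = "bur_spec"
  )
}

#' @export
print.bur_spec <- function(x, ...) {
  cat(sprintf(
    "<bur_spec> %s: tip radius %.2f mm, side half-angle %.1f deg\n",
    x$label, x$tip_radius, x$half_angle
  ))
  invisible(x)
}

check_bur <- function(bur, call = rlang::caller_env()) {
  if (!inherits(bur, "bur_spec")) {
    abort("`bur` must be a `bur_spec` created by `fissure_bur()`", call = call)
  }
  invisible(bur)
}
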