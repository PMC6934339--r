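#' Configuration for the arc-sweep interference oracle
#'
#' @param angular_step Sweep resolution in degrees of rotation (default
#'   0.001). Sets the accuracy near the resistance boundary: tapers within
#'   roughly half a step of the analytic limit may be classified either way.
#' @param max_rotation Largest rotation examined, degrees. The sweep is also
#'   capped at the angle where the arc passes the wall top, so the default of
#'   90 covers every geometry.
#' @param penetration_tol Minimum penetration depth (mm) counted as
#'   interference; guards against floating-point grazing contacts.
#' @param mesh_refinement Default subdivision count for
#'   [mesh_surface_area()].
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(angular_step = 0.001, max_rotation = 90,
                         penetration_tol = 1e-6, mesh_refinement = 64) {
  vals <- c(angular_step, max_rotation, penetration_tol, mesh_refinement)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all sweep-config values must be positive and finite")
  }
  if (angular_step >= max_rotation) {
    abort("`angular_step` must be smaller than `max_rotation`")
  }
  structure(
    list(
      angular_step = angular_step, max_rotation = max_rotation,
      penetration_tol = penetration_tol,
      mesh_refinement = as.integer(mesh_refinement)
    ),
    class = "sweep_config"
  )
}

#' Arc-sweep rotational-resistance oracle
#'
#' Brute-force check of the half-arcsine rule in the buccolingual plane. The
#' rotation axis sits at the origin (lingual cervical margin); the resisting
#' wall runs from `(base_length, 0)` up to
#' `(base_length - height * tan(taper), height)`; the restoration point
#' seated at the wall base traces the arc
#' `(base_length * cos(phi), base_length * sin(phi))`. The wall resists if,
#' for some sampled rotation `phi` with arc height still within the wall,
#' the arc point lies strictly inside the wall plane (by more than
#' `penetration_tol`).
#'
#' @inheritParams resists
#' @param cfg A [sweep_config()].
#' @return A one-row tibble: `resists` (logical) and `contact_height` (mm,
#'   the arc height at first interference, `NA` if none).
#' @examples
#' sweep_resists(12, height = 3, base_length = 8)
#' @export
sweep_resists <- function(taper, height, base_length, cfg = sweep_config()) {
  stopifnot(inherits(cfg, "sweep_config"))
  if (length(taper) != 1 || length(height) != 1 || length(base_length) != 1) {
    abort("`sweep_resists()` checks one geometry at a time")
  }
  if (!is.finite(taper) || taper < 0 || taper >= 45) {
    abort("`taper` must lie in [0, 45) degrees")
  }
  if (height < 0 || base_length <= 0) {
    abort("invalid geometry: need height >= 0 and base_length > 0")
  }
  # arc height exceeds the wall top beyond asin(H/B); nothing to hit there
  phi_top <- rad2deg(asin(pmin(height / base_length, 1)))
  phi_max <- min(cfg$max_rotation, phi_top)
  if (phi_max <= cfg$angular_step) {
    return(tibble::tibble(resists = FALSE, contact_height = NA_real_))
  }
  phi <- deg2rad(seq(cfg$angular_step, phi_max, by = cfg$angular_step))
  y <- base_length * sin(phi)
  x_arc <- base_length * cos(phi)
  x_wall <- base_length - y * tan(deg2rad(taper))
  hit <- which(x_arc < x_wall - cfg$penetration_tol & y <= height)
  if (length(hit) == 0) {
    tibble::tibble(resists = FALSE, contact_height = NA_real_)
  } else {
    tibble::tibble(resists = TRUE, contact_height = y[hit[1]])
  }
}

# --- surface triangulation oracle ------------------------------------------

# Sum of triangle areas for a parametric patch f(u, v) -> 3-vector,
# triangulated on an n x n grid over [0,1]^2.
patch_area <- function(f, n) {
  u <- seq(0, 1, length.out = n + 1)
  g <- expand.grid(u = u, v = u)
  p <- f(g$u, g$v) # (n+1)^2 x 3 matrix
  if (any(!is.finite(p))) abort("degenerate mesh: non-finite vertex")
  idx <- function(i, j) (j - 1) * (n + 1) + i
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
  tri_area <- function(v1, v2, v3) {
    e1 <- p[v2, , drop = FALSE] - p[v1, , drop = FALSE]
    e2 <- p[v3, , drop = FALSE] - p[v1, , drop = FALSE]
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  sum(tri_area(a, b, c)) + sum(tri_area(a, c, d))
}

#' Triangulation oracle for (grooved) preparation surface area
#'
#' Independently recomputes the prepared surface by building the walls,
#' occlusal table and (optionally) groove channels as parametric patches in
#' 3-D coordinates, triangulating each on a `refinement` x `refinement`
#' grid, and summing raw triangle areas. Planar faces are exact at any
#' refinement; curved groove surfaces converge quadratically. Used as the
#' numeric cross-check for [surface_area()] and [groove_augmentation()].
#'
#' @param md_width,bl_length,height Preparation dimensions, mm.
#' @param taper Wall taper(s), degrees: one uniform value or four values in
#'   mesial, distal, buccal, lingual order.
#' @param bur Optional [fissure_bur()]; when given, grooves are carved into
#'   the proximal wall(s) and the returned area is that of the grooved
#'   surface.
#' @param n_grooves 1 or 2 (ignored without `bur`).
#' @param refinement Grid subdivisions per patch.
#' @return Total prepared surface area, mm^2.
#' @examples
#' mesh_surface_area(5, 8, 3, 0) # 118 exactly
#' @export
mesh_surface_area <- function(md_width, bl_length, height, taper,
                              bur = NULL, n_grooves = 2, refinement = 64) {
  if (!length(taper) %in% c(1, 4)) {
    abort("`taper` must have length 1 (uniform) or 4 (M, D, B, Li)")
  }
  tp <- rep_len(taper, 4)
  grid1 <- tibble::tibble(
    md_width = md_width, bl_length = bl_length, height = height,
    taper = NA_real_,
    taper_m = tp[1], taper_d = tp[2], taper_b = tp[3], taper_li = tp[4]
  )
  top_dimensions(grid1) # errors on over-truncation
  W <- md_width; L <- bl_length; H <- height
  tm <- tan(deg2rad(tp[1])); td <- tan(deg2rad(tp[2]))
  tb <- tan(deg2rad(tp[3])); tli <- tan(deg2rad(tp[4]))
  n <- as.integer(refinement)

  y_lo <- function(z) z * tb
  y_hi <- function(z) L - z * tli
  x_lo <- function(z) z * tm
  x_hi <- function(z) W - z * td
  wall_m <- function(u, v) {
    z <- v * H
    cbind(x_lo(z), (1 - u) * y_lo(z) + u * y_hi(z), z)
  }
  wall_d <- function(u, v) {
    z <- v * H
    cbind(x_hi(z), (1 - u) * y_lo(z) + u * y_hi(z), z)
  }
  wall_b <- function(u, v) {
    z <- v * H
    cbind((1 - u) * x_lo(z) + u * x_hi(z), y_lo(z), z)
  }
  wall_li <- function(u, v) {
    z <- v * H
    cbind((1 - u) * x_lo(z) + u * x_hi(z), y_hi(z), z)
  }
  occlusal <- function(u, v) {
    cbind(
      x_lo(H) + u * (x_hi(H) - x_lo(H)),
      y_lo(H) + v * (y_hi(H) - y_lo(H)),
      rep(H, length(u))
    )
  }
  total <- patch_area(wall_m, n) + patch_area(wall_d, n) +
    patch_area(wall_b, n) + patch_area(wall_li, n) + patch_area(occlusal, n)

  if (!is.null(bur)) {
    check_bur(bur)
    if (!n_grooves %in% c(1, 2)) abort("`n_grooves` must be 1 or 2")
    r_top <- groove_profile_radius(bur, H)
    if (2 * r_top > L - H * (tb + tli)) {
      abort("groove too wide for the wall's top width")
    }
    rfun <- function(z) groove_profile_radius(bur, z)
    groove_patches <- function(wall_tan, axis_x, sgn) {
      e <- function(z) (H - z) * wall_tan
      a0 <- function(z) acos(pmin(pmax(-e(z) / rfun(z), -1), 1))
      channel <- function(u, v) {
        z <- v * H
        beta <- (2 * u - 1) * a0(z)
        cbind(
          axis_x + sgn * rfun(z) * cos(beta),
          L / 2 + rfun(z) * sin(beta),
          z
        )
      }
      strip <- function(u, v) {
        z <- v * H
        w <- 2 * sqrt(pmax(rfun(z)^2 - e(z)^2, 0))
        cbind(axis_x - sgn * e(z), L / 2 + (2 * u - 1) * w / 2, z)
      }
      halfdisc <- function(u, v) {
        beta <- (2 * u - 1) * pi / 2
        cbind(
          axis_x + sgn * v * rfun(H) * cos(beta),
          L / 2 + v * rfun(H) * sin(beta),
          rep(H, length(u))
        )
      }
      patch_area(channel, n) - patch_area(strip, n) - patch_area(halfdisc, n)
    }
    total <- total + groove_patches(tm, H * tm, +1)
    if (n_grooves == 2) total <- total + groove_patches(td, W - H * td, -1)
  }
  total
}
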