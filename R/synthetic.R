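#' The canonical premolar study grid
#'
#' The 12-cell parameter grid of the simulated maxillary premolar model:
#' a 5 mm mesiodistal by 8 mm buccolingual base, wall heights of 3, 4 and
#' 5 mm, and uniform four-wall tapers of 2, 6, 12 and 18 degrees. The
#' 172-style fissure bur used for supplemental grooves is attached as the
#' `"bur"` attribute.
#'
#' @return A 12-row preparation tibble (see [prep_grid()]) with attributes
#'   `provenance = "paper_grid"` and `bur` (a [fissure_bur()]).
#' @examples
#' premolar_grid()
#' @export
premolar_grid <- function() {
  grid <- prep_grid(height = c(3, 4, 5), taper = c(2, 6, 12, 18))
  attr(grid, "provenance") <- "paper_grid"
  attr(grid, "bur") <- fissure_bur()
  grid
}

#' Seeded random grids of valid preparations
#'
#' Draws preparation parameters uniformly within the given ranges and keeps
#' only geometrically possible preparations (rejection sampling on
#' over-truncation, rather than clamping, so accepted draws keep a simple
#' distribution). The four wall tapers are drawn independently. Reproducible
#' for a fixed seed; the caller's RNG state is left untouched.
#'
#' @param n Number of preparations to generate.
#' @param seed Integer seed.
#' @param ranges Named list of `c(min, max)` bounds for `height`, `md_width`,
#'   `bl_length` (mm) and `taper` (degrees). Defaults: height 1-8, width 3-8,
#'   length 5-12, taper 0-25.
#' @return An `n`-row preparation tibble with attributes
#'   `provenance = "random"` and `seed`.
#' @examples
#' random_prep_grid(5, seed = 1)
#' @export
random_prep_grid <- function(n, seed,
                             ranges = list(
                               height = c(1, 8), md_width = c(3, 8),
                               bl_length = c(5, 12), taper = c(0, 25)
                             )) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("`n` must be a positive count")
  defaults <- list(
    height = c(1, 8), md_width = c(3, 8),
    bl_length = c(5, 12), taper = c(0, 25)
  )
  ranges <- utils::modifyList(defaults, ranges)
  for (nm in names(defaults)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      abort(sprintf("`ranges$%s` must be a finite c(min, max)", nm))
    }
  }
  if (ranges$taper[1] < 0 || ranges$taper[2] >= 45) {
    abort("taper range must lie in [0, 45) degrees")
  }
  if (any(c(ranges$height[1], ranges$md_width[1], ranges$bl_length[1]) <= 0)) {
    abort("length ranges must be positive")
  }
  # feasibility: even the most favourable draw must avoid over-truncation
  best_inset <- 2 * ranges$height[1] * tan(deg2rad(ranges$taper[1]))
  if (ranges$md_width[2] - best_inset <= 0 || ranges$bl_length[2] - best_inset <= 0) {
    abort("impossible ranges: every draw in these bounds over-truncates")
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  draw <- function(m) {
    tibble::tibble(
      md_width = runif(m, ranges$md_width[1], ranges$md_width[2]),
      bl_length = runif(m, ranges$bl_length[1], ranges$bl_length[2]),
      height = runif(m, ranges$height[1], ranges$height[2]),
      taper_m = runif(m, ranges$taper[1], ranges$taper[2]),
      taper_d = runif(m, ranges$taper[1], ranges$taper[2]),
      taper_b = runif(m, ranges$taper[1], ranges$taper[2]),
      taper_li = runif(m, ranges$taper[1], ranges$taper[2])
    )
  }
  keep_valid <- function(d) {
    top_md <- d$md_width -
      d$height * (tan(deg2rad(d$taper_m)) + tan(deg2rad(d$taper_d)))
    top_bl <- d$bl_length -
      d$height * (tan(deg2rad(d$taper_b)) + tan(deg2rad(d$taper_li)))
    d[top_md > 0 & top_bl > 0, ]
  }

  acc <- keep_valid(draw(max(4L * n, 64L)))
  tries <- 0L
  while (nrow(acc) < n && tries < 200L) {
    acc <- dplyr::bind_rows(acc, keep_valid(draw(max(4L * n, 256L))))
    tries <- tries + 1L
  }
  if (nrow(acc) < n) {
    abort("rejection sampling failed: over-truncation dominates these ranges")
  }
  out <- acc[seq_len(n), ]
  uniform <- out$taper_m == out$taper_d &
    out$taper_m == out$taper_b & out$taper_m == out$taper_li
  out <- dplyr::mutate(out,
    taper = ifelse(uniform, .data$taper_m, NA_real_),
    .after = "height"
  )
  validate_prep_tbl(out)
  attr(out, "provenance") <- "random"
  attr(out, "seed") <- as.integer(seed)
  out
}
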