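#' Bundled published reference tables
#'
#' Reads the packaged reference fixture: every printed cell of the source
#' study's three result tables for the 5 x 8 mm premolar model — total
#' surface area per (height, taper) cell (`T1`), two-groove surface-area
#' loss / groove surface / net gain (`T2`), and per-height resistance limits
#' with base lengths and groove-wall values (`T3`).
#'
#' @return A tibble with columns `table_id`, `height`, `taper` (degrees,
#'   `NA` for per-height `T3` rows), `quantity` and `value`.
#' @examples
#' reference_tables()
#' @export
reference_tables <- function() {
  path <- system.file("extdata", "reference_tables.csv", package = "resistform")
  readr::read_csv(
    path,
    comment = "#", na = "NA",
    col_types = readr::cols(
      table_id = readr::col_character(),
      height = readr::col_double(),
      taper = readr::col_double(),
      quantity = readr::col_character(),
      value = readr::col_double()
    )
  )
}

# per-quantity comparison tolerances; areas are reported, never pass/failed,
# because the source's tapered-cell and groove formulas are not recoverable
# from the available text
replication_tolerances <- c(
  alpha3_limit = 0.05, groove_wall_taper = 0.05,
  base_length = 0.005, groove_base_length = 0.005,
  total_area = NA_real_, area_lost = NA_real_,
  groove_area = NA_real_, net_gain = NA_real_
)

#' Replicate the published tables from the model
#'
#' Runs the full analysis over the study grid and lines every model value up
#' against the corresponding printed reference cell: exact frustum areas
#' against `T1`, the groove-augmentation model against `T2`, and the
#' half-arcsine resistance limits, base lengths and groove-wall values
#' against `T3`. Formula-anchored quantities (angles and base lengths) carry
#' a pass/fail tolerance (0.05 degrees / 0.005 mm); area quantities carry
#' deviations only (`within_tol = NA`), since the source's tapered-cell and
#' groove derivations are not reproducible from its available text.
#'
#' @param grid A preparation grid, by default [premolar_grid()]. Must use a
#'   single base footprint.
#' @param bur The groove bur; defaults to the grid's `"bur"` attribute or a
#'   [fissure_bur()].
#' @return A tibble of class `replication_tbl` with columns `table_id`,
#'   `height`, `taper`, `quantity`, `model_value`, `paper_value`,
#'   `abs_deviation` and `within_tol`, ordered by table, height, taper,
#'   quantity.
#' @examples
#' rep <- replicate_study()
#' glance(rep)
#' @export
replicate_study <- function(grid = premolar_grid(),
                            bur = attr(grid, "bur") %||% fissure_bur()) {
  validate_prep_tbl(grid)
  check_bur(bur)
  base <- dplyr::distinct(grid, .data$md_width, .data$bl_length)
  if (nrow(base) != 1) {
    abort("`grid` must use a single base footprint to match the reference tables")
  }
  ref <- reference_tables()

  cells <- dplyr::distinct(ref[!is.na(ref$taper), ], .data$height, .data$taper)
  cell_grid <- prep_grid(
    height = unique(cells$height), taper = unique(cells$taper),
    md_width = base$md_width, bl_length = base$bl_length
  )
  areas <- surface_area(cell_grid)
  grooves <- groove_augmentation(cell_grid, bur = bur, n_grooves = 2)
  limits <- max_resistance_angle(sort(unique(ref$height)), base$bl_length)

  model_long <- dplyr::bind_rows(
    tibble::tibble(
      table_id = "T1", height = areas$height, taper = areas$taper,
      quantity = "total_area", model_value = areas$total_area
    ),
    tidyr::pivot_longer(
      dplyr::transmute(grooves,
        height = .data$height, taper = .data$taper,
        area_lost = -.data$removed_area,
        groove_area = .data$groove_area,
        net_gain = .data$net_gain
      ),
      cols = c("area_lost", "groove_area", "net_gain"),
      names_to = "quantity", values_to = "model_value"
    ) |>
      dplyr::mutate(table_id = "T2", .before = 1),
    tidyr::pivot_longer(
      tibble::tibble(
        height = limits$height,
        alpha3_limit = limits$theta_max,
        base_length = limits$base_length,
        groove_wall_taper = bur$half_angle,
        groove_base_length =
          groove_resisting_wall_distance(base$bl_length, bur)
      ),
      cols = -"height",
      names_to = "quantity", values_to = "model_value"
    ) |>
      dplyr::mutate(table_id = "T3", taper = NA_real_, .before = 1)
  )

  out <- ref |>
    dplyr::rename(paper_value = "value") |>
    dplyr::left_join(model_long,
      by = c("table_id", "height", "taper", "quantity")
    ) |>
    dplyr::mutate(
      abs_deviation = abs(.data$model_value - .data$paper_value),
      tolerance = unname(replication_tolerances[.data$quantity]),
      within_tol = .data$abs_deviation <= .data$tolerance
    ) |>
    dplyr::select(
      "table_id", "height", "taper", "quantity",
      "model_value", "paper_value", "abs_deviation", "tolerance", "within_tol"
    ) |>
    dplyr::arrange(.data$table_id, .data$height, .data$taper, .data$quantity)
  class(out) <- c("replication_tbl", class(out))
  out
}

# printed decimals per quantity, for report formatting
replication_digits <- c(
  total_area = 1, area_lost = 3, groove_area = 1, net_gain = 1,
  alpha3_limit = 1, groove_wall_taper = 1, base_length = 2,
  groove_base_length = 2
)

#' Serialise a replication report
#'
#' Writes the rows of [replicate_study()] in a deterministic order (table,
#' height, taper, quantity) as CSV (full precision, round-trippable), JSON,
#' or a markdown document with one pipe table per reference table, values
#' formatted at the precision the source prints.
#'
#' @param rows A `replication_tbl` (or compatible tibble).
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @param path Optional file path; when given, the document is also written
#'   there.
#' @return The document as a single character string, invisibly when `path`
#'   is given.
#' @examples
#' cat(emit_report(replicate_study(), format = "markdown"))
#' @export
emit_report <- function(rows, format = c("csv", "json", "markdown"), path = NULL) {
  format <- match.arg(format)
  cols <- c(
    "table_id", "height", "taper", "quantity",
    "model_value", "paper_value", "abs_deviation", "tolerance", "within_tol"
  )
  missing <- setdiff(cols, names(rows))
  if (length(missing) > 0) {
    abort(paste0("`rows` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  rows <- rows |>
    tibble::as_tibble() |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::arrange(.data$table_id, .data$height, .data$taper, .data$quantity)

  doc <- switch(format,
    csv = readr::format_csv(rows, na = "NA"),
    json = as.character(
      jsonlite::toJSON(rows, dataframe = "rows", digits = NA, na = "null", pretty = TRUE)
    ),
    markdown = report_markdown(rows)
  )
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}

report_markdown <- function(rows) {
  fmt <- function(x, q) {
    d <- replication_digits[q]
    d[is.na(d)] <- 3
    ifelse(is.na(x), "", sprintf(paste0("%.", d, "f"), x))
  }
  one_table <- function(tab) {
    sub <- rows[rows$table_id == tab, ]
    header <- paste0(
      "| height | taper | quantity | model | reference | deviation | within tol |\n",
      "|---|---|---|---|---|---|---|\n"
    )
    body <- ""
    if (nrow(sub) > 0) {
      body <- paste0(
        sprintf(
          "| %g | %s | %s | %s | %s | %s | %s |\n",
          sub$height,
          ifelse(is.na(sub$taper), "", sprintf("%g", sub$taper)),
          sub$quantity,
          fmt(sub$model_value, sub$quantity),
          fmt(sub$paper_value, sub$quantity),
          ifelse(is.na(sub$abs_deviation), "",
            sprintf("%.3f", sub$abs_deviation)
          ),
          ifelse(is.na(sub$within_tol), "-", ifelse(sub$within_tol, "yes", "NO"))
        ),
        collapse = ""
      )
    }
    paste0("## ", tab, "\n\n", header, body, "\n")
  }
  paste0(
    "# Replication report\n\n",
    paste(vapply(c("T1", "T2", "T3"), one_table, character(1)), collapse = "")
  )
}
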