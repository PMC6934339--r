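#' Tidy a replication report
#'
#' @param x A `replication_tbl` from [replicate_study()].
#' @param ... Unused.
#' @return The report rows as a plain tibble.
#' @method tidy replication_tbl
#' @export
tidy.replication_tbl <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "replication_tbl")
  tibble::as_tibble(out)
}

#' One-row summary of a replication report
#'
#' @param x A `replication_tbl` from [replicate_study()].
#' @param ... Unused.
#' @return A one-row tibble: number of rows, number of tolerance-checked
#'   (formula-anchored) rows, how many of those pass, the largest angle/length
#'   deviation among checked rows, and the largest area deviation among
#'   report-only rows.
#' @method glance replication_tbl
#' @export
glance.replication_tbl <- function(x, ...) {
  checked <- !is.na(x$within_tol)
  tibble::tibble(
    n_rows = nrow(x),
    n_checked = sum(checked),
    n_within_tol = sum(x$within_tol[checked]),
    max_checked_deviation = if (any(checked)) max(x$abs_deviation[checked]) else NA_real_,
    max_area_deviation = if (any(!checked)) max(x$abs_deviation[!checked]) else NA_real_
  )
}
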