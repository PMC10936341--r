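#' Tidy a facility assessment
#'
#' One row per scored scope (every subcategory, category, and the total)
#' with the full score breakdown.
#'
#' @param x A `pwat_assessment`.
#' @param ... Unused.
#' @return Tibble: `facility_id`, `period`, `scope_kind`, `scope_name`,
#'   `category`, `earned`, `possible`, `bonus`, `penalty`, `percentage`.
#' @method tidy pwat_assessment
#' @export
tidy.pwat_assessment <- function(x, ...) {
  x$scores |>
    dplyr::mutate(facility_id = x$facility_id, period = x$period,
                  .before = 1)
}

#' One-row summary of a facility assessment
#'
#' @param x A `pwat_assessment`.
#' @param ... Unused.
#' @return One-row tibble: identifiers, overall percentage, relative
#'   category total, penalty applied, and unit counts.
#' @method glance pwat_assessment
#' @export
glance.pwat_assessment <- function(x, ...) {
  tibble::tibble(facility_id = x$facility_id, period = x$period,
                 overall_percentage = x$overall_percentage,
                 relative_total = x$relative_total,
                 penalty = x$penalty,
                 room_count = x$room_count,
                 interview_count = x$interview_count)
}

#' Tidy an annual benchmark
#'
#' @param x A `pwat_benchmark`.
#' @param ... Unused.
#' @return Tibble in tidy results form: `facility_id`, `year`,
#'   `scope_kind`, `scope_name`, `metric`, `value`.
#' @method tidy pwat_benchmark
#' @export
tidy.pwat_benchmark <- function(x, ...) {
  benchmark_tidy(x)
}

#' One-row summary of an annual benchmark
#'
#' @param x A `pwat_benchmark`.
#' @param ... Unused.
#' @return One-row tibble with the year-averaged headline metrics.
#' @method glance pwat_benchmark
#' @export
glance.pwat_benchmark <- function(x, ...) {
  tibble::tibble(facility_id = x$facility_id, year = x$year,
                 n_assessments = length(x$contributing_periods),
                 overall_percentage = x$overall_percentage,
                 relative_total = x$relative_total)
}

#' Tidy a cross-site summary
#'
#' @param x A `pwat_cross_site`.
#' @param ... Unused.
#' @return Tibble: per scope, the cross-facility mean, min, max and the
#'   number of sites with a defined score.
#' @method tidy pwat_cross_site
#' @export
tidy.pwat_cross_site <- function(x, ...) {
  x$summary
}
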