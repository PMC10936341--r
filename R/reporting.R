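#' Descriptors where a facility fell short of the maximum
#'
#' Gap identification drives the facility's improvement goals: every
#' standard descriptor whose aggregated effective answer is below the
#' threshold (2, the maximum, by default — matching the reading of
#' "consistently scored below 2") is listed, heaviest-impact first
#' (ascending effective answer times weight, so a 0 on a weight-5 item
#' outranks a 1 on a weight-1 item). Where several units answered the
#' descriptor, the fraction of units below the threshold is reported as the
#' gap's prevalence.
#'
#' @param assessment A `pwat_assessment` from [assess_facility()].
#' @param instrument The [pwat_instrument()] used for the assessment.
#' @param threshold Gap threshold on the 0-2 answer scale (default 2).
#' @return Tibble: `descriptor_id`, `label`, `category`, `subcategory`,
#'   `value` (effective answer), `weight`, `impact` (value x weight),
#'   `threshold`, `prevalence` (fraction of answering units below
#'   threshold).
#' @export
identify_gaps <- function(assessment, instrument, threshold = 2) {
  instr <- tibble::as_tibble(instrument)
  prev <- assessment$unit_values |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$descriptor_id) |>
    dplyr::summarise(prevalence = mean(.data$value < threshold),
                     .groups = "drop")
  assessment$effective_answers |>
    dplyr::inner_join(instr |>
                        dplyr::filter(.data$modifier == "standard") |>
                        dplyr::select("id", "label", "category",
                                      "subcategory", "weight"),
                      by = c(descriptor_id = "id")) |>
    dplyr::filter(!is.na(.data$value), .data$value < threshold) |>
    dplyr::left_join(prev, by = "descriptor_id") |>
    dplyr::mutate(impact = .data$value * .data$weight,
                  threshold = threshold) |>
    dplyr::arrange(.data$impact, dplyr::desc(.data$weight),
                   .data$descriptor_id) |>
    dplyr::select("descriptor_id", "label", "category", "subcategory",
                  "value", "weight", "impact", "threshold", "prevalence")
}

#' Lowest-scoring subcategories to focus improvement goals on
#'
#' Facilities are asked to pick a handful of goals from their results; this
#' returns the `k` lowest defined subcategory percentages (ties broken in
#' favour of the subcategory with more possible points, i.e. the larger
#' share of the instrument), each with its descriptor-level gap list.
#'
#' @param assessment A `pwat_assessment`.
#' @param instrument The matching [pwat_instrument()].
#' @param k Number of subcategories to suggest (default 3).
#' @param threshold Gap threshold passed to [identify_gaps()].
#' @return Tibble: `subcategory`, `category`, `percentage`, `possible`,
#'   and a `gaps` list-column of per-subcategory gap tibbles. If fewer than
#'   `k` subcategories have a defined percentage, all are returned with a
#'   message.
#' @export
suggest_focus <- function(assessment, instrument, k = 3, threshold = 2) {
  if (k < 1) abort("k must be at least 1")
  subs <- assessment$scores |>
    dplyr::filter(.data$scope_kind == "subcategory",
                  !is.na(.data$percentage))
  if (nrow(subs) < k) {
    inform(paste0("only ", nrow(subs), " subcategories have defined scores; ",
                  "returning all of them"))
    k <- nrow(subs)
  }
  gaps <- identify_gaps(assessment, instrument, threshold = threshold)
  subs |>
    dplyr::arrange(.data$percentage, dplyr::desc(.data$possible),
                   .data$scope_name) |>
    dplyr::slice_head(n = k) |>
    dplyr::transmute(subcategory = .data$scope_name,
                     category = .data$category,
                     percentage = .data$percentage,
                     possible = .data$possible) |>
    dplyr::mutate(gaps = purrr::map(.data$subcategory, function(s) {
      gaps |> dplyr::filter(.data$subcategory == s)
    }))
}

#' Render a benchmark or cross-site summary as a report document
#'
#' Produces a deterministic document (no timestamps: identical input gives
#' byte-identical output) with the overall score, per-category and
#' per-subcategory tables at one decimal place, and — for a facility
#' benchmark with an attached assessment — the gap list and focus
#' suggestions.
#'
#' @param x A `pwat_benchmark` or `pwat_cross_site` object.
#' @param format `"markdown"` (a single string), `"csv"` (tidy
#'   scope/metric/value text), or `"json"`.
#' @param path Optional path to also write the document to.
#' @param assessment Optional `pwat_assessment` (typically the latest
#'   contributing period) used to append gap and focus sections to a
#'   facility report.
#' @param instrument Instrument for the gap sections (required with
#'   `assessment`).
#' @param k Focus suggestions to include (default 3).
#' @return The document as a single character string, invisibly when
#'   written to `path`.
#' @export
render_report <- function(x, format = c("markdown", "csv", "json"),
                          path = NULL, assessment = NULL,
                          instrument = NULL, k = 3) {
  format <- match.arg(format)
  doc <- if (inherits(x, "pwat_benchmark")) {
    render_benchmark(x, format, assessment, instrument, k)
  } else if (inherits(x, "pwat_cross_site")) {
    render_cross_site(x, format)
  } else {
    abort("render_report expects a pwat_benchmark or pwat_cross_site object")
  }
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}

fmt1 <- function(x) {
  ifelse(is.na(x), "-", formatC(round(x, 1), format = "f", digits = 1))
}

md_table <- function(df) {
  cells <- purrr::map(df, as.character)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- purrr::pmap_chr(cells, function(...) {
    paste0("| ", paste(c(...), collapse = " | "), " |")
  })
  paste(c(header, sep, rows), collapse = "\n")
}

benchmark_tidy <- function(x) {
  dplyr::bind_rows(
    x$scores |>
      dplyr::transmute(facility_id = x$facility_id, year = x$year,
                       scope_kind = .data$scope_kind,
                       scope_name = .data$scope_name,
                       metric = "percentage", value = .data$percentage),
    x$relative |>
      dplyr::transmute(facility_id = x$facility_id, year = x$year,
                       scope_kind = "category", scope_name = .data$category,
                       metric = "relative_score",
                       value = .data$relative_score),
    tibble::tibble(facility_id = x$facility_id, year = x$year,
                   scope_kind = "total", scope_name = "total",
                   metric = c("relative_total", "overall_percentage"),
                   value = c(x$relative_total, x$overall_percentage)))
}

render_benchmark <- function(x, format, assessment, instrument, k) {
  tidy_df <- benchmark_tidy(x)
  if (format == "csv") {
    return(readr::format_csv(tidy_df |>
                               dplyr::mutate(value = round(.data$value, 4))))
  }
  if (format == "json") {
    return(as.character(jsonlite::toJSON(tidy_df, dataframe = "rows",
                                         auto_unbox = TRUE, digits = 4,
                                         pretty = TRUE, na = "null")))
  }
  cats <- x$scores |> dplyr::filter(.data$scope_kind == "category")
  cat_tab <- cats |>
    dplyr::left_join(x$relative, by = c(scope_name = "category")) |>
    dplyr::transmute(category = .data$scope_name,
                     `score (%)` = fmt1(.data$percentage),
                     `relative score` = fmt1(.data$relative_score))
  sub_tab <- x$scores |>
    dplyr::filter(.data$scope_kind == "subcategory") |>
    dplyr::transmute(category = .data$category,
                     subcategory = .data$scope_name,
                     `score (%)` = fmt1(.data$percentage))
  parts <- c(
    paste0("# Welfare assessment benchmark: facility ", x$facility_id,
           " (", x$year, ")"),
    "",
    paste0("Contributing assessments: ",
           paste(x$contributing_periods, collapse = ", ")),
    "",
    paste0("**Overall score: ", fmt1(x$overall_percentage), "%**  "),
    paste0("**Relative category total: ", fmt1(x$relative_total),
           " / 600**"),
    "",
    "## Scores by category", "", md_table(cat_tab), "",
    "## Scores by subcategory", "", md_table(sub_tab), "")
  if (!is.null(assessment)) {
    if (is.null(instrument)) {
      abort("an instrument is required to render gap sections")
    }
    gaps <- identify_gaps(assessment, instrument)
    gap_tab <- gaps |>
      dplyr::slice_head(n = 15) |>
      dplyr::transmute(descriptor = .data$label,
                       subcategory = .data$subcategory,
                       score = fmt1(.data$value),
                       weight = .data$weight,
                       `rooms/units below` = fmt1(100 * .data$prevalence))
    focus <- suggest_focus(assessment, instrument, k = k)
    focus_tab <- focus |>
      dplyr::transmute(subcategory = .data$subcategory,
                       category = .data$category,
                       `score (%)` = fmt1(.data$percentage))
    parts <- c(parts,
               paste0("## Largest descriptor-level gaps (period ",
                      assessment$period, ")"), "",
               if (nrow(gap_tab) > 0) md_table(gap_tab) else
                 "No descriptor scored below the threshold.", "",
               "## Suggested focus subcategories", "",
               md_table(focus_tab), "")
  }
  paste(parts, collapse = "\n")
}

render_cross_site <- function(x, format) {
  wide <- x$by_facility |>
    dplyr::select("scope_kind", "scope_name", "category", "facility",
                  "percentage") |>
    tidyr::pivot_wider(names_from = "facility",
                       values_from = "percentage") |>
    dplyr::left_join(x$summary |>
                       dplyr::select("scope_kind", "scope_name", "mean"),
                     by = c("scope_kind", "scope_name"))
  if (format == "csv") {
    return(readr::format_csv(wide |>
                               dplyr::mutate(dplyr::across(
                                 dplyr::where(is.numeric),
                                 ~ round(.x, 4)))))
  }
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      list(summary = x$summary, facilities = x$facilities),
      dataframe = "rows", auto_unbox = TRUE, digits = 4, pretty = TRUE,
      na = "null")))
  }
  tab <- wide |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), fmt1)) |>
    dplyr::rename(scope = "scope_name") |>
    dplyr::select(-"scope_kind", -"category")
  rank_tab <- x$facilities |>
    dplyr::arrange(.data$rank) |>
    dplyr::transmute(facility = .data$facility,
                     `overall (%)` = fmt1(.data$overall_percentage),
                     rank = .data$rank)
  paste(c(
    paste0("# Cross-site welfare assessment summary (",
           nrow(x$facilities), " facilities)"),
    "",
    "## Scores by facility", "", md_table(tab), "",
    "## Facility ranking (overall score)", "", md_table(rank_tab), ""),
    collapse = "\n")
}
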