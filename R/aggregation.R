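#' Aggregate the units of one form type into effective answers
#'
#' Several room forms (or interviews) contribute to one facility-period
#' assessment. Aggregation happens at the descriptor level: the effective
#' answer is the mean of the non-NA unit answers (a fraction such as 5/3
#' when three rooms answer 2, 2, 1), and a descriptor every unit marked NA
#' stays excluded. A single site form passes through unchanged. The penalty
#' descriptor is aggregated as the mean of the per-room capped reductions,
#' not of the raw counts (the cap applies within a room); its capped value
#' is returned in the `penalty` attribute and its row is excluded from the
#' effective answers.
#'
#' @param forms Forms tibble for exactly one facility, period and form type.
#' @param instrument A [pwat_instrument()].
#' @return Tibble with columns `descriptor_id`, `value` (numeric effective
#'   answer, NA = excluded), `n_units` (units answering). Attribute
#'   `penalty` holds the mean per-room capped reduction (0 when no room
#'   reports a count) and attribute `n_units` the number of units seen.
#' @export
aggregate_units <- function(forms, instrument) {
  x <- tibble::as_tibble(forms)
  if (nrow(x) == 0) abort("no forms to aggregate")
  if (dplyr::n_distinct(x$form_type) > 1) {
    abort("aggregate_units expects a single form type; got mixed types")
  }
  if (dplyr::n_distinct(x$facility_id) > 1 ||
      dplyr::n_distinct(x$period) > 1) {
    abort("aggregate_units expects one facility-period")
  }
  instr <- tibble::as_tibble(instrument)
  cfg <- attr(instrument, "penalty_config") %||% list()
  rate <- cfg$points_per_singly_housed_animal %||% 1
  cap <- cfg$cap_points %||% 20

  pen_ids <- instr$id[instr$modifier == "penalty"]
  pen_rows <- x |> dplyr::filter(.data$descriptor_id %in% pen_ids,
                                 !is.na(.data$penalty_count))
  penalty <- if (nrow(pen_rows) > 0) {
    mean(penalty_points(pen_rows$penalty_count, rate = rate, cap = cap))
  } else {
    0
  }

  eff <- x |>
    dplyr::filter(!.data$descriptor_id %in% pen_ids) |>
    dplyr::group_by(.data$descriptor_id) |>
    dplyr::summarise(
      value = if (all(is.na(.data$value))) NA_real_ else
        mean(.data$value, na.rm = TRUE),
      n_units = sum(!is.na(.data$value)),
      .groups = "drop")
  attr(eff, "penalty") <- penalty
  attr(eff, "n_units") <- dplyr::n_distinct(x$unit_id)
  eff
}

#' Score a facility-period assessment from its forms
#'
#' Combines all forms submitted by a facility for one assessment period:
#' room forms and interviews are aggregated into per-descriptor effective
#' answers ([aggregate_units()]), the site form passes through, and every
#' subcategory, category, and the total are scored ([score_scope()]).
#' Descriptors of an absent form type — or left unanswered on present forms
#' — are excluded (treated as non-applicable) with a warning, never scored
#' as 0. The single-housing penalty (mean of per-room capped reductions) is
#' subtracted at the scopes named in the instrument's penalty configuration
#' (the facility total by default). Relative category scores are the
#' category percentages on a 0-100 scale, so their sum over the six
#' categories reaches 600 for a maximal facility before bonus points.
#'
#' @param forms Forms tibble for one facility and period (all form types).
#' @param instrument A [pwat_instrument()].
#' @return A `pwat_assessment` object; see [tidy()]/[glance()] methods,
#'   [identify_gaps()], [suggest_focus()] and [autoplot()].
#' @export
assess_facility <- function(forms, instrument) {
  x <- tibble::as_tibble(forms)
  if (nrow(x) == 0) abort("no forms supplied for assessment")
  if (dplyr::n_distinct(x$facility_id) > 1 ||
      dplyr::n_distinct(x$period) > 1) {
    abort("assess_facility expects forms for a single facility-period")
  }
  instr <- tibble::as_tibble(instrument)
  stray <- setdiff(x$descriptor_id, instr$id)
  if (length(stray) > 0) {
    warn(paste0("ignoring answers for descriptor(s) not in the instrument: ",
                paste(head(stray, 5), collapse = ", "),
                if (length(stray) > 5) ", ..." else ""))
    x <- x |> dplyr::filter(.data$descriptor_id %in% instr$id)
  }

  present <- intersect(pwat_form_types, unique(x$form_type))
  absent <- setdiff(unique(instr$form), present)
  if (length(absent) > 0) {
    warn(paste0("no ", paste(absent, collapse = "/"),
                " form(s) submitted; their descriptors are excluded from scoring"))
  }

  pieces <- purrr::map(present, function(ft) {
    aggregate_units(x |> dplyr::filter(.data$form_type == ft), instrument)
  })
  effective <- dplyr::bind_rows(pieces)
  penalty <- sum(purrr::map_dbl(pieces, ~ attr(.x, "penalty") %||% 0))

  # descriptors never answered anywhere are excluded, with a warning for
  # those whose form type was actually submitted
  unanswered <- instr |>
    dplyr::filter(!.data$id %in% effective$descriptor_id,
                  .data$modifier != "penalty")
  if (any(unanswered$form %in% present)) {
    n_un <- sum(unanswered$form %in% present)
    warn(paste0(n_un, " descriptor(s) of submitted forms were unanswered; ",
                "scored as non-applicable, not 0"))
  }

  scores <- score_all_scopes(effective, instrument, penalty = penalty)

  relative <- scores |>
    dplyr::filter(.data$scope_kind == "category") |>
    dplyr::transmute(category = .data$scope_name,
                     relative_score = .data$percentage)
  relative_total <- if (nrow(relative) > 0) sum(relative$relative_score)
                    else NA_real_
  overall <- scores |>
    dplyr::filter(.data$scope_kind == "total") |>
    dplyr::pull("percentage")

  unit_values <- x |>
    dplyr::filter(!.data$descriptor_id %in%
                    instr$id[instr$modifier == "penalty"]) |>
    dplyr::select("form_type", "unit_id", "descriptor_id", "value")

  structure(list(
    facility_id = x$facility_id[1],
    period = x$period[1],
    scores = scores,
    relative = relative,
    relative_total = relative_total,
    overall_percentage = overall,
    effective_answers = effective,
    unit_values = unit_values,
    penalty = penalty,
    room_count = dplyr::n_distinct(
      x$unit_id[x$form_type == "room"]),
    interview_count = dplyr::n_distinct(
      x$unit_id[x$form_type == "interview"]),
    instrument_version = attr(instrument, "version")
  ), class = "pwat_assessment")
}

#' @export
print.pwat_assessment <- function(x, ...) {
  cat(sprintf("<pwat_assessment %s %s>\n", x$facility_id, x$period))
  cat(sprintf("  overall: %.1f%%  relative total: %.1f / 600  (%d rooms, %d interviews)\n",
              x$overall_percentage, x$relative_total,
              x$room_count, x$interview_count))
  cats <- x$scores |> dplyr::filter(.data$scope_kind == "category")
  for (i in seq_len(nrow(cats))) {
    cat(sprintf("  %-16s %6.1f%%\n", cats$scope_name[i], cats$percentage[i]))
  }
  invisible(x)
}

#' Average a facility's assessments into its annual benchmark
#'
#' Benchmarking averages the assessments a facility completed within a year
#' element-wise: each subcategory, category and total percentage, the
#' relative category scores and their sum, and the overall percentage are
#' the means over the contributing periods (an undefined percentage in one
#' period is dropped from that metric's mean). A facility that completed a
#' single assessment passes through unchanged as its benchmark.
#'
#' @param assessments A list of `pwat_assessment` objects (or a single one)
#'   for one facility.
#' @param year Year label; defaults to the leading `[0-9]{4}` of the first
#'   period, else `"all"`.
#' @return A `pwat_benchmark` object.
#' @export
benchmark_year <- function(assessments, year = NULL) {
  if (inherits(assessments, "pwat_assessment")) {
    assessments <- list(assessments)
  }
  if (length(assessments) == 0) abort("no assessments to benchmark")
  fids <- unique(purrr::map_chr(assessments, "facility_id"))
  if (length(fids) > 1) {
    abort("benchmark_year expects assessments from a single facility")
  }
  periods <- purrr::map_chr(assessments, "period")
  if (is.null(year)) {
    m <- regmatches(periods[1], regexpr("^[0-9]{4}", periods[1]))
    year <- if (length(m) > 0) m else "all"
  }

  mean_defined <- function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  scores <- purrr::map(assessments, "scores") |>
    dplyr::bind_rows() |>
    dplyr::group_by(.data$scope_kind, .data$scope_name, .data$category) |>
    dplyr::summarise(percentage = mean_defined(.data$percentage),
                     .groups = "drop")
  relative <- purrr::map(assessments, "relative") |>
    dplyr::bind_rows() |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(relative_score = mean_defined(.data$relative_score),
                     .groups = "drop")

  structure(list(
    facility_id = fids,
    year = year,
    contributing_periods = periods,
    scores = scores,
    relative = relative,
    relative_total = mean_defined(
      purrr::map_dbl(assessments, "relative_total")),
    overall_percentage = mean_defined(
      purrr::map_dbl(assessments, "overall_percentage")),
    room_count = mean(purrr::map_int(assessments, "room_count")),
    interview_count = mean(purrr::map_int(assessments, "interview_count"))
  ), class = "pwat_benchmark")
}

#' @export
print.pwat_benchmark <- function(x, ...) {
  cat(sprintf("<pwat_benchmark %s %s: %d assessment(s) [%s]>\n",
              x$facility_id, x$year, length(x$contributing_periods),
              paste(x$contributing_periods, collapse = ", ")))
  cat(sprintf("  overall: %.1f%%  relative total: %.1f / 600\n",
              x$overall_percentage, x$relative_total))
  invisible(x)
}

#' Summarise benchmarks across sites
#'
#' Cross-site summary in the style of the multi-facility results table:
#' for every subcategory, category and the total, the unweighted mean,
#' minimum and maximum across facilities, together with a per-facility
#' overall ranking (facilities are labelled A, B, C, ... in input order for
#' anonymised reporting; disable with `anonymise = FALSE`).
#'
#' @param benchmarks List of `pwat_benchmark` objects, one per facility.
#' @param anonymise Label facilities A, B, C, ... in input order (default
#'   TRUE).
#' @return A `pwat_cross_site` object: list with `summary` (scope-wise
#'   mean/min/max tibble), `facilities` (per-facility overall scores and
#'   ranks), and `by_facility` (scope-by-facility percentage matrix, tidy).
#' @export
cross_site_summary <- function(benchmarks, anonymise = TRUE) {
  if (inherits(benchmarks, "pwat_benchmark")) benchmarks <- list(benchmarks)
  if (length(benchmarks) == 0) abort("no benchmarks to summarise")
  ids <- purrr::map_chr(benchmarks, "facility_id")
  labels <- if (anonymise) make_facility_labels(length(ids)) else ids

  by_fac <- purrr::map2(benchmarks, labels, function(b, lab) {
    b$scores |> dplyr::mutate(facility = lab)
  }) |> dplyr::bind_rows()

  summary <- by_fac |>
    dplyr::group_by(.data$scope_kind, .data$scope_name, .data$category) |>
    dplyr::summarise(
      mean = mean(.data$percentage, na.rm = TRUE),
      min = suppressWarnings(min(.data$percentage, na.rm = TRUE)),
      max = suppressWarnings(max(.data$percentage, na.rm = TRUE)),
      n_sites = sum(!is.na(.data$percentage)),
      .groups = "drop") |>
    dplyr::mutate(dplyr::across(c("mean", "min", "max"),
                                ~ ifelse(is.finite(.x), .x, NA_real_)))

  facilities <- tibble::tibble(
    facility = labels,
    facility_id = ids,
    overall_percentage = purrr::map_dbl(benchmarks, "overall_percentage"),
    relative_total = purrr::map_dbl(benchmarks, "relative_total")
  ) |>
    dplyr::mutate(rank = rank(-.data$overall_percentage,
                              ties.method = "min"))

  structure(list(summary = summary, facilities = facilities,
                 by_facility = by_fac),
            class = "pwat_cross_site")
}

#' @export
print.pwat_cross_site <- function(x, ...) {
  cat(sprintf("<pwat_cross_site: %d facilities>\n", nrow(x$facilities)))
  cats <- x$summary |> dplyr::filter(.data$scope_kind == "category")
  for (i in seq_len(nrow(cats))) {
    cat(sprintf("  %-16s mean %5.1f%%  range %.1f-%.1f%%\n",
                cats$scope_name[i], cats$mean[i], cats$min[i], cats$max[i]))
  }
  invisible(x)
}

make_facility_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else
    paste0(LETTERS[((seq_len(n) - 1) %/% 26)],
           LETTERS[((seq_len(n) - 1) %% 26) + 1])
}

#' Fraction of assessed rooms satisfying a condition on one descriptor
#'
#' Room-level findings are reported as the share of assessed rooms showing
#' them (for instance the fraction of rooms where abnormal behaviours were
#' recorded). Rooms answering NA on the descriptor are excluded from the
#' denominator; if no room answers, the prevalence is undefined (NA).
#'
#' @param forms Forms tibble (room records are selected internally).
#' @param descriptor_id The descriptor to examine.
#' @param predicate Function (or lambda) of the answer value returning
#'   logical; default `~ .x < 2` (room did not fully meet the descriptor).
#' @return Fraction in `[0, 1]`, or NA when no room answered.
#' @export
room_prevalence <- function(forms, descriptor_id, predicate = ~ .x < 2) {
  predicate <- rlang::as_function(predicate)
  v <- forms |>
    dplyr::filter(.data$form_type == "room",
                  .data$descriptor_id == !!descriptor_id,
                  !is.na(.data$value)) |>
    dplyr::pull("value")
  if (length(v) == 0) return(NA_real_)
  mean(predicate(v))
}
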