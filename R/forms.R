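#' Read completed assessment forms
#'
#' Forms are long-format records: one row per answered descriptor, keyed by
#' facility, assessment period, form type and unit (room identifier,
#' interview identifier, or `"site"`). The CSV dialect has the fixed header
#' `facility_id,period,form_type,unit_id,descriptor_id,value,penalty_count`;
#' `value` accepts 0, 1, 2 or NA, and `penalty_count` is the number of
#' singly housed animals, filled only on the penalty descriptor's row. The
#' JSON mirror is an array of form objects each holding a nested `answers`
#' array. Input order is preserved within each form.
#'
#' @param path Path to a forms file.
#' @param format `"csv"`, `"json"`, or `"auto"` (default; by extension).
#' @return Tibble with the seven columns above (`value` and `penalty_count`
#'   integer, NA allowed).
#' @seealso [validate_forms()], [write_forms()]
#' @export
read_forms <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) abort(paste0("no such forms file: ", path))
  if (format == "csv") {
    forms <- tryCatch(
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(
                        .default = readr::col_character())),
      error = function(e) abort(paste0("cannot parse forms CSV '", path,
                                       "': ", conditionMessage(e))))
  } else {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) abort(paste0(
                      "cannot parse forms JSON '", path, "': ",
                      conditionMessage(e))))
    forms <- tibble::as_tibble(obj) |>
      tidyr::unnest("answers")
  }
  required <- c("facility_id", "period", "form_type", "unit_id",
                "descriptor_id", "value")
  missing <- setdiff(required, names(forms))
  if (length(missing) > 0) {
    abort(paste0("forms input lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"penalty_count" %in% names(forms)) forms$penalty_count <- NA_integer_
  forms |>
    dplyr::mutate(value = as.integer(.data$value),
                  penalty_count = as.integer(.data$penalty_count)) |>
    dplyr::select(dplyr::all_of(c(required, "penalty_count")))
}

#' Write assessment forms
#'
#' @param forms Forms tibble as returned by [read_forms()] or
#'   [simulate_campaign()].
#' @param path Output path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension). JSON nests
#'   answers under one object per form.
#' @return `path`, invisibly.
#' @export
write_forms <- function(forms, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    readr::write_csv(forms, path, progress = FALSE, na = "NA")
  } else {
    nested <- forms |>
      tidyr::nest(answers = c("descriptor_id", "value", "penalty_count"))
    jsonlite::write_json(nested, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Validate completed forms against an instrument
#'
#' Pure check returning a tibble of violations; an empty report means the
#' forms score without error. Flags unknown descriptor ids, answers filed on
#' the wrong form type, out-of-domain values (anything outside 0/1/2, or a 1
#' on a yes/no descriptor), NA answers on descriptors that do not allow NA,
#' penalty counts on non-penalty descriptors or negative counts, duplicated
#' answers within a form, and — at severity `"warning"` — descriptors of a
#' present form left unanswered (scored as NA downstream, never as 0).
#'
#' @param forms Forms tibble (one or more records; see [read_forms()]).
#' @param instrument A [pwat_instrument()].
#' @return Tibble with columns `severity` (`"error"`/`"warning"`), `rule`,
#'   `facility_id`, `period`, `unit_id`, `descriptor_id`, `message`.
#' @export
validate_forms <- function(forms, instrument) {
  x <- tibble::as_tibble(forms)
  instr <- tibble::as_tibble(instrument)
  out <- list()
  add <- function(df, severity, rule, message) {
    if (nrow(df) == 0) return(invisible(NULL))
    out[[length(out) + 1]] <<- tibble::tibble(
      severity = severity, rule = rule,
      facility_id = df$facility_id, period = df$period,
      unit_id = df$unit_id, descriptor_id = df$descriptor_id,
      message = message)
  }

  bad_ft <- x |> dplyr::filter(!.data$form_type %in% pwat_form_types)
  add(bad_ft, "error", "unknown form type",
      paste0("unknown form_type '", bad_ft$form_type, "'"))

  unknown <- x |> dplyr::filter(!.data$descriptor_id %in% instr$id)
  add(unknown, "error", "unknown descriptor",
      paste0("descriptor '", unknown$descriptor_id,
             "' is not in the instrument"))

  known <- x |>
    dplyr::inner_join(instr |>
                        dplyr::select("id", "form", "response_kind",
                                      "modifier", "na_allowed"),
                      by = c(descriptor_id = "id"))

  wrong_form <- known |> dplyr::filter(.data$form_type != .data$form)
  add(wrong_form, "error", "form mismatch",
      paste0("descriptor '", wrong_form$descriptor_id, "' belongs to the ",
             wrong_form$form, " form, answered on a ", wrong_form$form_type,
             " form"))

  scored <- known |> dplyr::filter(.data$modifier != "penalty")
  bad_val <- scored |>
    dplyr::filter(!is.na(.data$value) & !.data$value %in% c(0L, 1L, 2L))
  add(bad_val, "error", "value out of range",
      paste0("value ", bad_val$value, " on descriptor '",
             bad_val$descriptor_id, "' is outside the 0/1/2 scale"))

  bad_bin <- scored |>
    dplyr::filter(.data$response_kind == "binary", !is.na(.data$value),
                  .data$value == 1L)
  add(bad_bin, "error", "binary value",
      paste0("descriptor '", bad_bin$descriptor_id,
             "' is yes(2)/no(0); value 1 is not admissible"))

  bad_na <- scored |>
    dplyr::filter(is.na(.data$value), !.data$na_allowed)
  add(bad_na, "error", "NA not allowed",
      paste0("descriptor '", bad_na$descriptor_id,
             "' does not allow a non-applicable answer"))

  stray_count <- known |>
    dplyr::filter(.data$modifier != "penalty", !is.na(.data$penalty_count))
  add(stray_count, "error", "stray penalty count",
      paste0("penalty_count set on non-penalty descriptor '",
             stray_count$descriptor_id, "'"))

  neg <- known |>
    dplyr::filter(.data$modifier == "penalty", !is.na(.data$penalty_count),
                  .data$penalty_count < 0)
  add(neg, "error", "negative penalty count",
      paste0("negative singly-housed count ", neg$penalty_count))

  dupe <- x |>
    dplyr::group_by(.data$facility_id, .data$period, .data$form_type,
                    .data$unit_id, .data$descriptor_id) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  add(dupe, "error", "duplicate answer",
      paste0("descriptor '", dupe$descriptor_id,
             "' answered more than once on unit '", dupe$unit_id, "'"))

  # descriptors of a present form type with no row at all on a unit
  units <- x |>
    dplyr::distinct(.data$facility_id, .data$period, .data$form_type,
                    .data$unit_id)
  expected <- units |>
    dplyr::inner_join(instr |> dplyr::select("id", form_type = "form"),
                      by = "form_type", relationship = "many-to-many") |>
    dplyr::rename(descriptor_id = "id")
  unanswered <- expected |>
    dplyr::anti_join(x, by = c("facility_id", "period", "form_type",
                               "unit_id", "descriptor_id"))
  add(unanswered, "warning", "unanswered",
      paste0("descriptor '", unanswered$descriptor_id,
             "' unanswered on unit '", unanswered$unit_id,
             "'; it will be scored as non-applicable, not 0"))

  if (length(out) == 0) {
    tibble::tibble(severity = character(), rule = character(),
                   facility_id = character(), period = character(),
                   unit_id = character(), descriptor_id = character(),
                   message = character())
  } else {
    dplyr::bind_rows(out)
  }
}
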